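# Independent oracles used by the property tests. These deliberately avoid
# the package's own matching/selection code paths.

# independent tokenizer: maximal alnum runs, lower-cased, 1-based spans
bf_tokenize <- function(text) {
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[[1]] == -1) {
    return(data.frame(token = character(0), start = integer(0), end = integer(0)))
  }
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  data.frame(token = tolower(substring(text, start, end)),
             start = start, end = end, stringsAsFactors = FALSE)
}

bf_norm <- function(s) paste(bf_tokenize(s)$token, collapse = " ")

# brute-force annotator: scan every O(n^2) token window against every
# class label; PREF beats SYN for the same (class, span)
bf_annotate <- function(text, ontologies) {
  toks <- bf_tokenize(text)
  n <- nrow(toks)
  rows <- list()
  for (ont in ontologies) {
    cl <- ont$classes
    for (ci in seq_len(nrow(cl))) {
      pref_n <- bf_norm(cl$pref_label[[ci]])
      entries <- data.frame(term = pref_n, type = "PREF", stringsAsFactors = FALSE)
      for (s in cl$synonyms[[ci]]) {
        sn <- bf_norm(s)
        if (nzchar(sn) && sn != pref_n) {
          entries <- rbind(entries, data.frame(term = sn, type = "SYN"))
        }
      }
      entries <- entries[!duplicated(entries$term), ]
      for (ei in seq_len(nrow(entries))) {
        for (i in seq_len(n)) {
          for (j in i:n) {
            win <- paste(toks$token[i:j], collapse = " ")
            if (identical(win, entries$term[[ei]])) {
              rows[[length(rows) + 1L]] <- data.frame(
                ontology = ont$acronym, class_id = cl$id[[ci]],
                match_type = entries$type[[ei]],
                start = toks$start[[i]], end = toks$end[[j]],
                matched_text = substring(text, toks$start[[i]], toks$end[[j]]),
                annotated_words = j - i + 1L, stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(ontorec:::empty_annotations())
  }
  out <- do.call(rbind, rows)
  # PREF wins over SYN for one class at one span
  key <- paste(out$ontology, out$class_id, out$start, out$end)
  out <- out[order(key, out$match_type != "PREF"), ]
  out <- out[!duplicated(paste(out$ontology, out$class_id, out$start, out$end)), ]
  out <- out[order(out$start, out$end, out$ontology, out$class_id, out$match_type), ]
  tibble::as_tibble(out)
}

# independent greedy selection: explicit sort + conflict sweep, written
# against the documented tie-break order
bf_select_points <- function(ann, cfg = recommender_config()) {
  if (nrow(ann) == 0) return(0)
  score <- ifelse(ann$match_type == "PREF", cfg$pref_score, cfg$syn_score)
  score <- (score + ifelse(ann$annotated_words > 1, cfg$multiword_bonus, 0)) *
    ann$annotated_words
  ord <- order(-score, ann$match_type != "PREF", -(ann$end - ann$start),
               ann$start, ann$class_id, ann$ontology)
  kept <- integer(0)
  for (i in ord) {
    if (!any(ann$start[[i]] <= ann$end[kept] & ann$start[kept] <= ann$end[[i]])) {
      kept <- c(kept, i)
    }
  }
  sum(score[kept])
}

# random in-memory candidate pool for property tests: a small vocabulary,
# several ontologies whose classes name vocabulary terms (with occasional
# synonym aliases), and a document sampled from the vocabulary
random_pool <- function(seed, n_ontologies = 4, n_terms = 10, doc_len = 14) {
  withr::with_seed(seed, {
    vocab <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
               "theta", "iota", "kappa", "lambda", "sigma")[seq_len(n_terms)]
    multi <- paste(sample(vocab, 2), collapse = " ")
    vocab_all <- c(vocab, multi)
    onts <- lapply(seq_len(n_ontologies), function(i) {
      acr <- sprintf("P%02d", i)
      terms <- sample(vocab_all, sample(3:min(7, length(vocab_all)), 1))
      n <- length(terms)
      parents <- character(n)
      if (n > 1) {
        for (k in 2:n) {
          if (stats::runif(1) < 0.6) {
            parents[k] <- sprintf("%s:%03d", acr, sample(k - 1, 1))
          }
        }
      }
      syn <- vapply(seq_len(n), function(k) {
        if (stats::runif(1) < 0.3) sample(setdiff(vocab_all, terms[k]), 1) else ""
      }, character(1))
      ontology(tibble::tibble(
        id = sprintf("%s:%03d", acr, seq_len(n)),
        pref_label = terms, synonyms = syn,
        definition_count = stats::rbinom(n, 2, 0.5),
        property_count = stats::rpois(n, 4),
        parents = parents
      ), acronym = acr, declared_size = n * sample(3:40, 1))
    })
    names(onts) <- vapply(onts, `[[`, character(1), "acronym")
    doc_words <- sample(c(vocab, "filler", "words", "only"), doc_len, replace = TRUE)
    list(doc = paste(doc_words, collapse = " "), ontologies = onts)
  })
}

# random annotation table over a synthetic 40-token line (for selection
# property tests); spans are token-aligned and may overlap freely
random_annotations <- function(seed, n = 10) {
  withr::with_seed(seed, {
    starts <- sort(sample(1:35, n, replace = TRUE))
    width <- sample(1:3, n, replace = TRUE)
    tibble::tibble(
      ontology = sample(c("A", "B"), n, replace = TRUE),
      class_id = sprintf("C%03d", sample(50, n, replace = TRUE)),
      match_type = sample(c("PREF", "SYN"), n, replace = TRUE),
      start = starts * 10L,
      end = (starts + width) * 10L - 3L,
      matched_text = "x",
      annotated_words = width
    )
  })
}
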
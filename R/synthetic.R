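#' Generate a synthetic ontology repository on disk
#'
#' Builds a seeded, fully reproducible test repository: a shared term
#' vocabulary with controlled overlap between ontologies, classes with
#' random synonym/definition/property counts and parent chains bounded by
#' `depth_max`, repository metadata with random presence flags and visit
#' counts, and documents sampled from the vocabulary plus filler words.
#' The same seed always produces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed governing every random choice.
#' @param n_ontologies Number of ontologies to generate.
#' @param vocab_size Number of distinct terms in the shared vocabulary.
#' @param terms_per_ontology Classes per ontology (each names one term).
#' @param multiword_fraction Fraction of vocabulary terms composed of 2-3
#'   words (in [0,1]).
#' @param shared_fraction Fraction of each ontology's terms drawn from a
#'   common core shared by all ontologies (in [0,1]); at 1 every ontology
#'   covers the same terms, so in set mode every combination is pruned.
#' @param depth_max Maximum hierarchy depth of any generated class.
#' @param corpus_length Number of term/filler slots per generated document.
#' @param n_documents Number of free-text documents to write.
#' @param n_repositories Number of repositories in the metadata table.
#' @return Invisibly, a list with the generated file paths (`ontologies`,
#'   `metadata`, `documents`, `keywords`) and the seed.
#' @export
generate_synthetic_repository <- function(dir, seed,
                                          n_ontologies = 5,
                                          vocab_size = 120,
                                          terms_per_ontology = 30,
                                          multiword_fraction = 0.3,
                                          shared_fraction = 0.5,
                                          depth_max = 8,
                                          corpus_length = 60,
                                          n_documents = 3,
                                          n_repositories = 3) {
  for (nm in c("n_ontologies", "vocab_size", "terms_per_ontology",
               "depth_max", "corpus_length", "n_documents", "n_repositories")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1) {
      abort_config(sprintf("`%s` must be a single number >= 1", nm))
    }
  }
  for (nm in c("multiword_fraction", "shared_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort_config(sprintf("`%s` must lie in [0,1]", nm))
    }
  }
  if (terms_per_ontology > vocab_size) {
    abort_config("`terms_per_ontology` cannot exceed `vocab_size`")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) abort_config("`seed` must be an integer")

  withr::with_seed(seed, {
    out <- build_synthetic_repository(
      n_ontologies, vocab_size, terms_per_ontology, multiword_fraction,
      shared_fraction, depth_max, corpus_length, n_documents, n_repositories)
  })

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(ontologies = character(0), metadata = NULL,
                documents = character(0), keywords = NULL, seed = seed)
  for (ont in out$ontologies) {
    p <- file.path(dir, paste0(ont$acronym, ".dict.txt"))
    write_dictionary(ont, p)
    paths$ontologies <- c(paths$ontologies, p)
  }
  paths$metadata <- file.path(dir, "metadata.tsv")
  write_repository_metadata(out$metadata, paths$metadata)
  for (i in seq_along(out$documents)) {
    p <- file.path(dir, sprintf("doc_%d.txt", i))
    con <- file(p, open = "wb")
    writeLines(out$documents[[i]], con, sep = "\n", useBytes = TRUE)
    close(con)
    paths$documents <- c(paths$documents, p)
  }
  paths$keywords <- file.path(dir, "keywords.txt")
  con <- file(paths$keywords, open = "wb")
  writeLines(out$keywords, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(paths)
}

# pronounceable pseudo-words, unique, in a deterministic shuffled order
make_word_pool <- function(n) {
  syll <- c("ba", "ce", "di", "fo", "gu", "ha", "ki", "lo", "mu", "ne",
            "po", "ra", "su", "ti", "vo", "wa", "ze", "bri", "clo", "sta")
  pairs <- expand.grid(a = syll, b = syll, stringsAsFactors = FALSE)
  two <- paste0(pairs$a, pairs$b)
  triples <- expand.grid(a = syll, b = syll, c = syll[1:5],
                         stringsAsFactors = FALSE)
  three <- paste0(triples$a, triples$b, triples$c)
  pool <- unique(c(two, three))
  if (n > length(pool)) abort_config("requested more words than the pool provides")
  sample(pool, n)
}

build_synthetic_repository <- function(n_ontologies, vocab_size,
                                       terms_per_ontology, multiword_fraction,
                                       shared_fraction, depth_max,
                                       corpus_length, n_documents,
                                       n_repositories) {
  n_multi <- round(vocab_size * multiword_fraction)
  n_single <- vocab_size - n_multi
  # words: single-word terms, components for multi-word terms, synonyms, filler
  n_syn_pool <- n_ontologies * terms_per_ontology * 3 + 10
  pool <- make_word_pool(n_single + 60 + n_syn_pool + 80)
  single_terms <- pool[seq_len(n_single)]
  components <- pool[seq_len(n_single + 60)] # includes single terms: nesting
  syn_pool <- pool[(n_single + 61):(n_single + 60 + n_syn_pool)]
  filler <- pool[(n_single + 60 + n_syn_pool + 1):length(pool)]
  multi_terms <- if (n_multi > 0) {
    vapply(seq_len(n_multi), function(i) {
      k <- sample(2:3, 1)
      paste(sample(components, k), collapse = " ")
    }, character(1))
  } else character(0)
  vocab <- c(single_terms, multi_terms)

  n_core <- ceiling(shared_fraction * terms_per_ontology)
  core <- if (n_core > 0) sample(vocab, n_core) else character(0)
  rest_pool <- setdiff(vocab, core)

  syn_cursor <- 0L
  ontologies <- lapply(seq_len(n_ontologies), function(oi) {
    acr <- sprintf("ONT%02d", oi)
    n_rest <- terms_per_ontology - n_core
    terms <- c(core, if (n_rest > 0) sample(rest_pool, min(n_rest, length(rest_pool))))
    n <- length(terms)
    depth <- integer(n)
    parents <- character(n)
    synonyms <- character(n)
    for (i in seq_len(n)) {
      if (i > 1 && stats::runif(1) < 0.8) {
        eligible <- which(depth[seq_len(i - 1)] < depth_max)
        if (length(eligible)) {
          p <- if (length(eligible) == 1) eligible else sample(eligible, 1)
          parents[i] <- sprintf("%s:%04d", acr, p)
          depth[i] <- depth[p] + 1L
        } else depth[i] <- 1L
      } else depth[i] <- 1L
      n_syn <- stats::rbinom(1, 3, 0.3)
      if (n_syn > 0) {
        fresh <- syn_pool[syn_cursor + seq_len(n_syn)]
        syn_cursor <<- syn_cursor + n_syn
        # occasionally alias another vocabulary term for cross-matching
        if (stats::runif(1) < 0.15) fresh[1] <- sample(vocab, 1)
        synonyms[i] <- paste(fresh, collapse = "|")
      }
    }
    classes <- tibble::tibble(
      id = sprintf("%s:%04d", acr, seq_len(n)),
      pref_label = terms,
      synonyms = synonyms,
      definition_count = stats::rbinom(n, 2, 0.4),
      property_count = stats::rpois(n, 4),
      parents = parents
    )
    ontology(classes, acronym = acr,
             declared_size = n * sample(5:60, 1))
  })

  repositories <- tibble::tibble(
    repository = sprintf("REPO%d", seq_len(n_repositories)),
    presence_weight = rep(1 / n_repositories, n_repositories),
    visits_weight = rep(1 / n_repositories, n_repositories)
  )
  usage <- dplyr::bind_rows(lapply(ontologies, function(o) {
    tibble::tibble(
      ontology = o$acronym,
      repository = repositories$repository,
      presence = stats::rbinom(n_repositories, 1, 0.85),
      visits = stats::rpois(n_repositories, lambda = 50 + 400 * stats::runif(1))
    )
  }))
  metadata <- repository_metadata(repositories, usage)

  documents <- vapply(seq_len(n_documents), function(d) {
    slots <- vapply(seq_len(corpus_length), function(s) {
      if (stats::runif(1) < 0.6) sample(vocab, 1) else sample(filler, 1)
    }, character(1))
    paste(slots, collapse = " ")
  }, character(1))
  keywords <- paste(sample(vocab, min(8, length(vocab))), collapse = ", ")

  list(ontologies = ontologies, metadata = metadata,
       documents = documents, keywords = keywords)
}
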
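#' Tokenize text into normalized words with source spans
#'
#' A token is a maximal run of letters or digits; hyphens and all other
#' punctuation separate tokens. Tokens are case-folded but keep the 1-based
#' inclusive character span of their original spelling.
#'
#' @param text A single string (may be empty).
#' @return A tibble with columns `token` (lower-cased), `start`, `end`.
#' @export
#' @examples
#' tokenize("CFS (chronic fatigue)")
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(0), start = integer(0), end = integer(0)))
  }
  loc <- stringr::str_locate_all(text, "[\\p{L}\\p{N}]+")[[1]]
  tibble::tibble(
    token = stringr::str_to_lower(stringr::str_sub(text, loc[, 1], loc[, 2])),
    start = as.integer(loc[, 1]),
    end = as.integer(loc[, 2])
  )
}

# canonical normalized form of a label: tokens joined by single spaces
normalize_label <- function(x) {
  vapply(x, function(s) paste(tokenize(s)$token, collapse = " "), character(1),
         USE.NAMES = FALSE)
}

# one row per dictionary entry: normalized term, token count, class, type.
# A synonym identical (after normalization) to its own class's preferred
# name is dropped so only the PREF entry matches that surface form.
term_dictionary <- function(ont) {
  cl <- ont$classes
  pref <- tibble::tibble(
    class_id = cl$id,
    term = normalize_label(cl$pref_label),
    match_type = "PREF"
  )
  syn <- tibble::tibble(
    class_id = rep(cl$id, lengths(cl$synonyms)),
    term = normalize_label(unlist(cl$synonyms, use.names = FALSE)),
    match_type = "SYN"
  )
  if (nrow(syn)) {
    own_pref <- pref$term[match(syn$class_id, pref$class_id)]
    syn <- syn[syn$term != own_pref, ]
  }
  dict <- dplyr::bind_rows(pref, syn)
  dict <- dict[nzchar(dict$term), ]
  dict$n_words <- lengths(strsplit(dict$term, " ", fixed = TRUE))
  dict
}

#' Annotate a document with ontology classes
#'
#' Dictionary-based concept recognition: every preferred name and synonym of
#' every class is matched, exactly and case-insensitively, against the
#' normalized token sequence of the document. All matches are returned --
#' including overlapping and nested spans, and multiple classes matching the
#' same span -- because the downstream criteria consume the full annotation
#' set before overlap resolution. For one class matching the same span via
#' both its preferred name and a synonym, only the PREF annotation is kept.
#'
#' @param doc An [input_document()] or a single string (treated as free text).
#' @param ontologies An [ontology()] or a list of them.
#' @return A tibble with one row per annotation: `ontology`, `class_id`,
#'   `match_type` (`"PREF"`/`"SYN"`), `start`, `end` (1-based inclusive
#'   character span), `matched_text`, `annotated_words`; sorted by
#'   (start, end, ontology, class_id, match_type).
#' @export
#' @examples
#' toy <- ontology(tibble::tibble(id = c("C1", "C2"),
#'                                pref_label = c("blood cell", "blood")),
#'                 acronym = "TOY")
#' annotate("a blood cell", toy)
annotate <- function(doc, ontologies) {
  doc <- as_input_document(doc)
  if (inherits(ontologies, "ontology")) ontologies <- list(ontologies)
  stopifnot(length(ontologies) >= 1,
            all(vapply(ontologies, inherits, logical(1), "ontology")))

  toks <- tokenize(doc$raw_text)
  out <- lapply(ontologies, function(ont) {
    annotate_one(toks, doc$raw_text, ont)
  })
  ann <- dplyr::bind_rows(out)
  if (nrow(ann) == 0) return(empty_annotations())
  dplyr::arrange(ann, .data$start, .data$end, .data$ontology,
                 .data$class_id, .data$match_type)
}

empty_annotations <- function() {
  tibble::tibble(ontology = character(0), class_id = character(0),
                 match_type = character(0), start = integer(0),
                 end = integer(0), matched_text = character(0),
                 annotated_words = integer(0))
}

annotate_one <- function(toks, raw_text, ont) {
  dict <- term_dictionary(ont)
  n <- nrow(toks)
  if (n == 0 || nrow(dict) == 0) return(empty_annotations())
  hits <- list()
  for (k in sort(unique(dict$n_words))) {
    if (k > n) break
    dk <- dict[dict$n_words == k, ]
    idx <- seq_len(n - k + 1L)
    windows <- if (k == 1) toks$token else
      vapply(idx, function(i) paste(toks$token[i:(i + k - 1L)], collapse = " "),
             character(1))
    m <- lapply(idx, function(i) which(dk$term == windows[[i]]))
    nm <- lengths(m)
    if (!any(nm > 0)) next
    win <- rep(idx, nm)
    row <- unlist(m, use.names = FALSE)
    hits[[length(hits) + 1L]] <- tibble::tibble(
      ontology = ont$acronym,
      class_id = dk$class_id[row],
      match_type = dk$match_type[row],
      start = toks$start[win],
      end = toks$end[win + k - 1L],
      annotated_words = k
    )
  }
  if (!length(hits)) return(empty_annotations())
  ann <- dplyr::bind_rows(hits)
  # PREF-over-SYN deduplication within one class at one span
  ann <- ann |>
    dplyr::group_by(.data$ontology, .data$class_id, .data$start, .data$end) |>
    dplyr::arrange(.data$match_type, .by_group = TRUE) |> # PREF < SYN
    dplyr::slice(1L) |>
    dplyr::ungroup()
  ann$matched_text <- stringr::str_sub(raw_text, ann$start, ann$end)
  ann[, c("ontology", "class_id", "match_type", "start", "end",
          "matched_text", "annotated_words")]
}

#' Keep only annotations covering a whole keyword
#'
#' For keyword input, partial annotations are discarded: an annotation
#' survives only when its span covers all the words of exactly one keyword.
#'
#' @param annotations Annotation tibble from [annotate()].
#' @param doc The [input_document()] the annotations were computed on; must
#'   have `input_type = "keywords"`.
#' @return The filtered annotation tibble.
#' @export
filter_keyword_annotations <- function(annotations, doc) {
  stopifnot(inherits(doc, "input_document"))
  if (doc$input_type != "keywords") {
    abort_config("filter_keyword_annotations() requires a keyword document")
  }
  if (nrow(annotations) == 0) return(annotations)
  kw <- doc$keywords
  # a keyword's token span is [start of first token, end of last token]
  kw_tok <- lapply(seq_len(nrow(kw)), function(i) {
    tk <- tokenize(kw$keyword[[i]])
    if (nrow(tk) == 0) return(c(NA_integer_, NA_integer_))
    c(kw$start[[i]] + tk$start[[1]] - 1L, kw$start[[i]] + tk$end[[nrow(tk)]] - 1L)
  })
  spans <- do.call(rbind, kw_tok)
  keep <- vapply(seq_len(nrow(annotations)), function(i) {
    any(annotations$start[[i]] == spans[, 1] & annotations$end[[i]] == spans[, 2],
        na.rm = TRUE)
  }, logical(1))
  annotations[keep, ]
}
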
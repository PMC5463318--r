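#' Score annotations
#'
#' Each annotation scores `(typeScore + multiWordScore) * annotatedWords`,
#' where the type score is `pref_score` (default 10) for a preferred-name
#' match and `syn_score` (default 5) for a synonym match, and the multi-word
#' score is `multiword_bonus` (default 3) when the annotation covers more
#' than one word, 0 otherwise. A two-word preferred-name match therefore
#' scores (10 + 3) * 2 = 26.
#'
#' @param annotations Annotation tibble from [annotate()] (or any data frame
#'   with columns `match_type` and `annotated_words`).
#' @param config A [recommender_config()].
#' @return Numeric vector of scores, one per annotation row.
#' @export
annotation_score <- function(annotations, config = recommender_config()) {
  stopifnot(all(c("match_type", "annotated_words") %in% names(annotations)))
  type_score <- ifelse(annotations$match_type == "PREF",
                       config$pref_score, config$syn_score)
  bonus <- ifelse(annotations$annotated_words > 1, config$multiword_bonus, 0)
  (type_score + bonus) * annotations$annotated_words
}

#' Resolve overlapping annotations
#'
#' When several annotations cover intersecting text fragments, only the
#' highest-scoring one contributes to coverage and detail. Annotations are
#' swept in order of descending [annotation_score()] (ties: PREF before SYN,
#' longer span, smaller start, class id, ontology) and kept when they do not
#' intersect any already-kept span.
#'
#' @inheritParams annotation_score
#' @return A list of class `annotation_selection`: `selected` and
#'   `discarded` annotation tibbles (both carrying a `score` column) and
#'   `raw_points`, the sum of scores over the selected annotations.
#' @export
select_annotations <- function(annotations, config = recommender_config()) {
  ann <- tibble::as_tibble(annotations)
  if (nrow(ann) == 0) {
    ann$score <- numeric(0)
    return(structure(list(selected = ann, discarded = ann, raw_points = 0),
                     class = "annotation_selection"))
  }
  ann$score <- annotation_score(ann, config)
  ord <- order(-ann$score,
               ann$match_type != "PREF",
               -(ann$end - ann$start),
               ann$start,
               ann$class_id,
               ann$ontology)
  ann <- ann[ord, ]
  keep <- logical(nrow(ann))
  kept_start <- integer(0)
  kept_end <- integer(0)
  for (i in seq_len(nrow(ann))) {
    s <- ann$start[[i]]; e <- ann$end[[i]]
    if (!any(s <= kept_end & kept_start <= e)) {
      keep[[i]] <- TRUE
      kept_start <- c(kept_start, s)
      kept_end <- c(kept_end, e)
    }
  }
  sel <- dplyr::arrange(ann[keep, ], .data$start)
  structure(list(selected = sel,
                 discarded = dplyr::arrange(ann[!keep, ], .data$start),
                 raw_points = sum(sel$score)),
            class = "annotation_selection")
}

#' @export
print.annotation_selection <- function(x, ...) {
  cat(sprintf("<annotation_selection> %d selected / %d discarded, %.6g raw points\n",
              nrow(x$selected), nrow(x$discarded), x$raw_points))
  print(x$selected)
  invisible(x)
}

#' Best achievable coverage points for a candidate pool
#'
#' The coverage normalizer: all candidates' annotations are pooled, overlap
#' resolution is applied to the pooled list, and the selected scores are
#' summed. No single candidate can exceed this value.
#'
#' @param annotations Pooled annotation tibble across every candidate
#'   ontology.
#' @inheritParams annotation_score
#' @return A single number (0 for an empty pool).
#' @export
max_coverage_points <- function(annotations, config = recommender_config()) {
  select_annotations(annotations, config)$raw_points
}

# raw (pre-normalization) specialization value; exported via specialization()
specialization_raw <- function(ontology, annotations, config = recommender_config()) {
  stopifnot(inherits(ontology, "ontology"))
  if (ontology$declared_size < 2) {
    abort_config(sprintf("ontology %s: specialization needs declared_size >= 2",
                         ontology$acronym))
  }
  if (nrow(annotations) == 0) return(0)
  depth <- ontology$classes$depth[match(annotations$class_id, ontology$classes$id)]
  if (anyNA(depth)) abort_config("annotation references a class not in the ontology")
  sum(annotation_score(annotations, config) + 2 * depth) /
    log10(ontology$declared_size)
}

#' Normalization context for a candidate pool
#'
#' Precomputes the run-level maxima that scale raw criterion values into
#' [0,1]: the pooled best coverage points, the largest raw specialization
#' value among candidates, and the per-repository maximum visit count.
#'
#' @param ontologies Named list of candidate [ontology()] objects (only
#'   those with at least one annotation).
#' @param annotations Pooled annotation tibble for those candidates.
#' @param metadata A [repository_metadata()] or `NULL`.
#' @inheritParams annotation_score
#' @return A list of class `normalization_context` with
#'   `max_coverage_points`, `max_specialization_raw`, and `max_visits`
#'   (tibble repository/max_visits).
#' @export
normalization_context <- function(ontologies, annotations,
                                  metadata = NULL,
                                  config = recommender_config()) {
  spec_raws <- vapply(ontologies, function(o) {
    specialization_raw(o, annotations[annotations$ontology == o$acronym, ], config)
  }, numeric(1))
  max_visits <- NULL
  if (!is.null(metadata)) {
    stopifnot(inherits(metadata, "repository_metadata"))
    pool <- toupper(vapply(ontologies, `[[`, character(1), "acronym"))
    u <- metadata$usage[metadata$usage$ontology %in% pool, ]
    max_visits <- metadata$repositories["repository"]
    max_visits$max_visits <- vapply(max_visits$repository, function(r) {
      v <- u$visits[u$repository == r]
      if (length(v)) max(v) else 0L
    }, numeric(1))
  }
  structure(list(
    max_coverage_points = max_coverage_points(annotations, config),
    max_specialization_raw = if (length(spec_raws)) max(spec_raws) else 0,
    max_visits = max_visits
  ), class = "normalization_context")
}

#' Coverage criterion
#'
#' The fraction of the input's annotatable content the ontology captures:
#' the sum of annotation scores after overlap resolution, divided by the
#' pool-wide best achievable points. Repeated occurrences of a matched term
#' each contribute, so term frequency is respected.
#'
#' @param ontology The candidate [ontology()].
#' @param annotations The candidate's annotation tibble for the document.
#' @param context A [normalization_context()] for the current run.
#' @inheritParams annotation_score
#' @return A number in [0,1].
#' @export
coverage <- function(ontology, annotations, context,
                     config = recommender_config()) {
  stopifnot(inherits(context, "normalization_context"))
  if (context$max_coverage_points <= 0) {
    abort_config("coverage undefined: no candidate annotates the input")
  }
  select_annotations(annotations, config)$raw_points / context$max_coverage_points
}

#' Acceptance criterion
#'
#' A proxy for community trust, independent of the input text:
#' `w_presence * presenceScore + w_visits * visitsScore`, where the presence
#' score is the weighted sum of per-repository presence flags and the visits
#' score the weighted sum of per-repository visit counts, each normalized by
#' the candidate pool's maximum for that repository (0 when the maximum
#' is 0).
#'
#' @param ontology The candidate [ontology()].
#' @param metadata A [repository_metadata()], or `NULL` (score 0).
#' @param context A [normalization_context()] carrying per-repository
#'   maximum visits; pass `NULL` to normalize against the metadata-wide
#'   maxima.
#' @inheritParams annotation_score
#' @return A number in [0,1].
#' @export
acceptance <- function(ontology, metadata, context = NULL,
                       config = recommender_config()) {
  if (is.null(metadata)) return(0)
  stopifnot(inherits(metadata, "repository_metadata"))
  acr <- toupper(ontology$acronym)
  reps <- metadata$repositories
  u <- metadata$usage[metadata$usage$ontology == acr, ]
  row_of <- match(reps$repository, u$repository)
  presence <- ifelse(is.na(row_of), 0, u$presence[row_of])
  visits <- ifelse(is.na(row_of), 0, u$visits[row_of])
  max_v <- if (!is.null(context) && !is.null(context$max_visits)) {
    context$max_visits$max_visits[match(reps$repository,
                                        context$max_visits$repository)]
  } else {
    vapply(reps$repository, function(r) {
      v <- metadata$usage$visits[metadata$usage$repository == r]
      if (length(v)) max(v) else 0L
    }, numeric(1))
  }
  visits_norm <- ifelse(max_v > 0, visits / max_v, 0)
  presence_score <- sum(reps$presence_weight * presence)
  visits_score <- sum(reps$visits_weight * visits_norm)
  config$w_presence * presence_score + config$w_visits * visits_score
}

#' Per-annotation detail score
#'
#' Richness of the matched class: the mean of three saturating sub-scores,
#' `min(|D|/k_d, 1)`, `min(|S|/k_s, 1)` and `min(|P|/k_p, 1)`, where |D|,
#' |S|, |P| are the class's definition, synonym and other-property counts.
#'
#' @param definition_count,synonym_count,property_count Non-negative counts
#'   for the matched class(es); vectorized.
#' @inheritParams annotation_score
#' @return Numeric vector in [0,1].
#' @export
#' @examples
#' detail_annotation(1, 2, 7) # (1 + 2/4 + 7/10) / 3
detail_annotation <- function(definition_count, synonym_count, property_count,
                              config = recommender_config()) {
  (pmin(definition_count / config$k_definitions, 1) +
     pmin(synonym_count / config$k_synonyms, 1) +
     pmin(property_count / config$k_properties, 1)) / 3
}

#' Detail criterion
#'
#' The mean [detail_annotation()] over the annotations selected by overlap
#' resolution (0 when nothing is selected).
#'
#' @param ontology The candidate [ontology()].
#' @param selection An `annotation_selection` from [select_annotations()]
#'   computed on the candidate's annotations.
#' @inheritParams annotation_score
#' @return A number in [0,1].
#' @export
detail <- function(ontology, selection, config = recommender_config()) {
  stopifnot(inherits(selection, "annotation_selection"))
  sel <- selection$selected
  if (nrow(sel) == 0) return(0)
  cl <- ontology$classes
  row <- match(sel$class_id, cl$id)
  if (anyNA(row)) abort_config("selected annotation references a class not in the ontology")
  mean(detail_annotation(cl$definition_count[row],
                         lengths(cl$synonyms)[row],
                         cl$property_count[row], config))
}

#' Specialization criterion
#'
#' How tailored the ontology is to the input's domain: over *all* of the
#' candidate's annotations (not just the selected ones),
#' `sum(annotationScore + 2 * depth) / log10(|o|)`, normalized by the
#' largest such raw value in the candidate pool. Depth is 1-based (1 =
#' root level); the size penalty `log10(|o|)` favors small, specialized
#' ontologies.
#'
#' @inheritParams coverage
#' @param raw If `TRUE`, return the pre-normalization value.
#' @return A number in [0,1] (or the raw value when `raw = TRUE`).
#' @export
specialization <- function(ontology, annotations, context = NULL,
                           config = recommender_config(), raw = FALSE) {
  value <- specialization_raw(ontology, annotations, config)
  if (raw) return(value)
  stopifnot(inherits(context, "normalization_context"))
  if (context$max_specialization_raw <= 0) return(0)
  value / context$max_specialization_raw
}
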
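#' Combine criterion scores into a relevance score
#'
#' The weighted sum `w_c * coverage + w_a * acceptance + w_d * detail +
#' w_s * specialization`; with weights summing to 1 and criteria in [0,1]
#' the relevance is also in [0,1].
#'
#' @param scores Data frame with columns `coverage`, `acceptance`, `detail`,
#'   `specialization` (one row per candidate).
#' @param config A [recommender_config()].
#' @return `scores` with a `relevance` column appended.
#' @export
combine_scores <- function(scores, config = recommender_config()) {
  stopifnot(all(c("coverage", "acceptance", "detail", "specialization") %in%
                  names(scores)))
  dplyr::mutate(tibble::as_tibble(scores),
                relevance = config$w_coverage * .data$coverage +
                  config$w_acceptance * .data$acceptance +
                  config$w_detail * .data$detail +
                  config$w_specialization * .data$specialization)
}

#' Rank scored candidates
#'
#' Sorts by relevance (descending), breaking ties by coverage, then
#' acceptance (both descending), then subject name (ascending), and assigns
#' consecutive ranks from 1. The order is independent of the input order.
#'
#' @param results Data frame with columns `subject`, `relevance`,
#'   `coverage`, `acceptance`.
#' @return The tibble sorted with a `rank` column first.
#' @export
rank_results <- function(results) {
  stopifnot(all(c("subject", "relevance", "coverage", "acceptance") %in%
                  names(results)))
  out <- dplyr::arrange(tibble::as_tibble(results),
                        dplyr::desc(.data$relevance),
                        dplyr::desc(.data$coverage),
                        dplyr::desc(.data$acceptance),
                        .data$subject)
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}

#' Legacy relevance scorer
#'
#' The single-formula scorer that predates the four-criterion method:
#' `sum(annotationScore + 2 * hierarchyLevel) / log10(|o|)` over all
#' annotations, with type scores 10 (PREF) / 8 (SYN) and no multi-word
#' bonus or overlap resolution. Under the default `depth_base_v1 = 0`
#' convention the root level counts as 0 (hierarchyLevel = depth - 1);
#' with `depth_base_v1 = 1` the 1-based depth is used directly. The raw
#' value is reported without cross-candidate normalization.
#'
#' @param ontology The candidate [ontology()] (`declared_size >= 2`).
#' @param annotations The candidate's annotation tibble.
#' @param config A [recommender_config()].
#' @return A non-negative number.
#' @export
score_v1 <- function(ontology, annotations, config = recommender_config()) {
  stopifnot(inherits(ontology, "ontology"))
  if (ontology$declared_size < 2) {
    abort_config(sprintf("ontology %s: score_v1 needs declared_size >= 2",
                         ontology$acronym))
  }
  if (nrow(annotations) == 0) return(0)
  depth <- ontology$classes$depth[match(annotations$class_id, ontology$classes$id)]
  if (anyNA(depth)) abort_config("annotation references a class not in the ontology")
  level <- if (config$depth_base_v1 == 0L) depth - 1L else depth
  type_score <- ifelse(annotations$match_type == "PREF",
                       config$pref_score_v1, config$syn_score_v1)
  sum(type_score + 2 * level) / log10(ontology$declared_size)
}

#' Convert a unit-interval score to the display scale
#'
#' Scores are computed in [0,1] and displayed in [0,100] with one decimal
#' place (halves round up).
#'
#' @param score Numeric vector in [0,1].
#' @return Numeric vector in [0,100], rounded to one decimal.
#' @export
#' @examples
#' to_display(0.845) # 84.5
to_display <- function(score) {
  stopifnot(is.numeric(score))
  if (any(is.na(score) | score < 0 | score > 1)) {
    abort_config("display scores must lie in [0,1]")
  }
  round_half_up(score * 100, 1)
}
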
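#' Enumerate candidate ontology sets
#'
#' All subsets of size 2 up to `max_set_size` of the candidate pool, in a
#' deterministic order (increasing size, members alphabetical).
#'
#' @param candidates Character vector of candidate acronyms, or a list of
#'   [ontology()] objects.
#' @param config A [recommender_config()].
#' @return A list of character vectors, each a sorted set of members.
#' @export
enumerate_sets <- function(candidates, config = recommender_config()) {
  if (is.list(candidates)) {
    candidates <- vapply(candidates, `[[`, character(1), "acronym")
  }
  acr <- sort(unique(candidates))
  sizes <- seq(2L, min(config$max_set_size, length(acr)))
  if (length(acr) < 2) return(list())
  out <- list()
  for (k in sizes) {
    cmb <- utils::combn(acr, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# sorted "start-end@score" strings of the selected fragments of one member;
# the score is part of the identity so that dropping one of two "twin"
# members provably cannot change the pooled selection's points
selected_fragments <- function(annotations, config) {
  sel <- select_annotations(annotations, config)$selected
  sort(paste0(sel$start, "-", sel$end, "@", sel$score))
}

#' Prune an ontology set before full evaluation
#'
#' A set is discarded without evaluation when it cannot improve coverage:
#' either two of its members cover exactly the same selected text
#' fragments (with the same annotation scores), or the pooled selection of
#' the whole set scores no more points than some proper subset of it.
#'
#' @param members Character vector of the set's member acronyms.
#' @param annotations Pooled annotation tibble for the candidate pool (an
#'   `ontology` column identifies each member's annotations).
#' @param config A [recommender_config()].
#' @return `TRUE` when the set should be discarded.
#' @export
set_pruned <- function(members, annotations, config = recommender_config()) {
  stopifnot(length(members) >= 2, !anyDuplicated(members))
  frags <- lapply(members, function(m) {
    selected_fragments(annotations[annotations$ontology == m, ], config)
  })
  for (i in seq_along(members)) {
    for (j in seq_len(i - 1L)) {
      if (identical(frags[[i]], frags[[j]])) return(TRUE)
    }
  }
  pooled <- function(mm) {
    select_annotations(annotations[annotations$ontology %in% mm, ], config)$raw_points
  }
  full <- pooled(members)
  for (k in seq_len(length(members) - 1L)) {
    for (sub in utils::combn(members, k, simplify = FALSE)) {
      if (pooled(sub) >= full - 1e-12) return(TRUE)
    }
  }
  FALSE
}

#' Joint coverage of an ontology set
#'
#' Pools the members' annotations, applies overlap resolution to the pooled
#' list, and normalizes the selected points by the pool-wide maximum -- so a
#' set's coverage is never below its best member's. Each selected
#' annotation is attributed to the member that supplied it, giving each
#' member's coverage contribution (fractions summing to 1).
#'
#' @inheritParams set_pruned
#' @param context A [normalization_context()] for the run.
#' @return A list: `coverage` in [0,1], `selection` (the pooled
#'   `annotation_selection`), and `contributions`, a tibble with columns
#'   `ontology`, `points`, `contribution`.
#' @export
coverage_set <- function(members, annotations, context,
                         config = recommender_config()) {
  stopifnot(inherits(context, "normalization_context"))
  pooled <- annotations[annotations$ontology %in% members, ]
  selection <- select_annotations(pooled, config)
  if (context$max_coverage_points <= 0) {
    abort_config("coverage undefined: no candidate annotates the input")
  }
  pts <- vapply(members, function(m) {
    sum(selection$selected$score[selection$selected$ontology == m])
  }, numeric(1))
  total <- sum(pts)
  contributions <- tibble::tibble(
    ontology = members,
    points = unname(pts),
    contribution = if (total > 0) unname(pts) / total else rep(0, length(members))
  )
  list(coverage = selection$raw_points / context$max_coverage_points,
       selection = selection, contributions = contributions)
}

#' Score an ontology set
#'
#' The set's relevance uses the same weighted combination as a single
#' ontology. Joint coverage comes from [coverage_set()]; acceptance,
#' detail and specialization are the members' single-ontology scores
#' averaged proportionally to each member's coverage contribution.
#'
#' @param members Character vector of member acronyms.
#' @param cov A [coverage_set()] result for the members.
#' @param member_scores Data frame of single-ontology criterion scores with
#'   columns `subject`, `acceptance`, `detail`, `specialization` covering
#'   every member.
#' @param config A [recommender_config()].
#' @return A one-row tibble: `subject` (members joined with `+`),
#'   the four criterion scores, `relevance`, plus `members` and
#'   `contributions` list-columns.
#' @export
score_set <- function(members, cov, member_scores,
                      config = recommender_config()) {
  w <- cov$contributions$contribution[match(members, cov$contributions$ontology)]
  if (abs(sum(w) - 1) > 1e-9) {
    stop("internal consistency error: contributions do not sum to 1", call. = FALSE)
  }
  row <- match(members, member_scores$subject)
  if (anyNA(row)) abort_config("member_scores is missing a set member")
  scores <- tibble::tibble(
    subject = paste(members, collapse = "+"),
    coverage = cov$coverage,
    acceptance = sum(w * member_scores$acceptance[row]),
    detail = sum(w * member_scores$detail[row]),
    specialization = sum(w * member_scores$specialization[row])
  )
  out <- combine_scores(scores, config)
  out$members <- list(members)
  out$contributions <- list(cov$contributions)
  out
}
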
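#' Recommender configuration
#'
#' All weights and constants of the recommendation method. The four
#' criterion weights combine coverage, acceptance, detail and specialization
#' into the relevance score and must sum to 1; the default 0.55/0.15/0.15/0.15
#' split reflects that input coverage is the dominant requirement.
#'
#' @param w_coverage,w_acceptance,w_detail,w_specialization Criterion
#'   weights, each >= 0, summing to 1.
#' @param w_presence,w_visits Acceptance-factor weights (repository presence
#'   vs. recent visits), each >= 0, summing to 1.
#' @param pref_score,syn_score Annotation type scores: a match on a class
#'   preferred name scores `pref_score` (default 10), a synonym match
#'   `syn_score` (default 5).
#' @param multiword_bonus Added to the type score when an annotation covers
#'   more than one word (default 3).
#' @param pref_score_v1,syn_score_v1 Type scores used by the legacy scorer
#'   [score_v1()] (defaults 10 and 8).
#' @param k_definitions,k_synonyms,k_properties Saturation constants of the
#'   detail criterion: the number of definitions / synonyms / other
#'   properties at which a matched class earns the maximum sub-score
#'   (defaults 1, 4, 10).
#' @param max_set_size Largest ontology-set size to enumerate (default 3).
#' @param depth_base_v1 Hierarchy-level convention for the legacy scorer:
#'   0 (default) counts the root level as 0, 1 counts it as 1. The current
#'   scorer always uses the 1-based convention.
#' @return A list of class `recommender_config`.
#' @export
recommender_config <- function(w_coverage = 0.55, w_acceptance = 0.15,
                               w_detail = 0.15, w_specialization = 0.15,
                               w_presence = 0.5, w_visits = 0.5,
                               pref_score = 10, syn_score = 5,
                               multiword_bonus = 3,
                               pref_score_v1 = 10, syn_score_v1 = 8,
                               k_definitions = 1, k_synonyms = 4,
                               k_properties = 10,
                               max_set_size = 3, depth_base_v1 = 0) {
  cfg <- list(
    w_coverage = w_coverage, w_acceptance = w_acceptance,
    w_detail = w_detail, w_specialization = w_specialization,
    w_presence = w_presence, w_visits = w_visits,
    pref_score = pref_score, syn_score = syn_score,
    multiword_bonus = multiword_bonus,
    pref_score_v1 = pref_score_v1, syn_score_v1 = syn_score_v1,
    k_definitions = k_definitions, k_synonyms = k_synonyms,
    k_properties = k_properties,
    max_set_size = as.integer(max_set_size),
    depth_base_v1 = as.integer(depth_base_v1)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  cw <- c(cfg$w_coverage, cfg$w_acceptance, cfg$w_detail, cfg$w_specialization)
  if (any(cw < 0) || abs(sum(cw) - 1) > 1e-9) {
    abort_config("criterion weights must be non-negative and sum to 1")
  }
  aw <- c(cfg$w_presence, cfg$w_visits)
  if (any(aw < 0) || abs(sum(aw) - 1) > 1e-9) {
    abort_config("w_presence + w_visits must equal 1 with both non-negative")
  }
  pos <- c("pref_score", "syn_score", "multiword_bonus", "pref_score_v1",
           "syn_score_v1", "k_definitions", "k_synonyms", "k_properties")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      abort_config(sprintf("`%s` must be a single positive number", nm))
    }
  }
  if (is.na(cfg$max_set_size) || cfg$max_set_size < 2) {
    abort_config("`max_set_size` must be an integer >= 2")
  }
  if (!cfg$depth_base_v1 %in% c(0L, 1L)) {
    abort_config("`depth_base_v1` must be 0 or 1")
  }
  structure(cfg, class = "recommender_config")
}

#' @export
print.recommender_config <- function(x, ...) {
  cat("<recommender_config>\n")
  cat(sprintf("  criterion weights: coverage %.2f, acceptance %.2f, detail %.2f, specialization %.2f\n",
              x$w_coverage, x$w_acceptance, x$w_detail, x$w_specialization))
  cat(sprintf("  acceptance factors: presence %.2f, visits %.2f\n",
              x$w_presence, x$w_visits))
  cat(sprintf("  annotation scores: PREF %g, SYN %g, multi-word bonus %g\n",
              x$pref_score, x$syn_score, x$multiword_bonus))
  cat(sprintf("  detail saturation: k_d %g, k_s %g, k_p %g; max set size %d\n",
              x$k_definitions, x$k_synonyms, x$k_properties, x$max_set_size))
  invisible(x)
}

#' Read a configuration file
#'
#' Reads a YAML (or plain `key: value`) file whose keys match the arguments
#' of [recommender_config()]; unspecified keys keep their defaults.
#'
#' @param path Path to the configuration file.
#' @return A [recommender_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read config '%s'", path), call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(recommender_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_config(sprintf("unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  do.call(recommender_config, vals)
}
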
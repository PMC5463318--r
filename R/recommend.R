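#' Recommend ontologies (or ontology sets) for an input
#'
#' The full pipeline: annotate the input with every candidate ontology,
#' discard partial annotations for keyword input, drop candidates with no
#' annotations, score the survivors on coverage, acceptance, detail and
#' specialization, combine the criteria into a relevance score, and rank.
#' In set mode, 2- to `max_set_size`-member combinations of the surviving
#' candidates are enumerated, pruned when they cannot improve coverage, and
#' scored jointly.
#'
#' @param input A single string, an [input_document()], or a file path
#'   (read as one string when the file exists).
#' @param ontologies An [ontology()] or list of them (distinct acronyms).
#' @param metadata Optional [repository_metadata()]; without it every
#'   candidate's acceptance score is 0.
#' @param config A [recommender_config()].
#' @param input_type `"text"` or `"keywords"`; ignored when `input` is
#'   already an `input_document`.
#' @param output `"ontologies"` (rank single ontologies, default) or
#'   `"sets"` (rank ontology sets).
#' @return An object of class `recommendation`: a list with `results` (the
#'   ranked tibble: `rank`, `subject`, `relevance`, `relevance_display`,
#'   the four criterion columns, `n_annotations`, `n_selected`), plus the
#'   pooled `annotations`, per-subject `selections`, `normalization`
#'   constants, candidate counts, `status`, `config` and an input summary.
#'   Use [tidy()][generics::tidy] for the results tibble and
#'   [write_report()] to serialize.
#' @export
recommend <- function(input, ontologies, metadata = NULL,
                      config = recommender_config(),
                      input_type = c("text", "keywords"),
                      output = c("ontologies", "sets")) {
  input_type <- match.arg(input_type)
  output <- match.arg(output)
  stopifnot(inherits(config, "recommender_config"))
  if (is.character(input) && length(input) == 1 && file.exists(input)) {
    input <- paste(readLines(input, encoding = "UTF-8", warn = FALSE),
                   collapse = "\n")
  }
  doc <- as_input_document(input, type = input_type)
  if (inherits(ontologies, "ontology")) ontologies <- list(ontologies)
  acronyms <- vapply(ontologies, `[[`, character(1), "acronym")
  if (anyDuplicated(acronyms)) {
    abort_config("candidate ontologies must have distinct acronyms")
  }
  names(ontologies) <- acronyms
  n_before <- length(ontologies)

  ann <- annotate(doc, ontologies)
  if (doc$input_type == "keywords") {
    ann <- filter_keyword_annotations(ann, doc)
  }
  keep <- acronyms[acronyms %in% unique(ann$ontology)]
  candidates <- ontologies[keep]
  n_after <- length(candidates)

  base <- list(
    input = list(type = doc$input_type, n_chars = nchar(doc$raw_text),
                 n_tokens = nrow(tokenize(doc$raw_text))),
    n_candidates = c(before = n_before, after = n_after),
    output = output, config = config, annotations = ann
  )
  if (n_after == 0) {
    res <- structure(c(base, list(
      results = empty_results(), selections = list(),
      normalization = NULL,
      status = "no ontology annotates the input; nothing to rank"
    )), class = "recommendation")
    return(res)
  }

  ctx <- normalization_context(candidates, ann, metadata, config)
  selections <- lapply(candidates, function(o) {
    select_annotations(ann[ann$ontology == o$acronym, ], config)
  })
  singles <- dplyr::bind_rows(lapply(keep, function(a) {
    o <- candidates[[a]]
    oa <- ann[ann$ontology == a, ]
    tibble::tibble(
      subject = a,
      coverage = coverage(o, oa, ctx, config),
      acceptance = acceptance(o, metadata, ctx, config),
      detail = detail(o, selections[[a]], config),
      specialization = specialization(o, oa, ctx, config),
      n_annotations = nrow(oa),
      n_selected = nrow(selections[[a]]$selected)
    )
  }))
  singles <- combine_scores(singles, config)

  if (output == "ontologies") {
    results <- rank_results(singles)
  } else {
    sets <- enumerate_sets(keep, config)
    kept_sets <- Filter(function(m) !set_pruned(m, ann, config), sets)
    if (!length(kept_sets)) {
      res <- structure(c(base, list(
        results = empty_results(), selections = selections,
        normalization = ctx,
        status = "every candidate set was pruned (no set improves on a single ontology)"
      )), class = "recommendation")
      return(res)
    }
    rows <- lapply(kept_sets, function(m) {
      cov <- coverage_set(m, ann, ctx, config)
      row <- score_set(m, cov, singles, config)
      row$n_annotations <- sum(ann$ontology %in% m)
      row$n_selected <- nrow(cov$selection$selected)
      row
    })
    results <- rank_results(dplyr::bind_rows(rows))
    selections <- c(selections, stats::setNames(
      lapply(kept_sets, function(m) {
        select_annotations(ann[ann$ontology %in% m, ], config)
      }),
      vapply(kept_sets, paste, character(1), collapse = "+")))
  }
  results$relevance_display <- to_display(results$relevance)
  results <- dplyr::relocate(results, "relevance_display", .after = "relevance")

  structure(c(base, list(
    results = results, selections = selections,
    normalization = ctx, status = "ok"
  )), class = "recommendation")
}

empty_results <- function() {
  tibble::tibble(rank = integer(0), subject = character(0),
                 relevance = numeric(0), relevance_display = numeric(0),
                 coverage = numeric(0), acceptance = numeric(0),
                 detail = numeric(0), specialization = numeric(0),
                 n_annotations = integer(0), n_selected = integer(0))
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("<recommendation> %s input (%d tokens), %d/%d candidates scored [%s]\n",
              x$input$type, x$input$n_tokens,
              x$n_candidates[["after"]], x$n_candidates[["before"]], x$status))
  if (nrow(x$results)) {
    shown <- dplyr::select(x$results, "rank", "subject", "relevance_display",
                           "coverage", "acceptance", "detail", "specialization")
    print(shown, n = 10)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a recommendation
#'
#' @param x A `recommendation` from [recommend()].
#' @param ... Unused.
#' @return The ranked results tibble (one row per candidate or set).
#' @export
tidy.recommendation <- function(x, ...) x$results

#' One-row summary of a recommendation run
#'
#' @param x A `recommendation` from [recommend()].
#' @param ... Unused.
#' @return A one-row tibble with input size, candidate counts, the
#'   normalization constants and the top subject and its relevance.
#' @export
glance.recommendation <- function(x, ...) {
  tibble::tibble(
    input_type = x$input$type,
    n_tokens = x$input$n_tokens,
    n_candidates = x$n_candidates[["before"]],
    n_scored = x$n_candidates[["after"]],
    n_ranked = nrow(x$results),
    max_coverage_points = if (is.null(x$normalization)) NA_real_ else
      x$normalization$max_coverage_points,
    top_subject = if (nrow(x$results)) x$results$subject[[1]] else NA_character_,
    top_relevance = if (nrow(x$results)) x$results$relevance[[1]] else NA_real_,
    status = x$status
  )
}

#' Plot a recommendation
#'
#' Bar chart of the four criterion scores per ranked subject, with the
#' combined relevance overlaid as a point.
#'
#' @param object A `recommendation` from [recommend()].
#' @param top_n Show at most this many subjects (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recommendation <- function(object, top_n = 10, ...) {
  res <- utils::head(object$results, top_n)
  if (nrow(res) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = object$status) +
             ggplot2::theme_void())
  }
  long <- tidyr::pivot_longer(
    dplyr::select(res, "subject", "coverage", "acceptance", "detail",
                  "specialization"),
    -"subject", names_to = "criterion", values_to = "score")
  long$subject <- factor(long$subject, levels = rev(res$subject))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score, y = .data$subject,
                                     fill = .data$criterion)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(
      data = dplyr::mutate(res, subject = factor(.data$subject,
                                                 levels = rev(res$subject))),
      ggplot2::aes(x = .data$relevance, y = .data$subject),
      inherit.aes = FALSE, shape = 18, size = 3) +
    ggplot2::labs(x = "score [0,1]", y = NULL, fill = NULL,
                  title = "Criterion scores by candidate",
                  subtitle = "diamond = combined relevance") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Serialize a recommendation report
#'
#' JSON (default) writes a self-contained report: input summary, candidate
#' counts, normalization constants, the configuration, and the ranked
#' results with both the all-annotation and selected-annotation counts.
#' TSV writes the ranked results table only, one row per subject with
#' columns rank, subject, relevance (display scale), the four criterion
#' scores and the annotation counts.
#'
#' @param x A `recommendation` from [recommend()].
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "tsv")) {
  stopifnot(inherits(x, "recommendation"))
  format <- match.arg(format)
  res <- dplyr::select(x$results, dplyr::any_of(c(
    "rank", "subject", "relevance", "relevance_display", "coverage",
    "acceptance", "detail", "specialization", "n_annotations", "n_selected")))
  if (format == "tsv") {
    out <- dplyr::rename(res, `relevance(0-100)` = "relevance_display")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(path))
  }
  report <- list(
    input = x$input,
    candidates = list(before = unname(x$n_candidates[["before"]]),
                      after = unname(x$n_candidates[["after"]])),
    output = x$output,
    status = x$status,
    normalization = if (is.null(x$normalization)) NULL else list(
      max_coverage_points = x$normalization$max_coverage_points,
      max_specialization_raw = x$normalization$max_specialization_raw),
    config = unclass(x$config),
    results = res
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
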
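#' Construct an ontology
#'
#' An ontology is a collection of classes, each carrying a preferred label,
#' synonyms, a definition count, a count of other properties, and parent
#' links within the same ontology. Class depth (1 = root level) is computed
#' from the parent links on construction.
#'
#' @param classes Data frame with one row per class. Required columns: `id`
#'   (unique identifier) and `pref_label` (non-empty). Optional columns:
#'   `synonyms` and `parents` (either pipe-separated strings or list-columns
#'   of character vectors), `definition_count` and `property_count`
#'   (non-negative integers, default 0).
#' @param acronym Short upper-case name for the ontology (e.g. `"SNOMEDCT"`).
#' @param declared_size Number of classes the ontology declares, `|o|`.
#'   Defaults to the number of loaded classes; may be larger when `classes`
#'   is a partial dictionary of a bigger ontology.
#' @return An object of class `ontology`: a list with `acronym`,
#'   `declared_size`, and `classes`, a tibble with list-columns `synonyms`
#'   and `parents` plus a computed `depth` column.
#' @export
#' @examples
#' ontology(
#'   tibble::tibble(id = c("A", "B"), pref_label = c("cell", "blood cell"),
#'                  parents = c("", "A")),
#'   acronym = "TOY"
#' )
ontology <- function(classes, acronym, declared_size = NULL) {
  stopifnot(is.data.frame(classes))
  if (!is_scalar_string(acronym) || !nzchar(trimws(acronym))) {
    abort_config("`acronym` must be a non-empty string")
  }
  acronym <- toupper(trimws(acronym))
  if (nrow(classes) < 1) {
    abort_config(sprintf("ontology %s: an ontology must contain at least one class", acronym))
  }
  req <- c("id", "pref_label")
  miss <- setdiff(req, names(classes))
  if (length(miss)) {
    abort_config(paste0("missing class columns: ", paste(miss, collapse = ", ")))
  }

  cl <- tibble::as_tibble(classes)
  cl$id <- as.character(cl$id)
  dup <- cl$id[duplicated(cl$id)]
  if (length(dup)) {
    abort_config(sprintf("ontology %s: duplicate class id '%s'", acronym, dup[[1]]))
  }
  cl$pref_label <- stringr::str_squish(as.character(cl$pref_label))
  if (any(!nzchar(cl$pref_label) | is.na(cl$pref_label))) {
    bad <- which(!nzchar(cl$pref_label) | is.na(cl$pref_label))[[1]]
    abort_config(sprintf("ontology %s: class '%s' has an empty preferred label",
                         acronym, cl$id[[bad]]))
  }

  cl$synonyms <- split_pipes(if ("synonyms" %in% names(cl)) cl$synonyms else rep("", nrow(cl)))
  # drop duplicate synonyms after case-folding, preserving first spelling
  cl$synonyms <- lapply(cl$synonyms, function(s) s[!duplicated(tolower(s))])
  cl$parents <- split_pipes(if ("parents" %in% names(cl)) cl$parents else rep("", nrow(cl)))

  for (col in c("definition_count", "property_count")) {
    v <- if (col %in% names(cl)) cl[[col]] else 0L
    v <- as.integer(v)
    if (any(is.na(v) | v < 0)) abort_config(sprintf("`%s` must be a non-negative integer", col))
    cl[[col]] <- v
  }

  unknown <- setdiff(unique(unlist(cl$parents)), cl$id)
  if (length(unknown)) {
    abort_config(sprintf("ontology %s: parent id '%s' does not resolve to any class",
                         acronym, unknown[[1]]))
  }

  n_loaded <- nrow(cl)
  if (is.null(declared_size)) declared_size <- n_loaded
  declared_size <- as.integer(declared_size)
  if (is.na(declared_size) || declared_size < 1 || declared_size < n_loaded) {
    abort_config(sprintf(
      "ontology %s: declared_size must be >= max(1, number of loaded classes)", acronym))
  }

  ont <- structure(
    list(acronym = acronym, declared_size = declared_size,
         classes = cl[, c("id", "pref_label", "synonyms", "definition_count",
                          "property_count", "parents")]),
    class = "ontology"
  )
  compute_depths(ont)
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %s: %d classes loaded, declared size %d, max depth %d\n",
              x$acronym, nrow(x$classes), x$declared_size, max(x$classes$depth)))
  print(x$classes, n = 5)
  invisible(x)
}

#' Compute hierarchy depths from parent links
#'
#' Assigns each class its hierarchy level: 1 for root classes (no parents),
#' and `1 + min(depth of parents)` otherwise, i.e. the length of the shortest
#' parent path to any root. Idempotent; called automatically by [ontology()].
#'
#' @param x An `ontology`.
#' @return The ontology with a recomputed `depth` column on `$classes`.
#' @export
compute_depths <- function(x) {
  stopifnot(inherits(x, "ontology"))
  cl <- x$classes
  n <- nrow(cl)
  idx <- stats::setNames(seq_len(n), cl$id)
  parent_idx <- lapply(cl$parents, function(p) unname(idx[p]))
  depth <- rep(NA_integer_, n)
  depth[lengths(parent_idx) == 0] <- 1L
  # relaxation over the DAG: min-parent-depth + 1
  repeat {
    changed <- FALSE
    for (i in which(is.na(depth))) {
      pd <- depth[parent_idx[[i]]]
      if (!anyNA(pd)) {
        depth[i] <- 1L + min(pd)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(depth)) {
    cyc <- find_cycle(cl$id, parent_idx, which(is.na(depth)))
    abort_config(sprintf("ontology %s: cycle in parent links: %s",
                         x$acronym, paste(cyc, collapse = " -> ")))
  }
  x$classes$depth <- depth
  x
}

# walk parent links from an unresolved node until a node repeats
find_cycle <- function(ids, parent_idx, unresolved) {
  start <- unresolved[[1]]
  seen <- integer(0)
  i <- start
  while (!(i %in% seen)) {
    seen <- c(seen, i)
    nxt <- parent_idx[[i]]
    nxt <- nxt[i_depth_unresolved(nxt, unresolved)]
    i <- nxt[[1]]
  }
  cyc <- c(seen[which(seen == i):length(seen)], i)
  ids[cyc]
}

i_depth_unresolved <- function(nxt, unresolved) nxt %in% unresolved

#' Read an ontology from an OBO flat file
#'
#' Parses OBO 1.2/1.4 `[Term]` stanzas. The stanza `name` becomes the
#' preferred label, `synonym` lines the synonyms, `def` lines are counted
#' into `definition_count`, `is_a` lines become parent links, and every
#' other tag-value line on the stanza is counted into `property_count`.
#' Obsolete terms are skipped; a term without a name is skipped with a
#' warning.
#'
#' @param path Path to an OBO file.
#' @param acronym Ontology acronym; defaults to the `ontology:` header tag
#'   (upper-cased) or, failing that, the file name.
#' @param declared_size Optional declared size override (see [ontology()]).
#' @return An [ontology()].
#' @export
load_obo <- function(path, acronym = NULL, declared_size = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read OBO file '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)

  if (is.null(acronym)) {
    hdr_end <- match(TRUE, startsWith(trimws(lines), "["), nomatch = length(lines) + 1L) - 1L
    hdr <- lines[seq_len(hdr_end)]
    ont_tag <- grep("^ontology:", hdr, value = TRUE)
    acronym <- if (length(ont_tag)) {
      trimws(sub("^ontology:", "", ont_tag[[1]]))
    } else {
      tools::file_path_sans_ext(basename(path))
    }
  }

  stanza_starts <- which(trimws(lines) == "[Term]")
  block_starts <- which(grepl("^\\[.*\\]$", trimws(lines)))
  rows <- list()
  for (s in stanza_starts) {
    nxt <- block_starts[block_starts > s]
    body <- lines[seq(s + 1L, if (length(nxt)) nxt[[1]] - 1L else length(lines))]
    body <- body[nzchar(trimws(body)) & grepl(":", body, fixed = TRUE)]
    body <- body[!startsWith(trimws(body), "!")]
    tags <- sub(":.*$", "", body)
    vals <- trimws(sub("^[^:]*:", "", body))
    rec <- function(tag) vals[tags == tag]

    if (any(tags == "is_obsolete") && tolower(rec("is_obsolete")[[1]]) == "true") next
    id <- rec("id")
    nm <- rec("name")
    if (!length(nm)) {
      warning(sprintf("OBO term %s has no name; record skipped",
                      if (length(id)) id[[1]] else "<missing id>"), call. = FALSE)
      next
    }
    syns <- vapply(rec("synonym"), obo_synonym_text, character(1), USE.NAMES = FALSE)
    parents <- vapply(rec("is_a"), function(v) {
      trimws(sub("\\s*[!{].*$", "", v))
    }, character(1), USE.NAMES = FALSE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = id[[1]], pref_label = nm[[1]],
      synonyms = list(syns), parents = list(parents),
      definition_count = sum(tags == "def"),
      property_count = sum(!tags %in% c("id", "name", "def", "synonym", "is_a", "is_obsolete"))
    )
  }
  if (!length(rows)) {
    abort_config(sprintf("OBO file '%s' contains no usable [Term] stanzas", path))
  }
  ontology(dplyr::bind_rows(rows), acronym = acronym, declared_size = declared_size)
}

# synonym: "text" SCOPE [xrefs]  -> text
obo_synonym_text <- function(v) {
  m <- regmatches(v, regexpr('"[^"]*"', v))
  if (length(m)) substr(m, 2, nchar(m) - 1L) else trimws(v)
}

#' Read an ontology from the plain-text dictionary dialect
#'
#' The dialect is a UTF-8, LF-terminated file with a header section of
#' `key=value` lines (`acronym=...`, optional `declared_size=...`), a blank
#' line, and then one tab-separated record per class with six fields:
#' id, preferred label, pipe-separated synonyms (may be empty), definition
#' count, property count, pipe-separated parent ids (may be empty).
#'
#' @param path Path to a dictionary file.
#' @return An [ontology()].
#' @seealso [write_dictionary()] for the inverse operation.
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read dictionary '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- match(TRUE, !nzchar(trimws(lines)))
  if (is.na(blank)) abort_config(sprintf("'%s': no blank line separating header from records", path))
  hdr <- lines[seq_len(blank - 1L)]
  hdr <- hdr[grepl("=", hdr, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", hdr))
  vals <- trimws(sub("^[^=]*=", "", hdr))
  header <- stats::setNames(as.list(vals), keys)
  if (is.null(header$acronym)) {
    header$acronym <- tools::file_path_sans_ext(basename(path))
  }

  if (blank >= length(lines)) {
    abort_config(sprintf("'%s': an ontology must contain at least one class", path))
  }
  body_lines <- lines[seq(blank + 1L, length(lines))]
  keep <- nzchar(trimws(body_lines))
  body_lines <- body_lines[keep]
  lineno <- (seq(blank + 1L, length(lines)))[keep]
  if (!length(body_lines)) {
    abort_config(sprintf("'%s': an ontology must contain at least one class", path))
  }
  parts <- strsplit(body_lines, "\t", fixed = TRUE)
  rows <- vector("list", length(parts))
  seen_ids <- character(0)
  for (k in seq_along(parts)) {
    p <- c(parts[[k]], rep("", 6L))[1:6]
    if (!nzchar(trimws(p[[1]]))) {
      abort_config(sprintf("'%s' line %d: missing class id", path, lineno[[k]]))
    }
    if (!nzchar(trimws(p[[2]]))) {
      abort_config(sprintf("'%s' line %d: missing pref_label for class '%s'",
                           path, lineno[[k]], p[[1]]))
    }
    if (p[[1]] %in% seen_ids) {
      abort_config(sprintf("'%s' line %d: duplicate class id '%s'", path, lineno[[k]], p[[1]]))
    }
    seen_ids <- c(seen_ids, p[[1]])
    rows[[k]] <- tibble::tibble(
      id = p[[1]], pref_label = p[[2]], synonyms = p[[3]],
      definition_count = as.integer(if (nzchar(p[[4]])) p[[4]] else 0L),
      property_count = as.integer(if (nzchar(p[[5]])) p[[5]] else 0L),
      parents = p[[6]]
    )
  }
  ontology(dplyr::bind_rows(rows), acronym = header$acronym,
           declared_size = if (!is.null(header$declared_size))
             as.integer(header$declared_size) else NULL)
}

#' Write an ontology in the dictionary dialect
#'
#' @param x An [ontology()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(x, path) {
  stopifnot(inherits(x, "ontology"))
  cl <- x$classes
  hdr <- c(sprintf("acronym=%s", x$acronym),
           sprintf("declared_size=%d", x$declared_size), "")
  recs <- paste(cl$id, cl$pref_label, join_pipes(cl$synonyms),
                cl$definition_count, cl$property_count, join_pipes(cl$parents),
                sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, recs), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Construct repository metadata
#'
#' Holds, for a named list of ontology repositories, the per-repository
#' weights used by the acceptance criterion together with each ontology's
#' presence flag (0/1) and recent visit (pageview) count in each repository.
#'
#' @param repositories Data frame with columns `repository`,
#'   `presence_weight`, `visits_weight`; each weight column must be
#'   non-negative and sum to 1.
#' @param usage Data frame with columns `ontology`, `repository`, `presence`
#'   (0 or 1), `visits` (integer >= 0). Ontologies absent from the table
#'   default to presence 0 and visits 0 everywhere.
#' @return An object of class `repository_metadata`.
#' @export
repository_metadata <- function(repositories, usage) {
  repositories <- tibble::as_tibble(repositories)
  stopifnot(all(c("repository", "presence_weight", "visits_weight") %in% names(repositories)))
  repositories$repository <- as.character(repositories$repository)
  for (col in c("presence_weight", "visits_weight")) {
    w <- as.numeric(repositories[[col]])
    if (any(is.na(w) | w < 0)) abort_config(sprintf("%s must be non-negative", col))
    if (abs(sum(w) - 1) > 1e-9) {
      abort_config(sprintf("%s must sum to 1 (got %.12g)", col, sum(w)))
    }
    repositories[[col]] <- w
  }

  usage <- tibble::as_tibble(usage)
  stopifnot(all(c("ontology", "repository", "presence", "visits") %in% names(usage)))
  usage$ontology <- toupper(as.character(usage$ontology))
  usage$repository <- as.character(usage$repository)
  if (!all(usage$repository %in% repositories$repository)) {
    abort_config("usage rows reference a repository not in the repository table")
  }
  if (!all(usage$presence %in% c(0, 1))) {
    abort_config("presence values must be exactly 0 or 1")
  }
  usage$presence <- as.integer(usage$presence)
  usage$visits <- as.integer(usage$visits)
  if (any(is.na(usage$visits) | usage$visits < 0)) {
    abort_config("visit counts must be non-negative integers")
  }
  structure(list(repositories = repositories, usage = usage),
            class = "repository_metadata")
}

#' @export
print.repository_metadata <- function(x, ...) {
  cat(sprintf("<repository_metadata> %d repositories, %d ontologies\n",
              nrow(x$repositories), dplyr::n_distinct(x$usage$ontology)))
  print(x$repositories)
  invisible(x)
}

#' Read repository metadata from a tab-separated file
#'
#' The file has two blocks separated by one blank line. The first block has
#' header `repository\tpresence_weight\tvisits_weight` and one row per
#' repository. The second block has header
#' `ontology\t<REPO>.presence\t<REPO>.visits\t...` (two columns per
#' repository, in the order of the first block) and one row per ontology.
#'
#' @param path Path to the metadata file.
#' @return A [repository_metadata()].
#' @export
load_repository_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read metadata '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- match(TRUE, !nzchar(trimws(lines)))
  if (is.na(blank)) abort_config(sprintf("'%s': expected two blocks separated by a blank line", path))

  b1 <- lines[seq(2L, blank - 1L)] # skip header row
  p1 <- strsplit(b1, "\t", fixed = TRUE)
  repositories <- tibble::tibble(
    repository = vapply(p1, `[[`, character(1), 1),
    presence_weight = as.numeric(vapply(p1, `[[`, character(1), 2)),
    visits_weight = as.numeric(vapply(p1, `[[`, character(1), 3))
  )

  b2 <- if (blank < length(lines)) lines[seq(blank + 1L, length(lines))] else character(0)
  b2 <- b2[nzchar(trimws(b2))]
  if (length(b2) < 1) abort_config(sprintf("'%s': missing per-ontology block", path))
  hdr2 <- strsplit(b2[[1]], "\t", fixed = TRUE)[[1]]
  expected <- c("ontology", as.vector(rbind(paste0(repositories$repository, ".presence"),
                                            paste0(repositories$repository, ".visits"))))
  if (!identical(hdr2, expected)) {
    abort_config(sprintf("'%s': per-ontology header must be: %s",
                         path, paste(expected, collapse = ", ")))
  }
  rows <- lapply(b2[-1], function(ln) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(p) != length(expected)) {
      abort_config(sprintf("'%s': row '%s' has %d fields, expected %d",
                           path, p[[1]], length(p), length(expected)))
    }
    tibble::tibble(
      ontology = p[[1]],
      repository = repositories$repository,
      presence = as.numeric(p[seq(2, length(p), by = 2)]),
      visits = as.numeric(p[seq(3, length(p), by = 2)])
    )
  })
  repository_metadata(repositories, dplyr::bind_rows(rows))
}

#' Write repository metadata in the tab-separated dialect
#'
#' @param x A [repository_metadata()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repository_metadata <- function(x, path) {
  stopifnot(inherits(x, "repository_metadata"))
  reps <- x$repositories
  b1 <- c("repository\tpresence_weight\tvisits_weight",
          sprintf("%s\t%.10g\t%.10g", reps$repository,
                  reps$presence_weight, reps$visits_weight))
  hdr2 <- c("ontology", as.vector(rbind(paste0(reps$repository, ".presence"),
                                        paste0(reps$repository, ".visits"))))
  wide <- x$usage |>
    dplyr::arrange(.data$ontology,
                   match(.data$repository, reps$repository))
  onts <- unique(wide$ontology)
  rows <- vapply(onts, function(o) {
    u <- wide[wide$ontology == o, ]
    u <- u[match(reps$repository, u$repository), ]
    paste(c(o, as.vector(rbind(u$presence, u$visits))), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(b1, "", paste(hdr2, collapse = "\t"), rows), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}
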
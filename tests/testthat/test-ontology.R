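test_that("ontology constructor enforces class invariants", {
  expect_error(
    ontology(tibble::tibble(id = c("A", "A"), pref_label = c("x", "y")), "T"),
    "duplicate class id 'A'")
  expect_error(
    ontology(tibble::tibble(id = "A", pref_label = "   "), "T"),
    "empty preferred label")
  expect_error(
    ontology(tibble::tibble(id = "A", pref_label = "x", parents = "GHOST"), "T"),
    "parent id 'GHOST' does not resolve")
  expect_error(
    ontology(tibble::tibble(id = character(0), pref_label = character(0)), "T"),
    "at least one class")
  # duplicate synonyms collapse after case-folding
  o <- ontology(tibble::tibble(id = "A", pref_label = "x",
                               synonyms = "Spine|spine|backbone"), "T")
  expect_equal(o$classes$synonyms[[1]], c("Spine", "backbone"))
  expect_equal(o$acronym, "T")
  expect_equal(ontology(tibble::tibble(id = "A", pref_label = "x"), "lower")$acronym,
               "LOWER")
})

test_that("declared size defaults to loaded classes and can only grow", {
  cls <- tibble::tibble(id = c("A", "B"), pref_label = c("x", "y"))
  expect_equal(ontology(cls, "T")$declared_size, 2L)
  expect_equal(ontology(cls, "T", declared_size = 120000)$declared_size, 120000L)
  expect_error(ontology(cls, "T", declared_size = 1), "declared_size")
})

test_that("depth is the shortest parent path, 1-based at the root", {
  # diamond: C is_a R and is_a B, so its shortest route to the root wins
  o <- ontology(tibble::tibble(
    id = c("R", "A", "B", "C"),
    pref_label = c("r", "a", "b", "c"),
    parents = c("", "R", "A", "R|B")
  ), "T")
  d <- setNames(o$classes$depth, o$classes$id)
  expect_equal(d[["R"]], 1L)
  expect_equal(d[["C"]], 2L)
  # isolated class
  expect_equal(ontology(tibble::tibble(id = "X", pref_label = "x"), "T")$classes$depth, 1L)
  # chain of 12
  chain <- ontology(tibble::tibble(
    id = paste0("N", 1:12), pref_label = paste("level", 1:12),
    parents = c("", paste0("N", 1:11))
  ), "T")
  expect_equal(max(chain$classes$depth), 12L)
  # idempotence
  expect_identical(compute_depths(chain)$classes$depth, chain$classes$depth)
})

test_that("depth relations hold on a random DAG", {
  set.seed(42)
  n <- 30
  parents <- vapply(seq_len(n), function(i) {
    if (i == 1 || runif(1) < 0.2) "" else {
      paste(sprintf("N%d", sample(i - 1, min(i - 1, sample(1:2, 1)))), collapse = "|")
    }
  }, character(1))
  o <- ontology(tibble::tibble(id = sprintf("N%d", 1:n),
                               pref_label = sprintf("node %d", 1:n),
                               parents = parents), "T")
  cl <- o$classes
  for (i in seq_len(n)) {
    p <- cl$parents[[i]]
    if (length(p) == 0) {
      expect_equal(cl$depth[[i]], 1L)
    } else {
      pd <- cl$depth[match(p, cl$id)]
      expect_equal(cl$depth[[i]], 1L + min(pd))
      expect_lte(cl$depth[[i]], 1L + max(pd))
    }
  }
})

test_that("parent cycles are reported with a witness cycle", {
  expect_error(
    ontology(tibble::tibble(id = c("A", "B"), pref_label = c("a", "b"),
                            parents = c("B", "A")), "T"),
    "cycle in parent links: .*A.*")
})

test_that("load_obo parses stanzas, counts tags, and computes depth", {
  obo <- c(
    "format-version: 1.2", "ontology: toyobo", "",
    "[Term]", "id: A", "name: leucocyte",
    "def: \"a white blood cell\" [PMID:1]",
    "synonym: \"white blood cell\" EXACT []",
    "synonym: \"wbc\" RELATED []",
    "xref: UMLS:C1", "xref: MESH:D2", "xref: SCTID:3",
    "",
    "[Term]", "id: B", "name: lymphocyte", "is_a: A ! leucocyte",
    "",
    "[Term]", "id: C", "name: t cell", "is_a: B",
    "",
    "[Term]", "id: D", "name: gone", "is_obsolete: true"
  )
  path <- withr::local_tempfile(lines = obo, fileext = ".obo")
  o <- load_obo(path)
  expect_equal(o$acronym, "TOYOBO")
  expect_equal(nrow(o$classes), 3) # obsolete term excluded
  a <- o$classes[o$classes$id == "A", ]
  expect_equal(a$synonyms[[1]], c("white blood cell", "wbc"))
  expect_equal(a$definition_count, 1L)
  expect_gte(a$property_count, 3L)
  expect_equal(o$classes$depth[match(c("A", "B", "C"), o$classes$id)], 1:3)

  # single root
  p1 <- withr::local_tempfile(lines = c("[Term]", "id: A", "name: leucocyte"),
                              fileext = ".obo")
  o1 <- load_obo(p1)
  expect_equal(nrow(o1$classes), 1)
  expect_equal(o1$classes$depth, 1L)
  expect_equal(o1$declared_size, 1L)

  # nameless term is skipped with a warning
  p2 <- withr::local_tempfile(
    lines = c("[Term]", "id: X", "", "[Term]", "id: Y", "name: kept"),
    fileext = ".obo")
  expect_warning(o2 <- load_obo(p2), "no name")
  expect_equal(o2$classes$id, "Y")

  # dangling is_a names the offending id
  p3 <- withr::local_tempfile(
    lines = c("[Term]", "id: X", "name: x", "is_a: NOPE"), fileext = ".obo")
  expect_error(load_obo(p3), "NOPE")
  expect_error(load_obo(file.path(tempdir(), "absent.obo")), "cannot read")
})

test_that("dictionary dialect round-trips and validates", {
  lines <- c("acronym=TOY", "declared_size=120000", "",
             "T:1\tbig concept\tsyn one|syn two\t1\t3\t",
             "T:2\tsmall concept\t\t0\t0\tT:1")
  path <- withr::local_tempfile(lines = lines, fileext = ".txt")
  o <- load_dictionary(path)
  expect_equal(o$declared_size, 120000L)
  expect_equal(nrow(o$classes), 2)
  expect_equal(o$classes$synonyms[[1]], c("syn one", "syn two"))
  expect_equal(o$classes$depth, c(1L, 2L))

  # round-trip: write then load yields field-identical ontologies
  out <- withr::local_tempfile(fileext = ".txt")
  write_dictionary(o, out)
  o2 <- load_dictionary(out)
  expect_identical(o2$acronym, o$acronym)
  expect_identical(o2$declared_size, o$declared_size)
  expect_identical(as.data.frame(o2$classes), as.data.frame(o$classes))

  # record with two parents
  lines3 <- c("acronym=TOY", "", "X\tx\t\t0\t0\t",
              "Y\ty\t\t0\t0\t", "Z\tz\t\t0\t0\tX|Y")
  p3 <- withr::local_tempfile(lines = lines3, fileext = ".txt")
  expect_length(load_dictionary(p3)$classes$parents[[3]], 2)

  # empty class section
  p4 <- withr::local_tempfile(lines = c("acronym=TOY", ""), fileext = ".txt")
  expect_error(load_dictionary(p4), "at least one class")

  # duplicate id and missing label carry the offending id / line number
  p5 <- withr::local_tempfile(lines = c("acronym=T", "", "A\ta\t\t0\t0\t",
                                        "A\tb\t\t0\t0\t"), fileext = ".txt")
  expect_error(load_dictionary(p5), "duplicate class id 'A'")
  p6 <- withr::local_tempfile(lines = c("acronym=T", "", "A\ta\t\t0\t0\t",
                                        "B\t\t\t0\t0\t"), fileext = ".txt")
  expect_error(load_dictionary(p6), "line 4")
})

test_that("repository metadata validates weights, flags and defaults", {
  reps <- tibble::tibble(repository = c("R1", "R2"),
                         presence_weight = c(0.5, 0.5),
                         visits_weight = c(0.7, 0.3))
  usage <- tibble::tibble(ontology = "ONT", repository = c("R1", "R2"),
                          presence = c(1, 0), visits = c(10, 0))
  m <- repository_metadata(reps, usage)
  expect_s3_class(m, "repository_metadata")

  bad_w <- reps; bad_w$presence_weight <- c(0.5, 0.6)
  expect_error(repository_metadata(bad_w, usage), "sum to 1")
  bad_p <- usage; bad_p$presence <- c(2, 0)
  expect_error(repository_metadata(reps, bad_p), "exactly 0 or 1")
  bad_v <- usage; bad_v$visits <- c(-1, 0)
  expect_error(repository_metadata(reps, bad_v), "non-negative")

  # an ontology absent from the table scores presence 0 / visits 0
  fx <- worked_examples("table3")
  ghost <- ontology(tibble::tibble(id = "G", pref_label = "ghost"), "GHOST")
  expect_equal(acceptance(ghost, m), 0)

  # file round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_repository_metadata(m, path)
  m2 <- load_repository_metadata(path)
  expect_equal(m2$repositories, m$repositories)
  expect_equal(dplyr::arrange(m2$usage, ontology, repository),
               dplyr::arrange(m$usage, ontology, repository))
})

test_that("keyword documents keep spans that reconstruct the raw text", {
  doc <- input_document("blood cell,  eye , chronic fatigue syndrome",
                        type = "keywords")
  kw <- doc$keywords
  expect_equal(kw$keyword, c("blood cell", "eye", "chronic fatigue syndrome"))
  # spans point at the exact keyword text and are disjoint and ordered
  expect_equal(substring(doc$raw_text, kw$start, kw$end), kw$keyword)
  expect_true(all(diff(kw$start) > 0))
  expect_true(all(kw$end[-nrow(kw)] < kw$start[-1]))
  # re-concatenation with ", " reproduces the raw text modulo whitespace
  expect_equal(paste(kw$keyword, collapse = ", "),
               gsub("\\s+", " ", gsub(" *, *", ", ", doc$raw_text)))
  expect_error(input_document(" , ", type = "keywords"), "no keywords")
})
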
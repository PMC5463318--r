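cfg <- recommender_config()

test_that("annotation scores follow the type score and multi-word bonus", {
  ann <- tibble::tibble(match_type = c("PREF", "SYN", "SYN", "PREF"),
                        annotated_words = c(2L, 1L, 3L, 1L))
  expect_equal(annotation_score(ann, cfg), c((10 + 3) * 2, 5, (5 + 3) * 3, 10))
})

test_that("overlap resolution keeps the best annotation per fragment", {
  fx <- worked_examples("table3")
  ann <- annotate(fx$doc, fx$ontologies)
  sel <- select_annotations(ann, cfg)
  expect_equal(sort(sel$selected$class_id), c("SCT:BC", "SCT:PLT"))
  expect_equal(sel$raw_points, 31)
  expect_equal(nrow(sel$discarded), 4)

  # single annotation selects itself
  one <- ann[1, ]
  expect_equal(nrow(select_annotations(one, cfg)$selected), 1)

  # identical span: PREF(10) beats SYN(5)
  two <- tibble::tibble(ontology = "T", class_id = c("P", "S"),
                        match_type = c("PREF", "SYN"), start = 1L, end = 4L,
                        matched_text = "cell", annotated_words = 1L)
  s2 <- select_annotations(two, cfg)
  expect_equal(s2$selected$class_id, "P")
  expect_equal(s2$discarded$class_id, "S")

  expect_equal(select_annotations(ann[0, ], cfg)$raw_points, 0)
})

test_that("selection invariants hold and match an independent greedy sweep", {
  for (seed in 1:25) {
    ann <- random_annotations(seed, n = sample(2:12, 1))
    sel <- select_annotations(ann, cfg)
    s <- sel$selected
    # no two selected annotations overlap
    if (nrow(s) > 1) {
      for (i in 2:nrow(s)) expect_gt(s$start[[i]], s$end[[i - 1]])
    }
    # raw points are the sum over selected
    expect_equal(sel$raw_points, sum(s$score))
    # every discarded annotation overlaps a selected one of >= score
    d <- sel$discarded
    for (i in seq_len(nrow(d))) {
      over <- s$start <= d$end[[i]] & d$start[[i]] <= s$end
      expect_true(any(over & s$score >= d$score[[i]]))
    }
    # equality with the independently coded greedy sweep
    expect_equal(sel$raw_points, bf_select_points(ann, cfg))
  }
})

test_that("the pool maximum dominates and sums over disjoint coverage", {
  a1 <- tibble::tibble(ontology = "A", class_id = "A1", match_type = "PREF",
                       start = 1L, end = 10L, matched_text = "x",
                       annotated_words = 2L) # 26
  a2 <- tibble::tibble(ontology = "B", class_id = "B1", match_type = "PREF",
                       start = 20L, end = 24L, matched_text = "y",
                       annotated_words = 1L) # 10
  expect_equal(max_coverage_points(a1, cfg), 26)
  expect_equal(max_coverage_points(dplyr::bind_rows(a1, a2), cfg), 36)
  # same span: the better one wins
  a3 <- a2; a3$start <- 1L; a3$end <- 10L
  expect_equal(max_coverage_points(dplyr::bind_rows(a1, a3), cfg), 26)
  expect_equal(max_coverage_points(a1[0, ], cfg), 0)
})

test_that("coverage self-normalizes and respects term frequency", {
  fx <- worked_examples("table3")
  ann <- annotate(fx$doc, fx$ontologies)
  ctx <- normalization_context(fx$ontologies, ann, config = cfg)
  expect_equal(ctx$max_coverage_points, 31)
  expect_equal(coverage(fx$ontologies$SNOMEDCT, ann, ctx, cfg), 1.0)
  expect_error(coverage(fx$ontologies$SNOMEDCT, ann,
                        structure(list(max_coverage_points = 0),
                                  class = "normalization_context"), cfg),
               "no candidate annotates")
})

test_that("acceptance combines presence and normalized visits", {
  reps <- tibble::tibble(repository = "R1", presence_weight = 1, visits_weight = 1)
  usage <- tibble::tibble(ontology = c("HI", "MID", "LO"), repository = "R1",
                          presence = c(1, 1, 0), visits = c(100, 50, 0))
  meta <- repository_metadata(reps, usage)
  hi <- ontology(tibble::tibble(id = "a", pref_label = "x"), "HI")
  mid <- ontology(tibble::tibble(id = "a", pref_label = "x"), "MID")
  lo <- ontology(tibble::tibble(id = "a", pref_label = "x"), "LO")
  expect_equal(acceptance(hi, meta, config = cfg), 1.0)
  expect_equal(acceptance(lo, meta, config = cfg), 0.0)
  # presence 1, visits at half the pool maximum, factor weights 0.5/0.5
  expect_equal(acceptance(mid, meta, config = cfg), 0.5 * 1 + 0.5 * 0.5)
  # zero-visit repository contributes nothing rather than dividing by zero
  usage0 <- usage; usage0$visits <- 0
  expect_equal(acceptance(hi, repository_metadata(reps, usage0), config = cfg), 0.5)
  expect_equal(acceptance(hi, NULL, config = cfg), 0)
})

test_that("per-annotation detail saturates at the k constants", {
  expect_equal(detail_annotation(1, 2, 7, cfg), (1 + 0.5 + 0.7) / 3)
  expect_equal(detail_annotation(0, 0, 0, cfg), 0)
  expect_equal(detail_annotation(3, 9, 25, cfg), 1)
  expect_equal(detail_annotation(c(1, 0), c(2, 0), c(7, 0), cfg),
               c((1 + 0.5 + 0.7) / 3, 0))
})

test_that("ontology detail reproduces the worked two-class examples", {
  fx <- worked_examples("table4")
  ann <- annotate(fx$doc, fx$ontologies)
  d1 <- detail(fx$ontologies$O1,
               select_annotations(ann[ann$ontology == "O1", ], cfg), cfg)
  d2 <- detail(fx$ontologies$O2,
               select_annotations(ann[ann$ontology == "O2", ], cfg), cfg)
  expect_equal(round_half_up(d1, 2), 0.87)
  expect_equal(round_half_up(d2, 2), 0.13)
  expect_equal(d1, (((1 + 2/4 + 7/10) / 3) + 1) / 2)
  expect_equal(d2, (((0 + 1/4 + 3/10) / 3) + ((0 + 0 + 2/10) / 3)) / 2)

  sat <- ontology(tibble::tibble(id = "s", pref_label = "alpha",
                                 synonyms = "a|b|c|d",
                                 definition_count = 2, property_count = 12), "SAT")
  a <- annotate("alpha", sat)
  expect_equal(detail(sat, select_annotations(a, cfg), cfg), 1.0)
  expect_equal(detail(sat, select_annotations(a[0, ], cfg), cfg), 0)
})

test_that("specialization rewards depth and penalizes size", {
  fx <- worked_examples("table5")
  ann <- annotate(fx$doc, fx$ontologies)
  r1 <- specialization(fx$ontologies$O1, ann[ann$ontology == "O1", ],
                       config = cfg, raw = TRUE)
  r2 <- specialization(fx$ontologies$O2, ann[ann$ontology == "O2", ],
                       config = cfg, raw = TRUE)
  expect_equal(r1, ((10 + 2 * 5) + (5 + 2 * 3)) / log10(120000))
  expect_equal(r2, ((5 + 2 * 6) + (10 + 2 * 12)) / log10(800))
  expect_equal(round_half_up(r1, 2), 6.10)
  # pool normalization: the most specialized candidate scores 1
  ctx <- normalization_context(fx$ontologies, ann, config = cfg)
  expect_equal(specialization(fx$ontologies$O2, ann[ann$ontology == "O2", ],
                              ctx, cfg), 1.0)
  expect_equal(specialization(fx$ontologies$O1, ann[ann$ontology == "O1", ],
                              ctx, cfg), r1 / r2)

  tiny <- ontology(tibble::tibble(id = "t", pref_label = "x"), "TINY")
  expect_error(specialization(tiny, ann[0, ], config = cfg, raw = TRUE),
               "declared_size >= 2")
})

test_that("specialization uses all annotations, coverage/detail only selected", {
  # two same-span annotations: selection keeps one, specialization sums both
  ont <- ontology(tibble::tibble(
    id = c("P", "S"), pref_label = c("melanoma", "skin melanoma"),
    synonyms = c("", "melanoma")
  ), "ALL", declared_size = 100)
  ann <- annotate("melanoma", ont)
  expect_equal(nrow(ann), 2)
  sel <- select_annotations(ann, cfg)
  expect_equal(nrow(sel$selected), 1)
  expect_equal(sel$raw_points, 10)
  raw <- specialization(ont, ann, config = cfg, raw = TRUE)
  expect_equal(raw, ((10 + 2 * 1) + (5 + 2 * 1)) / log10(100))
})

test_that("all criterion scores stay within [0,1] on random pools", {
  for (seed in c(3, 7, 11, 19)) {
    pool <- random_pool(seed)
    ann <- annotate(pool$doc, pool$ontologies)
    keep <- pool$ontologies[names(pool$ontologies) %in% ann$ontology]
    if (length(keep) == 0) next
    ctx <- normalization_context(keep, ann, config = cfg)
    specs <- vapply(keep, function(o) {
      oa <- ann[ann$ontology == o$acronym, ]
      c(coverage(o, oa, ctx, cfg),
        detail(o, select_annotations(oa, cfg), cfg),
        specialization(o, oa, ctx, cfg))
    }, numeric(3))
    expect_true(all(specs >= 0 & specs <= 1))
    # the pool maximum is attained (by at least one candidate)
    expect_equal(max(specs[3, ]), 1.0)
  }
})

test_that("adding a class covering new text never lowers raw coverage", {
  for (seed in c(5, 9)) {
    pool <- random_pool(seed)
    ont <- pool$ontologies[[1]]
    ann <- annotate(pool$doc, ont)
    before <- select_annotations(ann, cfg)$raw_points
    # a class matching a token the ontology does not currently cover
    grown <- ontology(
      dplyr::bind_rows(
        ont$classes,
        tibble::tibble(id = "NEW", pref_label = "filler", synonyms = list(character(0)),
                       definition_count = 0L, property_count = 0L,
                       parents = list(character(0)))),
      acronym = ont$acronym, declared_size = ont$declared_size + 1)
    after <- select_annotations(annotate(pool$doc, grown), cfg)$raw_points
    expect_gte(after, before)
  }
})
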
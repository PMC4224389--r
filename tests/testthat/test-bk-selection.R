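test_that("selection reproduces the hand-traced two-stage ledger", {
  f <- make_selection_fixture()
  res <- select_background_knowledge(f$s, f$t, list(f$x1, f$x2, f$x3, f$x4),
                                     k = 0.1)
  led <- as.data.frame(res$candidates)
  expect_identical(n_mappings(res$baseline), 4L)
  expect_equal(led$individual_gain, c(0.5, 0.5, 0.25, 0))
  # stage 1: X4 discarded; ranking X1 < X2 by lexicographic tie-break
  expect_identical(led$reason[led$bk_id == "X4"],
                   "stage1_gain_below_threshold")
  expect_identical(led$rank, c(1L, 2L, 3L, NA))
  # stage 2: X1 selected (gain 2/4), X2 now fully redundant (0/6 < k),
  # X3 still complements (1/6 >= k)
  expect_identical(res$selected, c("X1", "X3"))
  expect_equal(led$selected_gain[led$bk_id == "X1"], 0.5)
  expect_identical(led$reason[led$bk_id == "X2"],
                   "stage2_gain_below_threshold")
  expect_true(is.na(led$selected_gain[led$bk_id == "X2"]))
  expect_equal(led$selected_gain[led$bk_id == "X3"], 1 / 6)
  expect_identical(n_mappings(res$combined), 7L)
  # combined contains the baseline plus every selected alignment
  expect_true(all(align_keys(res$baseline) %in% align_keys(res$combined)))
  for (id in res$selected)
    expect_true(all(align_keys(res$alignments[[id]]) %in%
                      align_keys(res$combined)))
})

test_that("the threshold removes strictly below k: gain == k survives", {
  f <- make_selection_fixture()
  # X1's gain is exactly 0.5 at both stages
  res <- select_background_knowledge(f$s, f$t, list(f$x1), k = 0.5)
  expect_identical(res$selected, "X1")
  expect_equal(res$candidates$selected_gain[1], 0.5)
  res2 <- select_background_knowledge(f$s, f$t, list(f$x1), k = 0.51)
  expect_identical(res2$selected, character(0))
  expect_identical(res2$candidates$reason[1], "stage1_gain_below_threshold")
  expect_identical(n_mappings(res2$combined), n_mappings(res2$baseline))
})

test_that("degenerate selection inputs behave as specified", {
  f <- make_selection_fixture()
  res <- select_background_knowledge(f$s, f$t, list(), k = 0.02)
  expect_identical(n_mappings(res$combined), n_mappings(res$baseline))
  expect_identical(res$selected, character(0))
  s0 <- quick_lex("S", list(s1 = c(label = "only here")))
  t0 <- quick_lex("T", list(t1 = c(label = "only there")))
  expect_error(select_background_knowledge(s0, t0, list(f$x1)),
               "baseline .* empty|empty")
})

test_that("selection is deterministic", {
  f <- make_selection_fixture()
  srcs <- list(f$x2, f$x1, f$x3, f$x4)  # scrambled input order
  r1 <- select_background_knowledge(f$s, f$t, srcs, k = 0.1)
  r2 <- select_background_knowledge(f$s, f$t, srcs, k = 0.1)
  expect_identical(r1$selected, r2$selected)
  expect_equal(as.data.frame(r1$candidates), as.data.frame(r2$candidates))
  expect_equal(as.data.frame(r1$combined$mappings),
               as.data.frame(r2$combined$mappings))
  # tie between X1 and X2 resolves lexicographically regardless of order
  expect_identical(r1$selected[1], "X1")
})

test_that("selected gains respect the threshold on random problems", {
  for (sd in 1:5) {
    set.seed(sd)
    p <- generate_problem(problem_spec(
      n_shared = 60, direct_fraction = 0.5, n_source_only = 5,
      n_target_only = 5, seed = sd,
      sources = lapply(1:4, function(i)
        bk_source_spec(sprintf("B%d", i),
                       bridge_fraction = stats::runif(1, 0, 0.8)))))
    res <- select_background_knowledge(p$s, p$t, p$sources, k = 0.05)
    led <- as.data.frame(res$candidates)
    expect_true(all(led$selected_gain[led$selected] >= 0.05))
    expect_true(all(led$individual_gain[
      led$reason == "stage1_gain_below_threshold"] < 0.05))
    expect_gte(n_mappings(res$combined), n_mappings(res$baseline))
    # greedy does at least as well as the best single source
    best_single <- max(vapply(res$alignments, function(a)
      n_mappings(align_union(res$baseline, a)), numeric(1)))
    expect_gte(n_mappings(res$combined), best_single)
  }
})

test_that("prefiltering drops self, identical and low-overlap sources", {
  shared <- sprintf("common name %d", 1:6)
  mk <- function(id, names_) quick_lex(id, stats::setNames(
    lapply(names_, function(n) c(label = n)),
    paste0(id, "_", seq_along(names_))))
  s <- mk("S", shared)
  t <- mk("T", shared)
  same_id <- mk("S", c("whatever"))
  clone <- lexicon("CLONE", classes = s$classes, entries = s$entries,
                   normalize = FALSE)
  disjoint <- mk("D", c("nothing in common"))
  hi <- mk("HI", shared[1:4])        # high overlap with both
  lo <- mk("LO", shared[1])          # low overlap
  lo_score <- similarity_score(s, t, lo)
  hi_score <- similarity_score(s, t, hi)
  expect_true(lo_score > 0 && hi_score > lo_score)
  kept <- prefilter_sources(s, t, list(same_id, clone, disjoint, hi, lo),
                            min_score = 1e-4)
  expect_identical(vapply(kept, function(x) x$ontology_id, character(1)),
                   c("HI", "LO"))
  # a threshold between the two scores keeps only the stronger source
  kept2 <- prefilter_sources(s, t, list(hi, lo),
                             min_score = (lo_score + hi_score) / 2)
  expect_identical(vapply(kept2, function(x) x$ontology_id, character(1)),
                   "HI")
})

test_that("greedy matches the exhaustive optimum for disjoint sources", {
  for (sd in 1:5) {
    set.seed(sd)
    p <- generate_problem(problem_spec(
      n_shared = 40, direct_fraction = 0.5, disjoint_bridges = TRUE,
      seed = 100 + sd,
      sources = lapply(1:4, function(i)
        bk_source_spec(sprintf("B%d", i), bridge_n = sample(0:4, 1)))))
    greedy <- select_background_knowledge(p$s, p$t, p$sources, k = 1e-9)
    opt <- optimal_source_subset(p$s, p$t, p$sources,
                                 baseline = greedy$baseline)
    mapped <- length(unique(greedy$combined$mappings$source)) +
      length(unique(greedy$combined$mappings$target))
    expect_identical(mapped, opt$best_mapped_classes)
  }
})
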
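test_that("direct matching scores shared names by the weight product", {
  s <- quick_lex("S", list(
    s1 = c(label = "heart"),
    s2 = c(label = "cardiac muscle", exact = "heart muscle"),
    s3 = c(label = "spleen")))
  t <- quick_lex("T", list(
    t1 = c(label = "heart"),
    t2 = c(label = "heart muscle")))
  a <- lexical_match(s, t)
  m <- as.data.frame(a$mappings)
  expect_identical(nrow(m), 2L)
  expect_equal(m$similarity[m$source == "s1" & m$target == "t1"], 1.0)
  # label (1.0) x exact synonym (0.95)
  expect_equal(m$similarity[m$source == "s2" & m$target == "t2"], 0.95)
})

test_that("disjoint vocabularies and self-matching behave as specified", {
  s <- quick_lex("S", list(s1 = c(label = "heart")))
  t <- quick_lex("T", list(t1 = c(label = "lung")))
  expect_identical(n_mappings(lexical_match(s, t)), 0L)
  expect_error(lexical_match(s, s), "itself")
})

test_that("several shared names keep the best similarity", {
  s <- quick_lex("S", list(s1 = c(label = "a", related = "b")))
  t <- quick_lex("T", list(t1 = c(related = "a", label = "b")))
  a <- lexical_match(s, t)
  # both shared names score 1.0 * 0.85; max kept, single mapping
  expect_identical(n_mappings(a), 1L)
  expect_equal(a$mappings$similarity, 0.85)
})

test_that("direct matching is symmetric up to orientation", {
  set.seed(21)
  vocab <- replicate(40, paste(sample(letters, 5), collapse = ""))
  for (i in 1:10) {
    s <- random_lexicon("S", sample(3:20, 1), vocab)
    t <- random_lexicon("T", sample(3:20, 1), vocab)
    align_equal(lexical_match(s, t), align_reverse(lexical_match(t, s)))
  }
})

test_that("mediated matching bridges classes through a background class", {
  s <- quick_lex("S", list(s1 = c(label = "musculus cordis")))
  t <- quick_lex("T", list(t1 = c(label = "heart muscle")))
  x <- quick_lex("X", list(x1 = c(label = "cardiac muscle",
                                  exact = "musculus cordis",
                                  exact = "heart muscle")))
  expect_identical(n_mappings(lexical_match(s, t)), 0L)
  a <- mediated_match(s, t, x)
  expect_identical(n_mappings(a), 1L)
  # both bridges are label x exact = 0.95; min rule keeps 0.95
  expect_equal(a$mappings$similarity, 0.95)
  expect_identical(a$mappings$provenance, "mediated:X")
})

test_that("mediated similarity is the minimum of the two bridge legs", {
  s <- quick_lex("S", list(s1 = c(label = "alpha")))
  t <- quick_lex("T", list(t1 = c(label = "beta")))
  x <- quick_lex("X", list(x1 = c(label = "alpha", exact = "beta")))
  a <- mediated_match(s, t, x)
  # legs: 1.0 * 1.0 = 1.0 and 1.0 * 0.95 = 0.95 -> min = 0.95
  expect_equal(a$mappings$similarity, 0.95)
  # product combiner multiplies the legs instead
  ap <- mediated_match(s, t, x, combine = "product")
  expect_equal(ap$mappings$similarity, 0.95)
  x2 <- quick_lex("X", list(x1 = c(exact = "alpha", exact = "beta")))
  expect_equal(mediated_match(s, t, x2)$mappings$similarity, 0.95)
  expect_equal(mediated_match(s, t, x2, combine = "product")
               $mappings$similarity, 0.95^2)
})

test_that("an empty background lexicon yields no mediated mappings", {
  s <- quick_lex("S", list(s1 = c(label = "heart")))
  t <- quick_lex("T", list(t1 = c(label = "heart")))
  expect_identical(n_mappings(mediated_match(s, t, lexicon("X"))), 0L)
  expect_error(mediated_match(s, t, quick_lex("S", list(z = c(label = "q")))),
               "differ")
})

test_that("multiple bridging classes keep the best mediated similarity", {
  s <- quick_lex("S", list(s1 = c(label = "alpha", related = "gamma")))
  t <- quick_lex("T", list(t1 = c(label = "beta", related = "gamma")))
  x <- quick_lex("X", list(
    x1 = c(related = "alpha", related = "beta"),   # min(0.85, 0.85)
    x2 = c(label = "gamma")))                      # min(0.85, 0.85) via gamma
  a <- mediated_match(s, t, x)
  expect_identical(n_mappings(a), 1L)
  expect_equal(a$mappings$similarity, 0.85)
})

test_that("a background sub-lexicon of both inputs adds no new mappings", {
  set.seed(33)
  vocab <- replicate(30, paste(sample(letters, 6), collapse = ""))
  for (i in 1:10) {
    shared_names <- sample(vocab, 8)
    s <- quick_lex("S", stats::setNames(
      lapply(1:8, function(j) c(label = shared_names[j])),
      paste0("s", 1:8)))
    t <- quick_lex("T", stats::setNames(
      lapply(1:8, function(j) c(label = shared_names[j])),
      paste0("t", 1:8)))
    pick <- sample(1:8, 4)
    x <- quick_lex("X", stats::setNames(
      lapply(pick, function(j) c(label = shared_names[j])),
      paste0("x", seq_along(pick))))
    med <- mediated_match(s, t, x)
    dir <- lexical_match(s, t)
    expect_true(all(align_keys(med) %in% align_keys(dir)))
  }
})

test_that("union keeps keys once with the higher similarity", {
  s <- quick_lex("S", list(s1 = c(label = "a"), s2 = c(label = "b"),
                           s3 = c(label = "c")))
  t <- quick_lex("T", list(t1 = c(label = "a"), t2 = c(label = "b"),
                           t3 = c(label = "c")))
  a <- alignment("S", "T", data.frame(source = c("s1", "s2"),
                                      target = c("t1", "t2"),
                                      similarity = c(0.9, 0.8)))
  b <- alignment("S", "T", data.frame(source = c("s1", "s3"),
                                      target = c("t1", "t3"),
                                      similarity = c(0.95, 0.7)))
  u <- align_union(a, b)
  expect_identical(n_mappings(u), 3L)
  expect_equal(u$mappings$similarity[u$mappings$source == "s1"], 0.95)
  align_equal(align_union(a, a), a)  # idempotent
  d1 <- alignment("S", "T", data.frame(source = "s2", target = "t3",
                                       similarity = 0.5))
  expect_identical(n_mappings(align_union(a, d1)), 3L)  # disjoint adds up
  expect_error(align_union(a, alignment("S", "U", NULL)), "pairs")
})

test_that("union is associative and commutative on mapping keys", {
  set.seed(44)
  vocab <- replicate(25, paste(sample(letters, 5), collapse = ""))
  s <- random_lexicon("S", 15, vocab)
  t <- random_lexicon("T", 15, vocab)
  mk <- function() {
    n <- sample(2:6, 1)
    alignment("S", "T", data.frame(
      source = sample(s$classes, n, replace = TRUE),
      target = sample(t$classes, n, replace = TRUE),
      similarity = round(stats::runif(n, 0.5, 1), 3)))
  }
  for (i in 1:10) {
    a <- mk(); b <- mk(); c <- mk()
    align_equal(align_union(align_union(a, b), c),
                align_union(a, align_union(b, c)))
    expect_setequal(align_keys(align_union(a, b)),
                    align_keys(align_union(b, a)))
  }
})

test_that("hash-join matching agrees with brute-force enumeration", {
  set.seed(55)
  vocab <- replicate(35, paste(sample(letters, 5), collapse = ""))
  for (i in 1:15) {
    s <- random_lexicon("S", sample(2:25, 1), vocab)
    t <- random_lexicon("T", sample(2:25, 1), vocab)
    x <- random_lexicon("X", sample(2:10, 1), vocab)
    align_equal(lexical_match(s, t), brute_lexical_match(s, t))
    align_equal(mediated_match(s, t, x), brute_mediated_match(s, t, x))
  }
})

test_that("alignments round-trip through TSV and OAEI RDF", {
  s <- quick_lex("S", list(s1 = c(label = "a"), s2 = c(label = "b")))
  t <- quick_lex("T", list(t1 = c(label = "a"), t2 = c(label = "b")))
  a <- lexical_match(s, t)
  tsv <- tempfile(fileext = ".tsv")
  write_alignment_tsv(a, tsv)
  align_equal(read_alignment_tsv(tsv), a)
  rdf <- tempfile(fileext = ".rdf")
  write_alignment_rdf(a, rdf)
  back <- read_alignment_rdf(rdf)
  expect_identical(back$source_ontology, "S")
  expect_setequal(align_keys(back), align_keys(a))
  expect_equal(back$mappings$similarity, a$mappings$similarity)
})

test_that("reference cells with unknown status are ignored on read", {
  ref <- read_alignment_rdf(fixture("anatomy_reference.rdf"))
  expect_identical(n_mappings(ref), 4L)  # the fifth cell has relation "?"
  expect_identical(ref$source_ontology, "anatomy_s")
})
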
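# Shared helpers: tiny lexicon builders, brute-force matching oracles and
# random-instance generators used by the property and acceptance tests.

fixture <- function(name) system.file("extdata", name, package = "ontobk")

# Build a lexicon from a named list: class id -> named character vector of
# names, with the vector names giving the provenance category.
#   quick_lex("S", list(s1 = c(label = "heart", exact = "cardiac organ")))
quick_lex <- function(id, entries) {
  w <- synonym_weights()
  rows <- lapply(names(entries), function(cls) {
    nm <- entries[[cls]]
    data.frame(class_id = cls, name = unname(nm),
               weight = unname(w[names(nm)]), provenance = names(nm),
               stringsAsFactors = FALSE)
  })
  lexicon(id, classes = names(entries), entries = do.call(rbind, rows))
}

# Named weight lookup per class: list(class_id -> named numeric weights).
name_weights_by_class <- function(lex) {
  e <- as.data.frame(lex$entries)
  out <- lapply(split(seq_len(nrow(e)), e$class_id),
                function(i) stats::setNames(e$weight[i], e$name[i]))
  # classes without entries still participate (with no names)
  for (cls in setdiff(lex$classes, names(out))) out[[cls]] <- numeric(0)
  out
}

# Best shared-name similarity between two weight-named vectors; 0 if none.
pair_similarity <- function(wa, wb) {
  shared <- intersect(names(wa), names(wb))
  if (!length(shared)) return(0)
  max(wa[shared] * wb[shared])
}

# All-pairs reference implementation of the direct lexical matcher.
brute_lexical_match <- function(s, t) {
  ws <- name_weights_by_class(s)
  wt <- name_weights_by_class(t)
  rows <- list()
  for (cs in names(ws)) {
    for (ct in names(wt)) {
      sim <- pair_similarity(ws[[cs]], wt[[ct]])
      if (sim > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          source = cs, target = ct, similarity = sim,
          stringsAsFactors = FALSE)
    }
  }
  alignment(s$ontology_id, t$ontology_id,
            if (length(rows)) do.call(rbind, rows) else NULL)
}

# Triple-enumeration reference implementation of mediated matching.
brute_mediated_match <- function(s, t, x, combine = "min") {
  ws <- name_weights_by_class(s)
  wt <- name_weights_by_class(t)
  wx <- name_weights_by_class(x)
  rows <- list()
  for (cs in names(ws)) {
    for (ct in names(wt)) {
      best <- 0
      for (cx in names(wx)) {
        p <- pair_similarity(ws[[cs]], wx[[cx]])
        q <- pair_similarity(wt[[ct]], wx[[cx]])
        if (p > 0 && q > 0) {
          cand <- if (combine == "min") min(p, q) else p * q
          if (cand > best) best <- cand
        }
      }
      if (best > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          source = cs, target = ct, similarity = best,
          stringsAsFactors = FALSE)
    }
  }
  alignment(s$ontology_id, t$ontology_id,
            if (length(rows)) do.call(rbind, rows) else NULL)
}

# Random lexicon over a shared vocabulary (collisions across lexicons are
# the point: they create matches).
random_lexicon <- function(id, n_classes, vocab, max_synonyms = 2) {
  provs <- c("label", "exact", "related")
  rows <- lapply(seq_len(n_classes), function(i) {
    k <- sample(0:max_synonyms, 1)
    nms <- sample(vocab, 1 + k)
    data.frame(class_id = sprintf("%s_%03d", id, i), name = nms,
               provenance = c("label", sample(provs[-1], k, replace = TRUE)),
               stringsAsFactors = FALSE)
  })
  e <- do.call(rbind, rows)
  w <- synonym_weights()
  e$weight <- unname(w[e$provenance])
  lexicon(id, classes = unique(e$class_id), entries = e)
}

align_equal <- function(a, b) {
  expect_identical(a$source_ontology, b$source_ontology)
  expect_identical(a$target_ontology, b$target_ontology)
  ma <- as.data.frame(a$mappings)[, c("source", "target", "similarity")]
  mb <- as.data.frame(b$mappings)[, c("source", "target", "similarity")]
  rownames(ma) <- rownames(mb) <- NULL
  expect_equal(ma, mb)
}

align_keys <- function(a) paste(a$mappings$source, a$mappings$target,
                                sep = "\t")

# Hand-traceable selection fixture: 4 directly matchable concept pairs
# (baseline |B| = 4) plus 4 concept pairs with disjoint names (u5..u8 in
# S vs v5..v8 in T) recoverable only through a background source that
# knows both names.
make_selection_fixture <- function() {
  s <- quick_lex("S", stats::setNames(c(
    lapply(1:4, function(i) c(label = sprintf("direct %d", i))),
    lapply(5:8, function(i) c(label = sprintf("u%d", i)))),
    paste0("s", 1:8)))
  t <- quick_lex("T", stats::setNames(c(
    lapply(1:4, function(i) c(label = sprintf("direct %d", i))),
    lapply(5:8, function(i) c(label = sprintf("v%d", i)))),
    paste0("t", 1:8)))
  bridge_src <- function(id, concepts) {
    quick_lex(id, stats::setNames(
      lapply(concepts, function(i)
        c(label = sprintf("u%d", i), exact = sprintf("v%d", i))),
      sprintf("%s_%d", id, seq_along(concepts))))
  }
  list(s = s, t = t,
       x1 = bridge_src("X1", 5:6),   # individual gain 2/4 = 0.5
       x2 = bridge_src("X2", 5:6),   # redundant with X1
       x3 = bridge_src("X3", 7),     # individual gain 1/4 = 0.25
       x4 = quick_lex("X4", list(z = c(label = "unrelated name"))))
}
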
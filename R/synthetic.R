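#' Specify a synthetic background-knowledge source
#'
#' @param id Source identifier (unique within a problem).
#' @param bridge_fraction Fraction of the non-direct shared concepts this
#'   source can bridge (mutually exclusive with \code{bridge_n}).
#' @param bridge_n Absolute number of bridged concepts (overrides
#'   \code{bridge_fraction}).
#' @param noise_rate Probability that a bridge class additionally carries
#'   a synonym colliding with an unrelated concept's name, producing a
#'   known-false mediated mapping.
#' @return A list of class \code{bk_source_spec}.
#' @export
bk_source_spec <- function(id, bridge_fraction = NULL, bridge_n = NULL,
                           noise_rate = 0) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            noise_rate >= 0, noise_rate <= 1)
  if (is.null(bridge_fraction) && is.null(bridge_n))
    stop("one of bridge_fraction or bridge_n must be given")
  if (!is.null(bridge_fraction))
    stopifnot(bridge_fraction >= 0, bridge_fraction <= 1)
  structure(list(id = id, bridge_fraction = bridge_fraction,
                 bridge_n = bridge_n, noise_rate = noise_rate),
            class = "bk_source_spec")
}

#' Specify a synthetic ontology matching problem
#'
#' Describes a pair of ontologies S and T built over a shared concept
#' core: every shared concept becomes one class in each ontology and one
#' reference mapping (1-to-1 cardinality). A \code{direct_fraction} of the
#' shared concepts carry the same label in S and T and are therefore
#' recoverable by direct lexical matching; the rest have disjoint
#' vocabularies and can only be recovered through a background source
#' that knows both names. Each background source bridges a controllable
#' subset of those remaining concepts via classes carrying the S-name and
#' the T-name as synonyms; \code{noise_rate} injects lexical ambiguity
#' that produces known-false mediated mappings.
#'
#' @param n_shared Number of shared concepts.
#' @param n_source_only,n_target_only Classes unique to S / to T.
#' @param direct_fraction Fraction of shared concepts with identical
#'   labels in S and T.
#' @param synonyms_per_class Extra (unshared) exact synonyms per class.
#' @param sources List of [bk_source_spec()]s.
#' @param disjoint_bridges If TRUE, sources bridge mutually disjoint
#'   concept subsets (their joint demand must fit in the non-direct
#'   remainder); by default each source's bridge subset is drawn
#'   independently, so sources may be redundant.
#' @param seed Integer RNG seed; the same seed yields byte-identical
#'   generated ontologies.
#' @return A list of class \code{problem_spec}.
#' @export
problem_spec <- function(n_shared = 100, n_source_only = 20,
                         n_target_only = 20, direct_fraction = 0.6,
                         synonyms_per_class = 1, sources = list(),
                         disjoint_bridges = FALSE, seed = 42) {
  stopifnot(n_shared >= 1, n_source_only >= 0, n_target_only >= 0,
            direct_fraction >= 0, direct_fraction <= 1,
            synonyms_per_class >= 0)
  sources <- lapply(sources, function(s) {
    if (!inherits(s, "bk_source_spec")) do.call(bk_source_spec, s) else s
  })
  ids <- vapply(sources, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate source ids in problem spec")
  structure(list(n_shared = as.integer(n_shared),
                 n_source_only = as.integer(n_source_only),
                 n_target_only = as.integer(n_target_only),
                 direct_fraction = direct_fraction,
                 synonyms_per_class = as.integer(synonyms_per_class),
                 sources = sources,
                 disjoint_bridges = isTRUE(disjoint_bridges),
                 seed = as.integer(seed)),
            class = "problem_spec")
}

# Deterministic pseudo-word factory. Words are 1-3 tokens drawn from a
# moderate token pool so distinct names share tokens (exercising the
# hash-join path); uniqueness is enforced on the normalized form.
make_name_factory <- function() {
  used <- new.env(parent = emptyenv())
  syllables <- as.vector(outer(
    c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z"),
    c("a", "e", "i", "o", "u"), paste0))
  token_pool <- unique(vapply(seq_len(300), function(i)
    paste0(sample(syllables, sample(2:3, 1), replace = TRUE), collapse = ""),
    character(1)))
  function() {
    repeat {
      nt <- sample(1:3, 1, prob = c(0.15, 0.5, 0.35))
      w <- paste(sample(token_pool, nt, replace = TRUE), collapse = " ")
      if (is.null(used[[w]])) {
        used[[w]] <- TRUE
        return(w)
      }
    }
  }
}

#' Generate a synthetic matching problem with known ground truth
#'
#' Builds the lexicons for S, T and every background source described by
#' the spec, together with the reference alignment and a manifest holding
#' the construction-time bookkeeping: which concepts are directly
#' matchable, which concepts each source bridges, the expected mediated
#' mapping keys per source (true and known-false), and each source's
#' expected mapping gain against the direct baseline.
#'
#' By construction, with zero noise every mediated mapping from a
#' generated source is in the reference (precision 1) and the measured
#' 1-to-1 mapping gain of source i equals
#' \code{n_bridged_i / n_direct} exactly.
#'
#' @param spec A [problem_spec()].
#' @return A list of class \code{onto_problem} with elements \code{s},
#'   \code{t}, \code{sources} (list of \code{onto_lexicon}),
#'   \code{reference} (\code{onto_alignment}), \code{manifest},
#'   \code{spec}.
#' @export
generate_problem <- function(spec) {
  stopifnot(inherits(spec, "problem_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)
  new_name <- make_name_factory()
  n <- spec$n_shared
  n_direct <- round(spec$direct_fraction * n)
  direct <- sort(sample.int(n, n_direct))
  remaining <- setdiff(seq_len(n), direct)
  s_names <- vapply(seq_len(n), function(i) new_name(), character(1))
  t_names <- s_names
  t_names[remaining] <- vapply(remaining, function(i) new_name(),
                               character(1))
  s_iris <- canonical_iri(sprintf("S:%07d", seq_len(n + spec$n_source_only)))
  t_iris <- canonical_iri(sprintf("T:%07d", seq_len(n + spec$n_target_only)))

  build_entries <- function(iris, labels) {
    rows <- list(data.table::data.table(
      class_id = iris, name = labels, weight = 1, provenance = "label"))
    if (spec$synonyms_per_class > 0) {
      for (j in seq_len(spec$synonyms_per_class)) {
        rows[[j + 1L]] <- data.table::data.table(
          class_id = iris,
          name = vapply(iris, function(i) new_name(), character(1)),
          weight = 0.95, provenance = "exact")
      }
    }
    data.table::rbindlist(rows)
  }
  s_labels <- c(s_names, vapply(seq_len(spec$n_source_only),
                                function(i) new_name(), character(1)))
  t_labels <- c(t_names, vapply(seq_len(spec$n_target_only),
                                function(i) new_name(), character(1)))
  s_lex <- lexicon("S", classes = s_iris,
                   entries = build_entries(s_iris, s_labels))
  t_lex <- lexicon("T", classes = t_iris,
                   entries = build_entries(t_iris, t_labels))
  reference <- alignment("S", "T", data.table::data.table(
    source = s_iris[seq_len(n)], target = t_iris[seq_len(n)],
    similarity = 1, provenance = "reference"))

  src_lex <- list()
  src_manifest <- list()
  pool <- if (length(remaining) > 1L) sample(remaining) else remaining
  for (sspec in spec$sources) {
    n_bridge <- if (!is.null(sspec$bridge_n)) as.integer(sspec$bridge_n)
                else round(sspec$bridge_fraction * length(remaining))
    avail <- if (spec$disjoint_bridges) length(pool) else length(remaining)
    if (n_bridge > avail)
      stop("infeasible spec: source '", sspec$id, "' demands ", n_bridge,
           " bridges but only ", avail,
           " non-direct shared concepts are available")
    if (spec$disjoint_bridges) {
      bridges <- sort(utils::head(pool, n_bridge))
      pool <- utils::tail(pool, length(pool) - n_bridge)
    } else {
      bridges <- if (n_bridge > 0) {
        if (length(remaining) == 1L) remaining
        else sort(sample(remaining, n_bridge))
      } else integer(0)
    }
    bk_iris <- canonical_iri(sprintf("%s:%07d", sspec$id,
                                     seq_along(bridges)))
    rows <- vector("list", length(bridges))
    false_pairs <- list()
    noise_pool <- remaining  # collisions restricted to non-direct concepts
    for (bi in seq_along(bridges)) {
      concept <- bridges[bi]
      nms <- c(new_name(), s_names[concept], t_names[concept])
      prov <- c("label", "exact", "exact")
      if (sspec$noise_rate > 0 && stats::runif(1) < sspec$noise_rate &&
          length(setdiff(noise_pool, concept)) > 0) {
        victims <- setdiff(noise_pool, concept)
        d <- if (length(victims) == 1L) victims else sample(victims, 1)
        nms <- c(nms, t_names[d])
        prov <- c(prov, "related")
        false_pairs[[length(false_pairs) + 1L]] <- data.table::data.table(
          source = s_iris[concept], target = t_iris[d])
      }
      rows[[bi]] <- data.table::data.table(
        class_id = bk_iris[bi], name = nms,
        weight = unname(synonym_weights()[prov]), provenance = prov)
    }
    entries <- if (length(rows)) data.table::rbindlist(rows) else NULL
    src_lex[[sspec$id]] <- lexicon(sspec$id, classes = bk_iris,
                                   entries = entries)
    false_dt <- if (length(false_pairs)) data.table::rbindlist(false_pairs)
                else data.table::data.table(source = character(0),
                                            target = character(0))
    src_manifest[[sspec$id]] <- list(
      id = sspec$id, bridges = bridges, n_bridge = length(bridges),
      noise_rate = sspec$noise_rate,
      expected_gain = if (n_direct > 0) length(bridges) / n_direct
                      else NA_real_,
      true_keys = paste(s_iris[bridges], t_iris[bridges], sep = "\t"),
      false_pairs = false_dt)
  }
  manifest <- list(
    n_shared = n, n_direct = n_direct, direct_concepts = direct,
    nondirect_concepts = remaining, sources = src_manifest)
  structure(list(s = s_lex, t = t_lex, sources = unname(src_lex),
                 reference = reference, manifest = manifest, spec = spec),
            class = "onto_problem")
}

#' @export
print.onto_problem <- function(x, ...) {
  cat("<onto_problem> ", x$manifest$n_shared, " shared concepts (",
      x$manifest$n_direct, " direct), ", length(x$sources),
      " background sources\n", sep = "")
  invisible(x)
}

#' Generate a problem whose sources have prescribed mapping gains
#'
#' Builds a matching problem with \code{n_sources} background sources
#' whose expected 1-to-1 mapping gains against the direct baseline follow
#' the prescribed values: source i bridges
#' \code{round(gains[i] * n_direct)} of the non-direct shared concepts,
#' so with zero noise its measured gain equals
#' \code{round(gains[i] * n_direct) / n_direct} — the realized gain
#' recorded in the manifest's \code{expected_gain}. Bridge subsets are
#' drawn independently per source (sources may overlap). This is the
#' driver for correlation experiments between mapping gain and
#' F-measure.
#'
#' @param base A [problem_spec()] whose \code{sources} are ignored.
#' @param gains Numeric vector of prescribed gains (one source each).
#' @param noise_rate Noise rate applied to every source (constant noise
#'   keeps per-source precision approximately constant).
#' @param seed Overrides \code{base$seed} when non-NULL.
#' @return An \code{onto_problem}.
#' @export
generate_usefulness_gradient <- function(base, gains, noise_rate = 0,
                                         seed = NULL) {
  stopifnot(inherits(base, "problem_spec"), length(gains) >= 1,
            all(gains >= 0))
  n_direct <- round(base$direct_fraction * base$n_shared)
  n_remaining <- base$n_shared - n_direct
  if (n_direct == 0)
    stop("infeasible: a gradient problem needs a non-empty direct baseline")
  bridge_ns <- round(gains * n_direct)
  if (any(bridge_ns > n_remaining))
    stop("infeasible: prescribed gain ", max(gains), " requires ",
         max(bridge_ns), " bridges but only ", n_remaining,
         " non-direct concepts exist")
  ids <- sprintf("BK%02d", seq_along(gains))
  sources <- Map(function(id, bn) bk_source_spec(id, bridge_n = bn,
                                                 noise_rate = noise_rate),
                 ids, bridge_ns)
  spec <- problem_spec(n_shared = base$n_shared,
                       n_source_only = base$n_source_only,
                       n_target_only = base$n_target_only,
                       direct_fraction = base$direct_fraction,
                       synonyms_per_class = base$synonyms_per_class,
                       sources = unname(sources),
                       seed = if (is.null(seed)) base$seed else seed)
  generate_problem(spec)
}

#' Write a generated problem to disk
#'
#' Serializes S, T and each background source as OBO files, the reference
#' alignment in OAEI RDF and TSV, and the manifest (spec plus per-source
#' ground-truth bookkeeping) as JSON.
#'
#' @param problem An \code{onto_problem}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_problem <- function(problem, dir) {
  stopifnot(inherits(problem, "onto_problem"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_obo(problem$s, file.path(dir, "S.obo"))
  write_obo(problem$t, file.path(dir, "T.obo"))
  for (src in problem$sources)
    write_obo(src, file.path(dir, paste0(src$ontology_id, ".obo")))
  write_alignment_rdf(problem$reference, file.path(dir, "reference.rdf"))
  write_alignment_tsv(problem$reference, file.path(dir, "reference.tsv"))
  man <- problem$manifest
  man$sources <- lapply(man$sources, function(m) {
    m$false_pairs <- as.data.frame(m$false_pairs)
    m
  })
  man$spec <- lapply(unclass(problem$spec), function(x)
    if (is.list(x)) lapply(x, unclass) else x)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
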
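#' Prefilter candidate background sources
#'
#' Drops candidates that cannot usefully mediate the matching task:
#' sources that are one of the input ontologies themselves (same
#' \code{ontology_id} or identical class set), and sources whose
#' [similarity_score()] against the pair falls below \code{min_score}
#' (default 1e-4, i.e. 0.01\%) — a cheap guarantee of minimal domain
#' overlap before any mediated matching is attempted. Input order is
#' preserved.
#'
#' @param s,t Input \code{onto_lexicon}s.
#' @param sources List of candidate \code{onto_lexicon}s.
#' @param min_score Minimum similarity score to retain a source.
#' @param a,b Similarity-score weights, see [similarity_score()].
#' @return The retained sublist of \code{sources}.
#' @export
prefilter_sources <- function(s, t, sources, min_score = 1e-4,
                              a = 1, b = 0.9) {
  stopifnot(min_score >= 0, is.list(sources))
  keep <- vapply(sources, function(x) {
    stopifnot(inherits(x, "onto_lexicon"))
    if (identical(x$ontology_id, s$ontology_id) ||
        identical(x$ontology_id, t$ontology_id)) return(FALSE)
    if (setequal(x$classes, s$classes) || setequal(x$classes, t$classes))
      return(FALSE)
    similarity_score(s, t, x, a = a, b = b) >= min_score
  }, logical(1))
  sources[keep]
}

#' Two-stage automatic selection of background-knowledge sources
#'
#' Finding the smallest set of background sources that maximizes the
#' number of mapped classes is equivalent to set cover, hence
#' NP-complete; this greedy heuristic exploits the observation that the
#' sources with the largest individual mapping gain are the most likely
#' members of the optimal solution.
#'
#' Stage 1 (ranking): each source X_i is matched through
#' [mediated_match()] to give alignment A_i, and its mapping gain against
#' the direct baseline B is computed; sources with gain < k are
#' discarded and the survivors are ranked by gain, descending. Stage 2
#' (selection): starting from B' = B, the survivors are revisited in rank
#' order, each source's gain is recomputed against the current B' — so a
#' source is retained only if it complements what earlier selections
#' already contributed — and retained sources are merged into B'. The
#' threshold test is strictly "gain < k discards" at both stages, so a
#' gain of exactly k survives.
#'
#' Ties in gain are broken by larger alignment size, then lexicographic
#' source id, making the procedure fully deterministic. The stage-1
#' alignments are cached and reused in stage 2.
#'
#' @param s,t Input \code{onto_lexicon}s.
#' @param sources List of candidate \code{onto_lexicon}s (normally
#'   already passed through [prefilter_sources()]).
#' @param k Minimum mapping-gain threshold. The default 0.02 (2\%) is a
#'   conservative general-purpose value; 0.003 (0.3\%) suits
#'   high-precision matching settings.
#' @param gain_variant \code{"one_to_one"} (default, for tasks whose
#'   reference alignment has near 1-to-1 cardinality, see
#'   [mapping_gain_1to1()]) or \code{"general"} ([mapping_gain()]).
#' @param baseline Optional precomputed direct alignment; defaults to
#'   \code{lexical_match(s, t)}. Must be non-empty (the gain is undefined
#'   otherwise).
#' @param combine Bridge-similarity combiner for [mediated_match()].
#' @return An object of class \code{bk_selection}: a list with
#'   \item{baseline}{the direct alignment B}
#'   \item{candidates}{per-source ledger (data.table): \code{bk_id},
#'     \code{n_mappings}, \code{individual_gain}, \code{rank} (NA if
#'     discarded at stage 1), \code{selected_gain} (NA unless selected),
#'     \code{selected}, \code{reason}, \code{similarity_score},
#'     \code{effectiveness}}
#'   \item{selected}{character vector of selected bk_ids, in selection
#'     order}
#'   \item{alignments}{named list of the mediated alignments A_i}
#'   \item{combined}{B' = B united with every selected A_i}
#'   \item{threshold_k, gain_variant}{the parameters used}
#' @export
select_background_knowledge <- function(s, t, sources, k = 0.02,
                                        gain_variant = c("one_to_one",
                                                         "general"),
                                        baseline = NULL,
                                        combine = c("min", "product")) {
  gain_variant <- match.arg(gain_variant)
  combine <- match.arg(combine)
  stopifnot(k >= 0, is.list(sources))
  if (is.null(baseline)) baseline <- lexical_match(s, t)
  if (n_mappings(baseline) == 0L)
    stop("the direct baseline alignment is empty; mapping gain is undefined")
  gain_fun <- switch(gain_variant,
                     one_to_one = mapping_gain_1to1,
                     general = mapping_gain)
  ids <- vapply(sources, function(x) x$ontology_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate background ontology ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(sources)
  ledger <- data.table::data.table(
    bk_id = ids, n_mappings = integer(n), individual_gain = numeric(n),
    rank = NA_integer_, selected_gain = NA_real_, selected = FALSE,
    reason = NA_character_, similarity_score = numeric(n),
    effectiveness = numeric(n))
  alignments <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    a_i <- mediated_match(s, t, sources[[i]], combine = combine)
    alignments[[i]] <- a_i
    ledger$n_mappings[i] <- n_mappings(a_i)
    ledger$individual_gain[i] <- gain_fun(a_i, baseline)
    ledger$similarity_score[i] <- similarity_score(s, t, sources[[i]])
    ledger$effectiveness[i] <- effectiveness(a_i, s, t)
  }
  # stage 1: discard gains < k, rank survivors by gain desc
  survives <- ledger$individual_gain >= k
  ledger$reason[!survives] <- "stage1_gain_below_threshold"
  ord <- order(-ledger$individual_gain, -ledger$n_mappings, ledger$bk_id)
  ord <- ord[survives[ord]]
  ledger$rank[ord] <- seq_along(ord)
  # stage 2: greedy accumulation, re-evaluating against the growing B'
  combined <- baseline
  selected <- character(0)
  for (i in ord) {
    g2 <- gain_fun(alignments[[i]], combined)
    if (g2 < k) {
      ledger$reason[i] <- "stage2_gain_below_threshold"
    } else {
      ledger$selected_gain[i] <- g2
      ledger$selected[i] <- TRUE
      ledger$reason[i] <- "selected"
      combined <- align_union(combined, alignments[[i]])
      selected <- c(selected, ledger$bk_id[i])
    }
  }
  structure(list(baseline = baseline, candidates = ledger,
                 selected = selected, alignments = alignments,
                 combined = combined, threshold_k = k,
                 gain_variant = gain_variant),
            class = "bk_selection")
}

#' @export
print.bk_selection <- function(x, ...) {
  cat("<bk_selection> threshold k = ", x$threshold_k, ", gain variant = ",
      x$gain_variant, "\n", sep = "")
  cat("  baseline: ", n_mappings(x$baseline), " mappings; combined: ",
      n_mappings(x$combined), " mappings\n", sep = "")
  cat("  selected ", length(x$selected), "/", nrow(x$candidates),
      " sources", if (length(x$selected))
        paste0(": ", paste(x$selected, collapse = ", ")), "\n", sep = "")
  invisible(x)
}

#' Exhaustive search for the best source subset
#'
#' Diagnostic counterpart of [select_background_knowledge()]: enumerates
#' every subset of the candidate sources and reports the one maximizing
#' the number of distinct classes mapped by the union of the baseline
#' with the subset's mediated alignments (ties broken toward fewer
#' sources, then lexicographically). Exponential in the number of
#' sources — intended for benchmarking the greedy heuristic on small
#' instances, not for production use.
#'
#' @param s,t Input \code{onto_lexicon}s.
#' @param sources List of candidate \code{onto_lexicon}s (<= 15).
#' @param baseline Optional precomputed direct alignment.
#' @param combine Bridge-similarity combiner.
#' @return List with \code{best_ids}, \code{best_mapped_classes}, and
#'   \code{alignments} (the per-source mediated alignments).
#' @export
optimal_source_subset <- function(s, t, sources, baseline = NULL,
                                  combine = c("min", "product")) {
  combine <- match.arg(combine)
  if (length(sources) > 15L)
    stop("exhaustive search is limited to 15 sources")
  if (is.null(baseline)) baseline <- lexical_match(s, t)
  ids <- vapply(sources, function(x) x$ontology_id, character(1))
  alignments <- stats::setNames(
    lapply(sources, function(x) mediated_match(s, t, x, combine = combine)),
    ids)
  mapped_classes <- function(algn)
    length(unique(algn$mappings$source)) + length(unique(algn$mappings$target))
  best_ids <- character(0)
  best_score <- mapped_classes(baseline)
  n <- length(sources)
  for (mask in seq_len(2^n) - 1L) {
    take <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!length(take)) next
    algn <- baseline
    for (j in take) algn <- align_union(algn, alignments[[j]])
    sc <- mapped_classes(algn)
    if (sc > best_score ||
        (sc == best_score && length(take) < length(best_ids)) ||
        (sc == best_score && length(take) == length(best_ids) &&
         length(best_ids) > 0 &&
         paste(sort(ids[take]), collapse = ",") <
           paste(sort(best_ids), collapse = ","))) {
      best_ids <- ids[take]
      best_score <- sc
    }
  }
  list(best_ids = best_ids, best_mapped_classes = best_score,
       alignments = alignments)
}
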
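#' Greedy 1-to-1 alignment extraction (Ranked Selector)
#'
#' Sorts the mappings by similarity, descending, and sweeps them
#' greedily, accepting a mapping only if neither its source nor its
#' target class has already been used. The result is strictly 1-to-1 and
#' the operation is idempotent. Mappings of equal similarity are ordered
#' by (source IRI, target IRI) lexicographically — a declared convention
#' that makes the sweep deterministic across runs and platforms.
#'
#' @param a An \code{onto_alignment}.
#' @return A 1-to-1 sub-alignment of \code{a}.
#' @export
ranked_select_1to1 <- function(a) {
  stopifnot(inherits(a, "onto_alignment"))
  m <- a$mappings
  if (nrow(m) <= 1L) return(a)
  ord <- order(-m$similarity, m$source, m$target)
  m <- m[ord]
  used_s <- new.env(parent = emptyenv())
  used_t <- new.env(parent = emptyenv())
  take <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (is.null(used_s[[m$source[i]]]) && is.null(used_t[[m$target[i]]])) {
      take[i] <- TRUE
      used_s[[m$source[i]]] <- TRUE
      used_t[[m$target[i]]] <- TRUE
    }
  }
  alignment(a$source_ontology, a$target_ontology, m[take])
}

#' Evaluate an alignment against a reference
#'
#' Standard OAEI-style evaluation of class equivalence mappings: a
#' mapping is a true positive when its (source, target) class pair occurs
#' in the reference; similarity values and relations are ignored. If the
#' candidate alignment is oriented opposite to the reference it is
#' reversed before comparison.
#'
#' @param a The \code{onto_alignment} to evaluate.
#' @param reference The reference \code{onto_alignment}; must be
#'   non-empty and over the same ontology pair (either orientation).
#' @return An object of class \code{eval_report}: list with
#'   \code{true_positives}, \code{false_positives},
#'   \code{false_negatives}, \code{precision}, \code{recall},
#'   \code{fmeasure}. Precision is 1 when the alignment is empty;
#'   F-measure is 0 when precision + recall is 0.
#' @export
evaluate_alignment <- function(a, reference) {
  stopifnot(inherits(a, "onto_alignment"),
            inherits(reference, "onto_alignment"))
  if (n_mappings(reference) == 0L)
    stop("cannot evaluate against an empty reference alignment")
  if (reversed_pair(a, reference)) a <- align_reverse(a)
  if (!same_pair(a, reference))
    stop("alignment and reference cover different ontology pairs")
  tp <- length(intersect(mapping_keys(a), mapping_keys(reference)))
  fp <- n_mappings(a) - tp
  fn <- n_mappings(reference) - tp
  precision <- if (tp + fp == 0L) 1 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  fmeasure <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(true_positives = tp, false_positives = fp,
                 false_negatives = fn, precision = precision,
                 recall = recall, fmeasure = fmeasure),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> P = %.4f  R = %.4f  F = %.4f  (TP %d, FP %d, FN %d)\n",
    x$precision, x$recall, x$fmeasure,
    x$true_positives, x$false_positives, x$false_negatives))
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param x An \code{eval_report}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_eval_json <- function(x, path) {
  stopifnot(inherits(x, "eval_report"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
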
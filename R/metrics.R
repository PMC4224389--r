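#' Mapping gain of an alignment over a baseline
#'
#' The fraction of mappings in \code{a} that are novel with respect to the
#' baseline \code{b}, normalized by the size of \code{b}:
#' \deqn{MG(A, B) = |\{m \in A : m \notin B\}| / |B|}
#' Mappings are compared by their (source, target) class pair only. The
#' measure is deliberately asymmetric: it quantifies what \code{a}
#' contributes on top of \code{b}, under the premise that \code{a} will
#' be added to \code{b} to form the final alignment.
#'
#' @param a An \code{onto_alignment} (e.g. background-mediated).
#' @param b The baseline \code{onto_alignment}; must be non-empty.
#' @return Non-negative real; may exceed 1 when \code{a} carries more
#'   novel mappings than \code{b} has in total.
#' @export
mapping_gain <- function(a, b) {
  check_gain_args(a, b)
  novel <- setdiff(mapping_keys(a), mapping_keys(b))
  length(novel) / n_mappings(b)
}

#' Mapping gain restricted to previously unmapped classes
#'
#' The variant of [mapping_gain()] suited to tasks whose true alignment
#' has (near) 1-to-1 cardinality. A mapping in \code{a} counts only if it
#' connects a source class and a target class that are both unmapped in
#' the baseline \code{b}; a mapping that re-maps an already-mapped class
#' cannot be correct under 1-to-1 cardinality, so counting it would
#' overestimate the usefulness of the background source.
#'
#' @inheritParams mapping_gain
#' @return Non-negative real, always \code{<= mapping_gain(a, b)}.
#' @export
mapping_gain_1to1 <- function(a, b) {
  check_gain_args(a, b)
  used_s <- unique(b$mappings$source)
  used_t <- unique(b$mappings$target)
  m <- a$mappings
  sum(!(m$source %in% used_s) & !(m$target %in% used_t)) / n_mappings(b)
}

check_gain_args <- function(a, b) {
  stopifnot(inherits(a, "onto_alignment"), inherits(b, "onto_alignment"))
  if (!same_pair(a, b))
    stop("mapping gain requires alignments over the same ontology pair")
  if (n_mappings(b) == 0L)
    stop("mapping gain is undefined for an empty baseline alignment")
  invisible(TRUE)
}

#' Jaccard similarity of two ontologies
#'
#' Lexical estimate of the conceptual overlap between two ontologies: the
#' intersection is estimated by the number of class pairs matched by the
#' lexical matcher, giving
#' \deqn{J(O_1, O_2) = m / (|C_1| + |C_2| - m)}
#' where m is the matched-pair count. Two empty lexicons have similarity
#' 0 by convention.
#'
#' @param o1,o2 \code{onto_lexicon} objects.
#' @return Real in [0, 1]; symmetric in its arguments.
#' @export
jaccard_similarity <- function(o1, o2) {
  stopifnot(inherits(o1, "onto_lexicon"), inherits(o2, "onto_lexicon"))
  n1 <- n_classes(o1); n2 <- n_classes(o2)
  if (n1 + n2 == 0L) return(0)
  m <- n_mappings(lexical_match(o1, o2))
  m / (n1 + n2 - m)
}

#' Similarity score of a background source for an ontology pair
#'
#' Weighted combination of the Jaccard similarities between a candidate
#' background ontology x and each input ontology. With weights a >= b the
#' smaller of the two similarities receives the larger weight:
#' \deqn{score = a \cdot \min(J(S,X), J(T,X)) + b \cdot \max(J(S,X), J(T,X))}
#' so a source must be similar to both input ontologies — not just one —
#' to score highly. Defaults a = 1, b = 0.9.
#'
#' @param s,t Input \code{onto_lexicon}s.
#' @param x Candidate background \code{onto_lexicon}.
#' @param a,b Weights with \code{a >= b > 0}.
#' @return Non-negative real, at most \code{a + b}; symmetric in s, t.
#' @export
similarity_score <- function(s, t, x, a = 1, b = 0.9) {
  stopifnot(a >= b, b > 0)
  p <- jaccard_similarity(s, x)
  q <- jaccard_similarity(t, x)
  a * min(p, q) + b * max(p, q)
}

#' Effectiveness of a background-mediated alignment
#'
#' The size of the alignment obtained with a background source divided by
#' the average class count of the input ontologies:
#' \deqn{Eff = |A| / ((|C_S| + |C_T|) / 2)}
#' Unlike the mapping gain, effectiveness does not discount mappings
#' already found directly.
#'
#' @param a The mediated \code{onto_alignment}.
#' @param s,t Input \code{onto_lexicon}s (not both empty).
#' @return Non-negative real.
#' @export
effectiveness <- function(a, s, t) {
  stopifnot(inherits(a, "onto_alignment"),
            inherits(s, "onto_lexicon"), inherits(t, "onto_lexicon"))
  denom <- (n_classes(s) + n_classes(t)) / 2
  if (denom == 0) stop("effectiveness is undefined for two empty ontologies")
  n_mappings(a) / denom
}

#' Pearson correlation coefficient
#'
#' Thin wrapper around \code{stats::cor} with explicit argument checking:
#' requires paired observations of equal length at least 3 and non-zero
#' variance on both sides (degenerate inputs are an error rather than
#' NA).
#'
#' @param xs,ys Numeric vectors of equal length >= 3.
#' @return Pearson r in [-1, 1].
#' @export
pearson <- function(xs, ys) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) != length(ys))
    stop("xs and ys must have equal length")
  if (length(xs) < 3L)
    stop("need at least 3 paired observations")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("correlation is undefined when either variable has zero variance")
  stats::cor(xs, ys, method = "pearson")
}
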
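#' Direct lexical matching of two ontologies
#'
#' The weighted full-name matcher: two classes are mapped when they share
#' an identical normalized name (label or synonym). The similarity of a
#' mapping is the maximum over shared names of the product of the two
#' name weights, so a label-label match scores 1.0 and matches through
#' synonyms score less. The implementation is a hash join on the name
#' indexes — runtime is linear in the total entry count, never all-pairs.
#'
#' @param source,target \code{onto_lexicon} objects with different
#'   \code{ontology_id}s.
#' @return An \code{onto_alignment} with provenance \code{"direct"}.
#' @export
lexical_match <- function(source, target) {
  stopifnot(inherits(source, "onto_lexicon"), inherits(target, "onto_lexicon"))
  if (identical(source$ontology_id, target$ontology_id))
    stop("cannot match an ontology against itself (same ontology_id)")
  es <- source$entries[, list(name, source = class_id, ws = weight)]
  et <- target$entries[, list(name, target = class_id, wt = weight)]
  if (nrow(es) == 0L || nrow(et) == 0L)
    return(alignment(source$ontology_id, target$ontology_id))
  hits <- merge(es, et, by = "name", allow.cartesian = TRUE)
  if (nrow(hits) == 0L)
    return(alignment(source$ontology_id, target$ontology_id))
  best <- hits[, list(similarity = max(ws * wt)), by = list(source, target)]
  best$provenance <- "direct"
  alignment(source$ontology_id, target$ontology_id, best)
}

#' Indirect matching through a background ontology
#'
#' Matches each input ontology against the background lexicon and derives
#' a mapping between a source class s and a target class t whenever both
#' map to the same background class (mapping transitivity for equivalence
#' mappings). The similarity of a mediated mapping is the minimum of the
#' two bridge similarities (conservative; \code{combine = "product"} is
#' available); when several background classes bridge the same (s, t)
#' pair the best resulting similarity is kept.
#'
#' @param source,target Input \code{onto_lexicon}s.
#' @param bk Background-knowledge \code{onto_lexicon}; its
#'   \code{ontology_id} must differ from both inputs.
#' @param combine How to combine the two bridge similarities.
#' @return An \code{onto_alignment} with provenance
#'   \code{"mediated:<bk_id>"}.
#' @export
mediated_match <- function(source, target, bk,
                           combine = c("min", "product")) {
  combine <- match.arg(combine)
  stopifnot(inherits(bk, "onto_lexicon"))
  if (identical(bk$ontology_id, source$ontology_id) ||
      identical(bk$ontology_id, target$ontology_id))
    stop("background ontology must differ from both input ontologies")
  a_sx <- lexical_match(source, bk)
  a_tx <- lexical_match(target, bk)
  prov <- paste0("mediated:", bk$ontology_id)
  if (nrow(a_sx$mappings) == 0L || nrow(a_tx$mappings) == 0L)
    return(alignment(source$ontology_id, target$ontology_id))
  sx <- a_sx$mappings[, list(x = target, source, p = similarity)]
  tx <- a_tx$mappings[, list(x = target, target = source, q = similarity)]
  bridges <- merge(sx, tx, by = "x", allow.cartesian = TRUE)
  if (nrow(bridges) == 0L)
    return(alignment(source$ontology_id, target$ontology_id))
  bridges$sim <- if (combine == "min") pmin(bridges$p, bridges$q)
                 else bridges$p * bridges$q
  best <- bridges[, list(similarity = max(sim)), by = list(source, target)]
  best$provenance <- prov
  alignment(source$ontology_id, target$ontology_id, best)
}
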
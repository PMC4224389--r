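#' Build a run configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default:
#' the mapping-gain threshold \code{k} (0.02), the similarity-score
#' prefilter (1e-4, i.e. 0.01\%), the similarity-score weights
#' \code{a = 1}, \code{b = 0.9}, the gain variant (\code{"one_to_one"})
#' and the name-provenance weight table. A YAML file with any subset of
#' these fields can be loaded with [read_run_config()]; explicit
#' arguments override file values.
#'
#' @param source_path,target_path Paths to the input ontologies.
#' @param bk_dir Directory of candidate background ontologies
#'   (\code{.obo}/\code{.owl}/\code{.rdf} files); may be NULL.
#' @param reference_path Optional reference alignment (RDF or TSV).
#' @param out_dir Output directory for artifacts.
#' @param k Mapping-gain threshold.
#' @param prefilter Minimum similarity score for candidates.
#' @param a,b Similarity-score weights (\code{a >= b > 0}).
#' @param gain_variant \code{"one_to_one"} or \code{"general"}.
#' @param combine Bridge-similarity combiner for mediated matching.
#' @param weights Name-provenance weights, see [synonym_weights()].
#' @param one_to_one Extract a 1-to-1 alignment before evaluation.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(source_path = NULL, target_path = NULL,
                       bk_dir = NULL, reference_path = NULL,
                       out_dir = "ontobk_out", k = 0.02,
                       prefilter = 1e-4, a = 1, b = 0.9,
                       gain_variant = c("one_to_one", "general"),
                       combine = c("min", "product"),
                       weights = synonym_weights(), one_to_one = TRUE) {
  gain_variant <- match.arg(gain_variant)
  combine <- match.arg(combine)
  stopifnot(k >= 0, prefilter >= 0, a >= b, b > 0)
  structure(list(source_path = source_path, target_path = target_path,
                 bk_dir = bk_dir, reference_path = reference_path,
                 out_dir = out_dir, k = k, prefilter = prefilter,
                 a = a, b = b, gain_variant = gain_variant,
                 combine = combine, weights = weights,
                 one_to_one = one_to_one),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @param ... Overrides applied on top of the file's values.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  if (!is.null(vals$weights)) vals$weights <- unlist(vals$weights)
  do.call(run_config, vals)
}

#' Run the full background-knowledge selection pipeline
#'
#' Loads the input ontologies and every candidate background ontology,
#' computes the direct baseline alignment, prefilters and then selects
#' background sources by mapping gain, and writes the artifacts to
#' \code{config$out_dir}: \code{baseline.tsv}, \code{metrics.tsv} (the
#' per-source ledger), \code{selection.json}, \code{combined.tsv} and
#' \code{combined.rdf}, plus \code{final_1to1.tsv} and
#' \code{evaluation.json} when a reference alignment is supplied. Because
#' ontology parsing dominates the run time of lexical matching pipelines,
#' the load stage is logged separately from the selection stage.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the loaded lexicons, the
#'   \code{bk_selection} result, the final alignment and (if a reference
#'   was given) the \code{eval_report}.
#' @export
run_auto <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  tic <- Sys.time()
  s <- load_ontology(config$source_path, weights = config$weights)
  t <- load_ontology(config$target_path, weights = config$weights)
  bk_files <- if (is.null(config$bk_dir)) character(0) else
    sort(list.files(config$bk_dir, pattern = "\\.(obo|owl|rdf)$",
                    full.names = TRUE))
  sources <- lapply(bk_files, load_ontology, weights = config$weights)
  say(sprintf("[load] %d + %d input classes, %d background sources (%.2fs)",
              n_classes(s), n_classes(t), length(sources),
              as.numeric(Sys.time() - tic, units = "secs")))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tic <- Sys.time()
  baseline <- lexical_match(s, t)
  write_alignment_tsv(baseline, file.path(config$out_dir, "baseline.tsv"))
  say(sprintf("[match] baseline: %d direct mappings", n_mappings(baseline)))

  sources <- prefilter_sources(s, t, sources, min_score = config$prefilter,
                               a = config$a, b = config$b)
  sel <- select_background_knowledge(
    s, t, sources, k = config$k, gain_variant = config$gain_variant,
    baseline = baseline, combine = config$combine)
  say(sprintf("[select] %d/%d sources selected; combined: %d mappings (%.2fs)",
              length(sel$selected), nrow(sel$candidates),
              n_mappings(sel$combined),
              as.numeric(Sys.time() - tic, units = "secs")))

  utils::write.table(sel$candidates,
                     file.path(config$out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(threshold_k = config$k, gain_variant = config$gain_variant,
         baseline_mappings = n_mappings(baseline),
         combined_mappings = n_mappings(sel$combined),
         selected = as.list(sel$selected)),
    file.path(config$out_dir, "selection.json"),
    auto_unbox = TRUE, digits = NA)
  write_alignment_tsv(sel$combined, file.path(config$out_dir, "combined.tsv"))
  write_alignment_rdf(sel$combined, file.path(config$out_dir, "combined.rdf"))

  final <- if (config$one_to_one) ranked_select_1to1(sel$combined)
           else sel$combined
  if (config$one_to_one)
    write_alignment_tsv(final, file.path(config$out_dir, "final_1to1.tsv"))

  report <- NULL
  if (!is.null(config$reference_path)) {
    reference <- if (grepl("\\.tsv$", config$reference_path))
      read_alignment_tsv(config$reference_path)
    else read_alignment_rdf(config$reference_path,
                            source_ontology = s$ontology_id,
                            target_ontology = t$ontology_id)
    report <- evaluate_alignment(final, reference)
    write_eval_json(report, file.path(config$out_dir, "evaluation.json"))
    say(sprintf("[evaluate] P = %.4f  R = %.4f  F = %.4f",
                report$precision, report$recall, report$fmeasure))
  }
  invisible(list(s = s, t = t, baseline = baseline, selection = sel,
                 final = final, evaluation = report))
}
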
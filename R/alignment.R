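#' Construct an alignment
#'
#' An alignment is a set of equivalence mappings between classes of two
#' named ontologies. Each mapping carries a similarity in (0, 1] and a
#' provenance string (\code{"direct"} for lexical matches between the
#' inputs, \code{"mediated:<bk_id>"} for matches bridged through a
#' background ontology). At most one mapping is kept per
#' (source, target) class pair; on duplicates the highest similarity
#' wins.
#'
#' @param source_ontology,target_ontology Ontology identifiers (must
#'   differ).
#' @param mappings A data.frame with columns \code{source}, \code{target},
#'   \code{similarity} and optionally \code{provenance}.
#' @return An object of class \code{onto_alignment}: a list with elements
#'   \code{source_ontology}, \code{target_ontology} and \code{mappings}
#'   (a data.table sorted by source, target).
#' @export
alignment <- function(source_ontology, target_ontology, mappings = NULL) {
  stopifnot(is.character(source_ontology), is.character(target_ontology))
  if (identical(source_ontology, target_ontology))
    stop("source and target ontology must differ")
  if (is.null(mappings) || nrow(mappings) == 0L) {
    mappings <- data.table::data.table(
      source = character(0), target = character(0),
      similarity = numeric(0), provenance = character(0))
  } else {
    mappings <- data.table::as.data.table(mappings)
    if (!"provenance" %in% names(mappings)) mappings$provenance <- "direct"
    mappings <- mappings[, list(source = as.character(source),
                                target = as.character(target),
                                similarity = as.numeric(similarity),
                                provenance = as.character(provenance))]
    if (any(mappings$similarity <= 0 | mappings$similarity > 1))
      stop("similarities must lie in (0, 1]")
    data.table::setorder(mappings, source, target, -similarity, provenance)
    mappings <- mappings[!duplicated(mappings[, list(source, target)])]
    data.table::setorder(mappings, source, target)
  }
  structure(list(source_ontology = source_ontology,
                 target_ontology = target_ontology,
                 mappings = mappings),
            class = "onto_alignment")
}

#' @export
print.onto_alignment <- function(x, ...) {
  cat("<onto_alignment> ", x$source_ontology, " -> ", x$target_ontology,
      ": ", nrow(x$mappings), " mappings\n", sep = "")
  invisible(x)
}

#' Number of mappings in an alignment
#' @param a An \code{onto_alignment}.
#' @return Integer mapping count.
#' @export
n_mappings <- function(a) {
  stopifnot(inherits(a, "onto_alignment"))
  nrow(a$mappings)
}

# Internal (source, target) key used for all set algebra on mappings.
mapping_keys <- function(a) {
  paste(a$mappings$source, a$mappings$target, sep = "\t")
}

same_pair <- function(a, b) {
  identical(a$source_ontology, b$source_ontology) &&
    identical(a$target_ontology, b$target_ontology)
}

# TRUE if b is the same pair with orientation reversed.
reversed_pair <- function(a, b) {
  identical(a$source_ontology, b$target_ontology) &&
    identical(a$target_ontology, b$source_ontology)
}

#' Reverse the orientation of an alignment
#' @param a An \code{onto_alignment}.
#' @return The alignment with source/target swapped.
#' @export
align_reverse <- function(a) {
  stopifnot(inherits(a, "onto_alignment"))
  alignment(a$target_ontology, a$source_ontology,
            a$mappings[, list(source = target, target = source,
                              similarity, provenance)])
}

#' Union of two alignments
#'
#' Set union on (source, target) keys over the same ontology pair; when a
#' pair occurs in both alignments the mapping with the higher similarity
#' is kept. This is the operation that merges a background-mediated
#' alignment into the direct baseline.
#'
#' @param a,b Alignments over the same ontology pair.
#' @return An \code{onto_alignment} with \code{n_mappings <=
#'   n_mappings(a) + n_mappings(b)}.
#' @export
align_union <- function(a, b) {
  stopifnot(inherits(a, "onto_alignment"), inherits(b, "onto_alignment"))
  if (!same_pair(a, b))
    stop("cannot union alignments over different ontology pairs")
  alignment(a$source_ontology, a$target_ontology,
            rbind(a$mappings, b$mappings))
}

#' Write an alignment as TSV
#'
#' Columns \code{source_iri}, \code{target_iri}, \code{similarity},
#' \code{provenance}, preceded by header comments recording the ontology
#' pair.
#'
#' @param a An \code{onto_alignment}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_alignment_tsv <- function(a, path) {
  stopifnot(inherits(a, "onto_alignment"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# source_ontology: ", a$source_ontology),
               paste0("# target_ontology: ", a$target_ontology),
               "source_iri\ttarget_iri\tsimilarity\tprovenance"), con)
  m <- a$mappings
  if (nrow(m))
    writeLines(paste(m$source, m$target,
                     format(m$similarity, digits = 15, trim = TRUE),
                     m$provenance, sep = "\t"), con)
  invisible(path)
}

#' Read an alignment from TSV
#' @param path Path to a file written by [write_alignment_tsv()].
#' @return An \code{onto_alignment}.
#' @export
read_alignment_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  grab <- function(tag) {
    h <- grep(paste0("^# ", tag, ":"), lines, value = TRUE)
    if (!length(h)) stop("alignment TSV lacks '# ", tag, ":' header")
    trimws(sub(paste0("^# ", tag, ":"), "", h[[1]]))
  }
  src <- grab("source_ontology"); tgt <- grab("target_ontology")
  body <- lines[!startsWith(lines, "#")]
  tab <- data.table::fread(text = body, sep = "\t", header = TRUE,
                           colClasses = list(character = c(1, 2, 4)))
  alignment(src, tgt,
            tab[, list(source = source_iri, target = target_iri,
                       similarity, provenance)])
}

#' Write an alignment in the OAEI/INRIA Alignment format
#'
#' RDF/XML with one \code{Cell} per mapping, relation \code{"="} and the
#' similarity as \code{measure} — the interchange format used by the
#' Ontology Alignment Evaluation Initiative. Output is deterministic.
#'
#' @param a An \code{onto_alignment}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_alignment_rdf <- function(a, path) {
  stopifnot(inherits(a, "onto_alignment"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  m <- a$mappings
  cells <- if (nrow(m)) paste0(
    "  <map>\n    <Cell>\n",
    "      <entity1 rdf:resource=\"", esc(m$source), "\"/>\n",
    "      <entity2 rdf:resource=\"", esc(m$target), "\"/>\n",
    "      <measure rdf:datatype=\"http://www.w3.org/2001/XMLSchema#float\">",
    format(m$similarity, digits = 15, trim = TRUE), "</measure>\n",
    "      <relation>=</relation>\n",
    "    </Cell>\n  </map>") else character(0)
  out <- c(
    "<?xml version=\"1.0\" encoding=\"utf-8\"?>",
    paste0("<rdf:RDF xmlns=\"http://knowledgeweb.semanticweb.org/",
           "heterogeneity/alignment\""),
    "         xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    "         xmlns:xsd=\"http://www.w3.org/2001/XMLSchema#\">",
    "<Alignment>",
    "  <xml>yes</xml>",
    "  <level>0</level>",
    "  <type>11</type>",
    paste0("  <onto1>", esc(a$source_ontology), "</onto1>"),
    paste0("  <onto2>", esc(a$target_ontology), "</onto2>"),
    cells,
    "</Alignment>",
    "</rdf:RDF>")
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' Read an alignment from the OAEI/INRIA Alignment format
#'
#' Cells whose relation is \code{"?"} (unknown-status reference entries)
#' are ignored, matching standard OAEI evaluation practice.
#'
#' @param path Path to an Alignment-format RDF/XML file.
#' @param source_ontology,target_ontology Optional ontology ids; defaults
#'   to the file's \code{onto1}/\code{onto2} declarations.
#' @return An \code{onto_alignment}.
#' @export
read_alignment_rdf <- function(path, source_ontology = NULL,
                               target_ontology = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("cannot parse alignment RDF in ", path, ": ",
                         conditionMessage(e)))
  first_text <- function(xp) {
    n <- xml2::xml_find_first(doc, xp)
    if (inherits(n, "xml_missing")) NA_character_ else trimws(xml2::xml_text(n))
  }
  if (is.null(source_ontology))
    source_ontology <- first_text("//*[local-name()='onto1']")
  if (is.null(target_ontology))
    target_ontology <- first_text("//*[local-name()='onto2']")
  if (is.na(source_ontology) || !nzchar(source_ontology))
    source_ontology <- "onto1"
  if (is.na(target_ontology) || !nzchar(target_ontology))
    target_ontology <- "onto2"
  cells <- xml2::xml_find_all(doc, "//*[local-name()='Cell']")
  rows <- lapply(cells, function(cell) {
    ent <- function(tag) {
      n <- xml2::xml_find_first(cell, paste0("./*[local-name()='", tag, "']"))
      if (inherits(n, "xml_missing")) return(NA_character_)
      res <- xml2::xml_attr(n, "resource")
      if (!is.na(res) && nzchar(res)) res else trimws(xml2::xml_text(n))
    }
    rel <- ent("relation")
    if (!is.na(rel) && rel == "?") return(NULL)
    meas <- suppressWarnings(as.numeric(ent("measure")))
    data.table::data.table(source = ent("entity1"), target = ent("entity2"),
                           similarity = if (is.na(meas)) 1 else meas,
                           provenance = "reference")
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  maps <- if (length(rows)) data.table::rbindlist(rows) else NULL
  alignment(source_ontology, target_ontology, maps)
}
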
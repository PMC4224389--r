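#' Load an ontology into a lexicon
#'
#' Parses an ontology file and reduces it to the lexical representation
#' used by the matcher: named classes with their primary label(s) and all
#' synonym annotations. Supported inputs are OWL in RDF/XML (annotation
#' properties \code{rdfs:label} and the oboInOwl synonym properties) and
#' OBO 1.2/1.4 flat files (\code{name:} and scoped \code{synonym:} lines).
#' Obsolete/deprecated classes are excluded, since their deprecated
#' synonymy would pollute the name index. Only classes are lexicalized;
#' properties and individuals are ignored.
#'
#' @param path Path to the ontology file.
#' @param format One of \code{"auto"} (dispatch on file extension),
#'   \code{"owl"} or \code{"obo"}.
#' @param ontology_id Identifier for the lexicon; defaults to the file
#'   stem.
#' @param weights Name-provenance weights, see [synonym_weights()].
#' @return An \code{onto_lexicon}. A file that parses but declares no
#'   classes yields an empty lexicon with a warning.
#' @export
load_ontology <- function(path, format = c("auto", "owl", "obo"),
                          ontology_id = NULL, weights = synonym_weights()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("ontology file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, obo = "obo", owl = "owl", rdf = "owl", xml = "owl",
                     stop("cannot infer ontology format from extension '.",
                          ext, "'; pass format explicitly"))
  }
  if (is.null(ontology_id))
    ontology_id <- tools::file_path_sans_ext(basename(path))
  parsed <- switch(format,
                   obo = parse_obo(path),
                   owl = parse_owl(path))
  if (length(parsed$classes) == 0L)
    warning("no classes found in ", path)
  ent <- parsed$entries
  if (nrow(ent)) {
    unknown <- setdiff(ent$provenance, names(weights))
    if (length(unknown))
      stop("no weight configured for provenance: ",
           paste(unknown, collapse = ", "))
    ent$weight <- unname(weights[ent$provenance])
  }
  lexicon(ontology_id, classes = parsed$classes, entries = ent)
}

# OBO 1.2/1.4 flat-file parser: [Term] stanzas with id/name/synonym lines.
# Scope tags EXACT/RELATED/BROAD/NARROW; unscoped synonyms default to
# RELATED per the OBO specification. Obsolete terms are skipped.
parse_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stanza_starts <- grep("^\\[.*\\]\\s*$", lines)
  if (!length(stanza_starts) && length(grep("^(format-version|ontology):", lines)) == 0L)
    stop("not an OBO file (no header tags and no stanzas): ", path)
  ends <- c(stanza_starts[-1] - 1L, length(lines))
  classes <- character(0)
  rows <- vector("list", length(stanza_starts))
  for (i in seq_along(stanza_starts)) {
    head_line <- trimws(lines[stanza_starts[i]])
    if (head_line != "[Term]") next
    body <- lines[seq.int(stanza_starts[i] + 1L, ends[i])]
    body <- sub("\\s*!.*$", "", body)  # strip trailing comments
    tag <- sub("^([A-Za-z_]+):.*$", "\\1", body)
    val <- trimws(sub("^[A-Za-z_]+:\\s*", "", body))
    if (any(tag == "is_obsolete" & val == "true")) next
    id <- val[tag == "id"][1]
    if (is.na(id) || !nzchar(id)) next
    iri <- canonical_iri(id)
    classes <- c(classes, iri)
    nm <- val[tag == "name"]
    syn <- val[tag == "synonym"]
    prov <- character(0); nms <- character(0)
    if (length(nm)) { nms <- nm; prov <- rep("label", length(nm)) }
    for (s in syn) {
      m <- regmatches(s, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*([A-Z]*)', s))[[1]]
      if (length(m) < 2L || !nzchar(m[2])) next
      text <- gsub('\\\\(.)', "\\1", m[2])
      scope <- tolower(m[3])
      if (!scope %in% c("exact", "related", "broad", "narrow"))
        scope <- "related"
      nms <- c(nms, text); prov <- c(prov, scope)
    }
    if (length(nms))
      rows[[i]] <- data.table::data.table(class_id = iri, name = nms,
                                          provenance = prov)
  }
  entries <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (is.null(entries) || nrow(entries) == 0L)
    entries <- data.table::data.table(class_id = character(0),
                                      name = character(0),
                                      provenance = character(0))
  list(classes = unique(classes), entries = entries)
}

# RDF/XML OWL parser. Namespace prefixes vary across serializations, so
# nodes are located by local name: owl:Class elements (or rdf:Description
# typed as owl:Class) carrying rdf:about. Deprecated classes
# (owl:deprecated "true") are dropped.
parse_owl <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("cannot parse RDF/XML in ", path, ": ",
                         conditionMessage(e)))
  if (xml2::xml_name(xml2::xml_root(doc)) != "RDF")
    stop("not an RDF/XML document (root element is not rdf:RDF): ", path)
  cls_nodes <- xml2::xml_find_all(doc, paste0(
    "//*[local-name()='Class' and @*[local-name()='about']]",
    " | //*[local-name()='Description' and @*[local-name()='about']",
    " and ./*[local-name()='type' and contains(@*[local-name()='resource'],",
    " 'owl#Class')]]"))
  syn_map <- c(hasExactSynonym = "exact", hasRelatedSynonym = "related",
               hasBroadSynonym = "broad", hasNarrowSynonym = "narrow",
               hasSynonym = "related")
  classes <- character(0)
  rows <- vector("list", length(cls_nodes))
  for (i in seq_along(cls_nodes)) {
    node <- cls_nodes[[i]]
    iri <- xml2::xml_text(
      xml2::xml_find_first(node, "@*[local-name()='about']"))
    if (is.na(iri) || !nzchar(iri)) next
    iri <- canonical_iri(iri)
    dep <- xml2::xml_text(xml2::xml_find_all(
      node, "./*[local-name()='deprecated']"))
    if (any(trimws(dep) == "true")) next
    classes <- c(classes, iri)
    labels <- xml2::xml_text(xml2::xml_find_all(
      node, "./*[local-name()='label']"))
    nms <- labels
    prov <- rep("label", length(labels))
    for (tag in names(syn_map)) {
      vals <- xml2::xml_text(xml2::xml_find_all(
        node, paste0("./*[local-name()='", tag, "']")))
      vals <- vals[nzchar(trimws(vals))]
      nms <- c(nms, vals)
      prov <- c(prov, rep(syn_map[[tag]], length(vals)))
    }
    keep <- nzchar(trimws(nms))
    if (any(keep))
      rows[[i]] <- data.table::data.table(class_id = iri, name = nms[keep],
                                          provenance = prov[keep])
  }
  entries <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (is.null(entries) || nrow(entries) == 0L)
    entries <- data.table::data.table(class_id = character(0),
                                      name = character(0),
                                      provenance = character(0))
  list(classes = unique(classes), entries = entries)
}

#' Write a lexicon as an OBO 1.4 flat file
#'
#' The inverse of the OBO reader for generated ontologies: every class
#' becomes a \code{[Term]} stanza with its label as \code{name:} and the
#' remaining names as scoped \code{synonym:} lines. Output is
#' deterministic (stanzas and synonym lines sorted), so identical
#' lexicons serialize byte-identically.
#'
#' @param x An \code{onto_lexicon}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_obo <- function(x, path) {
  stopifnot(inherits(x, "onto_lexicon"))
  scope_of <- c(label = NA, exact = "EXACT", related = "RELATED",
                broad = "BROAD", narrow = "NARROW")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.4",
               paste0("ontology: ", x$ontology_id), ""), con)
  ents <- x$entries
  for (cls in x$classes) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", obo_id_of(cls)), con)
    e <- ents[class_id == cls]
    labs <- e[provenance == "label"]$name
    if (length(labs)) {
      writeLines(paste0("name: ", labs[1]), con)
      syn <- e[!(provenance == "label" & name == labs[1])]
    } else {
      syn <- e
    }
    if (nrow(syn)) {
      sc <- ifelse(is.na(scope_of[syn$provenance]), "EXACT",
                   scope_of[syn$provenance])
      writeLines(sort(paste0("synonym: \"", syn$name, "\" ", sc, " []")), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# Compact an OBO-library PURL back to a prefixed id for OBO output.
obo_id_of <- function(iri) {
  pre <- "http://purl.obolibrary.org/obo/"
  ifelse(startsWith(iri, pre),
         sub("_", ":", substring(iri, nchar(pre) + 1L)),
         iri)
}
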
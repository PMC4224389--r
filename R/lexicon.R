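#' Normalize a class name for lexical comparison
#'
#' Applies the canonical normalization under which two class names are
#' considered "identical": Unicode compatibility normalization (NFKC),
#' case folding to lower case, replacement of punctuation and symbol
#' characters by spaces, and collapsing/trimming of whitespace. The
#' function is deterministic and idempotent; an empty result is allowed
#' (callers drop empty entries).
#'
#' @param x Character vector of raw names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_name("NK-cell,  activated")  # "nk cell activated"
#' @export
normalize_name <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- stringi::stri_trans_nfkc(as.character(x))
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "[\\p{P}\\p{S}]+", " ")
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

#' Canonicalize a class identifier to a full IRI
#'
#' OBO-style prefixed identifiers (e.g. \code{"MA:0000007"}) are expanded
#' to OBO Library PURLs (\code{"http://purl.obolibrary.org/obo/MA_0000007"})
#' so that the same concept referenced from an OWL and an OBO serialization
#' compares equal. Strings that already look like IRIs (contain
#' \code{"://"}) are returned unchanged.
#'
#' @param id Character vector of identifiers (prefixed ids or IRIs).
#' @return Character vector of canonical IRIs.
#' @export
canonical_iri <- function(id) {
  id <- as.character(id)
  is_iri <- grepl("://", id, fixed = TRUE)
  is_obo <- !is_iri & grepl("^[A-Za-z_][A-Za-z0-9_.-]*:\\S+$", id)
  id[is_obo] <- paste0(
    "http://purl.obolibrary.org/obo/",
    sub(":", "_", id[is_obo], fixed = TRUE)
  )
  id
}

#' Default name-provenance weights
#'
#' Weights attached to a class name according to its provenance: primary
#' labels are the most reliable source of a class's name, exact synonyms
#' slightly less so, and related/broad/narrow synonyms least. The ordering
#' matters more than the absolute values; all weights must lie in (0, 1].
#'
#' @return Named numeric vector with entries \code{label}, \code{exact},
#'   \code{related}, \code{broad}, \code{narrow}.
#' @export
synonym_weights <- function() {
  c(label = 1.00, exact = 0.95, related = 0.85, broad = 0.85, narrow = 0.85)
}

#' Construct an ontology lexicon
#'
#' A lexicon is the minimal representation of an ontology needed for
#' full-name matching: a set of class IRIs plus a table of weighted
#' normalized names. Names are normalized with [normalize_name()]; empty
#' names are dropped; when the same (class, name) pair arises from several
#' provenances only the highest weight is kept.
#'
#' @param ontology_id Identifier for the ontology (URI or file stem).
#' @param classes Character vector of class IRIs (canonicalized).
#' @param entries A data.frame with columns \code{class_id}, \code{name}
#'   (raw or normalized), \code{weight} in (0, 1], \code{provenance}.
#' @param normalize Normalize the \code{name} column (default TRUE).
#' @return An object of class \code{onto_lexicon}: a list with elements
#'   \code{ontology_id}, \code{classes} (sorted character vector) and
#'   \code{entries} (a data.table sorted by class, name).
#' @export
lexicon <- function(ontology_id, classes = character(0),
                    entries = NULL, normalize = TRUE) {
  stopifnot(is.character(ontology_id), length(ontology_id) == 1L,
            nzchar(ontology_id))
  classes <- sort(unique(as.character(classes)))
  if (is.null(entries) || nrow(entries) == 0L) {
    entries <- data.table::data.table(
      class_id = character(0), name = character(0),
      weight = numeric(0), provenance = character(0))
  } else {
    entries <- data.table::as.data.table(entries)[
      , list(class_id = as.character(class_id),
             name = if (normalize) normalize_name(name) else as.character(name),
             weight = as.numeric(weight),
             provenance = as.character(provenance))]
    entries <- entries[nzchar(name)]
    if (any(entries$weight <= 0 | entries$weight > 1))
      stop("entry weights must lie in (0, 1]")
    # keep max weight per (class, name); deterministic tie-break on provenance
    data.table::setorder(entries, class_id, name, -weight, provenance)
    entries <- entries[!duplicated(entries[, list(class_id, name)])]
    missing <- setdiff(entries$class_id, classes)
    if (length(missing))
      stop("entries reference classes absent from the class set: ",
           paste(utils::head(missing, 3), collapse = ", "))
  }
  data.table::setorder(entries, class_id, name)
  structure(list(ontology_id = ontology_id, classes = classes,
                 entries = entries),
            class = "onto_lexicon")
}

#' @export
print.onto_lexicon <- function(x, ...) {
  cat("<onto_lexicon> ", x$ontology_id, ": ", length(x$classes),
      " classes, ", nrow(x$entries), " name entries\n", sep = "")
  invisible(x)
}

#' Number of classes in a lexicon
#' @param x An \code{onto_lexicon}.
#' @return Integer class count.
#' @export
n_classes <- function(x) {
  stopifnot(inherits(x, "onto_lexicon"))
  length(x$classes)
}

#' Name index of a lexicon
#'
#' @param x An \code{onto_lexicon}.
#' @return A data.table keyed by \code{name} with columns \code{name},
#'   \code{class_id}, \code{weight} — the inverse of [class_index()].
#' @export
name_index <- function(x) {
  stopifnot(inherits(x, "onto_lexicon"))
  idx <- x$entries[, list(name, class_id, weight)]
  data.table::setorder(idx, name, class_id)
  idx
}

#' Class index of a lexicon
#'
#' @param x An \code{onto_lexicon}.
#' @return A data.table keyed by \code{class_id} with columns
#'   \code{class_id}, \code{name}, \code{weight}.
#' @export
class_index <- function(x) {
  stopifnot(inherits(x, "onto_lexicon"))
  idx <- x$entries[, list(class_id, name, weight)]
  data.table::setorder(idx, class_id, name)
  idx
}

#' Write a lexicon to the internal TSV dump format
#'
#' Columns: \code{class_iri}, \code{name}, \code{weight},
#' \code{provenance}. Classes that carry no names are written with an
#' empty name so the class set round-trips. The ontology id is stored in
#' a \code{# ontology_id:} header comment.
#'
#' @param x An \code{onto_lexicon}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_lexicon_tsv <- function(x, path) {
  stopifnot(inherits(x, "onto_lexicon"))
  tab <- x$entries[, list(class_iri = class_id, name, weight, provenance)]
  bare <- setdiff(x$classes, tab$class_iri)
  if (length(bare))
    tab <- rbind(tab, data.table::data.table(
      class_iri = bare, name = "", weight = NA_real_, provenance = ""))
  data.table::setorder(tab, class_iri, name)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ontology_id: ", x$ontology_id), con)
  writeLines(paste(c("class_iri", "name", "weight", "provenance"),
                   collapse = "\t"), con)
  if (nrow(tab))
    writeLines(paste(tab$class_iri, tab$name,
                     ifelse(is.na(tab$weight), "", format(tab$weight, digits = 15)),
                     tab$provenance, sep = "\t"), con)
  invisible(path)
}

#' Read a lexicon from the internal TSV dump format
#'
#' @param path Path to a file written by [write_lexicon_tsv()].
#' @return An \code{onto_lexicon}.
#' @export
read_lexicon_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- grep("^# ontology_id:", lines, value = TRUE)
  if (!length(header)) stop("lexicon dump lacks an '# ontology_id:' header")
  oid <- trimws(sub("^# ontology_id:", "", header[[1]]))
  body <- lines[!startsWith(lines, "#")]
  tab <- data.table::fread(text = body, sep = "\t", header = TRUE,
                           colClasses = list(character = c(1, 2, 4)),
                           na.strings = NULL)
  ent <- tab[nzchar(name),
             list(class_id = class_iri, name, weight = as.numeric(weight),
                  provenance)]
  lexicon(oid, classes = tab$class_iri, entries = ent, normalize = FALSE)
}
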
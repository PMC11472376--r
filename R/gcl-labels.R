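## GCL label grammar: "DOMAIN.ELEMENT.INDEX", e.g. "RH.H6.3" = third position
## of helix six in the RH domain. Domain is one of RH/KD/PH; the element
## vocabulary is open (validated for grammar only); index is 1-based.

#' Parse common labels
#'
#' Parses canonical three-part common labels of the form
#' \code{"DOMAIN.ELEMENT.INDEX"} (e.g. \code{"RH.H6.3"}, the third position
#' of helix six in the RH domain). The domain token must be one of
#' \code{RH}, \code{KD}, \code{PH}; the element token is free-form
#' (alphanumeric); the index is an integer >= 1.
#'
#' @param x character vector of label strings.
#' @return data.frame with columns \code{domain}, \code{element},
#'   \code{index} and \code{label} (the canonical serialized form).
#' @examples
#' parseGCLLabel("RH.H6.3")
#' @export
parseGCLLabel <- function(x) {
  if (!length(x) || any(!nzchar(x)))
    stop("empty label string")
  parts <- strsplit(x, ".", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed label (need exactly two dots): ",
         paste(x[bad], collapse = ", "))
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  domain <- m[, 1L]; element <- m[, 2L]; idx_raw <- m[, 3L]
  bad <- !domain %in% .GCL_DOMAINS
  if (any(bad))
    stop("unknown domain token in: ", paste(x[bad], collapse = ", "),
         " (allowed: ", paste(.GCL_DOMAINS, collapse = ", "), ")")
  bad <- !grepl("^[A-Za-z0-9]+$", element)
  if (any(bad))
    stop("invalid element token in: ", paste(x[bad], collapse = ", "))
  bad <- !grepl("^[0-9]+$", idx_raw)
  index <- suppressWarnings(as.integer(idx_raw))
  bad <- bad | is.na(index) | index < 1L
  if (any(bad))
    stop("index must be an integer >= 1 in: ", paste(x[bad], collapse = ", "))
  data.frame(domain = domain, element = element, index = index,
             label = paste(domain, element, index, sep = "."),
             stringsAsFactors = FALSE)
}

#' Build canonical labels from components
#'
#' @param domain one of \code{"RH"}, \code{"KD"}, \code{"PH"}.
#' @param element element token (e.g. \code{"H4H5"}, \code{"HK"}).
#' @param index 1-based position within the element.
#' @return canonical label string(s).
#' @export
gclLabel <- function(domain, element, index) {
  lab <- paste(domain, element, as.integer(index), sep = ".")
  parseGCLLabel(lab)$label
}

#' Drop the index of a label: the secondary-structure-element key
#'
#' @param label character vector of canonical labels.
#' @return character vector \code{"DOMAIN.ELEMENT"}.
#' @examples
#' sseKey("RH.H4H5.2")   # "RH.H4H5"
#' @export
sseKey <- function(label) {
  p <- parseGCLLabel(label)
  paste(p$domain, p$element, sep = ".")
}

#' Construct a GCLTable
#'
#' @param subtype subtype tag (e.g. \code{"GRK5"} or a subfamily tag used by
#'   the synthetic generator).
#' @param entries data.frame with columns \code{residue_number},
#'   \code{residue_name}, \code{gcl_label}.
#' @return a validated \linkS4class{GCLTable}; row order is preserved.
#' @export
GCLTable <- function(subtype, entries) {
  entries$residue_number <- as.integer(entries$residue_number)
  entries$gcl_label <- parseGCLLabel(entries$gcl_label)$label
  rownames(entries) <- NULL
  new("GCLTable", subtype = subtype,
      entries = entries[, c("residue_number", "residue_name", "gcl_label")])
}

#' Read a common-label table from TSV
#'
#' Expects a header line \code{residue_number residue_name gcl_label}
#' (tab-separated), one row per labeled residue.
#'
#' @param file path to the TSV file.
#' @param subtype subtype tag the table belongs to.
#' @return a \linkS4class{GCLTable}.
#' @export
readGCLTable <- function(file, subtype) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("residue_number", "residue_name", "gcl_label")
  if (!all(need %in% names(df)))
    stop("GCL table must have columns: ", paste(need, collapse = ", "))
  ok <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch({ parseGCLLabel(df$gcl_label[i]); TRUE },
             error = function(e) FALSE)
  }, logical(1))
  if (!all(ok))
    stop("unparseable label at row(s): ",
         paste(which(!ok), collapse = ", "), " of ", file)
  GCLTable(subtype, df)
}

#' Write a common-label table as TSV
#'
#' @param table a \linkS4class{GCLTable}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeGCLTable <- function(table, file) {
  utils::write.table(entries(table), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Map structure residues to common labels
#'
#' Attaches the table's labels to a structure chain by residue number.
#' Residues absent from the table are retained but unlabeled (and take no
#' part in downstream scoring). A residue-name disagreement between table and
#' structure is a warning, not an error, so engineered mutants map cleanly.
#'
#' @param structure a \linkS4class{StructureModel} (single chain).
#' @param table a \linkS4class{GCLTable} whose subtype matches the declared
#'   subtype of the structure.
#' @param numbering which structure numbering the table is keyed to:
#'   \code{"resno"} (current, default) or \code{"orig"} (author numbering
#'   retained through renumbering).
#' @return a \linkS4class{LabeledStructure}. Coverage (fraction of table
#'   labels present) is recorded; zero overlap is an error.
#' @export
mapStructureToGCL <- function(structure, table, numbering = c("resno", "orig")) {
  numbering <- match.arg(numbering)
  res <- residues(structure)
  key <- if (numbering == "orig") res$orig_resno else res$resno
  e <- entries(table)
  hit <- match(key, e$residue_number)
  mapped <- !is.na(hit)
  if (!any(mapped))
    stop("no overlap between table and structure numbering")
  labels <- e$gcl_label[hit[mapped]]
  names(labels) <- as.character(res$resno[mapped])
  mism <- res$resno[mapped][res$resid[mapped] != e$residue_name[hit[mapped]]]
  if (length(mism))
    warning("residue-name mismatch between table and structure at residue(s): ",
            paste(mism, collapse = ", "))
  new("LabeledStructure", structure,
      subtype = subtype(table), labels = labels,
      coverage = sum(mapped) / nrow(e), mismatches = as.integer(mism))
}
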
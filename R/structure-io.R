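## PDB reading/writing is delegated to bio3d; this module adds the pieces the
## pipeline needs around it: the REMARK 2 resolution record, an
## occupancy-based altloc policy, chain splitting with 1-based renumbering
## (author numbering kept in orig_resno), and the resolution/fragment filter.

#' Construct a FilterPolicy
#'
#' @param maxResolution drop structures with resolution strictly above this
#'   (Angstrom); default 4.0, so 4.00 itself is kept.
#' @param minLabelCoverage drop structures mapping fewer than this fraction
#'   of the label table ("short fragments"); default 0.5.
#' @param excludeUnknownResolution drop structures without a resolution
#'   record; default TRUE.
#' @return a \linkS4class{FilterPolicy}.
#' @export
filterPolicy <- function(maxResolution = 4.0, minLabelCoverage = 0.5,
                         excludeUnknownResolution = TRUE) {
  new("FilterPolicy", maxResolution = maxResolution,
      minLabelCoverage = minLabelCoverage,
      excludeUnknownResolution = excludeUnknownResolution)
}

.parseResolution <- function(path) {
  ln <- grep("^REMARK   2 RESOLUTION\\.", readLines(path, warn = FALSE),
             value = TRUE)
  if (!length(ln)) return(NA_real_)
  rest <- sub(".*RESOLUTION\\.", "", ln[1])
  m <- regmatches(rest, regexpr("[0-9]+\\.?[0-9]*", rest))
  if (!length(m)) NA_real_ else as.numeric(m)
}

## derive an element symbol from the atom-name column when the PDB element
## field is blank; leading digits (1HB) denote hydrogens
.elementFromName <- function(elety) {
  nm <- toupper(sub("^[0-9]+", "", trimws(elety)))
  two <- c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE", "CU", "NI", "CO")
  ifelse(substr(nm, 1, 2) %in% two & nchar(nm) >= 2,
         substr(nm, 1, 2), substr(nm, 1, 1))
}

.applyAltlocPolicy <- function(a) {
  alt <- ifelse(is.na(a$alt), "", a$alt)
  if (!any(nzchar(alt))) return(a)
  key <- paste(a$resno, a$elety, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    o <- a$o[idx]; o[is.na(o)] <- 1
    best <- idx[o == max(o)]
    best[order(alt[best])][1L]   # ties: altloc 'A' / first alphabetically
  }))
  a[sort(keep), , drop = FALSE]
}

#' Read a PDB file into one StructureModel per chain
#'
#' Parses polymer residues (any residue carrying a carbon CA atom, so
#' modified amino acids are kept while waters, ions and ligands are not).
#' Resolution is taken from the \code{REMARK   2 RESOLUTION.} header when
#' present, else recorded as unknown (\code{NA}). Alternate locations are
#' reduced to the highest-occupancy conformer (ties to altloc "A").
#' Hydrogens are retained in the atom table but excluded by
#' \code{\link[=accessors]{heavyAtoms}}.
#'
#' @param path path to a PDB-format file.
#' @return list of \linkS4class{StructureModel}, one per chain (chain-id
#'   order). \code{orig_resno} equals \code{resno} until
#'   \code{\link{splitAndRenumberChains}} is applied.
#' @export
readStructures <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("unreadable or empty PDB file: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  a$elesy <- ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                    .elementFromName(a$elety), trimws(a$elesy))
  a$chain[is.na(a$chain)] <- "A"
  res <- .parseResolution(path)
  code <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  out <- lapply(split(seq_len(nrow(a)), a$chain), function(idx) {
    ca <- a[idx, , drop = FALSE]
    ## polymer residues: those with a carbon CA atom (excludes Ca2+ ions)
    poly <- unique(ca$resno[ca$elety == "CA" & toupper(ca$elesy) == "C"])
    ca <- ca[ca$resno %in% poly, , drop = FALSE]
    if (!nrow(ca)) return(NULL)
    ca <- .applyAltlocPolicy(ca)
    ca <- ca[order(ca$resno), , drop = FALSE]
    atoms <- data.frame(elety = ca$elety, elesy = toupper(ca$elesy),
                        resid = ca$resid, resno = ca$resno,
                        orig_resno = ca$resno, x = ca$x, y = ca$y, z = ca$z,
                        o = ifelse(is.na(ca$o), 1, ca$o),
                        alt = ifelse(is.na(ca$alt), "", ca$alt),
                        stringsAsFactors = FALSE)
    new("StructureModel", pdbCode = code, chainId = ca$chain[1],
        resolution = res, atoms = atoms)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) stop("no polymer atoms in ", path)
  names(out) <- vapply(out, function(m) paste0(m@pdbCode, "_", m@chainId), "")
  out
}

#' Split chains into independent structures renumbered from 1
#'
#' Each chain model becomes an independent structure whose residues are
#' renumbered sequentially from 1 in chain order; the author numbering is
#' retained in the \code{orig_resno} column so label tables keyed to author
#' numbering still apply (via \code{mapStructureToGCL(..., numbering =
#' "orig")}). Atom counts and coordinates are untouched.
#'
#' @param models list of \linkS4class{StructureModel}.
#' @return list of renumbered models (empty in, empty out).
#' @export
splitAndRenumberChains <- function(models) {
  lapply(models, function(m) {
    a <- m@atoms
    if (nrow(a)) {
      a$orig_resno <- a$resno
      a$resno <- cumsum(!duplicated(a$resno))
      m@atoms <- a
    }
    m
  })
}

#' Apply the resolution and fragment filters
#'
#' Drops structures with resolution strictly above the maximum, structures
#' without a resolution record (when the policy says so), and structures
#' whose label coverage falls below the fragment threshold. Every drop
#' carries a machine-readable reason.
#'
#' @param models list of \linkS4class{StructureModel} (or LabeledStructure).
#' @param coverage numeric vector of per-model label coverage, parallel to
#'   \code{models}; may be omitted when models are LabeledStructure.
#' @param policy a \linkS4class{FilterPolicy}.
#' @return list with elements \code{kept} (models), \code{dropped} (models)
#'   and \code{reasons} (data.frame \code{structure_id}, \code{reason} with
#'   one row per dropped model; reasons are \code{"resolution"},
#'   \code{"unknown_resolution"} or \code{"fragment"}).
#' @export
filterStructures <- function(models, coverage = NULL, policy = filterPolicy()) {
  if (is.null(coverage))
    coverage <- vapply(models, function(m)
      if (is(m, "LabeledStructure")) m@coverage else 1, numeric(1))
  stopifnot(length(coverage) == length(models))
  reason <- character(length(models))
  for (i in seq_along(models)) {
    r <- models[[i]]@resolution
    if (is.na(r)) {
      if (policy@excludeUnknownResolution) reason[i] <- "unknown_resolution"
    } else if (r > policy@maxResolution) {
      reason[i] <- "resolution"
    }
    if (!nzchar(reason[i]) && coverage[i] < policy@minLabelCoverage)
      reason[i] <- "fragment"
  }
  ids <- vapply(models, function(m) paste0(m@pdbCode, "_", m@chainId), "")
  drop <- nzchar(reason)
  list(kept = models[!drop], dropped = models[drop],
       reasons = data.frame(structure_id = ids[drop], reason = reason[drop],
                            stringsAsFactors = FALSE))
}

#' Write a StructureModel as a single-chain PDB file
#'
#' Mirrors the preprocessing outputs: one chain per file, with a
#' \code{REMARK   2} resolution record when the resolution is known.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeStructure <- function(model, file) {
  a <- model@atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   elesy = a$elesy, chain = rep(model@chainId, nrow(a)),
                   o = a$o, b = rep(0, nrow(a)))
  if (!is.na(model@resolution)) {
    body <- readLines(file, warn = FALSE)
    writeLines(c(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                         model@resolution), body), file)
  }
  invisible(file)
}
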
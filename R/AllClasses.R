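#' @import methods
NULL

.GCL_DOMAINS <- c("RH", "KD", "PH")
.GRK_SUBTYPES <- paste0("GRK", 1:7)

#' GCLTable: common-label table for one kinase subtype
#'
#' Maps author residue numbers of one GRK subtype to canonical common labels
#' (\code{"DOMAIN.ELEMENT.INDEX"}). Tables are read from TSV with columns
#' \code{residue_number}, \code{residue_name}, \code{gcl_label}.
#'
#' @slot subtype character(1), one of \code{GRK1}..\code{GRK7} or a synthetic
#'   subfamily tag such as \code{"GRK23"}.
#' @slot entries data.frame with columns \code{residue_number} (integer),
#'   \code{residue_name} (3-letter code) and \code{gcl_label} (canonical
#'   label string); labels and residue numbers are unique.
#' @export
setClass("GCLTable",
  representation(subtype = "character", entries = "data.frame"))

setValidity("GCLTable", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("residue_number", "residue_name", "gcl_label")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (length(object@subtype) != 1L || !nzchar(object@subtype))
    msg <- c(msg, "subtype must be a single non-empty string")
  dupl <- unique(e$gcl_label[duplicated(e$gcl_label)])
  if (length(dupl))
    msg <- c(msg, paste("duplicate labels:", paste(dupl, collapse = ", ")))
  dupn <- unique(e$residue_number[duplicated(e$residue_number)])
  if (length(dupn))
    msg <- c(msg, paste("duplicate residue numbers:",
                        paste(dupn, collapse = ", ")))
  ok <- tryCatch({ parseGCLLabel(e$gcl_label); TRUE },
                 error = function(err) conditionMessage(err))
  if (!isTRUE(ok)) msg <- c(msg, ok)
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' StructureModel: one polymer chain with coordinates
#'
#' A single protein chain parsed from a PDB file. Atoms are stored as a
#' data.frame in bio3d column convention plus \code{orig_resno}, the author
#' numbering retained through renumbering.
#'
#' @slot pdbCode character(1) structure identifier (file stem).
#' @slot chainId character(1) chain identifier.
#' @slot resolution numeric(1) in Angstrom; \code{NA} when the file carries
#'   no resolution record.
#' @slot atoms data.frame with columns \code{elety}, \code{elesy},
#'   \code{resid}, \code{resno}, \code{orig_resno}, \code{x}, \code{y},
#'   \code{z}, \code{o}, \code{alt}.
#' @export
setClass("StructureModel",
  representation(pdbCode = "character", chainId = "character",
                 resolution = "numeric", atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msg <- character()
  need <- c("elety", "elesy", "resid", "resno", "orig_resno",
            "x", "y", "z", "o", "alt")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msg <- c(msg, "non-finite coordinates")
    if (is.unsorted(a$resno))
      msg <- c(msg, "residue numbers must be non-decreasing")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' LabeledStructure: a chain with residues mapped to common labels
#'
#' @slot subtype character(1) declared subtype of the structure.
#' @slot labels named character: residue number (as character) -> canonical
#'   label, for labeled residues only.
#' @slot coverage numeric(1): fraction of the table's labels present in the
#'   structure.
#' @slot mismatches integer: residue numbers whose residue name differs
#'   between structure and table (mapping retained, flagged).
#' @export
setClass("LabeledStructure", contains = "StructureModel",
  representation(subtype = "character", labels = "character",
                 coverage = "numeric", mismatches = "integer"))

# ---- policy objects -------------------------------------------------------

#' Structure filter policy
#'
#' @slot maxResolution keep structures with resolution <= this (strictly
#'   above is dropped), Angstrom.
#' @slot minLabelCoverage drop structures mapping fewer than this fraction of
#'   table labels ("short fragments").
#' @slot excludeUnknownResolution drop structures without a resolution record.
#' @export
setClass("FilterPolicy",
  representation(maxResolution = "numeric", minLabelCoverage = "numeric",
                 excludeUnknownResolution = "logical"),
  prototype(maxResolution = 4.0, minLabelCoverage = 0.5,
            excludeUnknownResolution = TRUE))

setValidity("FilterPolicy", function(object) {
  if (object@maxResolution <= 0) return("maxResolution must be positive")
  if (object@minLabelCoverage < 0 || object@minLabelCoverage > 1)
    return("minLabelCoverage must lie in [0, 1]")
  TRUE
})

#' Closed/open state thresholds
#'
#' A structure is closed when the minimal inter-region heavy-atom distance is
#' strictly under \code{closedMax}, open when strictly over \code{openMin},
#' intermediate otherwise (boundary equality included in intermediate).
#'
#' @slot closedMax Angstrom, default 3.3.
#' @slot openMin Angstrom, default 5.0.
#' @slot regionA,regionB SSE keys (\code{"DOMAIN.ELEMENT"}) of the two lock
#'   regions, defaults \code{RH.H4H5} and \code{KD.HK}.
#' @export
setClass("StateThresholds",
  representation(closedMax = "numeric", openMin = "numeric",
                 regionA = "character", regionB = "character"),
  prototype(closedMax = 3.3, openMin = 5.0,
            regionA = "RH.H4H5", regionB = "KD.HK"))

setValidity("StateThresholds", function(object) {
  if (!(object@closedMax > 0 && object@closedMax < object@openMin))
    return("need 0 < closedMax < openMin")
  TRUE
})

#' Contact definition policy
#'
#' A residue pair is in contact when the chain-position gap is strictly
#' greater than \code{minSequenceGap} (long-range) and the minimal heavy-atom
#' distance is <= \code{heavyAtomCutoff} (inclusive).
#'
#' @slot heavyAtomCutoff Angstrom, default 4.5.
#' @slot minSequenceGap integer, default 5; a gap of exactly 5 is excluded.
#' @export
setClass("ContactPolicy",
  representation(heavyAtomCutoff = "numeric", minSequenceGap = "integer"),
  prototype(heavyAtomCutoff = 4.5, minSequenceGap = 5L))

setValidity("ContactPolicy", function(object) {
  if (object@heavyAtomCutoff <= 0) return("heavyAtomCutoff must be positive")
  if (object@minSequenceGap < 0L) return("minSequenceGap must be >= 0")
  TRUE
})

#' Change-network policy
#'
#' @slot residueThreshold residue-level edges require |cc_a + cc_b| strictly
#'   greater than this; default 1.
#' @slot requireSameSign keep only pairs whose two subfamily CC scores share
#'   a sign; default TRUE.
#' @export
setClass("NetworkPolicy",
  representation(residueThreshold = "numeric", requireSameSign = "logical"),
  prototype(residueThreshold = 1.0, requireSameSign = TRUE))

setValidity("NetworkPolicy", function(object) {
  if (object@residueThreshold < 0) return("residueThreshold must be >= 0")
  TRUE
})

#' SASA computation policy
#'
#' @slot probeRadius solvent probe radius, Angstrom (default 1.4).
#' @slot spherePoints number of sampling points per atom (default 960).
#' @slot radii named numeric, element symbol -> van der Waals radius.
#' @slot referenceMax named numeric, residue type -> maximum accessible
#'   surface area used to normalise rSASA.
#' @export
setClass("SasaPolicy",
  representation(probeRadius = "numeric", spherePoints = "integer",
                 radii = "numeric", referenceMax = "numeric"))

setValidity("SasaPolicy", function(object) {
  if (object@probeRadius <= 0) return("probeRadius must be positive")
  if (object@spherePoints < 92L) return("spherePoints must be >= 92")
  if (any(object@radii <= 0)) return("vdW radii must be positive")
  TRUE
})

# ---- result containers ----------------------------------------------------

#' ScoreTable: contact scores per label (or element) pair
#'
#' Holds per-pair Average Contact Scores (ACS, fraction of structures with a
#' contact at residue level; mean contact count at SSE level) for the closed
#' and open groups and the Conformational-Change score
#' \code{cc = acs_closed - acs_open}.
#'
#' @slot level "residue" or "sse".
#' @slot scores data.frame with columns \code{label_i}, \code{label_j},
#'   \code{acs_closed}, \code{acs_open}, \code{cc}, \code{no_change},
#'   \code{partition}.
#' @slot nClosed,nOpen group sizes.
#' @slot policy the ContactPolicy used.
#' @export
setClass("ScoreTable",
  representation(level = "character", scores = "data.frame",
                 nClosed = "integer", nOpen = "integer",
                 policy = "ContactPolicy"))

setValidity("ScoreTable", function(object) {
  if (!object@level %in% c("residue", "sse"))
    return("level must be 'residue' or 'sse'")
  s <- object@scores
  need <- c("label_i", "label_j")
  if (!all(need %in% names(s)))
    return("scores must have label_i / label_j columns")
  if (object@level == "residue" && nrow(s) && "cc" %in% names(s) &&
      any(abs(s$cc) > 1 + 1e-9))
    return("residue-level CC must lie in [-1, 1]")
  TRUE
})

#' ChangeNetwork: common-tendency conformational-change network
#'
#' Edges connect label (residue level) or element (SSE level) pairs whose CC
#' scores share a sign in both subfamilies; the edge weight is the sum of the
#' two subfamily CC scores, positive = closed-favoring.
#'
#' @slot level "residue" or "sse".
#' @slot edges data.frame with columns \code{label_i}, \code{label_j},
#'   \code{cc_a}, \code{cc_b}, \code{weight}, \code{direction}.
#' @export
setClass("ChangeNetwork",
  representation(level = "character", edges = "data.frame"))

setValidity("ChangeNetwork", function(object) {
  e <- object@edges
  need <- c("label_i", "label_j", "cc_a", "cc_b", "weight", "direction")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(sign(e$cc_a) != sign(e$cc_b)))
      return("edge CC scores must share a sign in both subfamilies")
    if (max(abs(e$weight - (e$cc_a + e$cc_b))) > 1e-9)
      return("edge weight must equal cc_a + cc_b")
  }
  TRUE
})

#' ConservationProfile: per-position conservation on the 0-11 scale
#'
#' @slot profile data.frame with columns \code{gcl_label}, \code{score}
#'   (0-11; 11 = fully conserved identity), \code{n_residues} (non-gap count),
#'   \code{gap_fraction}, \code{flag} ("ok", "low_confidence" for gap-heavy
#'   columns, "undefined" for all-gap columns).
#' @slot nSequences number of alignment rows scored.
#' @export
setClass("ConservationProfile",
  representation(profile = "data.frame", nSequences = "integer"))

setValidity("ConservationProfile", function(object) {
  p <- object@profile
  need <- c("gcl_label", "score", "n_residues", "gap_fraction", "flag")
  if (!all(need %in% names(p)))
    return(paste("profile must have columns:", paste(need, collapse = ", ")))
  sc <- p$score[p$flag != "undefined"]
  if (length(sc) && (any(sc < 0) || any(sc > 11)))
    return("scores must lie in [0, 11]")
  TRUE
})
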
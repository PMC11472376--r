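#' @rdname accessors
#' @export
setGeneric("pdbCode", function(x) standardGeneric("pdbCode"))
#' @rdname accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))
#' @rdname accessors
#' @export
setGeneric("structureResolution",
           function(x) standardGeneric("structureResolution"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("heavyAtoms", function(x) standardGeneric("heavyAtoms"))
#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("gclLabels", function(x) standardGeneric("gclLabels"))
#' @rdname accessors
#' @export
setGeneric("labelCoverage", function(x) standardGeneric("labelCoverage"))
#' @rdname accessors
#' @export
setGeneric("subtype", function(x) standardGeneric("subtype"))
#' @rdname accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
#' @rdname accessors
#' @export
setGeneric("scoreLevel", function(x) standardGeneric("scoreLevel"))
#' @rdname accessors
#' @export
setGeneric("ccScores", function(x) standardGeneric("ccScores"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("conservation", function(x) standardGeneric("conservation"))

# ---- accessor methods -----------------------------------------------------

#' Accessors for gclkit objects
#'
#' Small read-only accessors for the S4 containers: structure identity and
#' resolution, atom/residue tables, label maps and coverage, score tables,
#' network edges/nodes and conservation profiles.
#'
#' @param x a gclkit S4 object.
#' @param ... unused.
#' @return The corresponding slot content (see each class page).
#' @name accessors
NULL

#' @rdname accessors
setMethod("pdbCode", "StructureModel", function(x) x@pdbCode)
#' @rdname accessors
setMethod("chainId", "StructureModel", function(x) x@chainId)
#' @rdname accessors
setMethod("structureResolution", "StructureModel", function(x) x@resolution)
#' @rdname accessors
setMethod("atoms", "StructureModel", function(x, ...) x@atoms)

#' @rdname accessors
setMethod("heavyAtoms", "StructureModel", function(x) {
  a <- x@atoms
  a[!(toupper(a$elesy) %in% c("H", "D")), , drop = FALSE]
})

#' @rdname accessors
setMethod("residues", "StructureModel", function(x) {
  a <- x@atoms
  keep <- !duplicated(a$resno)
  data.frame(resno = a$resno[keep], orig_resno = a$orig_resno[keep],
             resid = a$resid[keep], stringsAsFactors = FALSE)
})

#' @rdname accessors
setMethod("gclLabels", "LabeledStructure", function(x) x@labels)
#' @rdname accessors
setMethod("labelCoverage", "LabeledStructure", function(x) x@coverage)
#' @rdname accessors
setMethod("subtype", "LabeledStructure", function(x) x@subtype)
#' @rdname accessors
setMethod("subtype", "GCLTable", function(x) x@subtype)
#' @rdname accessors
setMethod("entries", "GCLTable", function(x) x@entries)
#' @rdname accessors
setMethod("scoreLevel", "ScoreTable", function(x) x@level)
#' @rdname accessors
setMethod("ccScores", "ScoreTable", function(x) x@scores)
#' @rdname accessors
setMethod("networkEdges", "ChangeNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("networkNodes", "ChangeNetwork", function(x) {
  sort(unique(c(x@edges$label_i, x@edges$label_j)))
})

#' @rdname accessors
setMethod("conservation", "ConservationProfile", function(x) x@profile)

# ---- show methods ---------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  res <- if (is.na(object@resolution)) "unknown"
         else sprintf("%.2f A", object@resolution)
  cat(sprintf("%s of %s chain %s: %d residues, %d atoms, resolution %s\n",
              class(object), object@pdbCode, object@chainId,
              length(unique(object@atoms$resno)), nrow(object@atoms), res))
  if (is(object, "LabeledStructure"))
    cat(sprintf("  subtype %s, %d labeled residues, coverage %.2f\n",
                object@subtype, length(object@labels), object@coverage))
})

setMethod("show", "GCLTable", function(object) {
  cat(sprintf("GCLTable for %s: %d labeled positions\n",
              object@subtype, nrow(object@entries)))
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable (%s level): %d pairs, groups closed n=%d / open n=%d\n",
              object@level, nrow(object@scores),
              object@nClosed, object@nOpen))
  cat(sprintf("  contact policy: cutoff %.2f A, sequence gap > %d\n",
              object@policy@heavyAtomCutoff, object@policy@minSequenceGap))
})

setMethod("show", "ChangeNetwork", function(object) {
  cat(sprintf("ChangeNetwork (%s level): %d nodes, %d edges\n",
              object@level, length(networkNodes(object)),
              nrow(object@edges)))
})

setMethod("show", "ConservationProfile", function(object) {
  ok <- object@profile$flag != "undefined"
  cat(sprintf("ConservationProfile: %d positions over %d sequences, median score %.1f\n",
              nrow(object@profile), object@nSequences,
              stats::median(object@profile$score[ok])))
})
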
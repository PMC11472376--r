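## Closed/open classification by the ionic lock: the minimal heavy-atom
## distance between the bottom loop of the RH domain (RH.H4H5) and the
## bottom helix of the kinase domain (KD.HK). Under 3.3 A = closed, over
## 5.0 A = open, in between (including the boundaries) = intermediate.

#' Construct StateThresholds
#'
#' @param closedMax closed iff lock distance strictly under this (default
#'   3.3 Angstrom).
#' @param openMin open iff lock distance strictly over this (default 5.0).
#' @param regionA,regionB SSE keys of the two lock regions.
#' @return a \linkS4class{StateThresholds}.
#' @export
stateThresholds <- function(closedMax = 3.3, openMin = 5.0,
                            regionA = "RH.H4H5", regionB = "KD.HK") {
  new("StateThresholds", closedMax = closedMax, openMin = openMin,
      regionA = regionA, regionB = regionB)
}

## heavy atoms of labeled residues, with label + chain position attached
.labeledHeavy <- function(ls, atoms = c("heavy", "ca")) {
  atoms <- match.arg(atoms)
  a <- heavyAtoms(ls)
  if (atoms == "ca")
    a <- a[a$elety == "CA", , drop = FALSE]
  lab <- gclLabels(ls)
  hit <- match(as.character(a$resno), names(lab))
  a <- a[!is.na(hit), , drop = FALSE]
  a$label <- lab[hit[!is.na(hit)]]
  a
}

.pairwiseD2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
}

#' Minimal inter-region heavy-atom distance
#'
#' Minimum over all heavy-atom pairs (one atom from each region) of the
#' Euclidean distance, together with the residue pair achieving it. Ties are
#' broken by lexicographic order of the label pair.
#'
#' @param ls a \linkS4class{LabeledStructure}.
#' @param a,b SSE keys (\code{"DOMAIN.ELEMENT"}) of the two regions.
#' @param atoms \code{"heavy"} (default) or \code{"ca"} for a CA-only mode.
#' @return list with \code{distance} (Angstrom) and \code{pair}, a one-row
#'   data.frame \code{label_a}, \code{resname_a}, \code{label_b},
#'   \code{resname_b}.
#' @export
minRegionDistance <- function(ls, a = "RH.H4H5", b = "KD.HK",
                              atoms = c("heavy", "ca")) {
  atoms <- match.arg(atoms)
  h <- .labeledHeavy(ls, atoms)
  key <- sseKey(h$label)
  ha <- h[key == a, , drop = FALSE]
  hb <- h[key == b, , drop = FALSE]
  if (!nrow(ha)) stop("region absent from structure: ", a)
  if (!nrow(hb)) stop("region absent from structure: ", b)
  D2 <- .pairwiseD2(as.matrix(ha[, c("x", "y", "z")]),
                    as.matrix(hb[, c("x", "y", "z")]))
  ## minimal distance per residue pair, then global min with label tie-break
  ra <- ha$resno; rb <- hb$resno
  cand <- expand.grid(ia = unique(ra), ib = unique(rb))
  cand$d2 <- mapply(function(i, j) min(D2[ra == i, rb == j]),
                    cand$ia, cand$ib)
  cand$label_a <- gclLabels(ls)[as.character(cand$ia)]
  cand$label_b <- gclLabels(ls)[as.character(cand$ib)]
  best <- cand[order(cand$d2, cand$label_a, cand$label_b), ][1L, ]
  resn <- residues(ls)
  list(distance = sqrt(max(best$d2, 0)),
       pair = data.frame(
         label_a = best$label_a,
         resname_a = resn$resid[match(best$ia, resn$resno)],
         label_b = best$label_b,
         resname_b = resn$resid[match(best$ib, resn$resno)],
         stringsAsFactors = FALSE))
}

#' Classify lock distances into closed/intermediate/open
#'
#' Closed iff strictly under \code{closedMax}; open iff strictly over
#' \code{openMin}; otherwise intermediate (boundary equality is
#' intermediate). Intermediate structures are retained with a state call but
#' excluded from closed/open group scoring.
#'
#' @param distance numeric vector of lock distances (Angstrom, >= 0).
#' @param thresholds a \linkS4class{StateThresholds}.
#' @return factor with levels \code{closed}, \code{intermediate},
#'   \code{open}.
#' @export
classifyState <- function(distance, thresholds = stateThresholds()) {
  stopifnot(all(distance >= 0))
  out <- ifelse(distance < thresholds@closedMax, "closed",
         ifelse(distance > thresholds@openMin, "open", "intermediate"))
  factor(out, levels = c("closed", "intermediate", "open"))
}

#' Full state call for one structure
#'
#' Bundles the lock distance, the state and the closest residue pair (with
#' residue names) for subfamily-level tabulation.
#'
#' @param ls a \linkS4class{LabeledStructure}.
#' @param thresholds a \linkS4class{StateThresholds}.
#' @param atoms distance mode, as in \code{\link{minRegionDistance}}.
#' @return one-row data.frame: \code{structure_id}, \code{distance},
#'   \code{state}, \code{label_a}, \code{resname_a}, \code{label_b},
#'   \code{resname_b}.
#' @export
lockContactPair <- function(ls, thresholds = stateThresholds(),
                            atoms = c("heavy", "ca")) {
  md <- minRegionDistance(ls, thresholds@regionA, thresholds@regionB,
                          atoms = match.arg(atoms))
  cbind(data.frame(structure_id = paste0(ls@pdbCode, "_", ls@chainId),
                   distance = md$distance,
                   state = as.character(classifyState(md$distance, thresholds)),
                   stringsAsFactors = FALSE),
        md$pair)
}

#' State calls for a set of structures
#'
#' @param structures list of \linkS4class{LabeledStructure}.
#' @param thresholds a \linkS4class{StateThresholds}.
#' @return data.frame with one \code{\link{lockContactPair}} row per
#'   structure; suitable for the distance histogram and state tabulation.
#' @export
classifyStructures <- function(structures, thresholds = stateThresholds()) {
  do.call(rbind, lapply(structures, lockContactPair, thresholds = thresholds))
}
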
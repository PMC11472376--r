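## Shrake-Rupley solvent-accessible surface area: each heavy atom is covered
## with a deterministic quasi-uniform point shell at radius (vdW + probe);
## the accessible fraction is the share of points outside every other
## atom's expanded sphere. rSASA normalises residue SASA by a residue-type
## maximum accessible area (Tien et al. 2013 theoretical values).

.DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

## Theoretical maximum accessible surface areas (A^2) per residue type
.DEFAULT_MAXASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Construct a SasaPolicy
#'
#' @param probeRadius solvent probe radius in Angstrom (default 1.4, a water
#'   molecule).
#' @param spherePoints points per atom shell (default 960; more points =
#'   finer areas, roughly 1/sqrt(n) convergence).
#' @param radii named van der Waals radii per element symbol (Angstrom).
#' @param referenceMax named maximum accessible areas per residue type
#'   (Angstrom^2) for rSASA normalisation.
#' @return a \linkS4class{SasaPolicy}.
#' @export
sasaPolicy <- function(probeRadius = 1.4, spherePoints = 960L,
                       radii = .DEFAULT_VDW, referenceMax = .DEFAULT_MAXASA) {
  new("SasaPolicy", probeRadius = probeRadius,
      spherePoints = as.integer(spherePoints), radii = radii,
      referenceMax = referenceMax)
}

## deterministic quasi-uniform points on the unit sphere (golden spiral)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA over the heavy atoms of a structure; hydrogens are
#' excluded. Per-residue SASA is the sum over the residue's atoms.
#'
#' @param structure a \linkS4class{StructureModel}.
#' @param policy a \linkS4class{SasaPolicy}.
#' @return list with \code{atom} (numeric vector, one value per heavy atom,
#'   Angstrom^2) and \code{residue} (named numeric vector keyed by residue
#'   number).
#' @export
shrakeRupleySasa <- function(structure, policy = sasaPolicy()) {
  a <- heavyAtoms(structure)
  if (!nrow(a)) stop("structure has no heavy atoms")
  ele <- toupper(a$elesy)
  unknown <- setdiff(unique(ele), names(policy@radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r <- policy@radii[ele] + policy@probeRadius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  pts <- .spherePoints(policy@spherePoints)
  area <- numeric(n)
  D2 <- .pairwiseD2(xyz, xyz)
  for (i in seq_len(n)) {
    ## neighbours whose expanded sphere can reach atom i's shell
    nb <- which(D2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    buried <- rep(FALSE, nrow(p))
    for (j in nb) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      buried <- buried | d2 < r[j]^2
      if (all(buried)) break
    }
    area[i] <- 4 * pi * r[i]^2 * mean(!buried)
  }
  residue <- tapply(area, a$resno, sum)
  list(atom = area,
       residue = stats::setNames(as.numeric(residue), names(residue)))
}

#' Relative SASA of selected positions, closed vs open groups
#'
#' rSASA = residue SASA / reference maximum for its residue type, clamped to
#' [0, 1.2]. Group means and closed-minus-open differences are reported per
#' position; a structure missing a position is skipped for that position
#' with a warning.
#'
#' @param closed,open lists of \linkS4class{LabeledStructure}.
#' @param positions character vector of common labels to evaluate.
#' @param policy a \linkS4class{SasaPolicy}.
#' @return data.frame \code{position}, \code{mean_rsasa_closed},
#'   \code{mean_rsasa_open}, \code{difference} (closed minus open),
#'   \code{n_closed}, \code{n_open}.
#' @export
relativeSasaByState <- function(closed, open, positions,
                                policy = sasaPolicy()) {
  stopifnot(length(positions) > 0)
  groupVals <- function(group) {
    vals <- matrix(NA_real_, nrow = length(group), ncol = length(positions))
    for (k in seq_along(group)) {
      ls <- group[[k]]
      sasa <- shrakeRupleySasa(ls, policy)$residue
      lab <- gclLabels(ls)
      res <- residues(ls)
      for (m in seq_along(positions)) {
        hit <- names(lab)[lab == positions[m]]
        if (!length(hit)) {
          warning("position ", positions[m], " missing in ",
                  pdbCode(ls), "_", chainId(ls), "; skipped")
          next
        }
        rtype <- res$resid[match(as.integer(hit[1]), res$resno)]
        if (!rtype %in% names(policy@referenceMax))
          stop("no reference max ASA for residue type ", rtype)
        vals[k, m] <- min(max(sasa[[hit[1]]] / policy@referenceMax[[rtype]],
                              0), 1.2)
      }
    }
    vals
  }
  vc <- groupVals(closed); vo <- groupVals(open)
  data.frame(position = positions,
             mean_rsasa_closed = colMeans(vc, na.rm = TRUE),
             mean_rsasa_open = colMeans(vo, na.rm = TRUE),
             difference = colMeans(vc, na.rm = TRUE) -
                          colMeans(vo, na.rm = TRUE),
             n_closed = colSums(!is.na(vc)), n_open = colSums(!is.na(vo)),
             stringsAsFactors = FALSE)
}
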
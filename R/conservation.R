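## Alignment-column conservation on the 0-11 physicochemical scale: 11 for a
## fully conserved identity column, otherwise the number of the ten
## physicochemical property classes (Livingstone & Barton / AMAS convention)
## on which all non-gap residues agree -- a property conserved as present or
## conserved as absent counts; a column whose residues share the complete
## property profile of a class scores 10.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

.propertyClasses <- list(
  hydrophobic = c("I","L","V","C","A","G","M","F","Y","W","H","K","T"),
  polar       = c("Y","W","H","K","R","E","Q","D","N","S","T","C"),
  small       = c("V","C","A","G","D","N","S","T","P"),
  proline     = "P",
  tiny        = c("A","G","S"),
  aliphatic   = c("I","L","V"),
  aromatic    = c("F","Y","W","H"),
  charged     = c("H","K","R","E","D"),
  positive    = c("H","K","R"),
  negative    = c("E","D"))

#' The physicochemical property class table
#'
#' Ten amino-acid property classes (hydrophobic, polar, small, proline,
#' tiny, aliphatic, aromatic, charged, positive, negative) used by the 0-11
#' conservation score. Residues outside the standard twenty carry no
#' properties.
#'
#' @return logical matrix, rows = property classes, columns = one-letter
#'   residue codes.
#' @export
aaPropertyTable <- function() {
  m <- matrix(FALSE, nrow = length(.propertyClasses), ncol = length(.AA20),
              dimnames = list(names(.propertyClasses), .AA20))
  for (p in names(.propertyClasses)) m[p, .propertyClasses[[p]]] <- TRUE
  m
}

.alignmentMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "AAStringSet") || inherits(x, "XStringSet")) {
    w <- unique(Biostrings::width(x))
    if (length(w) != 1L)
      stop("alignment rows differ in width; input must be aligned")
    m <- do.call(rbind, strsplit(as.character(x), ""))
    rownames(m) <- names(x)
    return(m)
  }
  stop("expected an aligned AAStringSet or a character matrix")
}

.GAP_CHARS <- c("-", ".", "*", " ")

#' Score alignment-column conservation on the 0-11 scale
#'
#' Per column: 11 iff all non-gap residues are identical; otherwise the
#' number of physicochemical property classes (out of ten, see
#' \code{\link{aaPropertyTable}}) on which every non-gap residue agrees
#' (property present in all, or absent in all). A column whose residues
#' share a complete class profile scores 10. The shared set is computed over
#' non-gap residues; columns with a gap fraction above
#' \code{gapFlagThreshold} are flagged \code{low_confidence}, all-gap
#' columns \code{undefined} (score \code{NA}).
#'
#' @param x aligned \code{AAStringSet} or character matrix (rows =
#'   sequences, columns = positions); column names, when present, are used
#'   as position labels.
#' @param labels optional character vector of position labels overriding
#'   column names.
#' @param gapFlagThreshold flag columns with more than this gap fraction
#'   (default 0.5).
#' @return a \linkS4class{ConservationProfile}.
#' @export
conservationScores <- function(x, labels = NULL, gapFlagThreshold = 0.5) {
  m <- .alignmentMatrix(x)
  if (nrow(m) < 2L) stop("need at least two sequences")
  if (is.null(labels)) labels <- colnames(m)
  if (is.null(labels)) labels <- paste0("col", seq_len(ncol(m)))
  props <- aaPropertyTable()
  score <- numeric(ncol(m)); nres <- integer(ncol(m))
  gapf <- numeric(ncol(m)); flag <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- toupper(m[, j])
    isgap <- col %in% .GAP_CHARS
    res <- col[!isgap]
    nres[j] <- length(res)
    gapf[j] <- mean(isgap)
    if (!length(res)) {
      score[j] <- NA_real_; flag[j] <- "undefined"; next
    }
    u <- unique(res)
    if (length(u) == 1L) {
      score[j] <- 11
    } else {
      pv <- vapply(u, function(r)
        if (r %in% colnames(props)) props[, r] else rep(FALSE, nrow(props)),
        logical(nrow(props)))
      score[j] <- sum(apply(pv, 1L, function(row) all(row) || !any(row)))
    }
    flag[j] <- if (gapf[j] > gapFlagThreshold) "low_confidence" else "ok"
  }
  new("ConservationProfile",
      profile = data.frame(gcl_label = labels, score = score,
                           n_residues = nres, gap_fraction = gapf,
                           flag = flag, stringsAsFactors = FALSE),
      nSequences = nrow(m))
}

#' Filter per-subtype sequence sets to a common-species core
#'
#' Drops sequences whose ungapped length falls outside the reference length
#' +/- \code{window}, then keeps only species present in every subtype so
#' each subtype contributes the same species (and hence the same count).
#'
#' @param raw named list (one element per subtype) of \code{AAStringSet};
#'   sequence names are species identifiers (exact-match equality).
#' @param referenceLengths named numeric, subtype -> reference (human)
#'   ungapped length.
#' @param window length tolerance around the reference (default 50).
#' @return list with \code{sets} (filtered named list of AAStringSet),
#'   \code{species} (common species ids), \code{counts} (per-subtype
#'   sequence counts, all equal) and \code{total} (sum of counts).
#' @export
buildGclSequenceSet <- function(raw, referenceLengths, window = 50) {
  stopifnot(is.list(raw), !is.null(names(raw)))
  filtered <- lapply(names(raw), function(st) {
    s <- raw[[st]]
    len <- vapply(as.character(s), function(sq)
      sum(!strsplit(sq, "")[[1]] %in% .GAP_CHARS), integer(1))
    ref <- referenceLengths[[st]]
    if (is.null(ref) || is.na(ref))
      stop("no reference length for subtype ", st)
    s[len >= ref - window & len <= ref + window]
  })
  names(filtered) <- names(raw)
  common <- Reduce(intersect, lapply(filtered, names))
  if (!length(common)) stop("no common species")
  sets <- lapply(filtered, function(s) s[common])
  counts <- vapply(sets, length, integer(1))
  list(sets = sets, species = common, counts = counts, total = sum(counts))
}

#' Reduce an alignment to the reference's labeled columns
#'
#' Output columns are exactly the common-label positions of the reference
#' sequence: alignment columns holding a reference residue whose number
#' appears in the table are kept (named by their label), all other columns
#' are dropped. Other sequences contribute whatever the alignment places in
#' those columns, residue or gap.
#'
#' @param msa aligned \code{AAStringSet} (or character matrix) containing
#'   the reference row.
#' @param table a \linkS4class{GCLTable} keyed to the reference's ungapped
#'   residue numbering.
#' @param refId name of the reference (human) row.
#' @return character matrix, rows = sequences, columns = labeled positions
#'   (column names = canonical labels).
#' @export
gclAlign <- function(msa, table, refId) {
  m <- .alignmentMatrix(msa)
  if (!refId %in% rownames(m)) stop("reference sequence absent: ", refId)
  ref <- toupper(m[refId, ])
  isres <- !ref %in% .GAP_CHARS
  resnum <- cumsum(isres)
  e <- entries(table)
  keep <- which(isres & resnum %in% e$residue_number)
  out <- m[, keep, drop = FALSE]
  colnames(out) <- e$gcl_label[match(resnum[keep], e$residue_number)]
  out
}

## Mann-Whitney U with an exact small-sample route.
## Exact enumeration (tie-safe) when the group split is enumerable;
## tie-free exact distribution otherwise when there are no ties;
## tie-corrected normal approximation else.
.mannWhitneyU <- function(x, y, enumLimit = 2e5) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- any(duplicated(c(x, y)))
  if (choose(n, min(n1, n2)) <= enumLimit) {
    ## exhaustive enumeration of group assignments (exchangeable under H0)
    k <- min(n1, n2)
    combos <- utils::combn(n, k)
    rs <- colSums(matrix(r[combos], nrow = k))
    Uperm <- rs - k * (k + 1) / 2
    muk <- k * (n - k) / 2
    Uobs <- if (n1 <= n2) U else n1 * n2 - U   # U of the smaller group
    p <- mean(abs(Uperm - muk) >= abs(Uobs - muk) - 1e-9)
    method <- "exact enumeration"
  } else if (!ties) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
    method <- "exact distribution"
  } else {
    tt <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(U = U, p.value = p, method = method)
}

#' Compare conservation of a selected position set against background
#'
#' Two-sided Mann-Whitney U test of the selected positions' conservation
#' scores against all other (defined) positions. Small, enumerable splits
#' use exhaustive permutation enumeration (tie-safe); tie-free larger
#' samples use the exact U distribution; otherwise a tie-corrected normal
#' approximation is used.
#'
#' @param profile a \linkS4class{ConservationProfile}.
#' @param selected character vector of position labels (non-empty, strict
#'   subset of the profile's defined positions).
#' @return list: \code{U} (statistic of the selected group), \code{p.value},
#'   \code{method}, \code{median_selected}, \code{median_background},
#'   \code{n_selected}, \code{n_background}.
#' @export
comparePositionGroups <- function(profile, selected) {
  p <- conservation(profile)
  p <- p[p$flag != "undefined", , drop = FALSE]
  if (!length(selected)) stop("empty selected position set")
  sel <- p$gcl_label %in% selected
  if (!any(sel)) stop("selected positions absent from profile")
  if (all(sel)) stop("selected set must be a strict subset of all positions")
  x <- p$score[sel]; y <- p$score[!sel]
  mw <- .mannWhitneyU(x, y)
  c(mw, list(median_selected = stats::median(x),
             median_background = stats::median(y),
             n_selected = length(x), n_background = length(y)))
}
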
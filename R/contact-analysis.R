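## Binary long-range heavy-atom contacts at labeled positions, and their
## group statistics: the Average Contact Score (ACS, fraction of structures
## in a state group showing the contact; at SSE level the mean number of
## contacting residue pairs between two elements) and the
## Conformational-Change score CC = ACS_closed - ACS_open. Positive CC means
## the contact favors the closed state.

#' Construct a ContactPolicy
#'
#' The heavy-atom distance cutoff is an explicit parameter of this package
#' (default 4.5 Angstrom, a standard heavy-atom contact threshold) and is
#' echoed in every output. The sequence-gap rule is strict: residues must be
#' more than \code{minSequenceGap} chain positions apart.
#'
#' @param heavyAtomCutoff Angstrom; contact iff min heavy-atom distance is
#'   <= cutoff (inclusive).
#' @param minSequenceGap contact requires |pos_i - pos_j| > this (default 5,
#'   so a gap of exactly 5 never qualifies).
#' @return a \linkS4class{ContactPolicy}.
#' @export
contactPolicy <- function(heavyAtomCutoff = 4.5, minSequenceGap = 5L) {
  new("ContactPolicy", heavyAtomCutoff = heavyAtomCutoff,
      minSequenceGap = as.integer(minSequenceGap))
}

.pairPartition <- function(label_i, label_j) {
  di <- substr(label_i, 1, 2); dj <- substr(label_j, 1, 2)
  ifelse(di == "PH" & dj == "PH", "intra_ph",
  ifelse(di == "PH" | dj == "PH", "ph_cross", "core"))
}

## canonical unordered pair: label_i < label_j lexicographically
.orientPairs <- function(df) {
  swap <- df$label_i > df$label_j
  if (any(swap)) {
    tmp <- df$label_i[swap]
    df$label_i[swap] <- df$label_j[swap]
    df$label_j[swap] <- tmp
    if (all(c("pos_i", "pos_j") %in% names(df))) {
      tmp <- df$pos_i[swap]; df$pos_i[swap] <- df$pos_j[swap]
      df$pos_j[swap] <- tmp
    }
  }
  df
}

#' Long-range heavy-atom contact map of one structure
#'
#' A labeled residue pair is in contact iff the chain-position gap is
#' strictly over \code{minSequenceGap} and the minimal distance between
#' their heavy atoms is at most \code{heavyAtomCutoff} (inclusive). Only
#' labeled residues participate; unlabeled residues are invisible to the map.
#'
#' @param ls a \linkS4class{LabeledStructure}.
#' @param policy a \linkS4class{ContactPolicy}.
#' @return data.frame of contacting pairs with columns \code{label_i},
#'   \code{label_j} (canonical order, \code{label_i < label_j}),
#'   \code{pos_i}, \code{pos_j} (chain positions), \code{min_dist} and
#'   \code{partition} (\code{core} / \code{intra_ph} / \code{ph_cross}).
#'   Zero rows when no labeled residues are in contact.
#' @export
contactMap <- function(ls, policy = contactPolicy()) {
  empty <- data.frame(label_i = character(), label_j = character(),
                      pos_i = integer(), pos_j = integer(),
                      min_dist = numeric(), partition = character(),
                      stringsAsFactors = FALSE)
  h <- .labeledHeavy(ls)
  if (!nrow(h)) return(empty)
  resno <- sort(unique(h$resno))
  if (length(resno) < 2L) return(empty)
  idx <- split(seq_len(nrow(h)), h$resno)           # sorted by resno
  M <- as.matrix(h[, c("x", "y", "z")])
  D2 <- .pairwiseD2(M, M)
  lab <- gclLabels(ls)
  cut2 <- policy@heavyAtomCutoff^2
  rows <- list()
  n <- length(resno)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (resno[j] - resno[i] <= policy@minSequenceGap) next
    d2 <- min(D2[idx[[i]], idx[[j]]])
    if (d2 <= cut2 + 1e-9) {
      rows[[length(rows) + 1L]] <- data.frame(
        label_i = lab[[as.character(resno[i])]],
        label_j = lab[[as.character(resno[j])]],
        pos_i = resno[i], pos_j = resno[j],
        min_dist = sqrt(max(d2, 0)), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- .orientPairs(do.call(rbind, rows))
  out$partition <- .pairPartition(out$label_i, out$label_j)
  rownames(out) <- NULL
  out[order(out$label_i, out$label_j), ]
}

#' Average Contact Scores of one state group (residue level)
#'
#' For each labeled pair ever in contact within the group,
#' \code{acs = (number of structures with the contact) / (group size)}.
#' Pairs never in contact have ACS 0 and are stored implicitly (absent
#' rows).
#'
#' @param group non-empty list of \linkS4class{LabeledStructure}.
#' @param policy a \linkS4class{ContactPolicy}.
#' @return data.frame \code{label_i}, \code{label_j}, \code{acs},
#'   \code{n_structures}.
#' @export
averageContactScores <- function(group, policy = contactPolicy()) {
  if (!length(group)) stop("empty state group")
  keys <- unlist(lapply(group, function(ls) {
    cm <- contactMap(ls, policy)
    paste(cm$label_i, cm$label_j, sep = "|")
  }))
  n <- length(group)
  if (!length(keys))
    return(data.frame(label_i = character(), label_j = character(),
                      acs = numeric(), n_structures = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(keys)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  out <- data.frame(label_i = vapply(parts, `[`, "", 1L),
                    label_j = vapply(parts, `[`, "", 2L),
                    acs = as.numeric(tab) / n,
                    n_structures = n, stringsAsFactors = FALSE)
  out[order(out$label_i, out$label_j), ]
}

#' Element-level contact scores of one structure
#'
#' The contact score of an element pair is the number of residue-level
#' contacts with one residue labeled in each element; intra-element pairs
#' count when the residue pair passes the sequence-gap filter.
#'
#' @param ls a \linkS4class{LabeledStructure}.
#' @param policy a \linkS4class{ContactPolicy}.
#' @return data.frame \code{label_i}, \code{label_j} (SSE keys,
#'   \code{label_i <= label_j}), \code{count}.
#' @export
sseContactScores <- function(ls, policy = contactPolicy()) {
  cm <- contactMap(ls, policy)
  if (!nrow(cm))
    return(data.frame(label_i = character(), label_j = character(),
                      count = integer(), stringsAsFactors = FALSE))
  e <- data.frame(label_i = sseKey(cm$label_i), label_j = sseKey(cm$label_j),
                  stringsAsFactors = FALSE)
  e <- .orientPairs(e)
  tab <- table(paste(e$label_i, e$label_j, sep = "|"))
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  out <- data.frame(label_i = vapply(parts, `[`, "", 1L),
                    label_j = vapply(parts, `[`, "", 2L),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$label_i, out$label_j), ]
}

.groupScores <- function(group, policy, level) {
  n <- length(group)
  if (level == "residue") {
    sc <- averageContactScores(group, policy)
    data.frame(key = paste(sc$label_i, sc$label_j, sep = "|"),
               acs = sc$acs, stringsAsFactors = FALSE)
  } else {
    per <- do.call(rbind, lapply(unname(group), function(ls) {
      s <- sseContactScores(ls, policy)
      data.frame(key = paste(s$label_i, s$label_j, sep = "|"),
                 count = s$count, stringsAsFactors = FALSE)
    }))
    if (is.null(per) || !nrow(per))
      return(data.frame(key = character(), acs = numeric(),
                        stringsAsFactors = FALSE))
    tot <- tapply(per$count, per$key, sum)
    data.frame(key = names(tot), acs = as.numeric(tot) / n,
               stringsAsFactors = FALSE)
  }
}

#' Conformational-Change scores between the closed and open groups
#'
#' \code{cc = acs_closed - acs_open} per pair, at residue or SSE level.
#' Pairs observed in either group are retained; \code{cc == 0} rows are kept
#' and flagged \code{no_change} (zero indicates no contact change between the
#' states). PH-domain pairs are reported in their own partitions
#' (\code{intra_ph}, \code{ph_cross}) so they are never pooled into
#' cross-subfamily comparisons.
#'
#' @param closed,open non-empty lists of \linkS4class{LabeledStructure} of
#'   one subfamily.
#' @param policy a \linkS4class{ContactPolicy}.
#' @param level \code{"residue"} or \code{"sse"}.
#' @return a \linkS4class{ScoreTable}.
#' @export
conformationalChangeScores <- function(closed, open,
                                       policy = contactPolicy(),
                                       level = c("residue", "sse")) {
  level <- match.arg(level)
  if (!length(closed)) stop("empty state group: closed")
  if (!length(open)) stop("empty state group: open")
  gc <- .groupScores(closed, policy, level)
  go <- .groupScores(open, policy, level)
  keys <- sort(union(gc$key, go$key))
  acs_c <- stats::setNames(rep(0, length(keys)), keys)
  acs_c[gc$key] <- gc$acs
  acs_o <- stats::setNames(rep(0, length(keys)), keys)
  acs_o[go$key] <- go$acs
  parts <- strsplit(keys, "|", fixed = TRUE)
  li <- vapply(parts, `[`, "", 1L); lj <- vapply(parts, `[`, "", 2L)
  scores <- data.frame(label_i = li, label_j = lj,
                       acs_closed = as.numeric(acs_c),
                       acs_open = as.numeric(acs_o),
                       cc = as.numeric(acs_c) - as.numeric(acs_o),
                       stringsAsFactors = FALSE)
  scores$no_change <- scores$cc == 0
  scores$partition <- .pairPartition(
    if (level == "residue") scores$label_i else paste0(scores$label_i, ".1"),
    if (level == "residue") scores$label_j else paste0(scores$label_j, ".1"))
  rownames(scores) <- NULL
  new("ScoreTable", level = level, scores = scores,
      nClosed = length(closed), nOpen = length(open), policy = policy)
}

#' Export a ScoreTable as TSV
#'
#' @param st a \linkS4class{ScoreTable}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeScoreTable <- function(st, file) {
  out <- cbind(level = st@level, ccScores(st))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
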
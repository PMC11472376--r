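## Common-tendency change networks: pairs whose CC scores share a sign in
## both subfamilies (GRK2/3 and GRK4/5/6), weighted by the sum of the two CC
## scores. At residue level only pairs with |sum| strictly over the
## threshold (default 1) survive; opposite-signed pairs are excluded as
## subfamily biases rather than global movements.

#' Construct a NetworkPolicy
#'
#' @param residueThreshold residue-level edges require the absolute summed
#'   CC strictly greater than this; default 1.
#' @param requireSameSign keep only pairs whose two subfamily CC scores are
#'   both positive or both negative; default TRUE.
#' @return a \linkS4class{NetworkPolicy}.
#' @export
networkPolicy <- function(residueThreshold = 1.0, requireSameSign = TRUE) {
  new("NetworkPolicy", residueThreshold = residueThreshold,
      requireSameSign = requireSameSign)
}

#' Pairs with the same conformational tendency in two subfamilies
#'
#' Returns the pairs present in both score tables whose CC scores are
#' nonzero and share a sign (zero has no sign and is excluded). PH-domain
#' partitions never pool across subfamilies: only \code{core} pairs are
#' compared.
#'
#' @param ccA,ccB \linkS4class{ScoreTable}s at the same level (one per
#'   subfamily).
#' @return data.frame \code{label_i}, \code{label_j}, \code{cc_a},
#'   \code{cc_b}, \code{sum}.
#' @export
commonTendencyPairs <- function(ccA, ccB) {
  if (scoreLevel(ccA) != scoreLevel(ccB))
    stop("score tables are at different levels: ",
         scoreLevel(ccA), " vs ", scoreLevel(ccB))
  a <- ccScores(ccA); b <- ccScores(ccB)
  if ("partition" %in% names(a)) a <- a[a$partition == "core", ]
  if ("partition" %in% names(b)) b <- b[b$partition == "core", ]
  m <- merge(a[, c("label_i", "label_j", "cc")],
             b[, c("label_i", "label_j", "cc")],
             by = c("label_i", "label_j"), suffixes = c("_a", "_b"))
  keep <- m$cc_a != 0 & m$cc_b != 0 & sign(m$cc_a) == sign(m$cc_b)
  out <- m[keep, , drop = FALSE]
  names(out)[names(out) == "cc_a"] <- "cc_a"
  out$sum <- out$cc_a + out$cc_b
  out <- out[order(out$label_i, out$label_j), ]
  rownames(out) <- NULL
  out
}

#' Build a common-tendency change network
#'
#' Residue level keeps edges with \code{|sum|} strictly greater than the
#' policy threshold; SSE level keeps all common-tendency edges. The node set
#' is exactly the endpoints of surviving edges. Edge direction is
#' \code{closed} for positive weights (more contact in the closed state) and
#' \code{open} for negative weights.
#'
#' @param common data.frame from \code{\link{commonTendencyPairs}}.
#' @param policy a \linkS4class{NetworkPolicy}.
#' @param level \code{"residue"} or \code{"sse"}.
#' @return a \linkS4class{ChangeNetwork} (empty input gives an empty
#'   network).
#' @export
buildChangeNetwork <- function(common, policy = networkPolicy(),
                               level = c("residue", "sse")) {
  level <- match.arg(level)
  edges <- data.frame(label_i = character(), label_j = character(),
                      cc_a = numeric(), cc_b = numeric(),
                      weight = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (nrow(common)) {
    keep <- rep(TRUE, nrow(common))
    if (policy@requireSameSign)
      keep <- sign(common$cc_a) == sign(common$cc_b) &
        common$cc_a != 0 & common$cc_b != 0
    if (level == "residue")
      keep <- keep & abs(common$sum) > policy@residueThreshold
    s <- common[keep, , drop = FALSE]
    if (nrow(s)) {
      edges <- data.frame(label_i = s$label_i, label_j = s$label_j,
                          cc_a = s$cc_a, cc_b = s$cc_b, weight = s$sum,
                          direction = ifelse(s$sum > 0, "closed", "open"),
                          stringsAsFactors = FALSE)
      rownames(edges) <- NULL
    }
  }
  new("ChangeNetwork", level = level, edges = edges)
}

#' Rank network hubs by degree
#'
#' @param net a \linkS4class{ChangeNetwork}.
#' @param n number of top nodes to return.
#' @return data.frame \code{node}, \code{degree}, sorted by decreasing
#'   degree (ties alphabetical).
#' @export
hubNodes <- function(net, n = 5L) {
  e <- networkEdges(net)
  if (!nrow(e)) return(data.frame(node = character(), degree = integer()))
  deg <- table(c(e$label_i, e$label_j))
  out <- data.frame(node = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), ]
  rownames(out) <- NULL
  utils::head(out, n)
}

.asIgraph <- function(net) {
  e <- networkEdges(net)
  g <- igraph::graph_from_data_frame(
    e[, c("label_i", "label_j", "cc_a", "cc_b", "weight", "direction")],
    directed = FALSE,
    vertices = data.frame(name = networkNodes(net)))
  igraph::graph_attr(g, "level") <- net@level
  g
}

#' Export a change network
#'
#' Lossless, deterministic exports: \code{graphml} and \code{json} round-trip
#' through \code{\link{importGraph}}; \code{tsv} is a flat edge table with
#' columns \code{label_i}, \code{label_j}, \code{cc_a}, \code{cc_b},
#' \code{weight} (\code{= cc_a + cc_b}), \code{direction}.
#'
#' @param net a \linkS4class{ChangeNetwork}.
#' @param file output path.
#' @param format \code{"tsv"}, \code{"graphml"} or \code{"json"}.
#' @return the file path, invisibly.
#' @export
exportGraph <- function(net, file, format = c("tsv", "graphml", "json")) {
  format <- match.arg(format)
  e <- networkEdges(net)
  e <- e[order(e$label_i, e$label_j), , drop = FALSE]
  if (format == "tsv") {
    utils::write.table(e, file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "graphml") {
    igraph::write_graph(.asIgraph(net), file, format = "graphml")
  } else {
    jsonlite::write_json(
      list(level = net@level, nodes = networkNodes(net), edges = e),
      file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Import a change network written by exportGraph
#'
#' @param file path written by \code{\link{exportGraph}}.
#' @param format \code{"tsv"}, \code{"graphml"} or \code{"json"}.
#' @param level network level for TSV input (not stored in the flat table).
#' @return a \linkS4class{ChangeNetwork}.
#' @export
importGraph <- function(file, format = c("tsv", "graphml", "json"),
                        level = "residue") {
  format <- match.arg(format)
  if (format == "tsv") {
    e <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (!nrow(e))
      e <- data.frame(label_i = character(), label_j = character(),
                      cc_a = numeric(), cc_b = numeric(), weight = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
    return(new("ChangeNetwork", level = level, edges = e))
  }
  if (format == "graphml") {
    g <- igraph::read_graph(file, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    lvl <- igraph::graph_attr(g, "level")
    e <- if (nrow(ed))
      data.frame(label_i = ed$from, label_j = ed$to, cc_a = ed$cc_a,
                 cc_b = ed$cc_b, weight = ed$weight,
                 direction = ed$direction, stringsAsFactors = FALSE)
    else
      data.frame(label_i = character(), label_j = character(),
                 cc_a = numeric(), cc_b = numeric(), weight = numeric(),
                 direction = character(), stringsAsFactors = FALSE)
    e <- .orientPairs(e)
    e <- e[order(e$label_i, e$label_j), , drop = FALSE]
    rownames(e) <- NULL
    return(new("ChangeNetwork", level = lvl, edges = e))
  }
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  e <- as.data.frame(j$edges, stringsAsFactors = FALSE)
  if (!nrow(e))
    e <- data.frame(label_i = character(), label_j = character(),
                    cc_a = numeric(), cc_b = numeric(), weight = numeric(),
                    direction = character(), stringsAsFactors = FALSE)
  new("ChangeNetwork", level = j$level, edges = e)
}
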
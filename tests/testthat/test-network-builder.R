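mkScoreTable <- function(df, level = "residue", nClosed = 7L, nOpen = 3L) {
  df$no_change <- df$cc == 0
  df$partition <- if (level == "residue")
    gclkit:::.pairPartition(df$label_i, df$label_j) else "core"
  df$acs_closed <- pmax(df$cc, 0)
  df$acs_open <- pmax(-df$cc, 0)
  new("ScoreTable", level = level, scores = df, nClosed = nClosed,
      nOpen = nOpen, policy = contactPolicy())
}

pairDF <- function(li, lj, cc) {
  data.frame(label_i = li, label_j = lj, cc = cc, stringsAsFactors = FALSE)
}

test_that("common tendency requires same-signed nonzero CC in both tables", {
  a <- mkScoreTable(pairDF(c("KD.S1.1", "KD.S2.1", "KD.S3.1"),
                           c("RH.H1.1", "RH.H2.1", "RH.H3.1"),
                           c(0.6, 0.6, 0.6)))
  b <- mkScoreTable(pairDF(c("KD.S1.1", "KD.S2.1", "KD.S3.1"),
                           c("RH.H1.1", "RH.H2.1", "RH.H3.1"),
                           c(0.5, -0.2, 0)))
  common <- commonTendencyPairs(a, b)
  expect_equal(nrow(common), 1L)           # opposing and zero CC excluded
  expect_equal(common$label_i, "KD.S1.1")
  expect_equal(common$sum, 1.1)
})

test_that("tables at different levels are rejected", {
  a <- mkScoreTable(pairDF("KD.S1.1", "RH.H1.1", 0.5))
  b <- mkScoreTable(pairDF("KD.S1", "RH.H1", 0.5), level = "sse")
  expect_error(commonTendencyPairs(a, b), "level")
})

test_that("residue networks apply the strict |sum| > 1 rule", {
  common <- data.frame(
    label_i = c("KD.S1.1", "KD.S2.1", "KD.S3.1"),
    label_j = c("RH.H1.1", "RH.H2.1", "RH.H3.1"),
    cc_a = c(0.5, 0.6, -0.7), cc_b = c(0.5, 0.6, -0.6),
    sum = c(1.0, 1.2, -1.3), stringsAsFactors = FALSE)
  net <- buildChangeNetwork(common, level = "residue")
  e <- networkEdges(net)
  expect_equal(nrow(e), 2L)                # sum exactly 1.0 excluded
  expect_setequal(e$label_i, c("KD.S2.1", "KD.S3.1"))
  expect_equal(e$direction[e$label_i == "KD.S2.1"], "closed")
  expect_equal(e$direction[e$label_i == "KD.S3.1"], "open")
  expect_equal(e$weight, e$cc_a + e$cc_b)
  expect_setequal(networkNodes(net),
                  c("KD.S2.1", "RH.H2.1", "KD.S3.1", "RH.H3.1"))
})

test_that("SSE networks keep all common-tendency edges", {
  common <- data.frame(label_i = c("KD.S1", "KD.HB"),
                       label_j = c("RH.H1", "RH.HN"),
                       cc_a = c(0.3, -2), cc_b = c(0.2, -3),
                       sum = c(0.5, -5), stringsAsFactors = FALSE)
  net <- buildChangeNetwork(common, level = "sse")
  expect_equal(nrow(networkEdges(net)), 2L)
  expect_lte(nrow(networkEdges(net)), nrow(common))
})

test_that("empty input gives an empty, exportable network", {
  empty <- commonTendencyPairs(
    mkScoreTable(pairDF("KD.S1.1", "RH.H1.1", 0.2)),
    mkScoreTable(pairDF("KD.S1.1", "RH.H1.1", -0.2)))
  net <- buildChangeNetwork(empty, level = "residue")
  expect_equal(nrow(networkEdges(net)), 0L)
  expect_length(networkNodes(net), 0L)
  f <- tempfile(fileext = ".tsv")
  exportGraph(net, f, "tsv")
  expect_equal(nrow(networkEdges(importGraph(f, "tsv"))), 0L)
})

test_that("raising the residue threshold only removes edges", {
  set.seed(31)
  common <- data.frame(
    label_i = sprintf("KD.S1.%d", 1:20), label_j = sprintf("RH.H1.%d", 1:20),
    cc_a = runif(20, -1, 1), stringsAsFactors = FALSE)
  common$cc_b <- common$cc_a * runif(20, 0.5, 1.5)
  common$sum <- common$cc_a + common$cc_b
  prev <- Inf
  for (thr in c(0.2, 0.6, 1.0, 1.4)) {
    n <- nrow(networkEdges(buildChangeNetwork(
      common, networkPolicy(residueThreshold = thr), "residue")))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("graph exports round-trip losslessly", {
  common <- data.frame(
    label_i = c("KD.HB.3", "KD.HK.3", "KD.HKHL.4"),
    label_j = c("RH.H1.2", "RH.H4H5.2", "RH.H6.2"),
    cc_a = c(1, 1, -1), cc_b = c(1, 1, -1),
    sum = c(2, 2, -2), stringsAsFactors = FALSE)
  net <- buildChangeNetwork(common, level = "residue")
  for (fmt in c("tsv", "graphml", "json")) {
    f <- tempfile(fileext = paste0(".", fmt))
    exportGraph(net, f, fmt)
    back <- importGraph(f, fmt)
    expect_equal(networkEdges(back), networkEdges(net), tolerance = 1e-12,
                 ignore_attr = TRUE)
    if (fmt != "tsv") expect_equal(back@level, "residue")
  }
  # TSV carries the inputs verbatim
  f <- tempfile(fileext = ".tsv")
  exportGraph(net, f, "tsv")
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$weight, common$sum)
})

test_that("hub ranking orders nodes by degree", {
  common <- data.frame(
    label_i = c("KD.HKHL.1", "KD.HKHL.1", "KD.HKHL.1", "KD.S1.1"),
    label_j = c("RH.HN.1", "RH.H1.1", "KD.S1.1", "RH.HN.1"),
    cc_a = c(1, 1, 1, 1), cc_b = c(1, 1, 1, 1),
    sum = c(2, 2, 2, 2), stringsAsFactors = FALSE)
  net <- buildChangeNetwork(common, level = "residue")
  hubs <- hubNodes(net, 2)
  expect_equal(hubs$node[1], "KD.HKHL.1")
  expect_equal(hubs$degree[1], 3L)
})
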
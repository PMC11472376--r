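aaSet <- function(seqs) Biostrings::AAStringSet(setNames(unlist(seqs),
                                                         names(seqs)))

test_that("length-window filtering follows the reference +/- 50 rule", {
  raw <- list(GRK1 = aaSet(c(hs = strrep("A", 590), s1 = strrep("A", 545),
                             s2 = strrep("A", 529))))
  out <- buildGclSequenceSet(raw, c(GRK1 = 590))
  expect_setequal(names(out$sets$GRK1), c("hs", "s1"))   # 529 dropped
})

test_that("only species common to every subtype survive", {
  raw <- list(
    GRK1 = aaSet(c(A = "AAAA", B = "AAAA", C = "AAAA")),
    GRK2 = aaSet(c(A = "AAAA", B = "AAAA")),
    GRK3 = aaSet(c(A = "AAAA", B = "AAAA", C = "AAAA")))
  out <- buildGclSequenceSet(raw, c(GRK1 = 4, GRK2 = 4, GRK3 = 4))
  expect_setequal(out$species, c("A", "B"))
  expect_equal(unname(out$counts), c(2L, 2L, 2L))
  expect_equal(out$total, 6L)

  disjoint <- list(GRK1 = aaSet(c(A = "AAAA")), GRK2 = aaSet(c(B = "AAAA")))
  expect_error(buildGclSequenceSet(disjoint, c(GRK1 = 4, GRK2 = 4)),
               "no common species")
})

test_that("seven subtypes with k common species give 7k sequences", {
  sp <- sprintf("sp%02d", 1:37)
  raw <- lapply(setNames(paste0("GRK", 1:7), paste0("GRK", 1:7)),
                function(st) aaSet(setNames(rep("ACDEF", 37), sp)))
  out <- buildGclSequenceSet(raw, setNames(rep(5, 7), paste0("GRK", 1:7)))
  expect_equal(out$total, 259L)
})

test_that("gcl alignment keeps exactly the reference's labeled columns", {
  tab <- GCLTable("GRK1", data.frame(
    residue_number = c(1L, 2L, 4L), residue_name = c("ALA", "CYS", "GLU"),
    gcl_label = c("RH.H1.1", "RH.H1.2", "RH.H1.3"), stringsAsFactors = FALSE))
  msa <- aaSet(c(Homo_sapiens = "ACDE", other = "A-DE", third = "GC-E"))
  out <- gclAlign(msa, tab, "Homo_sapiens")
  expect_equal(colnames(out), c("RH.H1.1", "RH.H1.2", "RH.H1.3"))
  expect_equal(unname(out["other", ]), c("A", "-", "E"))  # gap preserved
  expect_error(gclAlign(msa, tab, "missing_ref"), "absent")

  # full labeling: identity round-trip
  tabF <- GCLTable("GRK1", data.frame(
    residue_number = 1:4, residue_name = "ALA",
    gcl_label = paste0("RH.H1.", 1:4), stringsAsFactors = FALSE))
  outF <- gclAlign(msa, tabF, "Homo_sapiens")
  expect_equal(unname(outF["Homo_sapiens", ]), c("A", "C", "D", "E"))
  expect_equal(dim(outF), c(3L, 4L))

  # reference gaps shift residue numbering
  msaG <- aaSet(c(Homo_sapiens = "A-CD", other = "AAAA"))
  tabG <- GCLTable("GRK1", data.frame(
    residue_number = 2L, residue_name = "CYS", gcl_label = "KD.S1.1",
    stringsAsFactors = FALSE))
  outG <- gclAlign(msaG, tabG, "Homo_sapiens")
  expect_equal(unname(outG["Homo_sapiens", ]), "C")   # column 3 = residue 2
})

test_that("identity columns score 11 and all-gap columns are undefined", {
  m <- rbind(c("I", "-", "A"), c("I", "-", "A"), c("I", "-", "C"))
  colnames(m) <- c("p1", "p2", "p3")
  prof <- conservation(conservationScores(m))
  expect_equal(prof$score[1], 11)
  expect_equal(prof$flag[2], "undefined")
  expect_true(is.na(prof$score[2]))
  expect_lt(prof$score[3], 11)
})

test_that("property agreement counting matches an independent recount", {
  cols <- list(c("I", "L", "V"), c("D", "E"), c("F", "Y", "W"),
               c("K", "R"), c("A", "G", "S"), c("W", "D"), c("P", "G"))
  m <- do.call(cbind, lapply(cols, function(cl)
    cl[rep(seq_along(cl), length.out = 4)]))   # 4 rows, same residue sets
  # recount with a plain loop over the shipped class table
  props <- aaPropertyTable()
  expected <- vapply(cols, function(cl) {
    agree <- 0L
    for (p in rownames(props)) {
      hav <- props[p, cl]
      if (all(hav) || !any(hav)) agree <- agree + 1L
    }
    agree
  }, integer(1))
  prof <- conservation(conservationScores(m))
  expect_equal(prof$score, as.numeric(expected))
  # {I,L,V}: agreement on everything except 'small' (V only)
  expect_equal(prof$score[1], 9)
})

test_that("scores are invariant to row order and duplicated sequences", {
  m <- rbind(A = c("I", "K", "P"), B = c("L", "R", "G"), C = c("V", "K", "P"))
  base <- conservation(conservationScores(m))$score
  perm <- conservation(conservationScores(m[c(3, 1, 2), ]))$score
  expect_equal(perm, base)
  dup <- conservation(conservationScores(m[c(1, 2, 3, 3), ]))$score
  expect_equal(dup, base)
})

test_that("gap-heavy columns are flagged low confidence", {
  m <- rbind(c("A", "A"), c("-", "A"), c("-", "C"), c("-", "C"))
  prof <- conservation(conservationScores(m))
  expect_equal(prof$flag, c("low_confidence", "ok"))
})

mkProfile <- function(scores) {
  new("ConservationProfile",
      profile = data.frame(
        gcl_label = sprintf("KD.S1.%d", seq_along(scores)),
        score = scores, n_residues = 5L, gap_fraction = 0,
        flag = "ok", stringsAsFactors = FALSE),
      nSequences = 5L)
}

test_that("identical group distributions give central U and p near 1", {
  prof <- mkProfile(c(3, 5, 7, 9, 3, 5, 7, 9))
  out <- comparePositionGroups(prof, sprintf("KD.S1.%d", 1:4))
  expect_equal(out$U, 4 * 4 / 2)
  expect_gt(out$p.value, 0.95)
})

test_that("complete separation drives U to its extreme", {
  prof <- mkProfile(c(10, 11, 10, 11, 1, 2, 1, 2))
  out <- comparePositionGroups(prof, sprintf("KD.S1.%d", 1:4))
  expect_equal(out$U, 16)          # n1*n2, all selected above background
  expect_lt(out$p.value, 0.05)
})

test_that("small-sample p equals exhaustive permutation enumeration", {
  set.seed(8)
  for (k in 1:5) {
    x <- sample(0:11, 5, replace = (k > 3))   # with and without ties
    y <- sample(0:11, 5, replace = (k > 3))
    while (length(unique(c(x, y))) == 1) y <- sample(0:11, 5)
    prof <- mkProfile(c(x, y))
    out <- comparePositionGroups(prof, sprintf("KD.S1.%d", 1:5))
    # independent brute force: all C(10,5) group assignments
    scores <- c(x, y)
    r <- rank(scores)
    mu <- 5 * 5 / 2
    Uobs <- sum(r[1:5]) - 15
    combos <- utils::combn(10, 5)
    stat <- apply(combos, 2, function(ix) sum(r[ix]) - 15)
    pBrute <- mean(abs(stat - mu) >= abs(Uobs - mu) - 1e-9)
    expect_equal(out$p.value, pBrute, tolerance = 1e-12)
  }
})

test_that("tie-free moderate samples match wilcox.test's exact p", {
  set.seed(21)
  x <- runif(9, 0, 6); y <- runif(12, 2, 10)
  prof <- new("ConservationProfile",
              profile = data.frame(
                gcl_label = sprintf("KD.S1.%d", 1:21),
                score = c(x, y), n_residues = 5L, gap_fraction = 0,
                flag = "ok", stringsAsFactors = FALSE),
              nSequences = 5L)
  out <- comparePositionGroups(prof, sprintf("KD.S1.%d", 1:9))
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(out$p.value, ref$p.value, tolerance = 1e-9)
  expect_equal(out$U, unname(ref$statistic))
})

test_that("planted high-conservation positions are detected", {
  msa <- generateMsa(msaSpec(seed = 2), file.path(tempdir(), "gclkit-msa2"))
  raw <- lapply(msa$fasta_files, Biostrings::readAAStringSet)
  names(raw) <- names(msa$fasta_files)
  refl <- vapply(raw, function(s)
    nchar(as.character(s[["Homo_sapiens"]])), integer(1))
  core <- buildGclSequenceSet(raw, refl)
  tab <- .tinyFamily()$tables[[1]]
  pooled <- do.call(rbind, lapply(core$sets, gclAlign, table = tab,
                                  refId = "Homo_sapiens"))
  prof <- conservationScores(pooled)
  p <- conservation(prof)
  expect_true(all(p$score[p$gcl_label %in% msa$truth$planted] == 11))
  out <- comparePositionGroups(prof, msa$truth$planted)
  expect_lt(out$p.value, 0.01)
  expect_gt(out$median_selected, out$median_background)
})
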
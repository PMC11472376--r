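chainStructure <- function(xyz, labels) {
  # one CA atom per residue at the given coordinates
  atoms <- data.frame(resno = seq_len(nrow(xyz)),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  names(labels) <- as.character(seq_len(nrow(xyz)))
  labelStructure(makeStructure(atoms), labels)
}

test_that("the sequence-gap rule is strict and the cutoff inclusive", {
  # residues 1 and 6: gap exactly 5, atoms 3 A apart -> not a contact
  xyz <- cbind(c(0, 100, 200, 300, 400, 3), 0, 0)
  labs <- paste0("RH.H1.", 1:6)
  cm <- contactMap(chainStructure(xyz, labs))
  expect_equal(nrow(cm), 0L)

  # residues 1 and 7: gap 6, min distance exactly at the cutoff -> contact
  xyz <- cbind(c(0, 100, 200, 300, 400, 500, 4.5), 0, 0)
  labs <- paste0("RH.H1.", 1:7)
  cm <- contactMap(chainStructure(xyz, labs))
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$min_dist, 4.5, tolerance = 1e-9)
})

test_that("contact maps equal the brute-force double loop", {
  for (seed in 1:8) {
    ls <- randomLabeledStructure(12, seed, box = 12)
    cm <- contactMap(ls)
    got <- sort(paste(cm$label_i, cm$label_j, sep = "|"))
    expect_identical(got, bruteContacts(ls))
  }
})

test_that("contact maps are symmetric-canonical and irreflexive", {
  ls <- randomLabeledStructure(20, 42, box = 14)
  cm <- contactMap(ls)
  expect_true(all(cm$label_i < cm$label_j))
  expect_false(any(cm$label_i == cm$label_j))
  expect_false(any(duplicated(paste(cm$label_i, cm$label_j))))
})

test_that("shrinking the cutoff never adds contacts", {
  ls <- randomLabeledStructure(18, 7, box = 12)
  wide <- contactMap(ls, contactPolicy(heavyAtomCutoff = 5.0))
  narrow <- contactMap(ls, contactPolicy(heavyAtomCutoff = 4.0))
  expect_true(all(paste(narrow$label_i, narrow$label_j) %in%
                    paste(wide$label_i, wide$label_j)))
})

test_that("average contact scores are the per-pair contact fractions", {
  near <- cbind(c(0, 100, 200, 300, 400, 500, 3), 0, 0)
  far <- cbind(c(0, 100, 200, 300, 400, 500, 50), 0, 0)
  labs <- paste0("KD.S1.", 1:7)
  g <- list(chainStructure(near, labs), chainStructure(far, labs))
  acs <- averageContactScores(g)
  expect_equal(nrow(acs), 1L)
  expect_equal(acs$acs, 0.5)

  acs7 <- averageContactScores(rep(list(chainStructure(near, labs)), 7))
  expect_equal(acs7$acs, 1.0)
  expect_error(averageContactScores(list()), "empty state group")
})

test_that("hand recount of a three-structure group matches ACS", {
  set.seed(99)
  group <- lapply(1:3, function(s) randomLabeledStructure(12, s + 100,
                                                          box = 12))
  acs <- averageContactScores(group)
  counts <- table(unlist(lapply(group, bruteContacts)))
  expect_equal(nrow(acs), length(counts))
  got <- setNames(acs$acs, paste(acs$label_i, acs$label_j, sep = "|"))
  expect_equal(got[names(counts)], as.numeric(counts) / 3,
               ignore_attr = TRUE)
})

test_that("element scores are the bucketed residue contact counts", {
  ls <- randomLabeledStructure(25, 17, box = 13)
  sse <- sseContactScores(ls)
  cm <- contactMap(ls)
  # independent aggregation of the brute-force list
  brute <- bruteContacts(ls)
  keys <- vapply(strsplit(brute, "|", fixed = TRUE), function(p) {
    k <- sort(c(sseKey(p[1]), sseKey(p[2])))
    paste(k[1], k[2], sep = "|")
  }, "")
  tab <- table(keys)
  got <- setNames(sse$count, paste(sse$label_i, sse$label_j, sep = "|"))
  expect_equal(sort(names(got)), sort(names(tab)))
  expect_equal(got[names(tab)], as.integer(tab), ignore_attr = TRUE)
  # conservation under aggregation
  expect_equal(sum(sse$count), nrow(cm))
})

test_that("CC scores recover planted truth with the documented signs", {
  cl <- familyGroup("GRK23", "closed")
  op <- familyGroup("GRK23", "open")
  st <- conformationalChangeScores(cl, op)
  sc <- ccScores(st)
  expect_equal(st@nClosed, 7L)
  expect_equal(st@nOpen, 3L)
  # planted closed-only pairs at +1, open-only at -1, "both" flagged no-change
  expect_equal(sc$cc[sc$label_i == "KD.HK.3" & sc$label_j == "RH.H4H5.2"], 1)
  expect_equal(sc$cc[sc$label_i == "KD.HB.3" & sc$label_j == "RH.H1.2"], 1)
  expect_equal(sc$cc[sc$label_i == "KD.HKHL.4" & sc$label_j == "RH.H6.2"], -1)
  expect_equal(sc$cc[sc$label_i == "KD.S1.4" & sc$label_j == "RH.H10.2"], 0)
  expect_true(sc$no_change[sc$cc == 0])
  # noiseless groups: ACS in {0,1}, CC in {-1,0,1}
  expect_true(all(sc$acs_closed %in% c(0, 1)))
  expect_true(all(sc$acs_open %in% c(0, 1)))
  expect_true(all(sc$cc %in% c(-1, 0, 1)))
})

test_that("identical groups give all-zero CC", {
  g <- familyGroup("GRK456", "closed")
  st <- conformationalChangeScores(g, g)
  expect_true(all(ccScores(st)$cc == 0))
  expect_true(all(ccScores(st)$no_change))
})

test_that("empty groups are rejected with the group named", {
  g <- familyGroup("GRK23", "closed")
  expect_error(conformationalChangeScores(list(), g), "closed")
  expect_error(conformationalChangeScores(g, list()), "open")
})

test_that("SSE-level CC equals the residue aggregation on planted data", {
  cl <- familyGroup("GRK456", "closed")
  op <- familyGroup("GRK456", "open")
  sse <- ccScores(conformationalChangeScores(cl, op, level = "sse"))
  expect_equal(sse$cc[sse$label_i == "KD.HK" & sse$label_j == "RH.H4H5"], 1)
  expect_equal(sse$cc[sse$label_i == "KD.HKHL" & sse$label_j == "RH.H6"], -1)
})

test_that("PH-domain pairs are partitioned away from core comparisons", {
  xyz <- cbind(c(0, 100, 200, 300, 400, 500, 3, 600, 3), 0, 0)
  labs <- c(paste0("PH.H12.", 1:6), "PH.SB.1", "RH.H1.1", "KD.S1.1")
  # contacts: residue1(PH.H12.1)-residue7(PH.SB.1) and residue1-residue9(KD.S1.1)
  cm <- contactMap(chainStructure(xyz, labs))
  expect_setequal(cm$partition, c("intra_ph", "ph_cross"))
  st <- conformationalChangeScores(list(chainStructure(xyz, labs)),
                                   list(chainStructure(xyz + 1000, labs)))
  expect_true(all(ccScores(st)$partition %in% c("intra_ph", "ph_cross")))
})

test_that("residue-level CC mass concentrates near zero on noisy data", {
  fam <- generateFamily(familySpec(coordinateNoise = 0.15, seed = 5),
                        file.path(tempdir(), "gclkit-noisy"))
  ls <- loadFamilyStructures(fam)
  inv <- fam$truth$structures
  cl <- ls[inv$subfamily == "GRK23" & inv$state == "closed"]
  op <- ls[inv$subfamily == "GRK23" & inv$state == "open"]
  sc <- ccScores(conformationalChangeScores(cl, op))
  nlab <- 54
  npairs <- nlab * (nlab - 1) / 2
  # nearly all label pairs show no contact change (implicit zeros)
  changed <- sum(sc$cc != 0)
  expect_lt(changed / npairs, 0.05)
})
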
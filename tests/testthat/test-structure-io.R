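writeFixturePdb <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(lines, file)
  file
}

pdbAtomLine <- function(serial, name, resn, chain, resno, x, y, z,
                        occ = 1.0, ele = "C", alt = " ") {
  sprintf("ATOM  %5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, x, y, z, occ, 0, ele)
}

test_that("reading splits chains and parses the resolution record", {
  f <- writeFixturePdb(c(
    "REMARK   2 RESOLUTION.    2.50 ANGSTROMS.",
    pdbAtomLine(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    pdbAtomLine(2, " CB ", "ALA", "A", 1, 1.5, 0, 0),
    pdbAtomLine(3, " CA ", "GLY", "B", 1, 10, 0, 0),
    "END"))
  models <- readStructures(f)
  expect_length(models, 2L)
  expect_equal(unname(vapply(models, chainId, "")), c("A", "B"))
  expect_equal(unname(vapply(models, structureResolution, 0)), c(2.5, 2.5))
  expect_equal(nrow(atoms(models[[1]])), 2L)   # chain A carries two atoms
})

test_that("files without a resolution record yield unknown resolution", {
  f <- writeFixturePdb(c(pdbAtomLine(1, " CA ", "ALA", "A", 1, 0, 0, 0),
                         "END"))
  m <- readStructures(f)[[1]]
  expect_true(is.na(structureResolution(m)))
})

test_that("hydrogens are kept in atoms but absent from heavy atoms", {
  f <- writeFixturePdb(c(
    pdbAtomLine(1, " CA ", "ALA", "A", 1, 0, 0, 0, ele = "C"),
    pdbAtomLine(2, " HA ", "ALA", "A", 1, 0.5, 0, 0, ele = "H"),
    pdbAtomLine(3, " N  ", "ALA", "A", 1, 1.2, 0, 0, ele = "N"),
    "END"))
  m <- readStructures(f)[[1]]
  expect_equal(nrow(atoms(m)), 3L)
  expect_equal(nrow(heavyAtoms(m)), 2L)
  expect_false("H" %in% heavyAtoms(m)$elesy)
})

test_that("waters and ligands are excluded, CA-bearing residues kept", {
  f <- writeFixturePdb(c(
    pdbAtomLine(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    "HETATM    2  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    pdbAtomLine(3, " CA ", "MSE", "A", 2, 4, 0, 0),   # modified aa with CA
    "END"))
  m <- readStructures(f)[[1]]
  expect_equal(sort(unique(atoms(m)$resid)), c("ALA", "MSE"))
})

test_that("altloc policy keeps the highest-occupancy conformer", {
  f <- writeFixturePdb(c(
    pdbAtomLine(1, " CA ", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdbAtomLine(2, " CA ", "ALA", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    pdbAtomLine(3, " CB ", "ALA", "A", 1, 1, 0, 0, occ = 0.5, alt = "A"),
    pdbAtomLine(4, " CB ", "ALA", "A", 1, 8, 8, 8, occ = 0.5, alt = "B"),
    "END"))
  m <- readStructures(f)[[1]]
  a <- atoms(m)
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$elety == "CA"], 9)       # occupancy 0.6 wins
  expect_equal(a$x[a$elety == "CB"], 1)       # tie -> altloc A
})

test_that("renumbering is sequential from 1 and preserves geometry", {
  f <- writeFixturePdb(c(
    pdbAtomLine(1, " CA ", "ALA", "A", 100, 0, 0, 0),
    pdbAtomLine(2, " CA ", "GLY", "A", 102, 4, 0, 0),
    pdbAtomLine(3, " CA ", "VAL", "A", 103, 8, 0, 0),
    pdbAtomLine(4, " CA ", "ALA", "B", 7, 0, 5, 0),
    pdbAtomLine(5, " CA ", "GLY", "B", 8, 4, 5, 0),
    "END"))
  models <- splitAndRenumberChains(readStructures(f))
  expect_length(models, 2L)
  rA <- residues(models[[1]])
  expect_equal(rA$resno, 1:3)
  expect_equal(rA$orig_resno, c(100L, 102L, 103L))
  rB <- residues(models[[2]])
  expect_equal(rB$resno, 1:2)
  # geometry untouched
  expect_equal(atoms(models[[1]])$x, c(0, 4, 8))
  expect_equal(splitAndRenumberChains(list()), list())
})

test_that("filtering drops by resolution, unknown resolution and coverage", {
  mk <- function(res) {
    m <- makeStructure(data.frame(resno = 1:2, x = c(0, 4), y = 0, z = 0),
                       pdbCode = paste0("S", res), resolution = res)
  }
  models <- list(mk(2.5), mk(4.2), mk(4.0), mk(NA_real_))
  out <- filterStructures(models, coverage = c(1, 1, 1, 1))
  expect_length(out$kept, 2L)          # 2.5 and exactly 4.00 kept
  expect_setequal(out$reasons$reason, c("resolution", "unknown_resolution"))

  out2 <- filterStructures(models[1], coverage = 0.3)
  expect_equal(out2$reasons$reason, "fragment")

  # keep unknown resolution when the policy allows
  out3 <- filterStructures(models[4], coverage = 1,
                           policy = filterPolicy(excludeUnknownResolution = FALSE))
  expect_length(out3$kept, 1L)
})

test_that("filtering partitions the input and is idempotent", {
  mk <- function(i, res) makeStructure(
    data.frame(resno = 1:2, x = c(0, 4), y = 0, z = 0),
    pdbCode = paste0("S", i), resolution = res)
  models <- lapply(seq_along(rs <- c(1.8, 2.5, 4.5, NA, 3.9)),
                   function(i) mk(i, rs[i]))
  cov <- c(1, 0.4, 1, 1, 0.9)
  out <- filterStructures(models, cov)
  expect_equal(length(out$kept) + length(out$dropped), length(models))
  keptCov <- cov[vapply(models, pdbCode, "") %in%
                   vapply(out$kept, pdbCode, "")]
  again <- filterStructures(out$kept, keptCov)
  expect_equal(length(again$kept), length(out$kept))
  expect_equal(nrow(again$reasons), 0L)
})

test_that("written structures read back identically", {
  fam <- .tinyFamily()
  m <- readStructures(fam$pdb_files[1])[[1]]
  f <- tempfile(fileext = ".pdb")
  writeStructure(m, f)
  m2 <- readStructures(f)[[1]]
  expect_equal(atoms(m2)[, c("x", "y", "z")], atoms(m)[, c("x", "y", "z")])
  expect_equal(structureResolution(m2), structureResolution(m))
})
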
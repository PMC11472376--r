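## Synthetic structure families with planted ground truth. Residues are
## short rigid fragments (N, CA, C, O, CB) laid out on a coarse scaffold:
## the chain runs along a line with 8 A spacing (so every long-range pair is
## far apart by construction), and each controlled pair -- the ionic lock and
## every planted contact change -- is relocated to its own isolated site
## where the two fragments face each other at an exact distance. Physical
## realism is explicitly not a goal; only the distance relations the
## pipeline consumes are controlled.

.defaultLayout <- function() {
  data.frame(
    domain = c("RH", "RH", "RH", "RH", "RH", "KD", "KD", "KD", "KD"),
    element = c("HN", "H1", "H4H5", "H6", "H10", "S1", "HB", "HK", "HKHL"),
    length = c(6L, 6L, 4L, 6L, 6L, 6L, 6L, 6L, 8L),
    stringsAsFactors = FALSE)
}

.defaultPlanted <- function() {
  data.frame(
    label_i = c("RH.H1.2", "RH.H6.2", "RH.H10.2"),
    label_j = c("KD.HB.3", "KD.HKHL.4", "KD.S1.4"),
    present_in = c("closed_only", "open_only", "both"),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic structure family
#'
#' Defaults mirror the study design: two subfamilies (GRK2/3-like and
#' GRK4/5/6-like) with 7+3 and 6+2 closed/open structures, an ionic lock at
#' 2.8 A (closed) / 6.5 A (open) between RH.H4H5.2 and KD.HK.3, zero
#' coordinate noise and three planted contact changes shared by both
#' subfamilies.
#'
#' @param subfamilies character vector of subfamily tags.
#' @param nClosed,nOpen integer vectors (parallel to \code{subfamilies}) of
#'   closed/open structure counts.
#' @param layout data.frame \code{domain}, \code{element}, \code{length}
#'   defining the chain (same layout for every subfamily).
#' @param lockClosed,lockOpen lock distances in Angstrom; must respect the
#'   state thresholds (strictly under 3.3 / over 5.0).
#' @param planted data.frame \code{label_i}, \code{label_j},
#'   \code{present_in} (\code{closed_only} / \code{open_only} /
#'   \code{both}); pairs must be long-range (gap > 5) and residue-disjoint
#'   from each other and from the lock pair.
#' @param coordinateNoise sd of isotropic Gaussian jitter per coordinate
#'   (Angstrom).
#' @param resolution value written to the REMARK 2 record.
#' @param seed RNG seed recorded in the truth record.
#' @return validated spec (list with class \code{"FamilySpec"}).
#' @export
familySpec <- function(subfamilies = c("GRK23", "GRK456"),
                       nClosed = c(7L, 6L), nOpen = c(3L, 2L),
                       layout = .defaultLayout(),
                       lockClosed = 2.8, lockOpen = 6.5,
                       planted = .defaultPlanted(),
                       coordinateNoise = 0, resolution = 2.5, seed = 1L) {
  stopifnot(length(nClosed) == length(subfamilies),
            length(nOpen) == length(subfamilies))
  th <- stateThresholds()
  if (!(lockClosed < th@closedMax && lockOpen > th@openMin))
    stop("infeasible geometry request: lock distances must fall strictly ",
         "under ", th@closedMax, " (closed) and over ", th@openMin, " (open)")
  labels <- .layoutLabels(layout)
  pos <- stats::setNames(seq_along(labels), labels)
  lockPair <- c("RH.H4H5.2", "KD.HK.3")
  if (!all(lockPair %in% labels))
    stop("layout must contain the lock elements RH.H4H5 and KD.HK")
  if (nrow(planted)) {
    bad <- !c(planted$label_i, planted$label_j) %in% labels
    if (any(bad))
      stop("planted labels outside layout: ",
           paste(unique(c(planted$label_i, planted$label_j)[bad]),
                 collapse = ", "))
    gap <- abs(pos[planted$label_j] - pos[planted$label_i])
    if (any(gap <= 5))
      stop("infeasible geometry request: planted pair(s) violate the ",
           "long-range gap rule: ",
           paste(planted$label_i[gap <= 5], planted$label_j[gap <= 5],
                 sep = "-", collapse = ", "))
    involved <- c(planted$label_i, planted$label_j)
    if (any(duplicated(involved)) || any(involved %in% lockPair))
      stop("infeasible geometry request: planted pairs must be ",
           "residue-disjoint and distinct from the lock pair")
    if (!all(planted$present_in %in% c("closed_only", "open_only", "both")))
      stop("present_in must be closed_only, open_only or both")
  }
  structure(list(subfamilies = subfamilies, nClosed = as.integer(nClosed),
                 nOpen = as.integer(nOpen), layout = layout,
                 lockClosed = lockClosed, lockOpen = lockOpen,
                 planted = planted, coordinateNoise = coordinateNoise,
                 resolution = resolution, seed = as.integer(seed)),
            class = "FamilySpec")
}

.layoutLabels <- function(layout) {
  unlist(lapply(seq_len(nrow(layout)), function(i)
    gclLabel(layout$domain[i], layout$element[i],
             seq_len(layout$length[i]))))
}

## fixed residue-name assignment: cycle the twenty types along the chain,
## with the lock pair pinned to Val/Arg (the conserved lock identities in
## the GRK4/5/6 subfamily)
.layoutResnames <- function(labels) {
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  nm <- aa3[(seq_along(labels) - 1L) %% 20L + 1L]
  nm[labels == "RH.H4H5.2"] <- "VAL"
  nm[labels == "KD.HK.3"] <- "ARG"
  nm
}

## one residue fragment: heavy-atom offsets along +x from its origin
.fragmentOffsets <- function(resname) {
  off <- rbind(N = c(0, 0, 0), CA = c(1.4, 0, 0), C = c(2.8, 0, 0),
               O = c(3.6, 0, 0))
  if (resname != "GLY") off <- rbind(off, CB = c(1.4, 1.2, 0))
  off
}

.FRAG_LEN <- 3.6   # x-extent of a fragment (N..O)

.buildStructureAtoms <- function(labels, resnames, state, lockD, planted,
                                 noise) {
  pos <- stats::setNames(seq_along(labels), labels)
  origin <- cbind(8 * (seq_along(labels) - 1), 0, 0)
  ## controlled pairs: the lock plus every planted change
  ctrl <- data.frame(label_i = "RH.H4H5.2", label_j = "KD.HK.3",
                     d = lockD, stringsAsFactors = FALSE)
  if (nrow(planted)) {
    inContact <- planted$present_in == "both" |
      (planted$present_in == "closed_only" & state == "closed") |
      (planted$present_in == "open_only" & state == "open")
    ctrl <- rbind(ctrl, data.frame(label_i = planted$label_i,
                                   label_j = planted$label_j,
                                   d = ifelse(inContact, 3.5, 9.0),
                                   stringsAsFactors = FALSE))
  }
  for (k in seq_len(nrow(ctrl))) {
    i <- pos[ctrl$label_i[k]]; j <- pos[ctrl$label_j[k]]
    lo <- min(i, j); hi <- max(i, j)
    site <- c(0, 60, 60 * k)
    origin[lo, ] <- site
    origin[hi, ] <- site + c(.FRAG_LEN + ctrl$d[k], 0, 0)
  }
  rows <- lapply(seq_along(labels), function(i) {
    off <- .fragmentOffsets(resnames[i])
    xyz <- sweep(off, 2L, origin[i, ], "+")
    data.frame(elety = rownames(off),
               elesy = substr(rownames(off), 1, 1),
               resid = resnames[i], resno = i, orig_resno = i,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               o = 1, alt = "", stringsAsFactors = FALSE)
  })
  a <- do.call(rbind, rows)
  rownames(a) <- NULL
  if (noise > 0) {
    a$x <- a$x + stats::rnorm(nrow(a), 0, noise)
    a$y <- a$y + stats::rnorm(nrow(a), 0, noise)
    a$z <- a$z + stats::rnorm(nrow(a), 0, noise)
  }
  a
}

#' Generate a synthetic structure family with planted truth
#'
#' Writes one single-chain PDB file per structure (with a REMARK 2
#' resolution record), one label table (TSV) per subfamily, and a JSON truth
#' record listing the expected state calls, the expected CC score of every
#' controlled pair and the expected common-tendency residue network. Output
#' is byte-deterministic for a given spec (seed included).
#'
#' @param spec a \code{\link{familySpec}}.
#' @param dir output directory (created if needed).
#' @return list: \code{pdb_files}, \code{table_files}, \code{tables}
#'   (GCLTable per subfamily), \code{truth} (list, also written to
#'   \code{truth.json}), \code{dir}.
#' @export
generateFamily <- function(spec, dir) {
  stopifnot(inherits(spec, "FamilySpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  labels <- .layoutLabels(spec$layout)
  resnames <- .layoutResnames(labels)
  tables <- lapply(spec$subfamilies, function(sf)
    GCLTable(sf, data.frame(residue_number = seq_along(labels),
                            residue_name = resnames, gcl_label = labels,
                            stringsAsFactors = FALSE)))
  names(tables) <- spec$subfamilies
  tableFiles <- vapply(spec$subfamilies, function(sf) {
    f <- file.path(dir, paste0("gcl_table_", sf, ".tsv"))
    writeGCLTable(tables[[sf]], f)
    f
  }, "")
  inventory <- list(); pdbFiles <- character()
  for (si in seq_along(spec$subfamilies)) {
    sf <- spec$subfamilies[si]
    states <- c(rep("closed", spec$nClosed[si]), rep("open", spec$nOpen[si]))
    for (k in seq_along(states)) {
      st <- states[k]
      id <- sprintf("%s_%s_%d", sf, st, k)
      lockD <- if (st == "closed") spec$lockClosed else spec$lockOpen
      a <- .buildStructureAtoms(labels, resnames, st, lockD, spec$planted,
                                spec$coordinateNoise)
      m <- new("StructureModel", pdbCode = id, chainId = "A",
               resolution = spec$resolution, atoms = a)
      f <- file.path(dir, paste0(id, ".pdb"))
      writeStructure(m, f)
      pdbFiles <- c(pdbFiles, f)
      inventory[[length(inventory) + 1L]] <-
        data.frame(id = paste0(id, "_A"), subfamily = sf, state = st,
                   lock_distance = lockD, file = basename(f),
                   stringsAsFactors = FALSE)
    }
  }
  inventory <- do.call(rbind, inventory)
  ## expected CC per controlled pair (identical in every subfamily)
  ccOf <- c(closed_only = 1, open_only = -1, both = 0)
  ctrl <- rbind(
    data.frame(label_i = "RH.H4H5.2", label_j = "KD.HK.3",
               present_in = "closed_only", stringsAsFactors = FALSE),
    spec$planted)
  ctrl <- .orientPairs(ctrl)
  expected_cc <- data.frame(label_i = ctrl$label_i, label_j = ctrl$label_j,
                            present_in = ctrl$present_in,
                            cc = as.numeric(ccOf[ctrl$present_in]),
                            stringsAsFactors = FALSE)
  nonzero <- expected_cc$cc != 0
  edges <- expected_cc[nonzero, , drop = FALSE]
  expected_edges <- data.frame(label_i = edges$label_i,
                               label_j = edges$label_j,
                               weight = 2 * edges$cc,
                               stringsAsFactors = FALSE)
  expected_edges <- expected_edges[order(expected_edges$label_i,
                                         expected_edges$label_j), ]
  rownames(expected_edges) <- NULL
  truth <- list(seed = spec$seed,
                lock = list(label_i = "RH.H4H5.2", label_j = "KD.HK.3",
                            closed = spec$lockClosed, open = spec$lockOpen),
                coordinate_noise = spec$coordinateNoise,
                structures = inventory,
                expected_cc = expected_cc,
                expected_network_edges = expected_edges)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  list(pdb_files = pdbFiles, table_files = tableFiles, tables = tables,
       truth = truth, dir = dir)
}

#' Read a generated family back as labeled structures
#'
#' Convenience loader exercising the standard input path: reads each PDB
#' file, renumbers the chain and maps it to its subfamily's label table.
#'
#' @param family result of \code{\link{generateFamily}}.
#' @return named list of \linkS4class{LabeledStructure} (names = structure
#'   ids from the truth record).
#' @export
loadFamilyStructures <- function(family) {
  inv <- family$truth$structures
  out <- vector("list", nrow(inv))
  for (i in seq_len(nrow(inv))) {
    models <- splitAndRenumberChains(
      readStructures(file.path(family$dir, inv$file[i])))
    out[[i]] <- mapStructureToGCL(models[[1]],
                                  family$tables[[inv$subfamily[i]]])
  }
  names(out) <- inv$id
  out
}

#' Specification of a synthetic alignment set
#'
#' Defaults mirror the study's sequence panel: 37 species shared across the
#' seven subtypes (one alignment per subtype), ten planted invariant
#' positions, background substitution rate 0.3.
#'
#' @param nSpecies species per subtype; the first is the human reference
#'   (\code{Homo_sapiens}).
#' @param subtypes character vector of subtype tags.
#' @param positions position labels (columns); default: the standard layout.
#' @param planted labels of invariant (fully conserved) positions.
#' @param rate per-residue background substitution probability in [0, 1].
#' @param seed RNG seed.
#' @return validated spec (list with class \code{"MsaSpec"}).
#' @export
msaSpec <- function(nSpecies = 37L, subtypes = paste0("GRK", 1:7),
                    positions = .layoutLabels(.defaultLayout()),
                    planted = c("RH.H1.1", "RH.H1.3", "RH.H4H5.2",
                                "RH.H6.4", "RH.H10.5", "KD.S1.5", "KD.HB.2",
                                "KD.HK.3", "KD.HKHL.2", "KD.HKHL.7"),
                    rate = 0.3, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (!all(planted %in% positions))
    stop("planted positions must be a subset of the layout positions")
  structure(list(nSpecies = as.integer(nSpecies), subtypes = subtypes,
                 positions = positions, planted = planted, rate = rate,
                 seed = as.integer(seed)),
            class = "MsaSpec")
}

.AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Generate synthetic per-subtype alignments with planted conservation
#'
#' Planted positions carry one invariant residue across every species and
#' subtype (conservation score 11); background positions start from a
#' subtype consensus and mutate independently per species at the stated
#' rate. Species identifiers are identical across subtypes so the
#' common-species filter keeps all of them. Deterministic for a given spec.
#'
#' @param spec a \code{\link{msaSpec}}.
#' @param dir output directory.
#' @return list: \code{fasta_files} (named by subtype), \code{truth} (list
#'   with planted labels, rate, species), \code{dir}.
#' @export
generateMsa <- function(spec, dir) {
  stopifnot(inherits(spec, "MsaSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  npos <- length(spec$positions)
  species <- c("Homo_sapiens",
               sprintf("species_%02d", seq_len(spec$nSpecies - 1L)))
  plantedRes <- sample(.AA1, length(spec$planted), replace = TRUE)
  names(plantedRes) <- spec$planted
  files <- character(length(spec$subtypes))
  names(files) <- spec$subtypes
  for (st in spec$subtypes) {
    consensus <- sample(.AA1, npos, replace = TRUE)
    isPlanted <- spec$positions %in% spec$planted
    consensus[isPlanted] <- plantedRes[spec$positions[isPlanted]]
    m <- matrix(rep(consensus, each = length(species)),
                nrow = length(species))
    if (spec$rate > 0) {
      bg <- which(!isPlanted)
      for (j in bg) {
        mut <- stats::runif(length(species)) < spec$rate
        if (any(mut))
          m[mut, j] <- vapply(which(mut), function(i)
            sample(setdiff(.AA1, consensus[j]), 1L), "")
      }
    }
    seqs <- Biostrings::AAStringSet(apply(m, 1L, paste, collapse = ""))
    names(seqs) <- species
    f <- file.path(dir, paste0("msa_", st, ".fasta"))
    Biostrings::writeXStringSet(seqs, f)
    files[st] <- f
  }
  truth <- list(seed = spec$seed, planted = spec$planted,
                planted_residues = as.list(plantedRes), rate = spec$rate,
                species = species, positions = spec$positions)
  jsonlite::write_json(truth, file.path(dir, "msa_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  list(fasta_files = files, truth = truth, dir = dir)
}
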
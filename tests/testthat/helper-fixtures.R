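# In-code fixtures: structures are built directly as atom tables, and the
# brute-force oracles below recompute distances/contacts with plain double
# loops, independent of the package's vectorised implementations.

makeStructure <- function(atoms, pdbCode = "toy", chainId = "A",
                          resolution = 2.0) {
  defaults <- data.frame(elety = "CA", elesy = "C", resid = "ALA",
                         o = 1, alt = "", stringsAsFactors = FALSE)
  for (col in names(defaults))
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  if (is.null(atoms$orig_resno)) atoms$orig_resno <- atoms$resno
  atoms$resno <- as.integer(atoms$resno)
  atoms$orig_resno <- as.integer(atoms$orig_resno)
  cols <- c("elety", "elesy", "resid", "resno", "orig_resno",
            "x", "y", "z", "o", "alt")
  new("StructureModel", pdbCode = pdbCode, chainId = chainId,
      resolution = resolution, atoms = atoms[order(atoms$resno), cols])
}

labelStructure <- function(model, labels, subtype = "GRKX") {
  # labels: named character, resno -> canonical label
  new("LabeledStructure", model, subtype = subtype, labels = labels,
      coverage = 1.0, mismatches = integer())
}

# random structure with labeled residues scattered in a box; each residue
# carries 1-4 heavy atoms within ~1.5 A of its centre
randomLabeledStructure <- function(nres, seed, box = 25) {
  set.seed(seed)
  elements <- c("H1", "H4H5", "H6", "HK", "HKHL", "S1")
  domains <- c("RH", "RH", "RH", "KD", "KD", "KD")
  rows <- list()
  labels <- character(nres)
  counts <- integer(length(elements))
  for (i in seq_len(nres)) {
    e <- sample(length(elements), 1)
    counts[e] <- counts[e] + 1L
    labels[i] <- paste(domains[e], elements[e], counts[e], sep = ".")
    centre <- runif(3, 0, box)
    natom <- sample(1:4, 1)
    for (k in seq_len(natom)) {
      p <- centre + runif(3, -1.5, 1.5)
      rows[[length(rows) + 1L]] <- data.frame(
        elety = c("CA", "CB", "CG", "CD")[k],
        elesy = sample(c("C", "N", "O", "S"), 1),
        resid = "ALA", resno = i, x = p[1], y = p[2], z = p[3],
        stringsAsFactors = FALSE)
    }
  }
  m <- makeStructure(do.call(rbind, rows))
  names(labels) <- as.character(seq_len(nres))
  labelStructure(m, labels)
}

eucl <- function(p, q) sqrt(sum((p - q)^2))

# brute-force minimal heavy-atom distance between two label sets
bruteRegionMin <- function(ls, keyA, keyB) {
  a <- heavyAtoms(ls)
  lab <- gclLabels(ls)
  a$label <- lab[as.character(a$resno)]
  a <- a[!is.na(a$label), ]
  keys <- sapply(strsplit(a$label, ".", fixed = TRUE),
                 function(p) paste(p[1], p[2], sep = "."))
  A <- a[keys == keyA, ]; B <- a[keys == keyB, ]
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- eucl(c(A$x[i], A$y[i], A$z[i]), c(B$x[j], B$y[j], B$z[j]))
    if (d < best) best <- d
  }
  best
}

# brute-force long-range contact list (canonically ordered label pairs)
bruteContacts <- function(ls, cutoff = 4.5, gap = 5) {
  a <- heavyAtoms(ls)
  lab <- gclLabels(ls)
  a <- a[as.character(a$resno) %in% names(lab), ]
  res <- sort(unique(a$resno))
  out <- character()
  for (ii in seq_along(res)) for (jj in seq_along(res)) {
    if (jj <= ii) next
    i <- res[ii]; j <- res[jj]
    if (j - i <= gap) next
    A <- a[a$resno == i, ]; B <- a[a$resno == j, ]
    dmin <- Inf
    for (x in seq_len(nrow(A))) for (y in seq_len(nrow(B)))
      dmin <- min(dmin, eucl(c(A$x[x], A$y[x], A$z[x]),
                             c(B$x[y], B$y[y], B$z[y])))
    if (dmin <= cutoff) {
      pair <- sort(c(lab[[as.character(i)]], lab[[as.character(j)]]))
      out <- c(out, paste(pair[1], pair[2], sep = "|"))
    }
  }
  sort(out)
}

rotateStructure <- function(ls, angle = 0.7, axis = c(1, 1, 0),
                            shift = c(5, -3, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  a <- atoms(ls)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  ls@atoms <- a
  ls
}

# tiny family used by several suites (cached per session)
.tinyFamily <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "gclkit-family")
      cache <<- generateFamily(familySpec(), d)
    }
    cache
  }
})

.tinyLabeled <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- loadFamilyStructures(.tinyFamily())
    cache
  }
})

familyGroup <- function(subfamily, state) {
  inv <- .tinyFamily()$truth$structures
  .tinyLabeled()[inv$subfamily == subfamily & inv$state == state]
}
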
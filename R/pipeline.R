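## End-to-end orchestration: structures (given or simulated) -> labels ->
## filters -> state calls -> per-subfamily residue/SSE score tables ->
## common-tendency networks -> conservation -> optional rSASA, with every
## table written as TSV and every policy echoed into a JSON manifest.

#' Assemble a run configuration
#'
#' Either \code{structures} + \code{tables} (paths) or a synthetic
#' \code{familySpec} must be supplied; likewise \code{msa} paths or an
#' \code{msaSpec}. The subfamily of each input structure file is declared by
#' the \code{subfamilyMap} (file-stem prefix -> subfamily), not inferred.
#'
#' @param familySpec a \code{\link{familySpec}} for synthetic input, or NULL.
#' @param structures character vector of PDB paths (ignored when
#'   \code{familySpec} given).
#' @param tables named character vector subfamily -> GCL table path.
#' @param subfamilyMap named character vector, file-stem prefix -> subfamily.
#' @param msaSpec a \code{\link{msaSpec}} for synthetic alignments, or NULL.
#' @param msa named character vector subtype -> FASTA path.
#' @param filter,thresholds,contacts,network,sasa policy objects.
#' @param sasaPositions labels for the rSASA comparison (NULL skips it).
#' @param seed integer seed for the run.
#' @return list with class \code{"RunConfig"}.
#' @export
runConfig <- function(familySpec = NULL, structures = character(),
                      tables = character(), subfamilyMap = character(),
                      msaSpec = NULL, msa = character(),
                      filter = filterPolicy(),
                      thresholds = stateThresholds(),
                      contacts = contactPolicy(),
                      network = networkPolicy(),
                      sasa = sasaPolicy(),
                      sasaPositions = NULL, seed = 1L) {
  structure(list(familySpec = familySpec, structures = structures,
                 tables = tables, subfamilyMap = subfamilyMap,
                 msaSpec = msaSpec, msa = msa, filter = filter,
                 thresholds = thresholds, contacts = contacts,
                 network = network, sasa = sasa,
                 sasaPositions = sasaPositions, seed = as.integer(seed)),
            class = "RunConfig")
}

.policyAsList <- function(p) {
  out <- lapply(slotNames(class(p)), function(s) {
    v <- slot(p, s)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  })
  names(out) <- slotNames(class(p))
  out
}

#' Serialize / parse a run configuration (YAML)
#'
#' Round-trip stable: \code{readRunConfig(writeRunConfig(cfg, f))}
#' reproduces \code{cfg} (policy objects are rebuilt from their fields).
#'
#' @param config a \code{\link{runConfig}}.
#' @param file YAML path.
#' @return \code{writeRunConfig}: the path, invisibly; \code{readRunConfig}:
#'   a \code{RunConfig}.
#' @export
writeRunConfig <- function(config, file) {
  x <- list(
    seed = config$seed,
    structures = as.list(config$structures),
    tables = as.list(config$tables),
    subfamilyMap = as.list(config$subfamilyMap),
    msa = as.list(config$msa),
    sasaPositions = as.list(config$sasaPositions),
    familySpec = if (!is.null(config$familySpec)) unclass(config$familySpec),
    msaSpec = if (!is.null(config$msaSpec)) unclass(config$msaSpec),
    filter = .policyAsList(config$filter),
    thresholds = .policyAsList(config$thresholds),
    contacts = .policyAsList(config$contacts),
    network = .policyAsList(config$network),
    sasa = .policyAsList(config$sasa))
  yaml::write_yaml(x, file, column.major = FALSE)
  invisible(file)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(file) {
  x <- yaml::read_yaml(file)
  asChr <- function(v) {
    if (is.null(v) || !length(v)) return(character())
    unlist(v)
  }
  asDF <- function(v) {   # yaml writes data.frames as row records
    do.call(rbind, lapply(v, function(row)
      as.data.frame(row, stringsAsFactors = FALSE)))
  }
  fs <- NULL
  if (!is.null(x$familySpec)) {
    f <- x$familySpec
    fs <- familySpec(
      subfamilies = unlist(f$subfamilies), nClosed = unlist(f$nClosed),
      nOpen = unlist(f$nOpen),
      layout = asDF(f$layout),
      lockClosed = f$lockClosed, lockOpen = f$lockOpen,
      planted = asDF(f$planted),
      coordinateNoise = f$coordinateNoise, resolution = f$resolution,
      seed = f$seed)
  }
  ms <- NULL
  if (!is.null(x$msaSpec)) {
    m <- x$msaSpec
    ms <- msaSpec(nSpecies = m$nSpecies, subtypes = unlist(m$subtypes),
                  positions = unlist(m$positions),
                  planted = unlist(m$planted), rate = m$rate, seed = m$seed)
  }
  runConfig(
    familySpec = fs, structures = asChr(x$structures),
    tables = asChr(x$tables), subfamilyMap = asChr(x$subfamilyMap),
    msaSpec = ms, msa = asChr(x$msa),
    filter = do.call(filterPolicy, x$filter),
    thresholds = do.call(stateThresholds, x$thresholds),
    contacts = do.call(contactPolicy, x$contacts),
    network = do.call(networkPolicy, x$network),
    sasa = do.call(sasaPolicy, lapply(x$sasa, function(v)
      if (is.list(v)) unlist(v) else v)),
    sasaPositions = if (length(x$sasaPositions)) unlist(x$sasaPositions),
    seed = x$seed)
}

.stageLog <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Stages: acquire structures (synthetic generation or file input), label,
#' filter (resolution/fragment), classify closed/open by the lock distance,
#' score residue- and SSE-level conformational changes per subfamily, build
#' common-tendency networks across the first two subfamilies, score
#' conservation with the selected-vs-background comparison, and (optionally)
#' compare rSASA by state. All tables are written as TSV under \code{outDir}
#' together with a JSON manifest echoing every policy value and the seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory for the report bundle.
#' @param verbose log one line per stage.
#' @return (invisibly) the report: a list with \code{inventory},
#'   \code{drops}, \code{states}, \code{scores} (per subfamily, residue and
#'   sse), \code{networks} (residue and sse \linkS4class{ChangeNetwork}),
#'   \code{conservation} (profile + group comparison), \code{rsasa} (or
#'   NULL) and \code{manifest}.
#' @export
runFullPipeline <- function(config, outDir, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  ## -- structures + tables -------------------------------------------------
  if (!is.null(config$familySpec)) {
    fam <- generateFamily(config$familySpec, file.path(outDir, "input"))
    pdbs <- fam$pdb_files
    tables <- fam$tables
    sfOf <- function(stem) sub("_(closed|open)_[0-9]+$", "", stem)
  } else {
    if (!length(config$structures)) stop("no structures configured")
    pdbs <- config$structures
    tables <- lapply(names(config$tables), function(sf)
      readGCLTable(config$tables[[sf]], sf))
    names(tables) <- names(config$tables)
    sfmap <- config$subfamilyMap
    sfOf <- function(stem) {
      hit <- which(vapply(names(sfmap), function(p) startsWith(stem, p),
                          logical(1)))
      if (!length(hit)) NA_character_ else sfmap[[hit[1]]]
    }
  }
  .stageLog(verbose, "input", "%d PDB file(s), %d label table(s)",
            length(pdbs), length(tables))

  models <- list()
  for (f in pdbs) models <- c(models, readStructures(f))
  models <- splitAndRenumberChains(models)
  labeled <- list()
  for (m in models) {
    sf <- sfOf(m@pdbCode)
    if (is.na(sf) || !sf %in% names(tables)) next
    labeled[[paste0(m@pdbCode, "_", m@chainId)]] <-
      mapStructureToGCL(m, tables[[sf]])
  }
  .stageLog(verbose, "label", "%d chain(s) labeled", length(labeled))

  flt <- filterStructures(labeled, policy = config$filter)
  kept <- flt$kept
  .stageLog(verbose, "filter", "%d kept, %d dropped", length(kept),
            nrow(flt$reasons))
  if (!length(kept)) stop("no structures pass the filters")

  states <- classifyStructures(kept, config$thresholds)
  states$subfamily <- vapply(kept, subtype, "")
  .stageLog(verbose, "classify", "closed %d / intermediate %d / open %d",
            sum(states$state == "closed"),
            sum(states$state == "intermediate"),
            sum(states$state == "open"))

  subfams <- unique(states$subfamily)
  scores <- list()
  for (sf in subfams) {
    cl <- kept[states$subfamily == sf & states$state == "closed"]
    op <- kept[states$subfamily == sf & states$state == "open"]
    if (!length(cl))
      stop("insufficient structures for closed/open comparison: ",
           "no closed structures in ", sf)
    if (!length(op))
      stop("insufficient structures for closed/open comparison: ",
           "no open structures in ", sf)
    scores[[sf]] <- list(
      residue = conformationalChangeScores(cl, op, config$contacts,
                                           "residue"),
      sse = conformationalChangeScores(cl, op, config$contacts, "sse"))
    .stageLog(verbose, "score", "%s: %d residue pairs, %d SSE pairs", sf,
              nrow(ccScores(scores[[sf]]$residue)),
              nrow(ccScores(scores[[sf]]$sse)))
  }

  networks <- NULL
  if (length(subfams) >= 2L) {
    a <- subfams[1]; b <- subfams[2]
    commonRes <- commonTendencyPairs(scores[[a]]$residue,
                                     scores[[b]]$residue)
    commonSse <- commonTendencyPairs(scores[[a]]$sse, scores[[b]]$sse)
    networks <- list(
      residue = buildChangeNetwork(commonRes, config$network, "residue"),
      sse = buildChangeNetwork(commonSse, config$network, "sse"),
      subfamilies = c(a, b))
    .stageLog(verbose, "network", "residue edges %d, SSE edges %d",
              nrow(networkEdges(networks$residue)),
              nrow(networkEdges(networks$sse)))
  }

  ## -- conservation --------------------------------------------------------
  consv <- NULL
  msaFiles <- character()
  if (!is.null(config$msaSpec)) {
    msaOut <- generateMsa(config$msaSpec, file.path(outDir, "input"))
    msaFiles <- msaOut$fasta_files
  } else if (length(config$msa)) {
    msaFiles <- config$msa
  }
  if (length(msaFiles)) {
    raw <- lapply(msaFiles, Biostrings::readAAStringSet)
    names(raw) <- names(msaFiles)
    refLens <- vapply(raw, function(s)
      sum(!strsplit(as.character(s[["Homo_sapiens"]]), "")[[1]] %in%
            .GAP_CHARS), integer(1))
    core <- buildGclSequenceSet(raw, refLens)
    refTable <- tables[[1]]
    aligned <- lapply(core$sets, gclAlign, table = refTable,
                      refId = "Homo_sapiens")
    pooled <- do.call(rbind, aligned)
    profile <- conservationScores(pooled)
    transition <- if (!is.null(networks)) networkNodes(networks$residue)
                  else character()
    comparison <- if (length(transition) &&
                      any(conservation(profile)$gcl_label %in% transition) &&
                      !all(conservation(profile)$gcl_label %in% transition))
      comparePositionGroups(profile, transition)
    consv <- list(profile = profile, comparison = comparison,
                  counts = core$counts, total = core$total,
                  transition_positions = transition)
    .stageLog(verbose, "conserve", "%d sequences (%d per subtype), %d positions",
              core$total, core$counts[[1]],
              nrow(conservation(profile)))
  }

  ## -- rSASA ---------------------------------------------------------------
  rsasa <- NULL
  if (!is.null(config$sasaPositions) && length(config$sasaPositions)) {
    cl <- kept[states$state == "closed"]
    op <- kept[states$state == "open"]
    rsasa <- relativeSasaByState(cl, op, config$sasaPositions, config$sasa)
    .stageLog(verbose, "sasa", "%d position(s) compared",
              nrow(rsasa))
  }

  ## -- report bundle -------------------------------------------------------
  wtsv <- function(df, name) {
    f <- file.path(outDir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  inventory <- data.frame(
    structure_id = vapply(labeled, function(m)
      paste0(m@pdbCode, "_", m@chainId), ""),
    subfamily = vapply(labeled, subtype, ""),
    resolution = vapply(labeled, structureResolution, numeric(1)),
    coverage = vapply(labeled, labelCoverage, numeric(1)),
    kept = !vapply(labeled, function(m)
      paste0(m@pdbCode, "_", m@chainId), "") %in% flt$reasons$structure_id,
    stringsAsFactors = FALSE)
  wtsv(inventory, "inventory.tsv")
  wtsv(flt$reasons, "dropped.tsv")
  wtsv(states, "state_calls.tsv")
  for (sf in names(scores)) {
    writeScoreTable(scores[[sf]]$residue,
                    file.path(outDir, paste0("cc_residue_", sf, ".tsv")))
    writeScoreTable(scores[[sf]]$sse,
                    file.path(outDir, paste0("cc_sse_", sf, ".tsv")))
  }
  if (!is.null(networks)) {
    exportGraph(networks$residue, file.path(outDir, "network_residue.tsv"),
                "tsv")
    exportGraph(networks$sse, file.path(outDir, "network_sse.tsv"), "tsv")
    exportGraph(networks$residue,
                file.path(outDir, "network_residue.graphml"), "graphml")
    exportGraph(networks$sse, file.path(outDir, "network_sse.graphml"),
                "graphml")
  }
  if (!is.null(consv)) {
    wtsv(conservation(consv$profile), "conservation.tsv")
  }
  if (!is.null(rsasa)) wtsv(rsasa, "rsasa.tsv")

  manifest <- list(
    seed = config$seed,
    policies = list(filter = .policyAsList(config$filter),
                    thresholds = .policyAsList(config$thresholds),
                    contacts = .policyAsList(config$contacts),
                    network = .policyAsList(config$network),
                    sasa = .policyAsList(config$sasa)),
    n_structures = length(labeled), n_kept = length(kept),
    states = as.list(table(states$state)),
    subfamilies = as.list(table(states$subfamily)))
  if (!is.null(consv)) {
    manifest$conservation <- list(
      total_sequences = consv$total,
      per_subtype = as.list(consv$counts),
      comparison = if (!is.null(consv$comparison))
        consv$comparison[c("U", "p.value", "method", "median_selected",
                           "median_background")])
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(inventory = inventory, drops = flt$reasons,
                 states = states, scores = scores, networks = networks,
                 conservation = consv, rsasa = rsasa, manifest = manifest))
}
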
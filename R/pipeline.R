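# End-to-end pipeline orchestration and deposition-style exports.

#' Pipeline configuration
#'
#' Collects all thresholds and paths for \code{\link{runPipeline}}. All
#' defaults equal the analysis thresholds used throughout the package
#' (test-frequency >= 100 targets, PD >= 10 vs PD <= 1 cliffs, hub degree
#' >= 10).
#'
#' @param inputDir directory holding compounds.tsv, activities.tsv,
#'   targets.tsv (as written by \code{\link{generateScreeningData}}).
#' @param outputDir directory for result files (created if missing); NULL
#'   to skip writing.
#' @param minTested extensively-tested threshold (default 100).
#' @param pdHi,pdLo promiscuity-cliff thresholds (defaults 10, 1).
#' @param hubMinDegree promiscuity-hub degree threshold (default 10).
#' @param simThreshold,logpThreshold aggregation-screen thresholds.
#' @param restrictions \code{\link{sizeRestrictions}} for the MMP search.
#' @param runFilters,runMmps stage toggles.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipelineConfig <- function(inputDir, outputDir = NULL, minTested = 100,
                           pdHi = 10, pdLo = 1, hubMinDegree = 10,
                           simThreshold = 0.85, logpThreshold = 3.0,
                           restrictions = sizeRestrictions(),
                           runFilters = TRUE, runMmps = TRUE) {
  stopifnot(minTested >= 1, pdLo < pdHi, hubMinDegree >= 1)
  structure(list(inputDir = inputDir, outputDir = outputDir,
                 minTested = minTested, pdHi = pdHi, pdLo = pdLo,
                 hubMinDegree = hubMinDegree, simThreshold = simThreshold,
                 logpThreshold = logpThreshold, restrictions = restrictions,
                 runFilters = runFilters, runMmps = runMmps),
            class = "pipeline_config")
}

#' Run the full promiscuity-analysis pipeline
#'
#' ingest -> standardize -> aggregate -> extensively-tested filter ->
#' liability filters -> PD census -> target classes / multiclass ligands ->
#' MMP search -> promiscuity cliffs -> PC network (hubs, pathways) ->
#' exports. The run summary records input and output counts per stage
#' (staged-attrition accounting); re-running with identical inputs and
#' configuration is bit-identical.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, a list with all intermediate objects and the
#'   \code{summary} (named list of stage counts).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  compTab <- stage("ingest", readCompoundTable(file.path(config$inputDir, "compounds.tsv")))
  actTab <- stage("ingest", readActivityTable(file.path(config$inputDir, "activities.tsv")))
  targTab <- stage("ingest", readTargetTable(file.path(config$inputDir, "targets.tsv")))

  compounds <- stage("standardize", standardizeMolecules(compTab))
  profilesAll <- stage("aggregate", aggregateProfiles(actTab))
  profilesExt <- stage("select_extensively_tested",
                       selectExtensivelyTested(profilesAll, config$minTested))

  summary <- list(
    n_input_compounds = nrow(compTab),
    n_standardized = length(compounds),
    n_rejected_structures = nrow(rejectedStructures(compounds)),
    n_activity_records = nrow(actTab),
    n_profiled = length(profilesAll),
    n_extensively_tested = length(profilesExt))

  if (config$runFilters) {
    filt <- stage("liability_filters",
                  applyFilterCascade(profilesExt, compounds,
                                     simThreshold = config$simThreshold,
                                     logpThreshold = config$logpThreshold))
    profiles <- filt$profiles
    report <- filt$report
  } else {
    keep <- intersect(compoundIds(profilesExt), compoundIds(compounds))
    profiles <- profilesExt[keep]
    report <- NULL
  }
  summary$n_pass_filters <- length(profiles)

  census <- stage("promiscuity", pdCensus(profiles))
  testedDistr <- stage("promiscuity", testedDistributionByPd(profiles))
  targets <- stage("target_classes", assignTargetClasses(targTab))
  classProf <- stage("target_classes",
                     classProfiles(profiles, targets, pdHi = config$pdHi))
  multiclassIds <- classProf$compound_id[classProf$is_multiclass]
  summary$n_pd_ge_hi <- sum(classProf$pd >= config$pdHi)
  summary$n_multiclass_ligands <- length(multiclassIds)
  summary$n_single_class_promiscuous <- length(singleClassPromiscuous(classProf))

  mmps <- NULL; cliffs <- NULL; network <- NULL; hubs <- character(0)
  pathways <- NULL
  if (config$runMmps) {
    passSet <- compounds[intersect(compoundIds(profiles), compoundIds(compounds))]
    mmps <- stage("mmp_search", findMMPs(passSet, config$restrictions))
    cliffs <- stage("cliff_detection",
                    detectPromiscuityCliffs(mmps, profiles,
                                            pdHi = config$pdHi,
                                            pdLo = config$pdLo))
    network <- stage("pc_network", buildPCNetwork(cliffs, multiclassIds))
    hubs <- stage("pc_network",
                  findPromiscuityHubs(network, config$hubMinDegree))
    pathways <- stage("pc_network", extractPathways(network))
    summary$n_mmps <- length(mmps)
    summary$n_promiscuity_cliffs <- length(cliffs)
    summary$n_network_nodes <- nrow(networkNodes(network))
    summary$n_hubs <- length(hubs)
    summary$n_pathways <- nrow(pathways)
  }

  if (!is.null(config$outputDir)) {
    od <- config$outputDir
    if (!dir.exists(od)) dir.create(od, recursive = TRUE)
    writeRejectedLog(compounds, file.path(od, "rejected_structures.tsv"))
    writeCensus(census, file.path(od, "census.tsv"))
    writeDistributions(testedDistr, file.path(od, "tested_distributions.tsv"))
    utils::write.table(classSizeTable(targets), file.path(od, "class_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(classProf, file.path(od, "class_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report))
      utils::write.table(report, file.path(od, "liability_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    exportMulticlassLigands(classProf, profiles, compounds,
                            file.path(od, "multiclass_ligands.tsv"))
    if (!is.null(mmps)) {
      utils::write.table(mmpTable(mmps), file.path(od, "mmps.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cliffTable(cliffs), file.path(od, "cliffs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      exportPCNetwork(network, file.path(od, "network_edges.tsv"),
                      file.path(od, "network.graphml"))
      utils::write.table(pathways, file.path(od, "pathways.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(od, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  invisible(list(compounds = compounds, profiles = profiles,
                 profilesAll = profilesAll, report = report, census = census,
                 testedDistr = testedDistr, targets = targets,
                 classProfiles = classProf, multiclassIds = multiclassIds,
                 mmps = mmps, cliffs = cliffs, network = network,
                 hubs = hubs, pathways = pathways, summary = summary))
}

#' Export the multiclass-ligand table
#'
#' Deposition-style tab-delimited file with exactly four columns in order:
#' compound id, SMILES, PD value, and the number of targets the compound
#' was tested against; one row per multiclass ligand, sorted by descending
#' PD and then id.
#'
#' @param classProf output of \code{\link{classProfiles}}.
#' @param profiles an \linkS4class{ActivityProfileSet}.
#' @param compounds a \linkS4class{CompoundSet}.
#' @param path output TSV path.
#' @return the exported data.frame, invisibly.
#' @export
exportMulticlassLigands <- function(classProf, profiles, compounds, path) {
  ids <- classProf$compound_id[classProf$is_multiclass]
  pd <- promiscuityDegree(profiles)[ids]
  nTested <- vapply(testedTargets(profiles)[ids], length, integer(1))
  smi <- smiles(compounds)[ids]
  df <- data.frame(compound_id = ids, smiles = unname(smi),
                   pd = unname(pd), n_tested = unname(nTested),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$pd, df$compound_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
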
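# Liability filters: PAINS substructure catalogs, aggregation-likeness
# heuristic (fingerprint similarity to known aggregators AND high logP),
# and a data-driven medicinal-chemistry rule engine.

#' Load a SMARTS catalog or rule file
#'
#' Plain-text, tab-separated, one pattern per line with columns
#' \code{rule_id}, \code{smarts} and optionally \code{category}; lines
#' starting with \code{#} are comments. Every pattern is validated against a
#' probe molecule; a malformed SMARTS raises a hard error naming the rule.
#'
#' @param path file path.
#' @return data.frame with columns rule_id, smarts, category.
#' @export
loadSmartsCatalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    rule_id = vapply(parts, `[`, character(1), 1L),
    smarts = vapply(parts, `[`, character(1), 2L),
    category = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "",
                      character(1)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$rule_id))
    stop("duplicate rule ids in ", path)
  probe <- .obMolRefs("CCO")
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({.smartsCounts(probe, df$smarts[i]); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("malformed SMARTS in rule ", sQuote(df$rule_id[i]),
                  " of ", path)
  }
  df
}

#' Default PAINS catalogs shipped with the package
#'
#' Three named catalogs of pan-assay interference substructure patterns
#' (families A, B, C). These are a representative self-curated subset of the
#' published PAINS substructure classes; site-specific catalog files can be
#' substituted without code changes. A compound is PAINS-flagged if any of
#' the three catalogs matches (pass-all policy).
#'
#' @return named list of three catalog data.frames.
#' @export
defaultPainsCatalogs <- function() {
  dir <- system.file("extdata", package = "PromCliff")
  list(pains_a = loadSmartsCatalog(file.path(dir, "pains_a.tsv")),
       pains_b = loadSmartsCatalog(file.path(dir, "pains_b.tsv")),
       pains_c = loadSmartsCatalog(file.path(dir, "pains_c.tsv")))
}

#' Default medicinal-chemistry rule set shipped with the package
#'
#' A representative self-curated subset of medicinal-chemistry structural
#' alerts, each assigned to a category (acylating agents, aldehydes,
#' chelators, reactive electrophiles, ...). Full external rule files can be
#' dropped in via \code{\link{loadSmartsCatalog}}. Matching is binary
#' reject; no demerit scoring.
#'
#' @return data.frame with columns rule_id, smarts, category.
#' @export
defaultMedchemRules <- function() {
  loadSmartsCatalog(system.file("extdata", "medchem_rules.tsv",
                                package = "PromCliff"))
}

#' Default reference list of known colloidal aggregators
#'
#' Small curated list of literature-known aggregating compounds used as the
#' similarity reference set of the aggregation-likeness screen.
#'
#' @return data.frame with columns ref_id, smiles.
#' @export
defaultAggregatorRefs <- function() {
  path <- system.file("extdata", "aggregators.tsv", package = "PromCliff")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ref_id", "smiles") %in% colnames(df)))
    stop("aggregator reference file must have columns ref_id, smiles")
  df
}

#' Screen compounds against PAINS catalogs
#'
#' @param compounds a \linkS4class{CompoundSet}.
#' @param catalogs named list of catalog data.frames (see
#'   \code{\link{defaultPainsCatalogs}}).
#' @return data.frame with one row per (compound, catalog, matched pattern):
#'   columns compound_id, catalog, rule_id. Compounds absent from the result
#'   matched nothing.
#' @export
screenPains <- function(compounds, catalogs = defaultPainsCatalogs()) {
  if (length(catalogs) == 0 || is.null(names(catalogs)))
    stop("catalogs must be a named list")
  .screenSmarts(compounds, catalogs)
}

#' Screen compounds against medicinal-chemistry rules
#'
#' @param compounds a \linkS4class{CompoundSet}.
#' @param rules data.frame of rules (see \code{\link{defaultMedchemRules}}).
#' @return data.frame with columns compound_id, rule_id, category; one row
#'   per violation.
#' @export
screenMedchemRules <- function(compounds, rules = defaultMedchemRules()) {
  hits <- .screenSmarts(compounds, list(medchem = rules))
  cat_of <- stats::setNames(rules$category, rules$rule_id)
  data.frame(compound_id = hits$compound_id, rule_id = hits$rule_id,
             category = unname(cat_of[hits$rule_id]),
             stringsAsFactors = FALSE)
}

# Shared pattern-major SMARTS scan over a CompoundSet.
.screenSmarts <- function(compounds, catalogs) {
  smi <- compounds@smiles
  ids <- compounds@ids
  out <- list()
  if (length(smi) > 0) {
    refs <- .obMolRefs(smi)
    for (cname in names(catalogs)) {
      cat_df <- catalogs[[cname]]
      for (i in seq_len(nrow(cat_df))) {
        counts <- tryCatch(.smartsCounts(refs, cat_df$smarts[i]),
                           error = function(e)
                             stop("SMARTS match failed for rule ",
                                  sQuote(cat_df$rule_id[i]), ": ",
                                  conditionMessage(e), call. = FALSE))
        hit <- which(counts > 0)
        if (length(hit) > 0)
          out[[length(out) + 1L]] <- data.frame(
            compound_id = ids[hit], catalog = cname,
            rule_id = cat_df$rule_id[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(compound_id = character(0), catalog = character(0),
                      rule_id = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Screen compounds for colloidal-aggregation likeness
#'
#' Mirrors the published aggregation-advisor logic: a compound is flagged if
#' its nearest Tanimoto similarity (FP2 path fingerprints) to a known
#' aggregator is at least \code{simThreshold} AND its atomic-contribution
#' logP is at least \code{logpThreshold}. Both conditions are required; a
#' perfect structural match with low logP is not flagged.
#'
#' @param compounds a \linkS4class{CompoundSet}.
#' @param refs reference aggregator list (data.frame ref_id, smiles).
#' @param simThreshold Tanimoto similarity threshold (default 0.85).
#' @param logpThreshold logP threshold (default 3.0).
#' @return data.frame with columns compound_id, aggregator_flag,
#'   nearest_similarity, nearest_ref, logp.
#' @export
screenAggregator <- function(compounds, refs = defaultAggregatorRefs(),
                             simThreshold = 0.85, logpThreshold = 3.0) {
  if (nrow(refs) == 0) stop("aggregator reference list is empty")
  ids <- compounds@ids
  if (length(ids) == 0)
    return(data.frame(compound_id = character(0), aggregator_flag = logical(0),
                      nearest_similarity = numeric(0), nearest_ref = character(0),
                      logp = numeric(0), stringsAsFactors = FALSE))
  fpQ <- .fp2Matrix(compounds@smiles)
  fpR <- .fp2Matrix(refs$smiles)
  sim <- .tanimotoMatrix(fpQ, fpR)
  nearestIdx <- max.col(sim, ties.method = "first")
  nearest <- sim[cbind(seq_len(nrow(sim)), nearestIdx)]
  logp <- calcLogP(compounds)
  data.frame(compound_id = ids,
             aggregator_flag = nearest >= simThreshold & logp >= logpThreshold,
             nearest_similarity = nearest,
             nearest_ref = refs$ref_id[nearestIdx],
             logp = unname(logp), stringsAsFactors = FALSE)
}

#' Atomic-contribution logP
#'
#' Octanol-water partition coefficient estimated as a sum of per-atom
#' contributions (Wildman-Crippen scheme as implemented in OpenBabel).
#' Deterministic for a given structure and invariant under SMILES
#' re-canonicalization.
#'
#' @param x a \linkS4class{CompoundSet} or a character vector of SMILES.
#' @return named numeric vector of logP values.
#' @examples
#' calcLogP(c(pentane = "CCCCC", hexane = "CCCCCC"))
#' @export
calcLogP <- function(x) {
  if (is(x, "CompoundSet")) {
    stats::setNames(.obLogP(x@smiles), x@ids)
  } else {
    stats::setNames(.obLogP(as.character(x)), names(x))
  }
}

#' Apply the full liability-filter cascade
#'
#' Runs the PAINS catalogs, the aggregation-likeness screen and the
#' medicinal-chemistry rules over all profiled compounds and retains only
#' compounds passing every filter. The final passing set is a pure
#' intersection: the stage order changes staged attrition counts, never the
#' result. Profiled compounds without a resolvable structure are excluded
#' with an explicit cause; there are no silent exclusions.
#'
#' @param profiles an \linkS4class{ActivityProfileSet}.
#' @param compounds a \linkS4class{CompoundSet} resolving the profile ids.
#' @param painsCatalogs named list of PAINS catalogs.
#' @param aggregatorRefs aggregator reference data.frame.
#' @param simThreshold,logpThreshold aggregation-screen thresholds.
#' @param medchemRules medicinal-chemistry rule data.frame.
#' @param order character vector giving the cascade stage order, a
#'   permutation of \code{c("pains", "aggregator", "medchem")}; affects the
#'   staged counts in the report attributes only.
#' @return list with elements \code{profiles} (passing
#'   \linkS4class{ActivityProfileSet}) and \code{report} (per-compound
#'   liability report data.frame with attribute \code{"stages"} holding the
#'   staged attrition counts).
#' @export
applyFilterCascade <- function(profiles, compounds,
                               painsCatalogs = defaultPainsCatalogs(),
                               aggregatorRefs = defaultAggregatorRefs(),
                               simThreshold = 0.85, logpThreshold = 3.0,
                               medchemRules = defaultMedchemRules(),
                               order = c("pains", "aggregator", "medchem")) {
  if (!setequal(order, c("pains", "aggregator", "medchem")))
    stop("order must be a permutation of pains, aggregator, medchem")
  pids <- compoundIds(profiles)
  hasStructure <- pids %in% compounds@ids
  present <- pids[hasStructure]
  sub <- compounds[present]

  painsHits <- screenPains(sub, painsCatalogs)
  agg <- screenAggregator(sub, aggregatorRefs, simThreshold, logpThreshold)
  med <- screenMedchemRules(sub, medchemRules)

  collapseHits <- function(hits, idcol = "rule_id") {
    sp <- split(hits[[idcol]], hits$compound_id)
    vapply(present, function(id) {
      v <- sp[[id]]
      if (is.null(v)) "" else paste(sort(unique(v)), collapse = ";")
    }, character(1))
  }
  catCols <- lapply(names(painsCatalogs), function(cn)
    collapseHits(painsHits[painsHits$catalog == cn, , drop = FALSE]))
  names(catCols) <- names(painsCatalogs)

  report <- data.frame(compound_id = pids, has_structure = hasStructure,
                       stringsAsFactors = FALSE)
  for (cn in names(catCols)) {
    col <- rep("", length(pids))
    col[hasStructure] <- catCols[[cn]]
    report[[cn]] <- col
  }
  report$pains_flag <- Reduce(`|`, lapply(names(catCols),
                                          function(cn) nzchar(report[[cn]])))
  aggRow <- match(pids, agg$compound_id)
  report$aggregator_flag <- ifelse(is.na(aggRow), FALSE,
                                   agg$aggregator_flag[aggRow])
  report$nearest_similarity <- agg$nearest_similarity[aggRow]
  report$nearest_ref <- agg$nearest_ref[aggRow]
  report$logp <- agg$logp[aggRow]
  medCol <- rep("", length(pids))
  medCol[hasStructure] <- collapseHits(med)
  report$medchem_violations <- medCol
  report$medchem_flag <- nzchar(medCol)
  report$passes_all <- report$has_structure & !report$pains_flag &
    !report$aggregator_flag & !report$medchem_flag

  flagOf <- list(pains = report$pains_flag,
                 aggregator = report$aggregator_flag,
                 medchem = report$medchem_flag)
  surviving <- report$has_structure
  stages <- data.frame(stage = "input", n_remaining = length(pids),
                       stringsAsFactors = FALSE)
  stages <- rbind(stages, data.frame(stage = "with_structure",
                                     n_remaining = sum(surviving)))
  for (st in order) {
    surviving <- surviving & !flagOf[[st]]
    stages <- rbind(stages, data.frame(stage = st, n_remaining = sum(surviving)))
  }
  attr(report, "stages") <- stages

  passing <- pids[report$passes_all]
  list(profiles = profiles[passing], report = report)
}
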
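# Deterministic synthetic screening-data generator with planted ground
# truth. The generator emulates the statistical structure of a large
# qualitative screening matrix: analog series over shared two-ring
# scaffolds (so MMPs exist by construction), per-compound tested-target
# sets of >= 100 targets with controlled overlap, planted promiscuity
# degrees spanning 0 to 20, optional contradictory duplicate calls, and
# spiked liability compounds for filter validation.

# Five 6-membered "inner" ring templates carrying the substituent slot
# (%s, appended to the ring-closure atom) and the link slot (%A). The five
# skeletons are pairwise non-isomorphic relative to link and substituent
# positions, so no two scaffolds are structural analogs of each other.
.RING_B <- c(benzene   = "c1ccc(%A)cc1%s",
             pyridine2 = "c1nc(%A)ccc1%s",
             pyridine6 = "n1cc(%A)ccc1%s",
             pyrimidine = "c1nc(%A)ncc1%s",
             pyrazine  = "c1nc(%A)cnc1%s")

# Five 5-membered "outer" rings attached via the link bond; chemically
# disjoint from the 6-ring vocabulary, so outer and inner rings can never
# be confused across scaffolds.
.RING_A <- c(thiophene2 = "-c2cccs2",
             thiophene3 = "-c2ccsc2",
             furan2     = "-c2ccco2",
             furan3     = "-c2cocc2",
             nmepyrrole = "-c2cccn2C")

# Substituent vocabulary (SMILES fragments attached at their first atom);
# "" is the hydrogen variant. All fragments have <= 3 heavy atoms: this
# keeps every intra-series pair within the default size restrictions AND
# guarantees that cutting the scaffold's ring-link bond can never satisfy
# the 2:1 core ratio, so no cross-series pair shares a core.
.SUBSTITUENTS <- c(H = "", F = "F", Cl = "Cl", Br = "Br", I = "I",
                   Me = "C", Et = "CC", nPr = "CCC", iPr = "C(C)C",
                   OH = "O", OMe = "OC", OEt = "OCC",
                   NH2 = "N", NHMe = "NC", NMe2 = "N(C)C",
                   CN = "C#N", CHF2 = "C(F)F", vinyl = "C=C",
                   SMe = "SC", amide = "C(N)=O", acid = "C(O)=O")

# Planted promiscuity degrees, one per substituent position within every
# scaffold series: inactive and single-target analogs dominate, with a
# promiscuous mid-range and four highly promiscuous members per series.
.PD_PLAN <- c(0, 0, 0, 0, 0, 0, 0,
              1, 1, 1, 1, 1,
              2, 3, 4, 5, 7,
              12, 13, 16, 20)

# Default liability spikes; labels name the filter family that must flag
# each compound. Aggregator spikes duplicate shipped reference aggregators
# with logP >= 3 (identity similarity).
.LIABILITY_SPIKES <- data.frame(
  compound_id = c("LIA01", "LIA02", "LIA03",
                  "LIA04", "LIA05", "LIA06",
                  "LIA07", "LIA08", "LIA09"),
  smiles = c("O=C1CSC(=S)N1",                    # rhodanine core
             "Oc1ccccc1O",                       # catechol
             "O=C1C=CC(=O)C=C1",                 # para-quinone
             "Clc1ccccc1C(c1ccccc1)(c1ccccc1)n1ccnc1",  # clotrimazole
             "CCCCCCCCCCCCc1ccccc1O",            # alkyl phenol aggregator
             "CCc1oc2ccccc2c1C(=O)c1cc(Br)c(O)c(Br)c1",  # benzbromarone
             "CC(=O)Cl",                         # acetyl chloride
             "CCCC=O",                           # butanal
             "CCN=C=O"),                         # ethyl isocyanate
  label = c("pains", "pains", "pains",
            "aggregator", "aggregator", "aggregator",
            "medchem", "medchem", "medchem"),
  stringsAsFactors = FALSE)

#' Specification of a synthetic screening data set
#'
#' Collects every knob of the generator; identical spec + seed always
#' yields byte-identical data. Defaults define the package's reference
#' study conditions: 25 scaffold series x 21 substituents = 525 compounds,
#' 160 targets over the eight target classes with enzyme-dominant sizes,
#' tested-set sizes of 120-160 targets per compound, planted PD values
#' from 0 to 20, and no conflicting calls.
#'
#' @param seed integer RNG seed.
#' @param ringA,ringB scaffold ring vocabularies (names of the shipped
#'   templates, or indices); the scaffold grid is their cross product.
#' @param substituents named character vector of substituent fragments
#'   ("" = hydrogen).
#' @param pdPlan planted PD per substituent position (recycled per series).
#' @param nTargets number of targets.
#' @param nTestedRange range of tested-set sizes per compound.
#' @param conflictRate fraction of tested-inactive pairs receiving an
#'   additional contradictory "active" call (in [0, 1)).
#' @param duplicateRate fraction of tested pairs receiving a consistent
#'   duplicate call.
#' @param singleClassSeries index of the series whose PD = 12 member is
#'   planted as single-class (active in enzymes only); NA for none.
#' @param liabilitySpikes data.frame(compound_id, smiles, label) of spiked
#'   liability compounds, or NULL.
#' @return list of class \code{"synthetic_spec"}.
#' @export
syntheticSpec <- function(seed = 1,
                          ringA = names(.RING_A), ringB = names(.RING_B),
                          substituents = .SUBSTITUENTS,
                          pdPlan = .PD_PLAN,
                          nTargets = 160, nTestedRange = c(120, 160),
                          conflictRate = 0, duplicateRate = 0.03,
                          singleClassSeries = 1,
                          liabilitySpikes = .LIABILITY_SPIKES) {
  stopifnot(conflictRate >= 0, conflictRate < 1,
            length(pdPlan) == length(substituents),
            max(pdPlan) <= min(nTestedRange),
            nTestedRange[2] <= nTargets)
  structure(list(seed = as.integer(seed),
                 ringA = .RING_A[ringA], ringB = .RING_B[ringB],
                 substituents = substituents, pdPlan = pdPlan,
                 nTargets = nTargets, nTestedRange = nTestedRange,
                 conflictRate = conflictRate, duplicateRate = duplicateRate,
                 singleClassSeries = singleClassSeries,
                 liabilitySpikes = liabilitySpikes),
            class = "synthetic_spec")
}

#' Generate analog series of compounds
#'
#' For every scaffold (cross product of the two ring vocabularies), one
#' single-site substituent variant per entry of the substituent vocabulary
#' (including the hydrogen variant) is built, so that every intra-series
#' pair is a true MMP within the default size restrictions while no
#' cross-series pair shares a core.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{compounds} (data.frame compound_id, smiles,
#'   scaffold, substituent) and \code{analogPairs} (data.frame of all true
#'   intra-series unordered pairs: compound_a, compound_b).
#' @export
generateCompoundSeries <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- list()
  s <- 0L
  for (a in names(spec$ringA)) {
    for (b in names(spec$ringB)) {
      s <- s + 1L
      scaffold <- sprintf("S%02d_%s_%s", s, b, a)
      tmpl <- sub("%A", spec$ringA[[a]], spec$ringB[[b]], fixed = TRUE)
      for (k in seq_along(spec$substituents)) {
        smi <- sub("%s", spec$substituents[[k]], tmpl, fixed = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = sprintf("CPD%02d%02d", s, k),
          smiles = smi, scaffold = scaffold,
          substituent = names(spec$substituents)[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  compounds <- do.call(rbind, rows)
  pairs <- do.call(rbind, lapply(split(compounds$compound_id,
                                       compounds$scaffold), function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(sort(ids), 2)
    data.frame(compound_a = cmb[1, ], compound_b = cmb[2, ],
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  list(compounds = compounds,
       analogPairs = pairs[order(pairs$compound_a, pairs$compound_b), ,
                           drop = FALSE])
}

# Target table with names engineered so the default keyword scheme
# classifies them; "Others" rows rely on the explicit class_label (the
# keyword scheme never assigns that class).
.syntheticTargets <- function(nTargets) {
  sizes <- round(nTargets * c(Enzymes = 0.375, `G protein-coupled receptors` = 0.15625,
                              `Transcription factors` = 0.09375,
                              `Ion channels` = 0.09375, Receptors = 0.09375,
                              Transporters = 0.0625, Others = 0.0625,
                              Unclassified = 0.0625))
  sizes[1] <- sizes[1] + (nTargets - sum(sizes))
  nameOf <- list(
    Enzymes = function(i) sprintf("serine/threonine kinase %d", i),
    `G protein-coupled receptors` = function(i)
      sprintf("G protein-coupled receptor %d", i),
    `Transcription factors` = function(i) sprintf("transcription factor %d", i),
    `Ion channels` = function(i) sprintf("potassium channel subunit %d", i),
    Receptors = function(i) sprintf("cytokine receptor %d", i),
    Transporters = function(i) sprintf("solute carrier transporter %d", i),
    Others = function(i) sprintf("structural protein %d", i),
    Unclassified = function(i) sprintf("uncharacterized protein %d", i))
  rows <- list()
  t <- 0L
  for (cl in names(sizes)) {
    for (i in seq_len(sizes[[cl]])) {
      t <- t + 1L
      rows[[t]] <- data.frame(
        target_id = sprintf("T%04d", t),
        protein_name = nameOf[[cl]](i),
        family_name = if (cl == "Enzymes") "protein kinase family" else "",
        class_label = if (cl == "Others") "Others" else "",
        true_class = cl, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate qualitative activity calls with planted truth
#'
#' Every compound is tested on a random target subset (size drawn from
#' \code{nTestedRange}); active calls are placed according to the planted
#' PD plan, spread over at least two target classes for PD >= 2 unless the
#' compound is planted single-class. Consistent duplicate calls are
#' injected at \code{duplicateRate}; contradictory duplicates at
#' \code{conflictRate} are placed on tested-inactive pairs, so the planted
#' PD remains the recovery truth while the conflicted pairs must end up in
#' the discarded set.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param compounds compound data.frame from
#'   \code{\link{generateCompoundSeries}} (optionally with spikes appended).
#' @return list with \code{activities} (compound_id, assay_id, target_id,
#'   outcome), \code{targets} (target table with true_class),
#'   \code{truth} (compound_id, planted_pd, planted_n_tested,
#'   planted_n_classes, planted_single_class), and \code{conflicts}
#'   (compound_id, target_id of injected contradictions).
#' @export
generateActivityCalls <- function(spec, compounds) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  targets <- .syntheticTargets(spec$nTargets)
  enzymeIds <- targets$target_id[targets$true_class == "Enzymes"]
  byClass <- split(targets$target_id, targets$true_class)

  nsub <- length(spec$substituents)
  scaffolds <- unique(compounds$scaffold)
  act <- list(); truthRows <- list(); conflictRows <- list()
  for (i in seq_len(nrow(compounds))) {
    id <- compounds$compound_id[i]
    subIdx <- match(compounds$substituent[i], names(spec$substituents))
    pdPlanned <- if (is.na(subIdx)) {
      12L  # liability spikes mimic false promiscuity
    } else spec$pdPlan[subIdx]
    singleClass <- !is.na(subIdx) && !is.na(spec$singleClassSeries) &&
      compounds$scaffold[i] == scaffolds[spec$singleClassSeries] &&
      pdPlanned %in% c(2, 3, 4, 12)
    nTested <- sample(seq(spec$nTestedRange[1], spec$nTestedRange[2]), 1)
    tested <- sort(sample(targets$target_id, nTested))
    if (singleClass) {
      pool <- intersect(tested, enzymeIds)
      if (length(pool) < pdPlanned)
        tested <- sort(union(tested, sample(enzymeIds, pdPlanned)))
      active <- sort(sample(intersect(tested, enzymeIds), pdPlanned))
    } else if (pdPlanned >= 2) {
      # spread actives over 2..6 classes for class-profile realism
      nCls <- min(pdPlanned, sample(2:6, 1))
      clsPool <- names(byClass)
      cls <- sample(clsPool, nCls)
      pool <- intersect(tested, unlist(byClass[cls], use.names = FALSE))
      while (length(pool) < pdPlanned) {
        cls <- unique(c(cls, sample(clsPool, 1)))
        pool <- intersect(tested, unlist(byClass[cls], use.names = FALSE))
      }
      active <- sort(sample(pool, pdPlanned))
    } else if (pdPlanned == 1) {
      active <- sample(tested, 1)
    } else active <- character(0)

    inactive <- setdiff(tested, active)
    conflicted <- character(0)
    if (spec$conflictRate > 0 && length(inactive) > 0) {
      nConf <- rbinom(1, length(inactive), spec$conflictRate)
      if (nConf > 0) conflicted <- sample(inactive, nConf)
    }
    outc <- ifelse(tested %in% active, "active", "inactive")
    rec <- data.frame(compound_id = id, target_id = tested, outcome = outc,
                      stringsAsFactors = FALSE)
    if (spec$duplicateRate > 0) {
      nDup <- rbinom(1, nrow(rec), spec$duplicateRate)
      if (nDup > 0) {
        dupIdx <- sample(nrow(rec), nDup)
        rec <- rbind(rec, rec[dupIdx, , drop = FALSE])
      }
    }
    if (length(conflicted) > 0) {
      rec <- rbind(rec, data.frame(compound_id = id, target_id = conflicted,
                                   outcome = "active", stringsAsFactors = FALSE))
      conflictRows[[length(conflictRows) + 1L]] <- data.frame(
        compound_id = id, target_id = conflicted, stringsAsFactors = FALSE)
    }
    act[[i]] <- rec
    activeCls <- unique(targets$true_class[match(active, targets$target_id)])
    truthRows[[i]] <- data.frame(
      compound_id = id, planted_pd = pdPlanned,
      planted_n_tested = length(tested) - length(conflicted),
      planted_n_classes = length(activeCls),
      planted_single_class = singleClass, stringsAsFactors = FALSE)
  }
  activities <- do.call(rbind, act)
  activities$assay_id <- sprintf("AS%06d", seq_len(nrow(activities)))
  activities <- activities[, c("compound_id", "assay_id", "target_id", "outcome")]
  conflicts <- if (length(conflictRows) > 0) do.call(rbind, conflictRows)
    else data.frame(compound_id = character(0), target_id = character(0),
                    stringsAsFactors = FALSE)
  list(activities = activities, targets = targets,
       truth = do.call(rbind, truthRows), conflicts = conflicts)
}

#' Append spiked liability compounds
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param compounds compound data.frame from
#'   \code{\link{generateCompoundSeries}}.
#' @return list with \code{compounds} (augmented data.frame) and
#'   \code{labels} (compound_id, label naming the filter family that must
#'   flag it; clean compounds carry label "clean").
#' @export
spikeLiabilities <- function(spec, compounds) {
  stopifnot(inherits(spec, "synthetic_spec"))
  spikes <- spec$liabilitySpikes
  labels <- data.frame(compound_id = compounds$compound_id, label = "clean",
                       stringsAsFactors = FALSE)
  if (!is.null(spikes) && nrow(spikes) > 0) {
    add <- data.frame(compound_id = spikes$compound_id,
                      smiles = spikes$smiles, scaffold = "spike",
                      substituent = NA_character_, stringsAsFactors = FALSE)
    compounds <- rbind(compounds, add)
    labels <- rbind(labels, data.frame(compound_id = spikes$compound_id,
                                       label = spikes$label,
                                       stringsAsFactors = FALSE))
  }
  list(compounds = compounds, labels = labels)
}

#' Generate a complete synthetic screening data set
#'
#' Convenience wrapper: compound series, liability spikes, activity calls
#' and ground-truth tables, optionally written as the TSV dialect the
#' ingest functions read (plus truth files).
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param dir output directory (NULL to skip writing).
#' @return list with compounds, activities, targets, truth, conflicts,
#'   labels, analogPairs.
#' @export
generateScreeningData <- function(spec = syntheticSpec(), dir = NULL) {
  series <- generateCompoundSeries(spec)
  spiked <- spikeLiabilities(spec, series$compounds)
  calls <- generateActivityCalls(spec, spiked$compounds)
  out <- list(compounds = spiked$compounds, activities = calls$activities,
              targets = calls$targets, truth = calls$truth,
              conflicts = calls$conflicts, labels = spiked$labels,
              analogPairs = series$analogPairs)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    wt <- function(df, f) utils::write.table(
      df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(out$compounds[c("compound_id", "smiles")], "compounds.tsv")
    wt(out$activities, "activities.tsv")
    wt(out$targets[c("target_id", "protein_name", "family_name", "class_label")],
       "targets.tsv")
    wt(out$truth, "truth_compounds.tsv")
    wt(out$conflicts, "truth_conflicts.tsv")
    wt(out$labels, "truth_labels.tsv")
    wt(out$analogPairs, "truth_analog_pairs.tsv")
  }
  out
}
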
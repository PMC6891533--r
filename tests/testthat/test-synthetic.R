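test_that("generation is deterministic under a fixed seed", {
  spec <- miniSpec(seed = 99)
  a <- generateScreeningData(spec)
  b <- generateScreeningData(spec)
  expect_identical(a$compounds, b$compounds)
  expect_identical(a$activities, b$activities)
  expect_identical(a$truth, b$truth)
})

test_that("series construction plants the combinatorial analog pairs", {
  spec <- syntheticSpec(ringA = "thiophene2", ringB = "benzene",
                        substituents = c(H = "", Cl = "Cl", Me = "C"),
                        pdPlan = c(0, 1, 12), liabilitySpikes = NULL)
  ser <- generateCompoundSeries(spec)
  expect_identical(nrow(ser$compounds), 3L)
  expect_identical(nrow(ser$analogPairs), 3L)  # C(3, 2)
  cs <- standardizeMolecules(ser$compounds[c("compound_id", "smiles")])
  found <- mmpTable(findMMPs(cs))
  expect_identical(sort(paste(found$compound_a, found$compound_b)),
                   sort(paste(ser$analogPairs$compound_a,
                              ser$analogPairs$compound_b)))
  # disjoint scaffolds share no cores
  two <- generateCompoundSeries(miniSpec())
  cs2 <- standardizeMolecules(two$compounds[c("compound_id", "smiles")])
  scaff <- stats::setNames(two$compounds$scaffold, two$compounds$compound_id)
  pairs <- mmpTable(findMMPs(cs2))
  expect_true(all(scaff[pairs$compound_a] == scaff[pairs$compound_b]))
})

test_that("planted PD and conflict bookkeeping are recovered exactly", {
  spec <- miniSpec(seed = 3, conflictRate = 0.1)
  dat <- generateScreeningData(spec)
  prof <- aggregateProfiles(dat$activities)
  pd <- promiscuityDegree(prof)
  truth <- stats::setNames(dat$truth$planted_pd, dat$truth$compound_id)
  expect_identical(unname(pd[names(truth)]), as.integer(truth))
  expect_gt(nrow(dat$conflicts), 0)
  disc <- discardedTargets(prof); tst <- testedTargets(prof)
  for (k in seq_len(nrow(dat$conflicts))) {
    id <- dat$conflicts$compound_id[k]; tg <- dat$conflicts$target_id[k]
    expect_true(tg %in% disc[[id]])
    expect_false(tg %in% tst[[id]])
  }
  nt <- vapply(tst, length, integer(1))
  expect_identical(unname(nt[dat$truth$compound_id]),
                   dat$truth$planted_n_tested)
})

test_that("liability spikes carry labels their filter family honors", {
  spec <- miniSpec()
  spec$liabilitySpikes <- PromCliff:::.LIABILITY_SPIKES
  sp <- spikeLiabilities(spec, generateCompoundSeries(spec)$compounds)
  expect_setequal(unique(sp$labels$label),
                  c("clean", "pains", "aggregator", "medchem"))
  spikes <- sp$labels[sp$labels$label != "clean", ]
  cs <- standardizeMolecules(
    sp$compounds[match(spikes$compound_id, sp$compounds$compound_id),
                 c("compound_id", "smiles")])
  painsIds <- unique(screenPains(cs)$compound_id)
  aggIds <- with(screenAggregator(cs), compound_id[aggregator_flag])
  medIds <- unique(screenMedchemRules(cs)$compound_id)
  flaggedBy <- list(pains = painsIds, aggregator = aggIds, medchem = medIds)
  for (k in seq_len(nrow(spikes))) {
    expect_true(spikes$compound_id[k] %in% flaggedBy[[spikes$label[k]]],
                label = paste(spikes$compound_id[k], "flagged by",
                              spikes$label[k]))
  }
})

test_that("written tables round-trip through the ingest readers", {
  d <- withr::local_tempdir()
  dat <- generateScreeningData(miniSpec(), d)
  comp <- readCompoundTable(file.path(d, "compounds.tsv"))
  act <- readActivityTable(file.path(d, "activities.tsv"))
  targ <- readTargetTable(file.path(d, "targets.tsv"))
  expect_identical(nrow(comp), nrow(dat$compounds))
  expect_identical(nrow(act), nrow(dat$activities))
  expect_identical(targ$target_id, dat$targets$target_id)
})
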
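test_that("PAINS screening flags interference chemotypes, not clean molecules", {
  cs <- standardizeMolecules(
    c("O=C1CSC(=S)N1", "CCO", "Oc1ccccc1O"),
    ids = c("rhodanine", "ethanol", "catechol"))
  hits <- screenPains(cs)
  expect_true("rhodanine" %in% hits$compound_id)
  expect_identical(hits$rule_id[hits$compound_id == "rhodanine"][1],
                   "rhodanine_core")
  expect_false("ethanol" %in% hits$compound_id)
  # a compound matched by exactly one catalog is still flagged overall
  cat_hit <- unique(hits$catalog[hits$compound_id == "catechol"])
  expect_identical(cat_hit, "pains_a")
  prof <- mkProfiles(list(
    rhodanine = list(tested = sprintf("T%d", 1:5), active = character(0)),
    ethanol = list(tested = sprintf("T%d", 1:5), active = character(0)),
    catechol = list(tested = sprintf("T%d", 1:5), active = character(0))))
  res <- applyFilterCascade(prof, cs)
  expect_setequal(compoundIds(res$profiles), "ethanol")
  expect_true(res$report$pains_flag[res$report$compound_id == "catechol"])
})

test_that("aggregation likeness requires both similarity and logP", {
  refs <- defaultAggregatorRefs()
  cs <- standardizeMolecules(
    c("Clc1ccccc1C(c1ccccc1)(c1ccccc1)n1ccnc1",  # = clotrimazole reference
      "Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1",          # = resveratrol, logP < 3
      "CCO"),
    ids = c("clotri", "resv", "ethanol"))
  res <- screenAggregator(cs, refs)
  expect_identical(res$nearest_similarity[res$compound_id == "clotri"], 1)
  expect_true(res$aggregator_flag[res$compound_id == "clotri"])
  # identity similarity alone is not enough: the conjunction needs logP >= 3
  expect_identical(res$nearest_similarity[res$compound_id == "resv"], 1)
  expect_lt(res$logp[res$compound_id == "resv"], 3)
  expect_false(res$aggregator_flag[res$compound_id == "resv"])
  expect_false(res$aggregator_flag[res$compound_id == "ethanol"])
  # threshold boundary: a flag flips exactly at the measured similarity
  s <- res$nearest_similarity[res$compound_id == "ethanol"]
  resLo <- screenAggregator(cs["ethanol"], refs, simThreshold = s,
                            logpThreshold = -10)
  resHi <- screenAggregator(cs["ethanol"], refs, simThreshold = s + 1e-9,
                            logpThreshold = -10)
  expect_true(resLo$aggregator_flag)
  expect_false(resHi$aggregator_flag)
  expect_error(screenAggregator(cs, refs[0, ]), "empty")
})

test_that("medicinal-chemistry rules flag reactive groups with categories", {
  cs <- standardizeMolecules(
    c("CC(=O)Cl", "CCCC=O", "NC(=O)c1ccccc1"),
    ids = c("acyl_cl", "butanal", "benzamide"))
  v <- screenMedchemRules(cs)
  expect_identical(v$category[v$compound_id == "acyl_cl"], "acylating_agent")
  expect_identical(v$category[v$compound_id == "butanal"], "aldehyde")
  # benzamide passes the shipped rule subset
  expect_false("benzamide" %in% v$compound_id)
})

test_that("malformed catalogs are rejected at load time", {
  d <- withr::local_tempdir()
  writeLines(c("ok\t[OX2H]\tx", "broken\t[[[\tx"), file.path(d, "bad.tsv"))
  expect_error(loadSmartsCatalog(file.path(d, "bad.tsv")), "broken")
  expect_error(loadSmartsCatalog(file.path(d, "missing.tsv")), "not found")
})

test_that("the filter cascade is order-independent and monotone", {
  spec <- miniSpec()
  comp <- generateCompoundSeries(spec)$compounds[1:8, ]
  comp <- rbind(comp[c("compound_id", "smiles")],
                data.frame(compound_id = c("pains1", "agg1", "med1"),
                           smiles = c("O=C1CSC(=S)N1",
                                      "CCCCCCCCCCCCc1ccccc1O",
                                      "CC(=O)Cl")))
  cs <- standardizeMolecules(comp)
  prof <- mkProfiles(stats::setNames(lapply(comp$compound_id, function(id)
    list(tested = sprintf("T%d", 1:10), active = character(0))),
    comp$compound_id))
  base <- applyFilterCascade(prof, cs)
  perms <- list(c("pains", "aggregator", "medchem"),
                c("medchem", "pains", "aggregator"),
                c("aggregator", "medchem", "pains"))
  for (ord in perms) {
    res <- applyFilterCascade(prof, cs, order = ord)
    expect_setequal(compoundIds(res$profiles), compoundIds(base$profiles))
  }
  # every excluded compound has a recorded cause
  rep <- base$report
  excluded <- rep[!rep$passes_all, ]
  expect_true(all(excluded$pains_flag | excluded$aggregator_flag |
                  excluded$medchem_flag | !excluded$has_structure))
  # adding a rule can only shrink the passing set (phenol alert added)
  extra <- rbind(defaultMedchemRules(),
                 data.frame(rule_id = "phenol_extra", smarts = "[OX2H]c",
                            category = "extra"))
  res2 <- applyFilterCascade(prof, cs, medchemRules = extra)
  expect_true(all(compoundIds(res2$profiles) %in% compoundIds(base$profiles)))
  # compounds without structure are excluded with an explicit cause
  prof2 <- mkProfiles(list(ghost = list(tested = sprintf("T%d", 1:10),
                                        active = character(0))))
  res3 <- applyFilterCascade(prof2, cs)
  expect_length(res3$profiles, 0)
  expect_false(res3$report$has_structure)
})

test_that("atomic-contribution logP behaves physically", {
  alkanes <- c(pentane = "CCCCC", hexane = "CCCCCC", heptane = "CCCCCCC",
               octane = "CCCCCCCC", nonane = "CCCCCCCCC")
  lp <- calcLogP(alkanes)
  expect_true(all(diff(lp) > 0))  # each CH2 adds a positive contribution
  # representation invariance under re-canonicalization
  expect_equal(unname(calcLogP("c1ccccc1CCO")), unname(calcLogP("OCCc1ccccc1")))
  # single-atom molecule: the tabulated contribution sum for CH4
  # (one aliphatic carbon + four hydrogens: 0.1441 + 4 x 0.1230)
  expect_equal(unname(calcLogP("C")), 0.6361, tolerance = 1e-6)
})
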
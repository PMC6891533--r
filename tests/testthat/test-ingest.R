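test_that("standardization canonicalizes, is idempotent and logs rejections", {
  cs <- standardizeMolecules(
    c("OCC", "CCO", "C1=CC=CC=C1", "not_a_smiles", "", "CC(=O)[O-].[Na+]"),
    ids = c("a", "b", "benzene", "bad", "blank", "salt"))
  smi <- smiles(cs)
  expect_identical(unname(smi["a"]), unname(smi["b"]))
  expect_identical(unname(smi["benzene"]), "c1ccccc1")
  expect_identical(unname(nHeavyAtoms(cs)["benzene"]), 6L)
  # salt handling: largest organic fragment kept, charge neutralized
  expect_identical(unname(smi["salt"]), "CC(=O)O")
  rej <- rejectedStructures(cs)
  expect_setequal(rej$compound_id, c("bad", "blank"))
  expect_identical(rej$reason[rej$compound_id == "bad"], "parse_error")
  expect_identical(rej$reason[rej$compound_id == "blank"], "empty_input")
  # idempotence: re-standardizing the canonical forms is a no-op
  cs2 <- standardizeMolecules(unname(smi), ids = names(smi))
  expect_identical(unname(smiles(cs2)), unname(smi))
})

test_that("profile aggregation follows the consistency rule", {
  # consistent duplicates collapse
  p1 <- aggregateProfiles(data.frame(
    compound_id = "C1", assay_id = c("A1", "A2"), target_id = "T1",
    outcome = c("active", "active")))
  expect_identical(activeTargets(p1)$C1, "T1")
  expect_identical(testedTargets(p1)$C1, "T1")
  # contradictory calls are discarded: neither tested nor active
  p2 <- aggregateProfiles(data.frame(
    compound_id = "C1", assay_id = c("A1", "A2"), target_id = "T1",
    outcome = c("active", "inactive")))
  expect_identical(discardedTargets(p2)$C1, "T1")
  expect_length(testedTargets(p2)$C1, 0)
  expect_identical(unname(promiscuityDegree(p2)), 0L)
  # independent targets within one assay stay independent
  p3 <- aggregateProfiles(data.frame(
    compound_id = "C1", assay_id = "A1", target_id = c("T1", "T2"),
    outcome = c("active", "inactive")))
  expect_setequal(testedTargets(p3)$C1, c("T1", "T2"))
  expect_identical(activeTargets(p3)$C1, "T1")
  # unknown outcome tokens are a hard error naming the token
  expect_error(aggregateProfiles(data.frame(
    compound_id = "C1", assay_id = "A1", target_id = "T1",
    outcome = "maybe")), "maybe")
})

test_that("aggregation is order-independent and conserving", {
  set.seed(11)
  rec <- data.frame(
    compound_id = sample(sprintf("C%d", 1:8), 300, replace = TRUE),
    assay_id = sample(sprintf("A%d", 1:20), 300, replace = TRUE),
    target_id = sample(sprintf("T%d", 1:15), 300, replace = TRUE),
    outcome = sample(c("active", "inactive"), 300, replace = TRUE))
  p <- aggregateProfiles(rec)
  pPerm <- aggregateProfiles(rec[sample(nrow(rec)), ])
  expect_identical(p@profiles, pPerm@profiles)
  # collapsing only reduces: calls >= tested + discarded per compound
  calls <- table(rec$compound_id)
  for (id in compoundIds(p)) {
    expect_gte(calls[[id]],
               length(testedTargets(p)[[id]]) + length(discardedTargets(p)[[id]]))
  }
  # every pair lands in exactly one bucket
  for (id in compoundIds(p)) {
    expect_length(intersect(testedTargets(p)[[id]], discardedTargets(p)[[id]]), 0)
    expect_true(all(activeTargets(p)[[id]] %in% testedTargets(p)[[id]]))
  }
})

test_that("extensively-tested selection applies the exact threshold", {
  prof <- mkProfiles(list(
    at100 = list(tested = sprintf("T%03d", 1:100), active = character(0)),
    at99 = list(tested = sprintf("T%03d", 1:99), active = character(0))))
  sel <- selectExtensivelyTested(prof, 100)
  expect_identical(compoundIds(sel), "at100")
  expect_length(selectExtensivelyTested(mkProfiles(list()), 100), 0)
  # monotone in the threshold
  for (thr in c(50, 99, 100, 101)) {
    expect_true(all(compoundIds(selectExtensivelyTested(prof, thr + 1)) %in%
                    compoundIds(selectExtensivelyTested(prof, thr))))
  }
})

test_that("table readers validate schemas and tokens", {
  d <- withr::local_tempdir()
  write.table(data.frame(compound_id = "C1", assay_id = "A1",
                         target_id = "T1", outcome = "hit"),
              file.path(d, "bad.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(readActivityTable(file.path(d, "bad.tsv")), "hit")
  write.table(data.frame(target_id = c("T1", "T1"), protein_name = "x"),
              file.path(d, "dup.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(readTargetTable(file.path(d, "dup.tsv")), "unique")
})
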
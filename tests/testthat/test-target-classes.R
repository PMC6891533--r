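test_that("keyword classification is ordered, exhaustive and exclusive", {
  targets <- data.frame(
    target_id = sprintf("T%d", 1:7),
    protein_name = c("adenosine receptor A2a", "tyrosine kinase ABL1",
                     "mystery protein 9", "sodium channel subunit alpha",
                     "solute carrier family 6", "nuclear receptor ROR-gamma",
                     "collagen alpha chain"),
    family_name = c("G protein-coupled receptor family", "", "", "", "", "", ""),
    class_label = c("", "", "", "", "", "", "Others"))
  cls <- assignTargetClasses(targets)$class
  expect_identical(as.character(cls),
                   c("G protein-coupled receptors", "Enzymes", "Unclassified",
                     "Ion channels", "Transporters", "Transcription factors",
                     "Others"))
  # receptor kinases are enzymes (specific before generic)
  rk <- assignTargetClasses(data.frame(
    target_id = "T1", protein_name = "beta-adrenergic receptor kinase 1"))
  expect_identical(as.character(rk$class), "Enzymes")
  # partition: sizes sum to the target count
  sizes <- classSizeTable(assignTargetClasses(targets))
  expect_identical(sum(sizes$n_targets), nrow(targets))
})

test_that("multiclass ligands need PD >= 10 across at least two classes", {
  targets <- assignTargetClasses(data.frame(
    target_id = sprintf("T%02d", 1:20),
    protein_name = c(sprintf("serine kinase %d", 1:12),
                     sprintf("potassium channel %d", 1:8))))
  enz <- sprintf("T%02d", 1:12); chan <- sprintf("T%02d", 13:20)
  prof <- mkProfiles(list(
    both = list(tested = c(enz, chan), active = c(enz[1:8], chan[1:4])),
    mono = list(tested = c(enz, chan), active = enz[1:12]),
    low = list(tested = c(enz, chan), active = c(enz[1:5], chan[1:4]))))
  cp <- classProfiles(prof, targets)
  expect_true(cp$is_multiclass[cp$compound_id == "both"])    # PD 12, 2 classes
  expect_false(cp$is_multiclass[cp$compound_id == "mono"])   # PD 12, 1 class
  expect_false(cp$is_multiclass[cp$compound_id == "low"])    # PD 9, 2 classes
  # multiclass and single-class PD>=10 compounds partition the PD>=10 set
  hi <- cp[cp$pd >= 10, ]
  expect_identical(sum(hi$is_multiclass) + sum(hi$n_active_classes == 1),
                   nrow(hi))
  # unknown target ids are a hard error listing the ids
  bad <- mkProfiles(list(x = list(tested = "TXX", active = "TXX")))
  expect_error(classProfiles(bad, targets), "TXX")
})

test_that("class-count histogram counts highly promiscuous compounds", {
  cp <- data.frame(compound_id = c("a", "b", "c", "d"),
                   pd = c(12, 15, 11, 3),
                   n_active_classes = c(1, 4, 4, 2))
  h <- classCountHistogram(cp)
  expect_identical(h, stats::setNames(c(1L, 2L), c("1", "4")))
  expect_identical(sum(h), sum(cp$pd >= 10))
  expect_length(classCountHistogram(cp[0, ]), 0)
  allOne <- classCountHistogram(data.frame(compound_id = "a", pd = 10,
                                           n_active_classes = 1))
  expect_identical(names(allOne), "1")
})

test_that("single-class promiscuous compounds need PD >= 2 in one class", {
  cp <- data.frame(compound_id = c("in3", "out1", "out2cls"),
                   pd = c(3, 1, 3),
                   n_active_classes = c(1, 1, 2))
  expect_identical(singleClassPromiscuous(cp), "in3")
})
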
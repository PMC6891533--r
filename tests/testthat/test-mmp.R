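test_that("single-cut enumeration respects bond eligibility", {
  cs <- standardizeMolecules(c("c1ccccc1", "CCc1ccccc1", "C"),
                             ids = c("benzene", "ethylbenzene", "methane"))
  fr <- enumerateSingleCuts(cs)
  # benzene: all bonds in the ring; methane: single heavy atom
  expect_false("benzene" %in% fr$compound_id)
  expect_false("methane" %in% fr$compound_id)
  # ethylbenzene: the two acyclic C-C bonds, orientation forced by size rule
  eb <- fr[fr$compound_id == "ethylbenzene", ]
  expect_identical(nrow(eb), 2L)
  expect_setequal(eb$core, c("*c1ccccc1", "*Cc1ccccc1"))
  expect_setequal(eb$substituent, c("*CC", "*C"))
  expect_true(all(eb$core_size + eb$substituent_size ==
                  nHeavyAtoms(cs)[["ethylbenzene"]]))
})

test_that("fragmentations reconstruct their parent molecule", {
  cs <- standardizeMolecules(
    c("CCc1ccccc1", "Clc1ccncc1", "COc1ccc(CC(N)=O)cc1", "CC(C)Cc1ccco1"),
    ids = sprintf("m%d", 1:4))
  fr <- enumerateSingleCuts(cs)
  expect_gt(nrow(fr), 0)
  parents <- smiles(cs)
  for (i in seq_len(nrow(fr))) {
    expect_identical(weldFragments(fr$core[i], fr$substituent[i]),
                     unname(parents[fr$compound_id[i]]))
  }
  # hydrogen welding restores the implicit hydrogen
  expect_identical(weldFragments("*c1ccccc1", "[*][H]"), "c1ccccc1")
})

test_that("MMP detection handles the canonical cases", {
  cs <- standardizeMolecules(
    c("Cc1ccc(-c2ccccc2)cc1", "Clc1ccc(-c2ccccc2)cc1",  # single-site Me/Cl
      "c1ccc(-c2ccccc2)cc1",                             # H analog
      "Clc1ccc(-c2ccc(N)cc2)cc1"),                       # Cl AND amine added
    ids = c("me", "cl", "h", "two"))
  pairs <- mmpTable(findMMPs(cs))
  key <- paste(pairs$compound_a, pairs$compound_b)
  # chlorine-for-methyl exchange and both H-replacement pairs
  expect_true("cl me" %in% key)
  expect_true("cl h" %in% key)
  expect_true("h me" %in% key)
  hcl <- pairs[key == "cl h", ]
  expect_identical(sort(c(hcl$substituent_a, hcl$substituent_b)),
                   sort(c("*Cl", "[*][H]")))
  # "two" differs from "cl" at one site (amine) but from "me" and "h" at two
  expect_true("cl two" %in% key)
  expect_false("me two" %in% key)
  expect_false("h two" %in% key)
  # identical structures under different ids never pair
  dup <- standardizeMolecules(c("CCc1ccccc1", "CCc1ccccc1"), ids = c("x", "y"))
  expect_identical(length(findMMPs(dup)), 0L)
})

test_that("transformation size difference is bounded", {
  # 18-heavy-atom terphenyl core passes the 2:1 ratio for large substituents;
  # nonyl vs H exceeds the 8-atom transformation difference, octyl does not
  core <- "c1ccc(-c2ccc(-c3ccc%scc3)cc2)cc1"
  cs <- standardizeMolecules(
    c(sprintf(core, "(CCCCCCCCC)"), sprintf(core, "(CCCCCCCC)"),
      sprintf(core, "")),
    ids = c("nonyl", "octyl", "h"))
  key <- with(mmpTable(findMMPs(cs)), paste(compound_a, compound_b))
  expect_true("h octyl" %in% key)      # diff 8: allowed
  expect_false("h nonyl" %in% key)     # diff 9: excluded
  expect_true("nonyl octyl" %in% key)  # diff 1: allowed
})

test_that("index-based search equals the brute-force pairwise oracle", {
  for (seed in c(21, 22)) {
    spec <- miniSpec(seed = seed)
    set.seed(seed)
    comp <- generateCompoundSeries(spec)$compounds
    comp <- comp[sample(nrow(comp), 20), ]
    cs <- standardizeMolecules(comp[c("compound_id", "smiles")])
    found <- mmpTable(findMMPs(cs))
    foundKeys <- sort(paste(found$compound_a, found$compound_b))
    expect_identical(foundKeys, bruteForceMMPPairs(cs))
    # order invariance
    perm <- cs[rev(seq_along(compoundIds(cs)))]
    found2 <- mmpTable(findMMPs(perm))
    expect_identical(found, found2)
  }
})

test_that("cliff detection applies both PD thresholds and counts shared targets", {
  cs <- standardizeMolecules(
    c("Clc1ccc(-c2ccccc2)cc1", "c1ccc(-c2ccccc2)cc1", "Cc1ccc(-c2ccccc2)cc1"),
    ids = c("prom", "inact", "mid"))
  mmps <- findMMPs(cs)
  shared <- sprintf("S%03d", 1:150)
  prof <- mkProfiles(list(
    prom = list(tested = c(shared, sprintf("P%03d", 1:28)),
                active = shared[1:34]),
    inact = list(tested = c(shared, sprintf("I%03d", 1:45)),
                 active = character(0)),
    mid = list(tested = shared, active = shared[1:2])))
  cliffs <- cliffTable(detectPromiscuityCliffs(mmps, prof))
  # PD (34, 0) pair is a cliff; (34, 2) is not; partner below threshold only
  expect_identical(cliffs$promiscuous_id, "prom")
  expect_identical(cliffs$partner_id, "inact")
  expect_identical(cliffs$shared_tested, 150L)
  expect_identical(cliffs$pd_promiscuous, 34L)
  # boundary: promiscuous side must reach pd_hi
  prof9 <- mkProfiles(list(
    prom = list(tested = shared, active = shared[1:9]),
    inact = list(tested = shared, active = character(0)),
    mid = list(tested = shared, active = shared[1:2])))
  expect_identical(length(detectPromiscuityCliffs(mmps, prof9)), 0L)
})
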
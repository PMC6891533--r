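test_that("promiscuity degree is the active-target count", {
  prof <- mkProfiles(list(
    inact = list(tested = sprintf("T%03d", 1:200), active = character(0)),
    multi = list(tested = sprintf("T%03d", 1:178),
                 active = sprintf("T%03d", 1:34)),
    single = list(tested = sprintf("T%03d", 1:120), active = "T007")))
  pd <- promiscuityDegree(prof)
  expect_identical(unname(pd[c("inact", "multi", "single")]), c(0L, 34L, 1L))
})

test_that("the PD census matches brute force and enforces its invariants", {
  cen <- pdCensus(c(0, 0, 0, 1, 1, 2, 10))
  expect_identical(cen$count, c(7L, 3L, 2L, 2L, 1L, 1L, 0L))
  expect_identical(pdCensus(numeric(0))$count, rep(0L, 7))
  allzero <- pdCensus(rep(0, 12))
  expect_identical(allzero$count[allzero$label == "PD = 0"], 12L)
  # property: census equals a direct scan on random PD vectors
  set.seed(5)
  for (rep in 1:5) {
    pd <- rpois(200, 3)
    cen <- pdCensus(pd)
    expect_identical(cen$count,
                     c(length(pd), sum(pd == 0), sum(pd == 1), sum(pd >= 2),
                       sum(pd >= 5), sum(pd >= 10), sum(pd >= 15)))
    expect_true(all(diff(cen$count[4:7]) <= 0))
  }
})

test_that("five-number summaries follow the linear-interpolation convention", {
  prof <- mkProfiles(list(
    a = list(tested = sprintf("T%d", 1:100), active = character(0)),
    b = list(tested = sprintf("T%d", 1:110), active = character(0)),
    c = list(tested = sprintf("T%d", 1:120), active = character(0)),
    d = list(tested = sprintf("T%d", 1:130), active = character(0)),
    e = list(tested = sprintf("T%d", 1:140), active = character(0))))
  distr <- testedDistributionByPd(prof)
  row <- distr[distr$group == "all", ]
  expect_identical(c(row$min, row$q1, row$median, row$q3, row$max),
                   c(100, 110, 120, 130, 140))
  # degenerate single-member summary
  one <- testedDistributionByPd(prof["c"])
  r1 <- one[one$group == "all", ]
  expect_true(all(c(r1$min, r1$q1, r1$median, r1$q3, r1$max) == 120))
  # permutation invariance
  distr2 <- testedDistributionByPd(prof[c("d", "b", "e", "a", "c")])
  expect_identical(distr$median, distr2$median)
})

test_that("boxplot outliers sit beyond the 1.5 IQR whiskers", {
  prof <- mkProfiles(stats::setNames(lapply(c(110, 111, 112, 113, 400),
    function(n) list(tested = sprintf("T%d", seq_len(n)),
                     active = character(0))), letters[1:5]))
  distr <- testedDistributionByPd(prof)
  out <- attr(distr, "outliers")[["all"]]
  expect_identical(out, 400)
  expect_identical(distr$max[distr$group == "all"], 113)
})

test_that("logP strata summaries depend only on the value multiset", {
  cs <- standardizeMolecules(
    c("CCCCC", "CCCCC", "CCCCCC", "CCCCCC"), ids = c("a", "b", "c", "d"))
  # stratum of identical molecules: q1 = median = q3 = that logP
  prof1 <- mkProfiles(list(
    a = list(tested = sprintf("T%d", 1:5), active = character(0)),
    b = list(tested = sprintf("T%d", 1:5), active = character(0))))
  d1 <- logpDistributionByPd(prof1, cs)
  r <- d1[d1$group == "PD = 0", ]
  expect_equal(r$q1, r$median)
  expect_equal(r$q3, r$median)
  expect_equal(r$median, unname(calcLogP("CCCCC")))
  # two strata with the same logP multiset summarize identically
  prof2 <- mkProfiles(list(
    a = list(tested = sprintf("T%d", 1:5), active = character(0)),
    c = list(tested = sprintf("T%d", 1:5), active = character(0)),
    b = list(tested = sprintf("T%d", 1:5), active = "T1"),
    d = list(tested = sprintf("T%d", 1:5), active = "T1")))
  d2 <- logpDistributionByPd(prof2, cs)
  expect_equal(d2[d2$group == "PD = 0", -1], d2[d2$group == "PD = 1", -1],
               ignore_attr = TRUE)
})
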
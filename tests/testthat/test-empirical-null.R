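test_that("empirical null percentiles use linear interpolation and sane tails", {
  set.seed(41)
  nn <- buildEmpiricalNull(rnorm(1000), statistic = "z")
  expect_equal(nn@classTable$p95, 1.645, tolerance = 0.15)

  n2 <- buildEmpiricalNull(as.numeric(1:100), statistic = "u")
  expect_equal(n2@classTable$p95, 95.05)

  # a class filled with cap substitutes is undefined
  vals <- c(rnorm(50), rep(27.3, 30))
  daf <- c(runif(50, 0.5, 1), runif(30, 0, 0.01))
  capped <- c(rep(FALSE, 50), rep(TRUE, 30))
  nd <- buildEmpiricalNull(vals, daf, "DAF", nClasses = 100, capped = capped,
                           statistic = "DIND")
  lowClass <- 1L
  expect_false(nd@classTable$defined[lowClass])
  expect_true(is.na(percentileRank(nd, 5, 0.005)))
})

test_that("percentile ranks are exact counting fractions", {
  panel <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3, 2)
  nn <- buildEmpiricalNull(panel, statistic = "s")
  expect_equal(percentileRank(nn, 0), 0)
  expect_equal(percentileRank(nn, 9), 1)
  for (v in c(2, 4.5, 7)) {
    expect_equal(percentileRank(nn, v), mean(panel <= v))
  }
})

test_that("directional calls need three families at 5% or two at 1%, strictly", {
  ev <- function(...) {
    x <- list(...)
    data.frame(statistic = names(x), rank = unlist(x))
  }
  # three distinct families at the 5% tails
  r <- callDirectionalTargets(ev(TajD = 0.03, FST = 0.97, DIND = 0.96))
  expect_equal(r$verdict, "directional_target")
  # two distinct families, both 1% tails
  r2 <- callDirectionalTargets(ev(FST = 0.995, DIND = 0.992))
  expect_equal(r2$verdict, "directional_target")
  # two statistics from the same family only
  r3 <- callDirectionalTargets(ev(TajD = 0.01, FayWuHnorm = 0.02))
  expect_equal(r3$verdict, "none")
  # strict boundaries: exactly 0.05 / 0.95 do not count
  r4 <- callDirectionalTargets(ev(TajD = 0.05, FST = 0.95, DIND = 0.95))
  expect_equal(r4$verdict, "none")
})

test_that("verdicts equal a brute-force re-derivation over random evidence", {
  set.seed(42)
  fm <- statFamilies()
  for (rep in 1:200) {
    pick <- sample(nrow(fm), sample(3:7, 1))
    ev <- data.frame(statistic = fm$statistic[pick],
                     rank = runif(length(pick)))
    got <- callDirectionalTargets(ev)$verdict
    m <- merge(ev, fm, by = "statistic")
    o5 <- ifelse(m$tail == "low", m$rank < 0.05, m$rank > 0.95)
    o1 <- ifelse(m$tail == "low", m$rank < 0.01, m$rank > 0.99)
    want <- if (length(unique(m$family[o5])) >= 3 ||
                length(unique(m$family[o1])) >= 2)
      "directional_target" else "none"
    expect_identical(got, want)
  }
})

test_that("the co-occurrence rule keeps the neutral false-positive rate low", {
  # under independent uniform ranks (the panel scored against itself),
  # fewer than 5% of genes may be called
  set.seed(43)
  fm <- statFamilies()[1:7, ]   # the single-population statistic set
  calls <- replicate(1000, {
    ev <- data.frame(statistic = fm$statistic, rank = runif(7))
    callDirectionalTargets(ev)$verdict == "directional_target"
  })
  expect_lt(mean(calls), 0.05)
})

test_that("balancing candidates require a strict 95th-percentile exceedance", {
  expect_equal(flagBalancingCandidates(c(YRI = 0.98), c(YRI = 0.5))$verdict,
               "balancing_candidate")
  expect_equal(flagBalancingCandidates(c(YRI = 0.90), c(YRI = 0.90))$verdict,
               "none")
  expect_equal(flagBalancingCandidates(c(YRI = 0.95), c(YRI = 0.95))$verdict,
               "none")
  # the MLHKA gate
  expect_equal(balancingVerdict(TRUE, c(0.2, 0.01)), "balancing_target")
  expect_equal(balancingVerdict(TRUE, c(0.2, 0.6)), "none")
  expect_equal(balancingVerdict(FALSE, c(0.001)), "none")
})

test_that("adding one panel member shifts ranks by at most 1/panel size", {
  set.seed(44)
  panel <- rnorm(200)
  n1 <- buildEmpiricalNull(panel, statistic = "s")
  n2 <- buildEmpiricalNull(c(panel, 0.31), statistic = "s")
  for (v in seq(-2, 2, by = 0.25)) {
    expect_lt(abs(percentileRank(n1, v) - percentileRank(n2, v)),
              1 / 200 + 1e-9)
  }
})
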
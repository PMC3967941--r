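hesn <- GenotypeCounts(3, 12, 72, "HESN")
ctr <- GenotypeCounts(2, 59, 375, "CTR")

test_that("exact HWE test matches an allele-shuffling oracle and handles edges", {
  set.seed(61)
  p <- hweExactTest(GenotypeCounts(2, 6, 12))
  expect_equal(p, oracleHweShuffleP(2, 6, 12), tolerance = 0.02)
  p2 <- hweExactTest(GenotypeCounts(0, 4, 4))
  expect_equal(p2, oracleHweShuffleP(0, 4, 4), tolerance = 0.02)
  # the HWE mode itself always has p = 1-ish mass coverage
  expect_equal(hweExactTest(GenotypeCounts(0, 2, 0)), 1)
  expect_equal(hweExactTest(GenotypeCounts(0, 0, 50)), 1)  # monomorphic
})

test_that("penetrance-model fit recovers itself on expectation-generated counts", {
  e <- popgenScan:::wtExpected(0.15, 1, 4, 0.2)
  cases <- GenotypeCounts(round(e$caseP[1] * 4000), round(e$caseP[2] * 4000),
                          round(e$caseP[3] * 4000))
  ctrls <- GenotypeCounts(round(e$ctrlP[1] * 8000), round(e$ctrlP[2] * 8000),
                          round(e$ctrlP[3] * 8000))
  f <- fitPenetranceModel(cases, ctrls, 0.2, "recessive")
  expect_lt(f@chisq, 0.05)
  expect_equal(f@q, 0.15, tolerance = 0.01)
  expect_equal(f@gamma, 4, tolerance = 0.1)
  # prevalence identity holds at the optimum
  expect_equal(f@Kp,
               f@alpha * ((1 - f@q)^2 + 2 * f@q * (1 - f@q) * f@beta +
                            f@q^2 * f@gamma),
               tolerance = 1e-8)
})

test_that("chi-square scales with cohort size while estimates stay put", {
  f1 <- fitPenetranceModel(hesn, ctr, 0.2, "recessive")
  big <- function(g, k) GenotypeCounts(g@counts[1] * k, g@counts[2] * k,
                                       g@counts[3] * k)
  f3 <- fitPenetranceModel(big(hesn, 3), big(ctr, 3), 0.2, "recessive")
  expect_equal(f3@q, f1@q, tolerance = 5e-3)
  expect_equal(f3@gamma, f1@gamma, tolerance = 0.05)
  expect_equal(f3@chisq, 3 * f1@chisq, tolerance = 0.05)
})

test_that("AIC selection prefers fewer parameters on ties and finds planted models", {
  fits <- lapply(c("general", "recessive"), function(m)
    fitPenetranceModel(hesn, ctr, 0.2, m))
  # identical chisq, 3 vs 2 free parameters -> 2-parameter model wins
  fA <- fits[[1]]; fB <- fits[[2]]
  fA@chisq <- 1; fA@AIC <- 1 + 2 * 3
  fB@chisq <- 1; fB@AIC <- 1 + 2 * 2
  expect_equal(selectBestModelAic(list(fA, fB))@model, "recessive")

  set.seed(62)
  hitRate <- mean(replicate(40, {
    cc <- simulateCaseControlCounts(0.25, 3, 3, 0.2, 2000, 2000)
    fits <- lapply(c("dominant", "recessive", "multiplicative"), function(m)
      fitPenetranceModel(cc$cases, cc$controls, 0.2, m))
    selectBestModelAic(fits)@model == "dominant"
  }))
  expect_gte(hitRate, 0.8)
})

test_that("penetrance parameters are recovered from sampled counts", {
  set.seed(63)
  qs <- replicate(60, {
    cc <- simulateCaseControlCounts(0.1, 1, 3, 0.2, 500, 2000)
    fitPenetranceModel(cc$cases, cc$controls, 0.2, "recessive")@q
  })
  expect_lt(abs(median(qs) - 0.1), 0.02)
})

test_that("permutation p matches exhaustive label enumeration on tiny tables", {
  tiny1 <- c(2, 1, 1); tiny2 <- c(0, 2, 2)
  for (model in c("genotypic", "recessive")) {
    exact <- oracleExhaustivePermP(tiny1, tiny2, model)
    got <- permutationAssociation(GenotypeCounts(tiny1[1], tiny1[2], tiny1[3]),
                                  GenotypeCounts(tiny2[1], tiny2[2], tiny2[3]),
                                  model, B = 20000, seed = 4)
    expect_equal(got$p, exact, tolerance = 0.015)
  }
  # degenerate table
  d <- permutationAssociation(GenotypeCounts(0, 0, 5),
                              GenotypeCounts(0, 0, 7), "genotypic", B = 100)
  expect_equal(d$p, 1)
})

test_that("genotype frequencies reproduce the cohort proportions", {
  gf <- genotypeFrequencies(hesn)
  expect_equal(gf$rareHomProportion, 3 / 87)
  expect_equal(gf$rareAlleleFrequency, 18 / 174)
  g0 <- genotypeFrequencies(GenotypeCounts(0, 0, 10))
  expect_equal(g0$rareHomProportion, 0)
  expect_equal(g0$rareAlleleFrequency, 0)
})

test_that("case/control simulator respects feasibility and expectations", {
  set.seed(64)
  cc <- simulateCaseControlCounts(0.079, 1, 3.23, 0.2, 87000, 436000)
  expect_equal(sum(cc$cases@counts), 87000)
  expect_equal(sum(cc$controls@counts), 436000)
  e <- popgenScan:::wtExpected(0.079, 1, 3.23, 0.2)
  expect_equal(as.numeric(cc$cases@counts) / 87000, e$caseP, tolerance = 0.02)
  expect_equal(as.numeric(cc$controls@counts) / 436000, e$ctrlP,
               tolerance = 0.02)
  # gamma = beta = 1 gives identical case/control distributions (HWE at q)
  e0 <- popgenScan:::wtExpected(0.3, 1, 1, 0.2)
  expect_equal(e0$caseP, e0$ctrlP, tolerance = 1e-12)
  expect_error(simulateCaseControlCounts(0.5, 1, 10, 0.9, 10, 10),
               "infeasible")
})
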
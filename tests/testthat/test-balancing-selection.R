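test_that("MLHKA recovers k on contrast fixtures and matches a grid-search oracle", {
  loci <- data.frame(locus = c("r1", "r2", "r3", "t"),
                     S = c(10, 10, 10, 20), D = c(20, 20, 20, 20),
                     n = 20, L = 1000, isTest = c(FALSE, FALSE, FALSE, TRUE))
  r <- mlhkaFitAndTest(loci)
  expect_equal(r@k, 2, tolerance = 0.02)
  # independent grid maximization of the same likelihood
  an <- sum(1 / (1:19))
  grid <- expand.grid(T = seq(0.5, 20, by = 0.05), k = seq(0.2, 5, by = 0.02))
  ll <- mapply(function(T, k) {
    kk <- c(1, 1, 1, k)
    th <- (loci$S + loci$D) / (kk * an + T + 1)
    sum(dpois(loci$S, kk * th * an, log = TRUE) +
          dpois(loci$D, th * (T + 1), log = TRUE))
  }, grid$T, grid$k)
  expect_equal(r@lnLAlt, max(ll), tolerance = 1e-3)
  expect_equal(r@k, grid$k[which.max(ll)], tolerance = 0.03)

  # null-consistent test locus
  loci2 <- loci; loci2$S[4] <- 10
  r2 <- mlhkaFitAndTest(loci2)
  expect_equal(r2@k, 1, tolerance = 0.01)
  expect_lt(r2@LRT, 1e-4)

  expect_error(mlhkaFitAndTest(transform(loci, D = 0)), "unidentifiable")
  expect_error(mlhkaFitAndTest(loci[3:4, ]), "reference")
})

test_that("MLHKA respects likelihood nesting on random data", {
  set.seed(51)
  for (rep in 1:25) {
    sim <- t(vapply(1:8, function(i) simulateOutgroupDivergence(5, 5, 20),
                    numeric(2)))
    df <- data.frame(locus = paste0("l", 1:8), S = sim[, 1], D = sim[, 2],
                     n = 20, L = 1000,
                     isTest = c(rep(FALSE, 7), TRUE))
    if (all(df$D == 0)) next
    r <- mlhkaFitAndTest(df)
    expect_gte(r@lnLAlt, r@lnLNull - 1e-6)
    expect_gte(r@LRT, 0)
    expect_gt(r@k, 0)
  }
})

test_that("coalescent p-values are conservative counts with correct tails", {
  set.seed(52)
  # the median of the null lands near p = 0.5
  sims <- replicate(300, tajimasD(sfsCounts(simulateCoalescentLocus(15, 5))))
  med <- median(sims, na.rm = TRUE)
  p <- coalescentPvalue(med, "D", n = 15, theta = 5, iterations = 300)
  expect_gt(p, 0.3); expect_lt(p, 0.7)
  # a wildly positive D is extreme
  p2 <- coalescentPvalue(3, "D", n = 40, theta = 10, iterations = 300)
  expect_lt(p2, 0.01)
  # lower tail mirrors
  p3 <- coalescentPvalue(-3, "D", n = 40, theta = 10, iterations = 200,
                         tail = "lower")
  expect_lt(p3, 0.05)
})

test_that("mutation-rate calibration follows the divergence arithmetic", {
  m <- calibrateMutationRate(60)
  expect_equal(m$muYear, 5e-6)
  expect_equal(m$muGeneration, 1.25e-4)
  expect_equal(calibrateMutationRate(0)$muYear, 0)
  expect_equal(calibrateMutationRate(60, divergenceYears = 1.2e7)$muYear,
               2.5e-6)
})

test_that("TMRCA is linear in divergence and inverse-linear in mu", {
  h <- makeT4()
  # mean distance to the all-ancestral MRCA: (0+1+2+3)/4 = 1.5
  r <- tmrcaPairwise(h, muYear = 5e-6, nBoot = 50)
  expect_equal(r$meanDivergence, 1.5)
  expect_equal(r$tmrcaYears, 1.5 / 5e-6)
  r2 <- tmrcaPairwise(h, muYear = 1e-5, nBoot = 0)
  expect_equal(r$tmrcaYears, 2 * r2$tmrcaYears)
  # identical chromosomes estimate zero
  mono <- HaplotypeMatrix(matrix(0L, 4, 2), c(1L, 5L), "P")
  expect_equal(tmrcaPairwise(mono, 1e-6, nBoot = 0)$tmrcaYears, 0)
  expect_error(tmrcaPairwise(h, muYear = 0), "muYear")
})

test_that("TMRCA estimator tracks the recorded true coalescent TMRCA", {
  set.seed(53)
  relerr <- replicate(100, {
    h <- simulateCoalescentLocus(20, 10)
    tru <- attr(h, "tmrca")
    est <- tmrcaPairwise(h, muYear = 10 / 2, nBoot = 0)$tmrcaYears
    abs(est - tru) / tru
  })
  expect_lt(median(relerr), 0.35)
})
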
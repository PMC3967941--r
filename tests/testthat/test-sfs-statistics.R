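T4 <- makeT4()

test_that("diversity estimators match direct formulas on the ladder fixture", {
  cc <- sfsCounts(T4, L = 100)
  expect_equal(wattersonTheta(cc), 3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-9)
  expect_equal(wattersonTheta(cc, perSite = TRUE), 0.016364, tolerance = 1e-4)
  expect_equal(nucleotideDiversityPi(cc), 10 / 6, tolerance = 1e-9)
  expect_equal(nucleotideDiversityPi(cc, perSite = TRUE),
               nucleotideDiversityPi(cc) / 100)

  # n = 2, S = 7: a_2 = 1
  c2 <- new("SFSCounts", n = 2L, S = 7L, xi = as.numeric(7), etaS = 7L,
            dSum = 7, L = 100, nExcluded = 0L)
  expect_equal(wattersonTheta(c2), 7)
})

test_that("Tajima's D reproduces the hand-evaluated constants and value", {
  cc <- sfsCounts(T4)
  k <- popgenScan:::tajimaConstants(4)
  expect_equal(k$e1, 0.0055096, tolerance = 1e-4)
  expect_equal(k$e2, 0.0026900, tolerance = 1e-3)
  expect_equal(tajimasD(cc), 0.168, tolerance = 5e-3)

  mono <- HaplotypeMatrix(matrix(0L, 4, 2), c(1L, 5L), "P")
  expect_true(is.na(tajimasD(sfsCounts(mono))))
})

test_that("Fu & Li's starred statistics match frozen hand computations", {
  cc <- sfsCounts(T4)
  fl <- fuLiStar(cc)
  # frozen values from an independent arithmetic evaluation of the
  # Simonsen-corrected constants at n=4, S=3, etaS=2, pi=5/3
  expect_equal(unname(fl["Dstar"]), 0.16766, tolerance = 1e-4)
  expect_equal(unname(fl["Fstar"]), 0.14993, tolerance = 1e-4)

  # all-singleton spectrum drives D* negative
  m <- diag(6)[, 1:5]; storage.mode(m) <- "integer"
  hs <- HaplotypeMatrix(m, seq_len(5) * 3, "P")
  expect_lt(unname(fuLiStar(sfsCounts(hs))["Dstar"]), 0)
})

test_that("normalized Fay & Wu's H matches the hand-evaluated variance", {
  cc <- sfsCounts(T4)
  expect_equal(fayWuHNorm(cc), -0.709, tolerance = 1e-3)
  # all-singleton unfolded spectrum gives positive H
  m <- diag(6)[, 1:5]; storage.mode(m) <- "integer"
  hs <- HaplotypeMatrix(m, seq_len(5) * 3, "P")
  expect_gt(fayWuHNorm(sfsCounts(hs)), 0)
  # no resolved sites -> missing
  h2 <- T4
  h2@ancestral <- rep("unresolved", 10)
  expect_true(is.na(fayWuHNorm(sfsCounts(h2))))
})

test_that("pi equals the quadratic-time pair-enumeration oracle on random matrices", {
  set.seed(11)
  for (rep in 1:100) {
    m <- randomHapMatrix(sample(4:10, 1), sample(5:20, 1))
    h <- HaplotypeMatrix(m, cumsum(sample(1:9, ncol(m), replace = TRUE)), "P")
    cc <- sfsCounts(h)
    expect_equal(nucleotideDiversityPi(cc),
                 oraclePairwiseSum(m) / choose(nrow(m), 2))
  }
})

test_that("normalized statistics ignore L; per-site variants scale by L", {
  set.seed(12)
  m <- randomHapMatrix(8, 12)
  h <- HaplotypeMatrix(m, seq_len(12) * 10, "P")
  cA <- sfsCounts(h, L = 120); cB <- sfsCounts(h, L = 1200)
  expect_equal(tajimasD(cA), tajimasD(cB))
  expect_equal(fayWuHNorm(cA), fayWuHNorm(cB))
  expect_equal(fuLiStar(cA), fuLiStar(cB))
  expect_equal(wattersonTheta(cA, TRUE) / 10, wattersonTheta(cB, TRUE))
})

test_that("sliding windows tile from the region start and flag against a null", {
  set.seed(13)
  h <- simulateCoalescentLocus(10, 8, regionLength = 20000)
  w <- slidingWindowStat(h, "D", span = 5000, step = 500)
  expect_equal(nrow(w), 31)          # floor((20000-5000)/500)+1
  expect_equal(w$start[1], 1)
  expect_equal(w$end[1], 5000)

  # brute-force flag check on a null built from a toy panel
  panelVals <- rnorm(50)
  null <- buildEmpiricalNull(panelVals, statistic = "D")
  wf <- slidingWindowStat(h, "D", span = 5000, step = 500, null = null)
  thr <- quantile(panelVals, 0.05, type = 7)
  ok <- !is.na(wf$value)
  expect_identical(wf$below5th[ok], wf$value[ok] < thr)
  expect_true(all(is.na(wf$value) | !is.na(wf$below5th)))
})
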
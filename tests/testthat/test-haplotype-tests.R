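# fixture with a fully worked EHH decay: core at site 1 (derived = rows 1-4)
ehhFixture <- function() {
  calls <- rbind(c(1, 1, 0, 0),
                 c(1, 1, 0, 0),
                 c(1, 0, 1, 0),
                 c(1, 0, 1, 1),
                 c(0, 0, 0, 0),
                 c(0, 1, 1, 0))
  HaplotypeMatrix(calls, c(100L, 200L, 300L, 400L), "P")
}

test_that("EHH follows the homozygosity-ratio definition on a worked example", {
  h <- ehhFixture()
  cv <- ehhCurve(h, 1, core = "derived", side = "right", minEhh = 0)
  # split 2/2 at site 2: (1+1)/6; still 2/2 at site 3; 2/1/1 at site 4: 1/6
  expect_equal(cv$ehh, c(1, 1 / 3, 1 / 3, 1 / 6), tolerance = 1e-9)
  expect_equal(cv$offset, c(0, 100, 200, 300))

  # identical core haplotypes keep EHH = 1
  hid <- HaplotypeMatrix(rbind(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0), c(0, 1, 0)),
                         c(10L, 20L, 30L), "P")
  cid <- ehhCurve(hid, 1, core = "derived", side = "right", minEhh = 0)
  expect_true(all(cid$ehh == 1))

  # all-distinct haplotypes give EHH = 0
  hd <- HaplotypeMatrix(rbind(c(1, 1, 1), c(1, 0, 1), c(1, 1, 0), c(1, 0, 0),
                              c(0, 0, 0), c(0, 1, 1)),
                        c(10L, 20L, 30L), "P")
  cd <- ehhCurve(hd, 1, core = "derived", side = "right", minEhh = 0)
  expect_equal(cd$ehh[3], 0)
})

test_that("EHH curves are non-increasing and iHH matches the hand trapezoid", {
  h <- ehhFixture()
  expect_equal(integratedEHH(h, 1, "derived", minEhh = 0), 125)
  # 100*(1+1/3)/2 + 100*(1/3+1/3)/2 + 100*(1/3+1/6)/2 = 125
  set.seed(31)
  for (rep in 1:10) {
    hr <- simulateCoalescentLocus(16, 10, regionLength = 20000)
    dm <- derivedCalls(hr)
    daf <- colSums(dm) / 16
    foc <- which(daf >= 0.3 & daf <= 0.7)[1]
    if (is.na(foc)) next
    for (s in c("left", "right")) {
      cv <- ehhCurve(hr, foc, "derived", side = s, minEhh = 0)
      if (!is.null(cv)) expect_true(all(diff(cv$ehh) <= 1e-12))
    }
  }
})

test_that("unstandardized iHS is 0 for mirror-image classes and negative for a homogeneous derived class", {
  # two allele classes with identical internal structure
  calls <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
  h <- HaplotypeMatrix(calls, c(50L, 100L, 150L), "P")
  expect_equal(ihsUnstandardized(h, 2), 0)

  # derived identical, ancestral all distinct -> iHH_D > iHH_A -> negative
  calls2 <- rbind(c(1, 1, 0, 1), c(1, 1, 0, 1), c(1, 1, 0, 1),
                  c(0, 0, 0, 0), c(0, 1, 0, 1), c(0, 0, 1, 1))
  h2 <- HaplotypeMatrix(calls2, c(10L, 60L, 110L, 160L), "P")
  expect_lt(ihsUnstandardized(h2, 2), 0)
})

test_that("iHS standardization centers each DAF bin of its own panel", {
  set.seed(32)
  raw <- rnorm(600, mean = rep(c(-0.5, 0.4, 0), 200), sd = 1)
  daf <- runif(600)
  z <- suppressWarnings(standardizeIhs(raw, daf, bins = 10))
  brk <- seq(0, 1, length.out = 11)
  cls <- findInterval(daf, brk, rightmost.closed = TRUE)
  for (k in unique(cls)) {
    expect_lt(abs(mean(z[cls == k])), 1e-9)
    expect_equal(sd(z[cls == k]), 1, tolerance = 1e-9)
  }
  # constant raw values standardize to 0
  zc <- suppressWarnings(standardizeIhs(rep(1.5, 50), runif(50), bins = 5))
  expect_true(all(zc == 0))
})

test_that("lnRsb is 0 for identical populations and centers on its panel median", {
  set.seed(33)
  h <- simulateCoalescentLocus(16, 10, regionLength = 20000)
  foc <- floor(nSite(h) / 2)
  expect_equal(lnRsbRaw(h, h, foc), 0)
  panel <- rnorm(100, 2, 1)
  z <- normalizeLnRsb(panel, panel)
  expect_equal(median(z), 0, tolerance = 1e-12)
})

test_that("DIND forms the iPiA/iPiD ratio with the cap and relabeling invariance", {
  set.seed(34)
  h <- simulateCoalescentLocus(24, 30, regionLength = 20000)
  dt <- dindTable(h, flankEach = 5)
  expect_gt(nrow(dt), 0)
  ok <- !dt$capped & !is.na(dt$dind)
  expect_equal(dt$dind[ok], dt$iPiA[ok] / dt$iPiD[ok])
  # the +20 cap rule
  expect_equal(dindApplyCap(c(7.3, 2.0, NA), c(FALSE, FALSE, TRUE)),
               c(7.3, 2.0, 27.3))
  # equal diversity in both classes gives 1
  calls <- rbind(c(1, 1, 0, 1, 0), c(1, 0, 1, 0, 1),
                 c(0, 1, 0, 1, 0), c(0, 0, 1, 0, 1))
  hq <- HaplotypeMatrix(calls, c(10L, 20L, 30L, 40L, 50L), "P")
  r <- dindStatistic(hq, 3, flankEach = 2)
  expect_equal(r$dind, 1)
  # relabeling haplotypes within classes leaves DIND unchanged
  m <- haploCalls(h)
  perm <- sample(nrow(m))
  hp <- HaplotypeMatrix(m[perm, ], sitePositions(h), "P",
                        regionStart = h@regionStart, regionEnd = h@regionEnd)
  j <- which(!is.na(dt$dind))[1]
  jIdx <- which(sitePositions(h) == dt$pos[j])
  r1 <- dindStatistic(h, jIdx, flankEach = 5)
  r2 <- dindStatistic(hp, jIdx, flankEach = 5)
  expect_equal(r1$dind, r2$dind)
})

test_that("DIND requires the full flank complement on each side", {
  set.seed(35)
  h <- simulateCoalescentLocus(12, 10, regionLength = 10000)
  expect_null(dindStatistic(h, 1, flankEach = 5))            # no left flank
  expect_null(dindStatistic(h, nSite(h), flankEach = 5))     # no right flank
})
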
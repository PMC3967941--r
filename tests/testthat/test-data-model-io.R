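test_that("VCF write/read round trip preserves calls, positions, pops and ancestry", {
  set.seed(101)
  h <- simulateCoalescentLocus(12, 6, regionLength = 5000)
  # flip some ancestral states to exercise the AA tag
  h@ancestral[1] <- "alt"
  h@calls[, 1] <- 1L - h@calls[, 1]
  f <- tempfile(fileext = ".vcf")
  writeHaplotypeVCF(h, f)
  region <- regionSpec(regionId(h), "chr1", 1, 5000)
  back <- readHaplotypes(f, region, popMapForVCF(h))
  expect_identical(unname(haploCalls(back)), unname(haploCalls(h)))
  expect_identical(sitePositions(back), sitePositions(h))
  expect_identical(popLabels(back), popLabels(h))
  expect_identical(ancestralState(back), ancestralState(h))
})

test_that("multiallelic, indel and unphased sites are skipped; missing kept", {
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSA\tSB",
           "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
           "chr1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT\t0|1\t0|2",   # multiallelic
           "chr1\t300\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0|0",     # unphased
           "chr1\t400\t.\tAT\tA\t.\tPASS\t.\tGT\t0|0\t0|1",    # indel
           "chr1\t500\t.\tC\tT\t.\tPASS\t.\tGT\t.\t0|1",       # missing ok
           "chr1\t600\t.\tG\tC\t.\tPASS\t.\tGT\t1|0\t0|0")
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  region <- regionSpec("r", "chr1", 1, 1000)
  pops <- data.frame(sample = c("SA", "SB"), pop = c("CEU", "CEU"))
  expect_message(h <- readHaplotypes(f, region, pops), "3 site")
  expect_equal(nSite(h), 3L)
  expect_equal(nHap(h), 4L)
  expect_identical(sitePositions(h), c(100L, 500L, 600L))
  expect_true(all(is.na(haploCalls(h)[1:2, 2])))   # SA missing at 500
  expect_error(readHaplotypes(f, region,
                              data.frame(sample = "SX", pop = "CEU")),
               "no samples")
})

test_that("outgroup parsimony resolves majority and leaves ties unresolved", {
  expect_identical(polarizeAncestral("A", "G", "A", "A", "G"), "ref")
  expect_identical(polarizeAncestral("A", "G", "G", "A", NA), "unresolved")
  expect_identical(polarizeAncestral("A", "G", "C", NA, NA), "unresolved")
  expect_identical(polarizeAncestral("A", "G", "G", NA, NA), "alt")
  expect_identical(polarizeAncestral("A", "G", "A", "G", "G"), "alt")
  # vectorized
  expect_identical(polarizeAncestral(c("A", "A"), c("G", "G"),
                                     c("A", "C"), c("A", NA), c("G", NA)),
                   c("ref", "unresolved"))
})

test_that("accessibility fraction and the 80% keep/drop rule", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000"), bed)
  mask <- readAccessibilityMask(bed)
  r <- regionSpec("g", "chr1", 1, 1000)
  a <- accessibilityFraction(r, mask)
  expect_equal(a$fraction, 1.0)
  expect_true(a$keep)

  writeLines(c("chr1\t0\t799"), bed)      # 1..799 accessible
  a2 <- accessibilityFraction(r, readAccessibilityMask(bed))
  expect_equal(a2$fraction, 0.799)
  expect_false(a2$keep)

  writeLines(c("chr1\t0\t800"), bed)
  a3 <- accessibilityFraction(r, readAccessibilityMask(bed))
  expect_equal(a3$fraction, 0.800)
  expect_true(a3$keep)

  # chromosome absent from mask
  r2 <- regionSpec("g2", "chr9", 1, 1000)
  a4 <- accessibilityFraction(r2, readAccessibilityMask(bed))
  expect_equal(a4$fraction, 0)
  expect_false(a4$keep)
})

test_that("sfsCounts matches hand enumeration on the ladder fixture", {
  cc <- sfsCounts(makeT4(), L = 100)
  expect_equal(cc@S, 3L)
  expect_equal(cc@xi, c(1, 1, 1))
  expect_equal(cc@dSum, 10)
  expect_equal(cc@etaS, 2L)

  mono <- HaplotypeMatrix(matrix(0L, 4, 3), c(10, 20, 30), "P")
  cm <- sfsCounts(mono)
  expect_equal(cm@S, 0L)
  expect_true(all(cm@xi == 0))
})

test_that("SFS counts are invariant to haplotype relabeling and respect missing-data rules", {
  set.seed(7)
  for (rep in 1:20) {
    m <- randomHapMatrix(10, 15)
    h <- HaplotypeMatrix(m, seq_len(15) * 7, "P")
    hp <- HaplotypeMatrix(m[sample(10), ], seq_len(15) * 7, "P")
    c1 <- sfsCounts(h); c2 <- sfsCounts(hp)
    expect_equal(c1@dSum, c2@dSum)
    expect_equal(c1@xi, c2@xi)
    expect_equal(c1@dSum, oraclePairwiseSum(m))
    expect_true(sum(c1@xi) <= c1@S)
  }
  # a site with a missing call is excluded from all counts
  m <- randomHapMatrix(6, 8)
  m2 <- m; m2[1, 3] <- NA_integer_
  h2 <- HaplotypeMatrix(m2, seq_len(8) * 5, "P")
  cc <- sfsCounts(h2)
  expect_equal(cc@nExcluded, 1L)
  expect_equal(cc@dSum, oraclePairwiseSum(m[, -3, drop = FALSE]))
})

test_that("site table reports reduced-n frequencies and MAF <= 0.5", {
  m <- rbind(c(1L, 0L), c(1L, NA), c(0L, 1L), c(0L, 1L))
  h <- HaplotypeMatrix(m, c(5L, 9L), c("A", "A", "A", "A"))
  st <- siteTable(h)
  expect_equal(st$DAF_A, c(0.5, 2 / 3))
  expect_true(all(st$MAF_A <= 0.5))
})
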
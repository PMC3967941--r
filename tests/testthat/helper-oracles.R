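# Independent oracles and small fixtures, coded separately from the package
# implementation paths they check.

# the four-haplotype ladder fixture: 10 sites, 3 segregating
makeT4 <- function() {
  calls <- matrix(0L, nrow = 4, ncol = 10)
  calls[2, 1] <- 1L
  calls[3, 1:2] <- 1L
  calls[4, 1:3] <- 1L
  HaplotypeMatrix(calls, positions = seq(10, 100, by = 10),
                  popLabels = "POP", regionStart = 1L, regionEnd = 100L)
}

# brute-force pairwise-difference sum by explicit pair enumeration
oraclePairwiseSum <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot
}

# random biallelic haplotype matrix (no missing calls)
randomHapMatrix <- function(n = 8, L = 12) {
  repeat {
    m <- matrix(rbinom(n * L, 1, runif(1, 0.2, 0.8)), nrow = n)
    if (any(colSums(m) > 0 & colSums(m) < n)) break
  }
  storage.mode(m) <- "integer"
  m
}

# exhaustive permutation p-value for a 2-cohort genotype table by direct
# enumeration of all case-label assignments
oracleExhaustivePermP <- function(caseCounts, ctrlCounts,
                                  model = "genotypic") {
  geno <- rep.int(1:3, caseCounts + ctrlCounts)
  nCase <- sum(caseCounts)
  collapse <- function(v) if (model == "recessive") c(v[1], v[2] + v[3]) else v
  stat <- function(tc, tn) {
    tab <- rbind(collapse(tc), collapse(tn))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  obs <- stat(caseCounts, ctrlCounts)
  combos <- utils::combn(length(geno), nCase)
  stats <- apply(combos, 2, function(ix) {
    stat(tabulate(geno[ix], 3L), tabulate(geno[-ix], 3L))
  })
  mean(stats >= obs - 1e-9)
}

# Monte-Carlo shuffling oracle for the exact HWE test: distribute 2n
# alleles into n random diploids and tabulate the heterozygote count
oracleHweShuffleP <- function(rareHom, het, commonHom, nShuffle = 40000) {
  n <- rareHom + het + commonHom
  rare <- 2 * rareHom + het
  alleles <- c(rep(1L, rare), rep(0L, 2 * n - rare))
  hets <- replicate(nShuffle, {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  })
  tb <- table(hets) / nShuffle
  pObs <- tb[as.character(het)]
  sum(tb[tb <= pObs + 1e-9])
}
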
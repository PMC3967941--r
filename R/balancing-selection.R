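#' @include sfs-statistics.R
NULL

# log-likelihood of the HKA model with theta profiled out.
# Given T and per-locus k, the ML theta_i has the closed form
# (S_i + D_i) / (k_i a_i + T + 1) because both counts are Poisson in theta.
hkaProfileLnL <- function(S, D, an, k, T) {
  theta <- (S + D) / (k * an + T + 1)
  muS <- k * theta * an
  muD <- theta * (T + 1)
  sum(stats::dpois(S, muS, log = TRUE) + stats::dpois(D, muD, log = TRUE))
}

#' Maximum-likelihood HKA test
#'
#' Fits polymorphism/divergence counts across loci under
#' S_i ~ Poisson(k_i theta_i a_{n_i}) and D_i ~ Poisson(theta_i (T + 1)),
#' with k fixed at 1 for reference loci and free at test loci. Direct
#' numerical maximum likelihood (theta profiled out in closed form, T and k
#' optimized on the log scale); the likelihood-ratio statistic is compared
#' to a chi-square with one degree of freedom per free k. k > 1 indicates
#' an excess of polymorphism over divergence (balancing selection).
#'
#' @param loci data.frame with columns \code{locus}, \code{S}, \code{D},
#'   \code{n}, \code{L}, \code{isTest}.
#' @return An \linkS4class{HKAResult}.
#' @export
mlhkaFitAndTest <- function(loci) {
  stopifnot(all(c("S", "D", "n", "isTest") %in% names(loci)))
  if (sum(!loci$isTest) < 2) stop("need >= 2 reference loci")
  if (all(loci$D == 0)) stop("all D are 0: divergence time unidentifiable")
  if (any(loci$n < 2)) stop("all sample sizes must be >= 2")
  S <- loci$S; D <- loci$D
  an <- vapply(loci$n, harmonicA, numeric(1))
  testIdx <- which(loci$isTest)
  nTest <- length(testIdx)

  nullObj <- function(logT) -hkaProfileLnL(S, D, an, rep(1, length(S)),
                                           exp(logT))
  on <- stats::optimize(nullObj, c(-12, 12))
  lnL0 <- -on$objective
  T0 <- exp(on$minimum)

  if (nTest == 0) {
    return(new("HKAResult", theta = (S + D) / (an + T0 + 1), T = T0,
               k = numeric(0), lnLNull = lnL0, lnLAlt = lnL0,
               LRT = 0, df = 0, p = 1))
  }
  altObj <- function(par) {
    k <- rep(1, length(S)); k[testIdx] <- exp(par[-1])
    -hkaProfileLnL(S, D, an, k, exp(par[1]))
  }
  # start at the null T with k seeded from the marginal S/D contrast
  kSeed <- pmax((S[testIdx] / pmax(D[testIdx], 0.5)) /
                  stats::median(S[!loci$isTest] / pmax(D[!loci$isTest], 0.5)),
                0.05)
  oa <- stats::optim(c(log(T0), log(kSeed)), altObj, method = "BFGS",
                     control = list(maxit = 500))
  lnL1 <- -oa$value
  if (lnL1 < lnL0) {     # nesting guard: the null is a feasible alt point
    oa2 <- stats::optim(c(log(T0), rep(0, nTest)), altObj, method = "BFGS",
                        control = list(maxit = 500))
    if (-oa2$value > lnL1) { oa <- oa2; lnL1 <- -oa2$value }
    lnL1 <- max(lnL1, lnL0)
  }
  Th <- exp(oa$par[1])
  kh <- exp(oa$par[-1])
  kAll <- rep(1, length(S)); kAll[testIdx] <- kh
  LRT <- max(0, 2 * (lnL1 - lnL0))
  new("HKAResult", theta = (S + D) / (kAll * an + Th + 1), T = Th,
      k = kh, lnLNull = lnL0, lnLAlt = lnL1, LRT = LRT,
      df = nTest, p = stats::pchisq(LRT, df = nTest, lower.tail = FALSE))
}

#' Coalescent-simulation p-value for a neutrality statistic
#'
#' Simulates \code{iterations} independent loci under a neutral coalescent
#' (optionally with a demography) at fixed theta, computes the chosen
#' statistic on each, and returns the conservative Monte-Carlo p-value
#' p = (1 + #{simulated >= observed}) / (iterations + 1) for the upper
#' tail (mirrored for the lower tail).
#'
#' @param observed observed statistic value.
#' @param stat one of "D", "Dstar", "Fstar", "H", "pi", "thetaW", "S".
#' @param n haplotype sample size.
#' @param theta scaled mutation rate of the locus.
#' @param demography optional \code{\link{demographyConfig}}.
#' @param iterations number of simulations (default 10000).
#' @param tail "upper" or "lower".
#' @return numeric(1) p-value.
#' @export
coalescentPvalue <- function(observed, stat = c("D", "Dstar", "Fstar", "H",
                                                "pi", "thetaW", "S"),
                             n, theta, demography = NULL,
                             iterations = 10000,
                             tail = c("upper", "lower")) {
  stat <- match.arg(stat); tail <- match.arg(tail)
  sims <- vapply(seq_len(iterations), function(i) {
    h <- simulateCoalescentLocus(n, theta, demography)
    cc <- sfsCounts(h)
    switch(stat,
           D = tajimasD(cc),
           Dstar = unname(fuLiStar(cc)["Dstar"]),
           Fstar = unname(fuLiStar(cc)["Fstar"]),
           H = fayWuHNorm(cc),
           pi = nucleotideDiversityPi(cc),
           thetaW = wattersonTheta(cc),
           S = as.numeric(cc@S))
  }, numeric(1))
  if (mean(is.na(sims)) > 0.5)
    stop("statistic undefined in more than half of the simulations")
  sims <- sims[!is.na(sims)]
  if (tail == "upper") (1 + sum(sims >= observed)) / (length(sims) + 1)
  else                 (1 + sum(sims <= observed)) / (length(sims) + 1)
}

#' Calibrate a per-region mutation rate from outgroup divergence
#'
#' mu per year = fixed differences / (2 x divergence time); the factor 2
#' counts the two lineages separating the species. The per-generation rate
#' multiplies by the generation time (default 25 years; human-chimpanzee
#' divergence default 6 My).
#'
#' @param fixedDifferences count of fixed differences to the outgroup over
#'   the region.
#' @param divergenceYears species divergence time in years.
#' @param generationYears generation time in years.
#' @return list(muYear, muGeneration).
#' @export
calibrateMutationRate <- function(fixedDifferences,
                                  divergenceYears = 6e6,
                                  generationYears = 25) {
  stopifnot(fixedDifferences >= 0)
  muYear <- fixedDifferences / (2 * divergenceYears)
  list(muYear = muYear, muGeneration = muYear * generationYears)
}

#' TMRCA from mean pairwise divergence to the MRCA
#'
#' Estimates the time to the most recent common ancestor as the average
#' number of differences between each sampled chromosome and the MRCA
#' sequence, divided by the per-region per-year mutation rate. The MRCA
#' defaults to the ancestral allele at every segregating site. The SD is a
#' site-bootstrap (resampling segregating sites with replacement).
#'
#' @param hap a HaplotypeMatrix (fully polarized sites are used).
#' @param muYear mutation rate per region per year (> 0).
#' @param mrca optional 0/1 vector (derived coding) of the MRCA at each
#'   site; default all-ancestral.
#' @param nBoot bootstrap resamples for the SD (default 1000).
#' @return list(meanDivergence, tmrcaYears, sdYears, method).
#' @export
tmrcaPairwise <- function(hap, muYear, mrca = NULL, nBoot = 1000) {
  if (muYear <= 0) stop("muYear must be > 0")
  m <- derivedCalls(hap)
  keep <- colSums(is.na(m)) == 0
  m <- m[, keep, drop = FALSE]
  if (is.null(mrca)) mrca <- rep(0L, ncol(m))
  stopifnot(length(mrca) == ncol(m))
  diffs <- abs(sweep(m, 2, mrca))
  d <- rowSums(diffs)
  meanD <- mean(d)
  tm <- meanD / muYear
  sdY <- NA_real_
  if (ncol(m) > 0 && nBoot > 0) {
    bs <- vapply(seq_len(nBoot), function(b) {
      j <- sample.int(ncol(m), replace = TRUE)
      mean(rowSums(diffs[, j, drop = FALSE])) / muYear
    }, numeric(1))
    sdY <- stats::sd(bs)
  }
  list(meanDivergence = meanD, tmrcaYears = tm, sdYears = sdY,
       method = "mean pairwise distance to MRCA; SD by site bootstrap")
}
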
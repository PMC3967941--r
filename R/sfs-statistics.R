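#' @include io.R
NULL

#' Watterson's theta
#'
#' theta_W = S / a_n with a_n = sum_{i=1}^{n-1} 1/i; the segregating-sites
#' estimator of the population mutation rate.
#'
#' @param c an \linkS4class{SFSCounts}.
#' @param perSite divide by the accessible length L?
#' @return numeric(1).
#' @export
wattersonTheta <- function(c, perSite = FALSE) {
  th <- c@S / harmonicA(c@n)
  if (perSite) th / c@L else th
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences between sampled chromosomes:
#' pi = (pairwise-difference sum) / choose(n, 2).
#'
#' @inheritParams wattersonTheta
#' @return numeric(1).
#' @export
nucleotideDiversityPi <- function(c, perSite = FALSE) {
  pi <- c@dSum / choose(c@n, 2)
  if (perSite) pi / c@L else pi
}

# Tajima (1989) variance constants for sample size n
tajimaConstants <- function(n) {
  a1 <- harmonicA(n); a2 <- harmonicB(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' D = (pi - theta_W) / sqrt(e1 S + e2 S (S - 1)). Negative values indicate
#' an excess of rare variants (sweep-like spectra), positive values an
#' excess of intermediate-frequency variants (balancing-like spectra).
#' Undefined (NA) when S = 0 so that monomorphic windows never contribute a
#' spurious zero to empirical nulls.
#'
#' @param c an \linkS4class{SFSCounts}.
#' @return numeric(1), NA if S = 0.
#' @export
tajimasD <- function(c) {
  S <- c@S
  if (S == 0) return(NA_real_)
  k <- tajimaConstants(c@n)
  num <- nucleotideDiversityPi(c) - wattersonTheta(c)
  num / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# Fu & Li (1993) starred-test constants with the Simonsen, Churchill &
# Aquadro (1995) corrections (the constants used by DnaSP / libsequence).
fuLiConstants <- function(n) {
  a  <- harmonicA(n); b <- harmonicB(n)
  a1 <- a + 1 / n                       # a_{n+1}
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * a1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           (2 * (n - 1) * a) / n^2 - 8 * b / n) / (a^2 + b)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * a1) /
           (3 * n * (n - 1))) / a - vF
  list(a = a, b = b, uD = uD, vD = vD, uF = uF, vF = vF)
}

#' Fu and Li's D* and F*
#'
#' Singleton-based neutrality tests that need no outgroup: D* contrasts the
#' number of segregating sites with the singleton count, F* contrasts pi
#' with the singleton count. Singletons are minor-allele-count-1 sites.
#'
#' @param c an \linkS4class{SFSCounts}.
#' @return named numeric vector \code{c(Dstar=, Fstar=)}, NA if S = 0.
#' @export
fuLiStar <- function(c) {
  n <- c@n; S <- c@S; eta <- c@etaS
  if (S == 0) return(c(Dstar = NA_real_, Fstar = NA_real_))
  k <- fuLiConstants(n)
  dNum <- (n / (n - 1)) * S - k$a * eta
  dDen <- sqrt(k$uD * S + k$vD * S^2)
  fNum <- nucleotideDiversityPi(c) - ((n - 1) / n) * eta
  fDen <- sqrt(k$uF * S + k$vF * S^2)
  c(Dstar = dNum / dDen, Fstar = fNum / fDen)
}

#' Normalized Fay and Wu's H
#'
#' Contrasts pi with theta_L = (1/(n-1)) sum i xi_i, normalized by the Zeng
#' et al. (2006) variance with theta estimated by Watterson's theta and
#' theta^2 by S(S-1)/(a_n^2 + b_n). Only ancestrally resolved sites enter:
#' pi, theta_L and the S in the variance are all computed from the unfolded
#' spectrum \code{xi}. Strongly negative H marks an excess of
#' high-frequency derived alleles, the hallmark of a (near-)complete sweep.
#'
#' @param c an \linkS4class{SFSCounts}.
#' @return numeric(1), NA when no resolved segregating sites exist.
#' @export
fayWuHNorm <- function(c) {
  n <- c@n
  xi <- c@xi
  Sres <- sum(xi)
  if (Sres == 0) return(NA_real_)
  i <- seq_len(n - 1L)
  piRes <- sum(2 * i * (n - i) * xi) / (n * (n - 1))
  thetaL <- sum(i * xi) / (n - 1)
  a <- harmonicA(n); b <- harmonicB(n)
  bn1 <- b + 1 / n^2                       # b_{n+1}
  th <- Sres / a
  th2 <- Sres * (Sres - 1) / (a^2 + b)
  v <- th * (n - 2) / (6 * (n - 1)) +
    th2 * (18 * n^2 * (3 * n + 2) * bn1 -
             (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  (piRes - thetaL) / sqrt(v)
}

#' Whole-region statistic table
#'
#' Convenience wrapper computing all SFS statistics of a region for one or
#' more populations, in the layout of the package's TSV outputs.
#'
#' @param hap a HaplotypeMatrix.
#' @param pops populations to summarize (default: all present).
#' @param L accessible length for per-site scaling (default region span).
#' @return data.frame: region_id, pop, n, S, thetaW_site, pi_site, TajD,
#'   FuLiDstar, FuLiFstar, FayWuHnorm.
#' @export
regionStatistics <- function(hap, pops = unique(popLabels(hap)), L = NULL) {
  do.call(rbind, lapply(pops, function(p) {
    cc <- sfsCounts(hap, p, L = L)
    fl <- fuLiStar(cc)
    data.frame(region_id = regionId(hap), pop = p, n = cc@n, S = cc@S,
               thetaW_site = wattersonTheta(cc, perSite = TRUE),
               pi_site = nucleotideDiversityPi(cc, perSite = TRUE),
               thetaW = wattersonTheta(cc),
               pi = nucleotideDiversityPi(cc),
               TajD = tajimasD(cc),
               FuLiDstar = unname(fl["Dstar"]),
               FuLiFstar = unname(fl["Fstar"]),
               FayWuHnorm = fayWuHNorm(cc))
  }))
}

#' Sliding-window neutrality statistic
#'
#' Tiles fixed-span windows from the region start (trailing partial windows
#' dropped) and computes one statistic per window on the sites it contains.
#' Windows with no segregating sites yield NA. When an
#' \linkS4class{EmpiricalNull} is supplied each window is flagged if its
#' value falls below the null's 5th percentile — the presentation used for
#' sweep valleys in sliding-window plots.
#'
#' @param hap a HaplotypeMatrix.
#' @param stat one of "H", "D", "pi", "thetaW".
#' @param span window span in bp (default 5000).
#' @param step window step in bp (default 500).
#' @param pop population (default: all haplotypes).
#' @param null optional \linkS4class{EmpiricalNull} for the 5th-percentile
#'   flag.
#' @return data.frame: start, end, stat, value, below5th.
#' @export
slidingWindowStat <- function(hap, stat = c("H", "D", "pi", "thetaW"),
                              span = 5000, step = 500, pop = NULL,
                              null = NULL) {
  stat <- match.arg(stat)
  stopifnot(span >= step)
  starts <- seq(hap@regionStart, hap@regionEnd - span + 1, by = step)
  pos <- sitePositions(hap)
  res <- lapply(starts, function(s) {
    j <- which(pos >= s & pos <= s + span - 1)
    val <- NA_real_
    if (length(j) > 0) {
      w <- hap[, j]
      w@regionStart <- as.integer(s); w@regionEnd <- as.integer(s + span - 1)
      cc <- try(sfsCounts(w, pop, L = span), silent = TRUE)
      if (!inherits(cc, "try-error") && cc@S > 0)
        val <- switch(stat,
                      H = fayWuHNorm(cc),
                      D = tajimasD(cc),
                      pi = nucleotideDiversityPi(cc, perSite = TRUE),
                      thetaW = wattersonTheta(cc, perSite = TRUE))
    }
    val
  })
  out <- data.frame(start = starts, end = starts + span - 1,
                    stat = stat, value = unlist(res))
  out$below5th <- NA
  if (!is.null(null)) {
    p05 <- null@classTable$p05[1]
    out$below5th <- !is.na(out$value) & out$value < p05
  }
  out
}
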
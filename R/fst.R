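#' @include io.R
NULL

#' Hudson's per-SNP FST
#'
#' FST = 1 - Hw/Hb with Hw the mean within-population heterozygosity
#' (2p(1-p) with the n/(n-1) small-sample correction) and Hb =
#' p1(1-p2) + p2(1-p1) the between-population heterozygosity. Slightly
#' negative estimates are reported as-is so empirical percentiles stay
#' unbiased. Vectorized over sites.
#'
#' @param c1,c2 allele counts (either allele, used consistently) in each
#'   population.
#' @param n1,n2 haplotype sample sizes (>= 2).
#' @return numeric vector; NA where the pooled sample is monomorphic.
#' @export
fstHudson <- function(c1, n1, c2, n2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  p1 <- c1 / n1; p2 <- c2 / n2
  hw <- (2 * p1 * (1 - p1) * n1 / (n1 - 1) +
         2 * p2 * (1 - p2) * n2 / (n2 - 1)) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- 1 - hw / hb
  mono <- (c1 + c2 == 0) | (c1 + c2 == n1 + n2)
  fst[mono] <- NA_real_
  fst
}

#' Per-SNP FST table for a population pair
#'
#' @param hap a HaplotypeMatrix containing both populations.
#' @param pair character(2) of population codes, e.g. \code{c("CEU","YRI")}.
#' @return data.frame: chrom, pos, pair, p1, p2, MAF_pooled, FST (NA at
#'   pooled-monomorphic or incomplete sites).
#' @export
fstPerSnp <- function(hap, pair) {
  stopifnot(length(pair) == 2)
  m <- haploCalls(hap)
  r1 <- popLabels(hap) == pair[1]
  r2 <- popLabels(hap) == pair[2]
  if (sum(r1) < 2 || sum(r2) < 2) stop("need >= 2 haplotypes per population")
  ok1 <- colSums(is.na(m[r1, , drop = FALSE])) == 0
  ok2 <- colSums(is.na(m[r2, , drop = FALSE])) == 0
  c1 <- colSums(m[r1, , drop = FALSE])
  c2 <- colSums(m[r2, , drop = FALSE])
  n1 <- sum(r1); n2 <- sum(r2)
  fst <- fstHudson(c1, n1, c2, n2)
  fst[!(ok1 & ok2)] <- NA_real_
  pPool <- (c1 + c2) / (n1 + n2)
  data.frame(chrom = hap@chrom, pos = sitePositions(hap),
             pair = paste(pair, collapse = "/"),
             p1 = c1 / n1, p2 = c2 / n2,
             MAF_pooled = pmin(pPool, 1 - pPool), FST = fst)
}
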
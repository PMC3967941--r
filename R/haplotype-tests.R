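#' @include io.R
NULL

# Complete-site submatrix for one population: sites with any missing call
# in the population are excluded from haplotype-homozygosity computations.
completeSites <- function(hap, pop = NULL) {
  x <- if (is.null(pop)) hap else subsetPop(hap, pop)
  m <- derivedCalls(x)            # NA columns where ancestry unresolved
  raw <- haploCalls(x)
  keepRaw <- colSums(is.na(raw)) == 0
  list(hap = x, raw = raw, der = m, pos = sitePositions(x),
       complete = keepRaw, anc = ancestralState(x))
}

# one-sided EHH refinement walk over site indices `sites` (in walk order)
ehhWalk <- function(mat, rows, sites, positions, focalPos,
                    maxExtent, minEhh, normPairs) {
  k <- length(rows)
  g <- rep(1L, k)
  off <- 0
  offs <- 0
  vals <- 1
  trunc <- "extent_exhausted"
  for (j in sites) {
    d <- abs(positions[j] - focalPos)
    if (d > maxExtent) { trunc <- "max_extent"; break }
    g <- match(paste(g, mat[rows, j]), unique(paste(g, mat[rows, j])))
    tb <- tabulate(g)
    e <- sum(choose(tb, 2)) / normPairs
    offs <- c(offs, d)
    vals <- c(vals, e)
    if (e < minEhh) { trunc <- "ehh_floor"; break }
  }
  list(offset = offs, ehh = vals, truncation = trunc)
}

#' Extended haplotype homozygosity curve
#'
#' EHH around a focal SNP for one allele class, computed one side at a
#' time: at each successive site the core haplotypes are partitioned by
#' their extended haplotype and EHH = sum_h C(k_h,2) / C(k_core,2). The
#' walk stops beyond \code{maxExtent} bp (default 100 kb per side) or once
#' EHH drops below \code{minEhh} (default 0.05; the crossing point is kept
#' so the integral is conservative).
#'
#' @param hap a HaplotypeMatrix.
#' @param focal focal site index (into \code{sitePositions(hap)}).
#' @param core "derived", "ancestral" (needs polarization) or "pooled"
#'   (site-EHH, EHHS: all haplotypes grouped from the focal allele onward
#'   and normalized by focal-site homozygosity).
#' @param side "left" or "right".
#' @param pop population (default all haplotypes).
#' @param maxExtent maximum extent in bp per side.
#' @param minEhh truncation floor.
#' @return data.frame with \code{offset} (bp, >= 0) and \code{ehh};
#'   attribute \code{truncation} records why the walk stopped. NA (NULL)
#'   when fewer than 2 core haplotypes exist.
#' @export
ehhCurve <- function(hap, focal, core = c("derived", "ancestral", "pooled"),
                     side = c("right", "left"), pop = NULL,
                     maxExtent = 1e5, minEhh = 0.05) {
  core <- match.arg(core); side <- match.arg(side)
  cs <- completeSites(hap, pop)
  if (!cs$complete[focal]) return(NULL)
  usable <- which(cs$complete)
  sites <- if (side == "right") usable[usable > focal]
           else rev(usable[usable < focal])
  if (core == "pooled") {
    rows <- seq_len(nrow(cs$raw))
    k <- length(rows)
    g0 <- cs$raw[, focal] + 1L
    h0 <- sum(choose(tabulate(g0), 2)) / choose(k, 2)
    if (h0 == 0) return(NULL)
    # walk with groups seeded by the focal allele; normalize by h0
    g <- g0
    offs <- 0; vals <- 1; trunc <- "extent_exhausted"
    for (j in sites) {
      d <- abs(cs$pos[j] - cs$pos[focal])
      if (d > maxExtent) { trunc <- "max_extent"; break }
      g <- match(paste(g, cs$raw[rows, j]),
                 unique(paste(g, cs$raw[rows, j])))
      e <- sum(choose(tabulate(g), 2)) / choose(k, 2) / h0
      offs <- c(offs, d); vals <- c(vals, e)
      if (e < minEhh) { trunc <- "ehh_floor"; break }
    }
    out <- data.frame(offset = offs, ehh = vals)
    attr(out, "truncation") <- trunc
    return(out)
  }
  der <- cs$der
  if (any(is.na(der[, focal]))) return(NULL)   # unresolved focal
  want <- if (core == "derived") 1L else 0L
  rows <- which(der[, focal] == want)
  if (length(rows) < 2) return(NULL)
  w <- ehhWalk(cs$raw, rows, sites, cs$pos, cs$pos[focal],
               maxExtent, minEhh, choose(length(rows), 2))
  out <- data.frame(offset = w$offset, ehh = w$ehh)
  attr(out, "truncation") <- w$truncation
  out
}

# trapezoidal integral of an EHH curve over physical distance
trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Integrated EHH for one allele class (both sides)
#'
#' @inheritParams ehhCurve
#' @return numeric(1) iHH in bp-weighted EHH units; NA if the class has
#'   fewer than 2 haplotypes.
#' @export
integratedEHH <- function(hap, focal, core = "derived", pop = NULL,
                          maxExtent = 1e5, minEhh = 0.05) {
  tot <- 0
  for (s in c("left", "right")) {
    cv <- ehhCurve(hap, focal, core = core, side = s, pop = pop,
                   maxExtent = maxExtent, minEhh = minEhh)
    if (is.null(cv)) return(NA_real_)
    tot <- tot + trapezoid(cv$offset, cv$ehh)
  }
  tot
}

#' Unstandardized iHS
#'
#' ln(iHH_A / iHH_D): the log-ratio of integrated EHH around the ancestral
#' and derived alleles of a polarized SNP. Negative values mean the derived
#' haplotype carries unusually long homozygosity (an ongoing sweep).
#'
#' @inheritParams ehhCurve
#' @return numeric(1); NA when either class has < 2 carriers or zero iHH.
#' @export
ihsUnstandardized <- function(hap, focal, pop = NULL,
                              maxExtent = 1e5, minEhh = 0.05) {
  ia <- integratedEHH(hap, focal, "ancestral", pop, maxExtent, minEhh)
  id <- integratedEHH(hap, focal, "derived", pop, maxExtent, minEhh)
  if (is.na(ia) || is.na(id) || ia == 0 || id == 0) return(NA_real_)
  log(ia / id)
}

#' Standardize raw iHS within DAF bins
#'
#' Standardizes raw ln(iHH_A/iHH_D) values to mean 0, sd 1 within
#' derived-allele-frequency bins, using a calibration panel of raw values
#' (typically all SNPs in the flanks of randomly chosen genic SNPs).
#'
#' @param raw,daf query raw values and their DAFs.
#' @param panelRaw,panelDaf calibration panel raw values and DAFs
#'   (default: the query itself).
#' @param bins number of equal-width DAF bins on (0, 1) (default 50).
#' @param minPerBin occupancy below which a warning is emitted (default 50).
#' @return numeric vector of standardized iHS; NA where the query's bin is
#'   empty in the panel.
#' @export
standardizeIhs <- function(raw, daf, panelRaw = raw, panelDaf = daf,
                           bins = 50, minPerBin = 50) {
  brk <- seq(0, 1, length.out = bins + 1)
  cut2 <- function(x) pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE),
                                1L), bins)
  pb <- cut2(panelDaf); qb <- cut2(daf)
  ok <- !is.na(panelRaw)
  mu <- tapply(panelRaw[ok], pb[ok], mean)
  sd <- tapply(panelRaw[ok], pb[ok], stats::sd)
  cnt <- tapply(panelRaw[ok], pb[ok], length)
  if (any(cnt < minPerBin))
    warning("some occupied DAF bins have fewer than ", minPerBin,
            " calibration SNPs")
  m <- mu[as.character(qb)]; s <- sd[as.character(qb)]
  out <- (raw - m) / s
  out[is.na(m)] <- NA_real_
  # constant panel within a bin: raw == mean -> 0
  deg <- !is.na(m) & (is.na(s) | s == 0)
  out[deg] <- ifelse(abs(raw[deg] - m[deg]) < 1e-12, 0, NA_real_)
  unname(out)
}

#' Raw cross-population lnRsb
#'
#' ln(iES_pop1 / iES_pop2): the log-ratio of integrated site-EHH (EHHS,
#' pooled alleles) between two populations at one SNP. Positive values mean
#' population 1 has the longer haplotype homozygosity (a sweep at or near
#' fixation in population 1).
#'
#' @param hap1,hap2 HaplotypeMatrix objects for the two populations (may be
#'   the same object subset by \code{pop}).
#' @param focal1,focal2 focal site index in each matrix (same SNP).
#' @inheritParams ehhCurve
#' @return numeric(1); NA if either iES is 0 or undefined.
#' @export
lnRsbRaw <- function(hap1, hap2, focal1, focal2 = focal1,
                     maxExtent = 1e5, minEhh = 0.05) {
  ies <- function(h, f) {
    tot <- 0
    for (s in c("left", "right")) {
      cv <- ehhCurve(h, f, core = "pooled", side = s,
                     maxExtent = maxExtent, minEhh = minEhh)
      if (is.null(cv)) return(NA_real_)
      tot <- tot + trapezoid(cv$offset, cv$ehh)
    }
    tot
  }
  i1 <- ies(hap1, focal1); i2 <- ies(hap2, focal2)
  if (is.na(i1) || is.na(i2) || i1 == 0 || i2 == 0) return(NA_real_)
  log(i1 / i2)
}

#' Normalize lnRsb against a calibration panel
#'
#' (lnRsb' - median) / sd, with median and sd taken from a calibration set
#' of raw lnRsb values.
#' @param raw query raw lnRsb values.
#' @param panel calibration raw lnRsb values (default: the query).
#' @return numeric vector.
#' @export
normalizeLnRsb <- function(raw, panel = raw) {
  p <- panel[!is.na(panel)]
  (raw - stats::median(p)) / stats::sd(p)
}

#' DIND test at one SNP
#'
#' Derived intra-allelic nucleotide diversity: the ratio iPi_A / iPi_D of
#' mean pairwise differences among ancestral-allele and derived-allele
#' carriers, computed over a constant window of 40 flanking variants (20 on
#' each side of the focal SNP). A derived haplotype with no internal
#' diversity (iPi_D = 0) is returned with \code{capped = TRUE} and a
#' missing value; \code{\link{dindApplyCap}} later replaces capped values
#' by the panel-wide finite maximum plus 20. SNPs without 20 complete
#' flanking variants per side get no DIND at all (the constant-window
#' calibration is preserved, not diluted).
#'
#' @param hap a HaplotypeMatrix.
#' @param focal focal site index.
#' @param pop population (default all haplotypes).
#' @param flankEach number of flanking variants per side (default 20).
#' @return list(daf, iPiA, iPiD, dind, capped); NULL when the flank
#'   requirement fails; dind NA when a class has < 2 carriers.
#' @export
dindStatistic <- function(hap, focal, pop = NULL, flankEach = 20) {
  cs <- completeSites(hap, pop)
  if (!cs$complete[focal] || any(is.na(cs$der[, focal]))) return(NULL)
  usable <- which(cs$complete)
  left <- usable[usable < focal]
  right <- usable[usable > focal]
  if (length(left) < flankEach || length(right) < flankEach) return(NULL)
  flank <- c(utils::tail(left, flankEach), utils::head(right, flankEach))
  dfoc <- cs$der[, focal]
  n <- length(dfoc)
  daf <- mean(dfoc)
  meanPi <- function(rows) {
    k <- length(rows)
    if (k < 2) return(NA_real_)
    cc <- colSums(cs$raw[rows, flank, drop = FALSE])
    sum(cc * (k - cc)) / choose(k, 2)
  }
  iPiA <- meanPi(which(dfoc == 0))
  iPiD <- meanPi(which(dfoc == 1))
  if (is.na(iPiA) || is.na(iPiD))
    return(list(daf = daf, iPiA = iPiA, iPiD = iPiD,
                dind = NA_real_, capped = FALSE))
  if (iPiD == 0)
    return(list(daf = daf, iPiA = iPiA, iPiD = 0,
                dind = NA_real_, capped = TRUE))
  list(daf = daf, iPiA = iPiA, iPiD = iPiD,
       dind = iPiA / iPiD, capped = FALSE)
}

#' DIND over all eligible SNPs of a region
#'
#' @param hap a HaplotypeMatrix.
#' @param pop population code.
#' @param flankEach flanking variants per side (default 20).
#' @return data.frame: pos, daf, iPiA, iPiD, dind, capped (one row per SNP
#'   with the full flank complement; capped rows carry NA dind until
#'   \code{\link{dindApplyCap}}).
#' @export
dindTable <- function(hap, pop = NULL, flankEach = 20) {
  x <- if (is.null(pop)) hap else subsetPop(hap, pop)
  rows <- lapply(seq_len(nSite(x)), function(j) {
    r <- dindStatistic(x, j, flankEach = flankEach)
    if (is.null(r)) return(NULL)
    data.frame(pos = sitePositions(x)[j], daf = r$daf, iPiA = r$iPiA,
               iPiD = r$iPiD, dind = r$dind, capped = r$capped)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pos = integer(), daf = numeric(), iPiA = numeric(),
                      iPiD = numeric(), dind = numeric(), capped = logical())
  out
}

#' Replace capped DIND values by the dataset maximum plus 20
#'
#' Applies the convention for iPi_D = 0: such SNPs receive the maximum
#' finite DIND observed over the whole dataset plus 20, so they always rank
#' above every finite value.
#'
#' @param dind numeric DIND values (NA where capped).
#' @param capped logical flags from \code{\link{dindTable}}.
#' @return numeric vector with capped entries filled in.
#' @export
dindApplyCap <- function(dind, capped) {
  mx <- suppressWarnings(max(dind[!capped], na.rm = TRUE))
  if (!is.finite(mx)) mx <- 0
  dind[capped] <- mx + 20
  dind
}
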
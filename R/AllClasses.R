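#' @import methods
NULL

#' Phased haplotype matrix for one genomic region
#'
#' The central data container of the package: a matrix of phased biallelic
#' calls (rows = haploid chromosomes, columns = polymorphic sites) for one
#' genomic region, together with physical coordinates, REF/ALT alleles,
#' per-haplotype population labels, and a per-site ancestral-state
#' assignment obtained by outgroup parsimony.
#'
#' Calls are coded 0 = REF, 1 = ALT, \code{NA} = missing. The
#' \code{ancestral} slot holds one of \code{"ref"}, \code{"alt"},
#' \code{"unresolved"} per site; statistics that need a polarized (unfolded)
#' spectrum use only resolved sites.
#'
#' @slot regionId character(1) region identifier.
#' @slot chrom character(1) chromosome name.
#' @slot positions integer vector of 1-based physical positions, strictly
#'   increasing.
#' @slot ref,alt character vectors of reference / alternate alleles.
#' @slot calls integer matrix of 0/1/NA phased calls, one row per haploid
#'   chromosome.
#' @slot popLabels character vector, one population code per haplotype.
#' @slot ancestral character vector in \code{c("ref","alt","unresolved")}.
#' @slot regionStart,regionEnd 1-based inclusive region bounds.
#'
#' @export
setClass("HaplotypeMatrix",
  representation(
    regionId  = "character",
    chrom     = "character",
    positions = "integer",
    ref       = "character",
    alt       = "character",
    calls     = "matrix",
    popLabels = "character",
    ancestral = "character",
    regionStart = "integer",
    regionEnd   = "integer"
  )
)

setValidity("HaplotypeMatrix", function(object) {
  msg <- character()
  p <- object@positions
  if (length(p) && any(diff(p) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (nrow(object@calls) < 2)
    msg <- c(msg, "need at least 2 haplotypes")
  if (ncol(object@calls) != length(p))
    msg <- c(msg, "calls columns must match positions")
  if (length(object@popLabels) != nrow(object@calls))
    msg <- c(msg, "popLabels must have one entry per haplotype")
  if (length(object@popLabels) == 0L)
    msg <- c(msg, "popLabels must be non-empty")
  if (length(object@ref) != length(p) || length(object@alt) != length(p))
    msg <- c(msg, "ref/alt must have one entry per site")
  if (length(object@ancestral) != length(p))
    msg <- c(msg, "ancestral must have one entry per site")
  if (length(object@ancestral) &&
      !all(object@ancestral %in% c("ref", "alt", "unresolved")))
    msg <- c(msg, "ancestral states must be ref/alt/unresolved")
  bad <- object@calls[!is.na(object@calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    msg <- c(msg, "calls must be 0, 1 or NA (biallelic)")
  if (length(object@regionStart) == 1L && length(object@regionEnd) == 1L &&
      object@regionStart > object@regionEnd)
    msg <- c(msg, "regionStart must be <= regionEnd")
  if (length(p) && length(object@regionStart) == 1L &&
      (p[1] < object@regionStart || p[length(p)] > object@regionEnd))
    msg <- c(msg, "positions must lie within the region bounds")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeMatrix
#'
#' @param calls 0/1/NA matrix, rows = haploid chromosomes.
#' @param positions 1-based physical positions (strictly increasing).
#' @param popLabels population code per haplotype; recycled if length 1.
#' @param ancestral per-site ancestral state (\code{"ref"}, \code{"alt"} or
#'   \code{"unresolved"}); defaults to all \code{"ref"} (fully polarized to
#'   the reference, as produced by the simulators).
#' @param ref,alt allele strings per site.
#' @param regionId,chrom identifiers.
#' @return A \linkS4class{HaplotypeMatrix}.
#' @export
HaplotypeMatrix <- function(calls, positions, popLabels,
                            ancestral = NULL,
                            ref = NULL, alt = NULL,
                            regionId = "region", chrom = "chr1",
                            regionStart = NULL, regionEnd = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  L <- ncol(calls)
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("G", L)
  if (is.null(ancestral)) ancestral <- rep("ref", L)
  if (length(popLabels) == 1L) popLabels <- rep(popLabels, nrow(calls))
  positions <- as.integer(positions)
  if (is.null(regionStart))
    regionStart <- if (length(positions)) min(positions) else 1L
  if (is.null(regionEnd))
    regionEnd <- if (length(positions)) max(positions) else 1L
  new("HaplotypeMatrix",
      regionId = regionId, chrom = chrom,
      positions = positions,
      ref = as.character(ref), alt = as.character(alt),
      calls = calls, popLabels = as.character(popLabels),
      ancestral = as.character(ancestral),
      regionStart = as.integer(regionStart),
      regionEnd = as.integer(regionEnd))
}

#' Per-region site-frequency-spectrum summary
#'
#' Sufficient statistics for all SFS-based neutrality tests of one region in
#' one population: sample size, segregating-site count, the unfolded SFS
#' over ancestrally resolved sites, the (unpolarized) singleton count, the
#' sum of pairwise differences, and the accessible length used for per-site
#' scaling.
#'
#' @slot n haplotypes used.
#' @slot S segregating sites in the population (complete sites only).
#' @slot xi unfolded SFS: \code{xi[i]} = resolved segregating sites whose
#'   derived allele is carried by i chromosomes (i = 1..n-1).
#' @slot etaS singleton count (minor allele count 1, polarization-free).
#' @slot dSum sum of pairwise differences over all \code{choose(n,2)} pairs.
#' @slot L accessible length (bp) for per-site scaling.
#' @slot nExcluded sites dropped because of missing calls in the population.
#' @export
setClass("SFSCounts",
  representation(n = "integer", S = "integer", xi = "numeric",
                 etaS = "integer", dSum = "numeric", L = "numeric",
                 nExcluded = "integer"))

setValidity("SFSCounts", function(object) {
  msg <- character()
  if (object@n < 2) msg <- c(msg, "n must be >= 2")
  if (object@S < 0) msg <- c(msg, "S must be >= 0")
  if (length(object@xi) != object@n - 1L)
    msg <- c(msg, "xi must have length n-1")
  if (object@dSum < 0) msg <- c(msg, "dSum must be >= 0")
  if (object@L <= 0) msg <- c(msg, "L must be > 0")
  if (sum(object@xi) > object@S + 1e-9)
    msg <- c(msg, "sum(xi) cannot exceed S")
  if (length(msg)) msg else TRUE
})

#' Empirical null distribution from a control-locus panel
#'
#' Percentile tables (optionally binned on MAF or DAF) built from a panel of
#' putatively neutral control loci; the calibration object behind every
#' outlier call. Raw panel values are retained per class so percentile ranks
#' are exact counting fractions, not table lookups.
#'
#' @slot statistic statistic name.
#' @slot population population (or population pair) label.
#' @slot binVariable "none", "MAF" or "DAF".
#' @slot breaks class boundaries on the binning variable.
#' @slot classTable data.frame: class, n, p01/p05/p95/p99, reliable, defined.
#' @slot classValues list of raw panel values per class.
#' @slot panelId identifier of the source panel.
#' @export
setClass("EmpiricalNull",
  representation(statistic = "character", population = "character",
                 binVariable = "character", breaks = "numeric",
                 classTable = "data.frame", classValues = "list",
                 panelId = "character"))

setValidity("EmpiricalNull", function(object) {
  msg <- character()
  if (!object@binVariable %in% c("none", "MAF", "DAF"))
    msg <- c(msg, "binVariable must be none/MAF/DAF")
  ct <- object@classTable
  ok <- !is.na(ct$p05) & !is.na(ct$p95)
  if (any(ok) && any(ct$p05[ok] > ct$p95[ok]))
    msg <- c(msg, "percentiles must be monotone within a class")
  if (length(msg)) msg else TRUE
})

#' 2x3 case/control genotype counts
#'
#' Genotype counts for one cohort, ordered rare-homozygote / heterozygote /
#' common-homozygote (the convention of the association tables this package
#' consumes).
#'
#' @slot cohort cohort label.
#' @slot counts named integer vector (rareHom, het, commonHom).
#' @export
setClass("GenotypeCounts",
  representation(cohort = "character", counts = "integer"))

setValidity("GenotypeCounts", function(object) {
  msg <- character()
  if (length(object@counts) != 3L) msg <- c(msg, "need exactly 3 counts")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (sum(object@counts) <= 0) msg <- c(msg, "total must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct GenotypeCounts
#' @param rareHom,het,commonHom non-negative integer counts.
#' @param cohort cohort label.
#' @return A \linkS4class{GenotypeCounts}.
#' @export
GenotypeCounts <- function(rareHom, het, commonHom, cohort = "cohort") {
  new("GenotypeCounts", cohort = cohort,
      counts = c(rareHom = as.integer(rareHom), het = as.integer(het),
                 commonHom = as.integer(commonHom)))
}

#' Fitted Wittke-Thompson disequilibrium-penetrance model
#'
#' Maximum-likelihood fit of the penetrance model that explains
#' Hardy-Weinberg deviation in cases through a genetic model: susceptibility
#' allele frequency q, baseline risk alpha (risk in non-susceptible
#' homozygotes), heterozygote and homozygote relative risks beta and gamma,
#' with population prevalence Kp fixed.
#'
#' @slot model one of general/dominant/recessive/additive/multiplicative.
#' @slot q,alpha,beta,gamma,Kp parameters at the optimum.
#' @slot chisq minimized 6-cell goodness-of-fit statistic.
#' @slot df degrees of freedom (1 general, 2 constrained).
#' @slot p goodness-of-fit p-value.
#' @slot AIC chisq + 2 * number of free parameters.
#' @slot nFree number of free parameters.
#' @export
setClass("PenetranceModelFit",
  representation(model = "character", q = "numeric", alpha = "numeric",
                 beta = "numeric", gamma = "numeric", Kp = "numeric",
                 chisq = "numeric", df = "numeric", p = "numeric",
                 AIC = "numeric", nFree = "numeric"))

setValidity("PenetranceModelFit", function(object) {
  msg <- character()
  if (object@q <= 0 || object@q >= 1) msg <- c(msg, "q must be in (0,1)")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Maximum-likelihood HKA fit
#'
#' Joint fit of per-locus polymorphism (S) and divergence (D) counts under
#' the HKA model with selection parameters k at test loci: S_i ~
#' Poisson(k_i theta_i a_ni), D_i ~ Poisson(theta_i (T + 1)), k = 1 at
#' reference loci. k > 1 indicates an excess of polymorphism relative to
#' divergence (balancing selection).
#'
#' @slot theta per-locus theta estimates (alternative model).
#' @slot T shared divergence time (coalescent units).
#' @slot k selection-parameter estimates, one per test locus.
#' @slot lnLNull,lnLAlt log-likelihoods under k=1 and free k.
#' @slot LRT likelihood-ratio statistic 2*(lnLAlt - lnLNull).
#' @slot df number of free k parameters.
#' @slot p chi-square p-value.
#' @export
setClass("HKAResult",
  representation(theta = "numeric", T = "numeric", k = "numeric",
                 lnLNull = "numeric", lnLAlt = "numeric",
                 LRT = "numeric", df = "numeric", p = "numeric"))

setValidity("HKAResult", function(object) {
  msg <- character()
  if (any(object@k <= 0)) msg <- c(msg, "k must be positive")
  if (object@LRT < -1e-6) msg <- c(msg, "LRT must be non-negative")
  if (length(msg)) msg else TRUE
})
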
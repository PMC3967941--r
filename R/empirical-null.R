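#' @include AllClasses.R
NULL

#' Build an empirical null from a control-locus panel
#'
#' Percentile tables (1st/5th/95th/99th, linear interpolation) of a
#' statistic over a panel of control loci, optionally binned into
#' equal-width MAF classes on [0, 0.5] or DAF classes on [0, 1]. Classes
#' with fewer than 20 observations are flagged unreliable; empty classes
#' (and DIND classes dominated by capped values, see \code{capped}) are
#' undefined and never produce significance calls.
#'
#' @param values panel statistic values (NA dropped).
#' @param binValues optional MAF/DAF per value.
#' @param binVariable "none", "MAF" or "DAF".
#' @param nClasses number of classes (conventionally 50 for MAF, 100 for
#'   DAF).
#' @param capped optional logical: values that are cap substitutes (the
#'   iPi_D = 0 rule); a class whose 95th percentile falls among capped
#'   values (> 5\% capped) is marked undefined.
#' @param statistic,population,panelId labels stored with the null.
#' @param minReliable minimum class count to be deemed reliable.
#' @return An \linkS4class{EmpiricalNull}.
#' @export
buildEmpiricalNull <- function(values, binValues = NULL,
                               binVariable = c("none", "MAF", "DAF"),
                               nClasses = 1L, capped = NULL,
                               statistic = "stat", population = "pop",
                               panelId = "panel", minReliable = 20L) {
  binVariable <- match.arg(binVariable)
  if (binVariable == "none") {
    breaks <- c(-Inf, Inf); nClasses <- 1L
    cls <- rep(1L, length(values))
  } else {
    hi <- if (binVariable == "MAF") 0.5 else 1.0
    breaks <- seq(0, hi, length.out = nClasses + 1)
    cls <- pmin(pmax(findInterval(binValues, breaks,
                                  rightmost.closed = TRUE), 1L), nClasses)
  }
  if (is.null(capped)) capped <- rep(FALSE, length(values))
  ok <- !is.na(values)
  tab <- lapply(seq_len(nClasses), function(k) {
    v <- values[ok & cls == k]
    cp <- capped[ok & cls == k]
    nv <- length(v)
    if (nv == 0)
      return(data.frame(class = k, n = 0L, p01 = NA, p05 = NA, p95 = NA,
                        p99 = NA, reliable = FALSE, defined = FALSE))
    qs <- stats::quantile(v, c(0.01, 0.05, 0.95, 0.99), type = 7,
                          names = FALSE)
    defined <- mean(cp) <= 0.05     # 95th percentile not a cap substitute
    data.frame(class = k, n = nv, p01 = qs[1], p05 = qs[2], p95 = qs[3],
               p99 = qs[4], reliable = nv >= minReliable,
               defined = defined)
  })
  vals <- lapply(seq_len(nClasses), function(k) values[ok & cls == k])
  new("EmpiricalNull", statistic = statistic, population = population,
      binVariable = binVariable, breaks = breaks,
      classTable = do.call(rbind, tab), classValues = vals,
      panelId = panelId)
}

# class index of a query bin value (or 1 for unbinned nulls)
nullClassOf <- function(null, binValue = NULL) {
  if (null@binVariable == "none") return(1L)
  if (is.null(binValue)) stop("this null is binned; supply a bin value")
  n <- nrow(null@classTable)
  pmin(pmax(findInterval(binValue, null@breaks, rightmost.closed = TRUE),
            1L), n)
}

#' Percentile rank of a value within its null class
#'
#' Fraction of panel values less than or equal to the query, an exact
#' counting fraction over the stored panel values (not a table lookup).
#'
#' @param null an \linkS4class{EmpiricalNull}.
#' @param value query statistic value.
#' @param binValue MAF/DAF of the query for binned nulls.
#' @return rank in [0, 1]; NA for undefined classes or NA input.
#' @export
percentileRank <- function(null, value, binValue = NULL) {
  if (is.na(value)) return(NA_real_)
  k <- nullClassOf(null, binValue)
  if (!null@classTable$defined[k]) return(NA_real_)
  v <- null@classValues[[k]]
  mean(v <= value)
}

#' Default statistic-to-signature-family map
#'
#' Groups statistics by the selection signature they read, with the tail
#' that marks a sweep: low diversity, negative SFS statistics, high
#' differentiation, high DIND. Kept as data so alternative groupings are
#' testable.
#'
#' @return data.frame: statistic, family, tail ("low"/"high").
#' @export
statFamilies <- function() {
  data.frame(
    statistic = c("thetaW", "pi", "TajD", "FuLiDstar", "FuLiFstar",
                  "FayWuHnorm", "FST", "DIND", "iHS", "lnRsb"),
    family = c("diversity", "diversity", "SFS", "SFS", "SFS", "SFS",
               "differentiation", "haplotype", "haplotype", "haplotype"),
    tail = c("low", "low", "low", "low", "low", "low",
             "high", "high", "high", "high"))
}

#' Composite directional-selection call for one gene
#'
#' A gene is called a directional-selection target in a population when,
#' with all statistics calibrated against the control panel, either (i) at
#' least three distinct signature families each contribute a statistic past
#' its 5\% tail, or (ii) at least two distinct families are past their 1\%
#' tails. Tails are strict: rank > 0.95 / < 0.05 (and > 0.99 / < 0.01).
#'
#' @param evidence data.frame with columns \code{statistic} and \code{rank}
#'   (percentile rank in [0,1]; NA ranks ignored).
#' @param familyMap statistic/family/tail table
#'   (default \code{\link{statFamilies}()}).
#' @return list: verdict ("directional_target" or "none"), the evidence
#'   rows that are outliers, and the families hit at each tail.
#' @export
callDirectionalTargets <- function(evidence, familyMap = statFamilies()) {
  ev <- merge(evidence, familyMap, by = "statistic")
  ev <- ev[!is.na(ev$rank), , drop = FALSE]
  out5 <- ifelse(ev$tail == "low", ev$rank < 0.05, ev$rank > 0.95)
  out1 <- ifelse(ev$tail == "low", ev$rank < 0.01, ev$rank > 0.99)
  fam5 <- unique(ev$family[out5])
  fam1 <- unique(ev$family[out1])
  verdict <- if (length(fam5) >= 3 || length(fam1) >= 2)
    "directional_target" else "none"
  list(verdict = verdict,
       outliers = ev[out5, c("statistic", "family", "rank")],
       families5 = fam5, families1 = fam1)
}

#' Flag balancing-selection candidates from whole-gene diversity
#'
#' A gene is a balancing-selection candidate when its whole-gene theta_W or
#' pi exceeds the control panel's 95th percentile (strict) in at least one
#' population. Candidates are only reported as balancing targets after the
#' MLHKA gate (see \code{\link{balancingVerdict}}).
#'
#' @param thetaWRanks,piRanks named numeric vectors of percentile ranks per
#'   population.
#' @return list: verdict ("balancing_candidate" or "none"), populations in
#'   which the threshold is passed.
#' @export
flagBalancingCandidates <- function(thetaWRanks, piRanks) {
  pops <- union(names(thetaWRanks), names(piRanks))
  hit <- vapply(pops, function(p) {
    isTRUE(thetaWRanks[p] > 0.95) || isTRUE(piRanks[p] > 0.95)
  }, logical(1))
  list(verdict = if (any(hit)) "balancing_candidate" else "none",
       populations = pops[hit])
}

#' Final balancing-selection verdict (MLHKA gate)
#'
#' A gene is reported as a balancing-selection target only when it was
#' candidate-flagged on diversity and the MLHKA test rejects neutrality
#' (p < 0.05) in at least one population.
#'
#' @param candidate logical candidate flag from
#'   \code{\link{flagBalancingCandidates}}.
#' @param mlhkaP numeric vector of MLHKA p-values (one per population).
#' @return "balancing_target" or "none".
#' @export
balancingVerdict <- function(candidate, mlhkaP) {
  if (isTRUE(candidate) && any(mlhkaP < 0.05, na.rm = TRUE))
    "balancing_target" else "none"
}
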
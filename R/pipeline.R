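#' @include empirical-null.R haplotype-tests.R fst.R simulate.R balancing-selection.R association.R
NULL

#' Default scan configuration
#'
#' All thresholds of the scan are explicit here and serialized into every
#' results directory: panel size and demography, MAF/DAF binning (50 / 100
#' classes), sliding-window span/step (5000/500 bp), outlier tails (5\% and
#' 1\%, strict), the DIND flank count (20 per side) and the EHH extent
#' (100 kb per side).
#'
#' @param seed master RNG seed.
#' @return a nested list of settings.
#' @export
scanConfigDefaults <- function(seed = 1) {
  list(seed = seed,
       panel = list(nLoci = 200, n = 40, thetaMeanLog = log(8),
                    thetaSdLog = 0.4, regionLength = 10000,
                    demography = "constant"),
       bins = list(MAF = 50L, DAF = 100L),
       window = list(span = 5000L, step = 500L),
       tails = list(outer = 0.05, inner = 0.01),
       dind = list(flankEach = 20L),
       ehh = list(maxExtent = 1e5, minEhh = 0.05),
       ihs = list(enable = FALSE, bins = 50L, minPerBin = 50L),
       fstPair = NULL)
}

resolveConfig <- function(config) {
  base <- scanConfigDefaults()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  utils::modifyList(base, config)
}

panelFromConfig <- function(cfg) {
  dem <- switch(cfg$panel$demography,
                constant = demographyConstant(cfg$panel$n),
                bottleneck = demographyBottleneck(cfg$panel$n),
                stop("unknown panel demography"))
  generateControlPanel(cfg$panel$nLoci, dem,
                       thetaMeanLog = cfg$panel$thetaMeanLog,
                       thetaSdLog = cfg$panel$thetaSdLog,
                       regionLength = cfg$panel$regionLength)
}

# per-SNP DIND rows (with DAF) for a list of loci; cap applied jointly
dindPanelTable <- function(loci, pop = NULL, flankEach = 20) {
  rows <- lapply(loci, function(h) {
    d <- dindTable(h, pop = pop, flankEach = flankEach)
    if (nrow(d)) d$region_id <- regionId(h)
    d
  })
  out <- do.call(rbind, rows[vapply(rows, nrow, integer(1)) > 0])
  if (is.null(out))
    return(data.frame(pos = integer(), daf = numeric(), iPiA = numeric(),
                      iPiD = numeric(), dind = numeric(),
                      capped = logical(), region_id = character()))
  out
}

#' Run the directional-selection scan
#'
#' End-to-end workflow: generate (or accept) a neutral control panel,
#' compute whole-region statistics and per-SNP DIND for panel and test
#' loci, build empirical nulls (whole-gene statistics unbinned; DIND
#' binned in 100 DAF classes with the joint cap rule), score each test
#' gene, and emit composite selection calls plus sliding-window tracks.
#' Deterministic given \code{config$seed}.
#'
#' @param testLoci named list of \linkS4class{HaplotypeMatrix} test genes.
#' @param panel optional list of control-locus HaplotypeMatrix objects;
#'   generated from the config when NULL.
#' @param config a config list (see \code{\link{scanConfigDefaults}}) or a
#'   YAML path; NULL = defaults.
#' @param outDir optional directory; when given, TSV/JSON/YAML outputs are
#'   written there.
#' @param pop population to scan (default: first label of the first test
#'   locus).
#' @return list: regionStats, snpDind, calls (one row per gene), nulls,
#'   config.
#' @export
runScan <- function(testLoci, panel = NULL, config = NULL, outDir = NULL,
                    pop = NULL) {
  cfg <- resolveConfig(config)
  set.seed(cfg$seed)
  if (is.null(panel)) panel <- panelFromConfig(cfg)
  if (is.null(pop)) pop <- popLabels(testLoci[[1]])[1]
  fe <- cfg$dind$flankEach

  panelStats <- do.call(rbind, lapply(panel, regionStatistics, pops = pop))
  testStats <- do.call(rbind, lapply(testLoci, regionStatistics, pops = pop))

  nulls <- list()
  for (st in c("thetaW_site", "pi_site", "TajD", "FuLiDstar", "FuLiFstar",
               "FayWuHnorm"))
    nulls[[st]] <- buildEmpiricalNull(panelStats[[st]], statistic = st,
                                      population = pop, panelId = "panel")

  pd <- dindPanelTable(panel, pop = pop, flankEach = fe)
  td <- dindPanelTable(testLoci, pop = pop, flankEach = fe)
  allDind <- dindApplyCap(c(pd$dind, td$dind), c(pd$capped, td$capped))
  pd$dindCapped <- allDind[seq_len(nrow(pd))]
  td$dindCapped <- if (nrow(td)) allDind[nrow(pd) + seq_len(nrow(td))]
                   else numeric(0)
  nulls$DIND <- buildEmpiricalNull(pd$dindCapped, binValues = pd$daf,
                                   binVariable = "DAF",
                                   nClasses = cfg$bins$DAF,
                                   capped = pd$capped, statistic = "DIND",
                                   population = pop, panelId = "panel")

  # gene-level DIND evidence: the per-locus maximum (over SNPs in defined
  # DAF classes) is calibrated against the same per-locus maximum on the
  # panel — comparing maxima to per-SNP nulls would overstate outliers
  definedDaf <- function(daf) {
    cls <- nullClassOf(nulls$DIND, daf)
    nulls$DIND@classTable$defined[cls]
  }
  perLocusMax <- function(tab) {
    if (nrow(tab) == 0) return(c(none = NA_real_))
    ok <- definedDaf(tab$daf) & !is.na(tab$dindCapped)
    vapply(split(tab$dindCapped[ok], tab$region_id[ok]),
           function(v) if (length(v)) max(v) else NA_real_, numeric(1))
  }
  pdMax <- perLocusMax(pd)
  nulls$DINDgene <- buildEmpiricalNull(pdMax, statistic = "DINDgene",
                                       population = pop, panelId = "panel")

  # optional cross-population arm: per-SNP FST against a MAF-binned null
  fstPair <- cfg$fstPair
  fstRanks <- NULL
  if (!is.null(fstPair)) {
    panelFst <- do.call(rbind, lapply(panel, function(h) {
      ft <- fstPerSnp(h, fstPair); ft$region_id <- regionId(h); ft
    }))
    nulls$FST <- buildEmpiricalNull(panelFst$FST,
                                    binValues = panelFst$MAF_pooled,
                                    binVariable = "MAF",
                                    nClasses = cfg$bins$MAF,
                                    statistic = "FST",
                                    population = paste(fstPair,
                                                       collapse = "/"),
                                    panelId = "panel")
    # gene-level evidence calibrated on per-locus maxima (see DIND note)
    pfMax <- vapply(split(panelFst$FST, panelFst$region_id),
                    function(v) if (any(!is.na(v))) max(v, na.rm = TRUE)
                                else NA_real_, numeric(1))
    nulls$FSTgene <- buildEmpiricalNull(pfMax, statistic = "FSTgene",
                                        population = paste(fstPair,
                                                           collapse = "/"),
                                        panelId = "panel")
    fstRanks <- lapply(testLoci, function(h) {
      ft <- fstPerSnp(h, fstPair)
      ok <- !is.na(ft$FST)
      if (!any(ok)) return(NA_real_)
      percentileRank(nulls$FSTgene, max(ft$FST[ok]))
    })
  }

  # optional iHS arm: panel-calibrated standardization
  ihsRanks <- NULL
  if (isTRUE(cfg$ihs$enable)) {
    rawIhsTab <- function(h) {
      dm <- derivedCalls(h)
      daf <- colSums(dm) / nrow(dm)
      idx <- which(!is.na(daf) & daf > 0.05 & daf < 0.95)
      if (!length(idx)) return(NULL)
      data.frame(daf = daf[idx],
                 raw = vapply(idx, function(j)
                   ihsUnstandardized(h, j, maxExtent = cfg$ehh$maxExtent,
                                     minEhh = cfg$ehh$minEhh), numeric(1)))
    }
    calTabs <- lapply(panel, rawIhsTab)
    calTab <- do.call(rbind, calTabs)
    zMaxPanel <- vapply(calTabs, function(tb) {
      if (is.null(tb)) return(NA_real_)
      z <- standardizeIhs(tb$raw, tb$daf, calTab$raw, calTab$daf,
                          bins = cfg$ihs$bins, minPerBin = cfg$ihs$minPerBin)
      if (all(is.na(z))) NA_real_ else max(abs(z), na.rm = TRUE)
    }, numeric(1))
    nulls$iHS <- buildEmpiricalNull(zMaxPanel, statistic = "iHSgene",
                                    population = pop, panelId = "panel")
    ihsRanks <- lapply(testLoci, function(h) {
      tb <- rawIhsTab(h)
      if (is.null(tb)) return(NA_real_)
      z <- standardizeIhs(tb$raw, tb$daf, calTab$raw, calTab$daf,
                          bins = cfg$ihs$bins, minPerBin = cfg$ihs$minPerBin)
      if (all(is.na(z))) return(NA_real_)
      percentileRank(nulls$iHS, max(abs(z), na.rm = TRUE))
    })
  }

  statMap <- c(thetaW = "thetaW_site", pi = "pi_site", TajD = "TajD",
               FuLiDstar = "FuLiDstar", FuLiFstar = "FuLiFstar",
               FayWuHnorm = "FayWuHnorm")
  calls <- lapply(names(testLoci), function(g) {
    rs <- testStats[testStats$region_id == regionId(testLoci[[g]]), ]
    ev <- do.call(rbind, lapply(names(statMap), function(sname) {
      data.frame(statistic = sname,
                 rank = percentileRank(nulls[[statMap[sname]]],
                                       rs[[statMap[sname]]][1]))
    }))
    gd <- td[td$region_id == regionId(testLoci[[g]]), , drop = FALSE]
    dindRank <- NA_real_
    if (nrow(gd)) {
      ok <- definedDaf(gd$daf) & !is.na(gd$dindCapped)
      if (any(ok))
        dindRank <- percentileRank(nulls$DINDgene, max(gd$dindCapped[ok]))
    }
    ev <- rbind(ev, data.frame(statistic = "DIND", rank = dindRank))
    if (!is.null(fstRanks))
      ev <- rbind(ev, data.frame(statistic = "FST", rank = fstRanks[[g]]))
    if (!is.null(ihsRanks))
      ev <- rbind(ev, data.frame(statistic = "iHS", rank = ihsRanks[[g]]))
    dc <- callDirectionalTargets(ev)
    bc <- flagBalancingCandidates(
      stats::setNames(ev$rank[ev$statistic == "thetaW"], pop),
      stats::setNames(ev$rank[ev$statistic == "pi"], pop))
    data.frame(gene = g, pop = pop,
               directional = dc$verdict,
               nFamilies5 = length(dc$families5),
               nFamilies1 = length(dc$families1),
               balancingCandidate = bc$verdict,
               dindRank = dindRank,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)

  out <- list(regionStats = testStats, panelStats = panelStats,
              snpDind = td, calls = calls, nulls = nulls, config = cfg)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(testStats, file.path(outDir, "region_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(td, file.path(outDir, "snp_dind.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(calls, file.path(outDir, "calls.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    yaml::write_yaml(c(cfg, list(package = as.character(
      utils::packageVersion("popgenScan")))),
      file.path(outDir, "config.yaml"))
    jsonlite::write_json(lapply(nulls, function(nl) nl@classTable),
                         file.path(outDir, "nulls.json"))
  }
  out
}

#' Run the balancing/association follow-up
#'
#' For each balancing candidate: the maximum-likelihood HKA test on
#' supplied polymorphism/divergence counts, coalescent-simulation p-values
#' for Tajima's D (upper tail — balancing spectra are positive), and the
#' pairwise TMRCA with a divergence-calibrated mutation rate. Optionally,
#' case/control association on a genotype table: penetrance-model fits
#' over all models with AIC selection, exact HWE, and permutation
#' association.
#'
#' @param candidates named list of HaplotypeMatrix for candidate regions
#'   (may be empty).
#' @param hkaLoci data.frame of HKA inputs (locus, S, D, n, L, isTest) in
#'   which each candidate appears as a test locus named as in
#'   \code{candidates}.
#' @param fixedDifferences named vector: human-outgroup fixed differences
#'   per candidate region (for the mutation-rate calibration).
#' @param genotypes optional list(cases=, controls=) of
#'   \linkS4class{GenotypeCounts} for the association arm.
#' @param Kp trait prevalence for the penetrance fit.
#' @param config config list or YAML path (seed, iteration counts).
#' @param outDir optional output directory.
#' @return list: hka (per candidate), coalP, tmrca, association.
#' @export
runFollowup <- function(candidates, hkaLoci = NULL,
                        fixedDifferences = NULL, genotypes = NULL,
                        Kp = 0.20, config = NULL, outDir = NULL) {
  cfg <- resolveConfig(config)
  iters <- cfg$coalescentIterations %||% 2000
  set.seed(cfg$seed)
  hka <- list(); coalP <- list(); tmrca <- list()
  for (g in names(candidates)) {
    hap <- candidates[[g]]
    if (!is.null(hkaLoci)) {
      loci <- hkaLoci
      loci$isTest <- loci$locus == g
      hka[[g]] <- mlhkaFitAndTest(loci)
    }
    cc <- sfsCounts(hap)
    thetaHat <- wattersonTheta(cc)
    obs <- tajimasD(cc)
    if (!is.na(obs) && thetaHat > 0)
      coalP[[g]] <- coalescentPvalue(obs, "D", n = cc@n, theta = thetaHat,
                                     iterations = iters, tail = "upper")
    if (!is.null(fixedDifferences) && !is.na(fixedDifferences[g]) &&
        fixedDifferences[g] > 0) {
      mu <- calibrateMutationRate(fixedDifferences[g])
      tmrca[[g]] <- tmrcaPairwise(hap, mu$muYear)
    }
  }
  assoc <- NULL
  if (!is.null(genotypes)) {
    fits <- lapply(c("general", "dominant", "recessive", "additive",
                     "multiplicative"), function(m)
      fitPenetranceModel(genotypes$cases, genotypes$controls, Kp, m))
    names(fits) <- vapply(fits, function(f) f@model, character(1))
    best <- selectBestModelAic(fits)
    assoc <- list(
      fits = fits, best = best@model,
      hweCases = hweExactTest(genotypes$cases),
      hweControls = hweExactTest(genotypes$controls),
      permGenotypic = permutationAssociation(genotypes$cases,
        genotypes$controls, "genotypic", B = cfg$permB %||% 10000,
        seed = cfg$seed),
      permRecessive = permutationAssociation(genotypes$cases,
        genotypes$controls, "recessive", B = cfg$permB %||% 10000,
        seed = cfg$seed))
  }
  res <- list(hka = hka, coalP = coalP, tmrca = tmrca, association = assoc,
              config = cfg)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    js <- list(
      hka = lapply(hka, function(h) list(T = h@T, k = h@k, LRT = h@LRT,
                                         df = h@df, p = h@p)),
      coalescent_p = coalP,
      tmrca = tmrca,
      association = if (is.null(assoc)) NULL else list(
        best = assoc$best,
        fits = lapply(assoc$fits, function(f)
          list(model = f@model, q = f@q, alpha = f@alpha, beta = f@beta,
               gamma = f@gamma, chisq = f@chisq, df = f@df, p = f@p,
               AIC = f@AIC)),
        hwe = list(cases = assoc$hweCases, controls = assoc$hweControls),
        permutation = list(genotypic = assoc$permGenotypic$p,
                           recessive = assoc$permRecessive$p)))
    jsonlite::write_json(js, file.path(outDir, "followup.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
  }
  res
}
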
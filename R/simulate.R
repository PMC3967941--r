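#' @include io.R
NULL

#' Demography configuration for the coalescent simulator
#'
#' Piecewise-constant population sizes with clean splits, looking backwards
#' in time. Time is measured in units of 2N0 generations and sizes are
#' relative to N0; theta is defined per locus on the same scale
#' (E[pi] = theta for a constant-size population).
#'
#' @param sampleSizes named integer vector: haplotypes sampled per
#'   population.
#' @param epochs named list (one entry per population, plus any ancestral
#'   population) of data.frames with columns \code{time} (epoch start,
#'   backwards) and \code{size} (relative size); first row must have
#'   time 0 for sampled populations.
#' @param splits optional data.frame with columns \code{time},
#'   \code{derived}, \code{ancestral}: at \code{time}, lineages of
#'   \code{derived} join \code{ancestral}.
#' @return a list with class \code{"demographyConfig"}.
#' @export
demographyConfig <- function(sampleSizes, epochs, splits = NULL) {
  stopifnot(!is.null(names(sampleSizes)), all(sampleSizes >= 1))
  for (e in epochs) {
    stopifnot(all(diff(e$time) > 0), all(e$size > 0))
  }
  structure(list(sampleSizes = sampleSizes, epochs = epochs,
                 splits = splits), class = "demographyConfig")
}

#' Built-in demographies
#'
#' \code{demographyConstant} is a single constant-size population (the
#' African-like default of the control panel). \code{demographyBottleneck}
#' adds an out-of-Africa-like bottleneck: size drops to \code{bnSize}
#' between \code{bnStart} and \code{bnEnd} (backwards, 2N0-generation
#' units) and returns to 1 earlier than that. \code{demographyTwoPopSplit}
#' is two equal-size populations without migration that merge \code{tau}
#' time units ago — the divergence model behind the FST calibration tests.
#'
#' @param n,n1,n2 haplotype sample sizes.
#' @param pop,pops population labels.
#' @param bnSize,bnStart,bnEnd bottleneck depth and interval.
#' @param tau split time (2N0-generation units).
#' @return a \code{\link{demographyConfig}}.
#' @export
demographyConstant <- function(n, pop = "POP") {
  demographyConfig(stats::setNames(n, pop),
                   stats::setNames(list(data.frame(time = 0, size = 1)), pop))
}

#' @rdname demographyConstant
#' @export
demographyBottleneck <- function(n, pop = "POP", bnSize = 0.1,
                                 bnStart = 0.02, bnEnd = 0.06) {
  demographyConfig(stats::setNames(n, pop),
    stats::setNames(list(data.frame(time = c(0, bnStart, bnEnd),
                                    size = c(1, bnSize, 1))), pop))
}

#' @rdname demographyConstant
#' @export
demographyTwoPopSplit <- function(n1, n2, tau, pops = c("POP1", "POP2")) {
  eps <- list(data.frame(time = 0, size = 1),
              data.frame(time = 0, size = 1))
  names(eps) <- pops
  demographyConfig(stats::setNames(c(n1, n2), pops), eps,
                   splits = data.frame(time = tau, derived = pops[2],
                                       ancestral = pops[1]))
}

# relative population size at (backwards) time t
epochSizeAt <- function(epochTable, t) {
  epochTable$size[max(which(epochTable$time <= t + 1e-12))]
}

#' Simulate one locus under the neutral coalescent
#'
#' Hudson-style n-coalescent with piecewise-constant demography and
#' infinite-sites mutation: the genealogy is built by exponential waiting
#' times (rate C(k,2)/relative-size per population), mutations are placed
#' as Poisson(theta/2 x total branch length) uniformly on branches, and
#' each mutation becomes one biallelic site whose derived allele is carried
#' by the leaves below it. No intra-locus recombination. The true TMRCA
#' (2N0-generation units) is recorded as an attribute.
#'
#' @param n haplotype sample size (ignored when \code{demography} is
#'   given).
#' @param theta per-locus scaled mutation rate (E[S] = theta a_n at
#'   constant size).
#' @param demography optional \code{\link{demographyConfig}}; default a
#'   single constant-size population.
#' @param regionLength bp span over which site positions are scattered.
#' @param regionId,chrom identifiers.
#' @param seed optional RNG seed (recorded as an attribute).
#' @return A \linkS4class{HaplotypeMatrix} with attributes \code{tmrca}
#'   and \code{seed}; ancestral states are exact ("ref" everywhere).
#' @export
simulateCoalescentLocus <- function(n = NULL, theta, demography = NULL,
                                    regionLength = 10000,
                                    regionId = "locus", chrom = "chr1",
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(demography)) {
    stopifnot(!is.null(n), n >= 2)
    demography <- demographyConstant(n)
  }
  ss <- demography$sampleSizes
  nTot <- sum(ss)
  popOf <- rep(names(ss), ss)

  parent <- integer(2 * nTot - 1)
  nodeTime <- numeric(2 * nTot - 1)
  active <- seq_len(nTot)                 # node ids of live lineages
  linPop <- popOf
  nextNode <- nTot + 1L
  t <- 0
  splits <- demography$splits
  splitsLeft <- if (is.null(splits)) splits else splits[order(splits$time), ]

  while (length(active) > 1) {
    kPer <- table(factor(linPop, levels = names(demography$epochs)))
    sizes <- vapply(names(kPer), function(p)
      epochSizeAt(demography$epochs[[p]], t), numeric(1))
    rates <- ifelse(kPer >= 2, choose(kPer, 2) / sizes, 0)
    totalRate <- sum(rates)

    boundaries <- unlist(lapply(demography$epochs, function(e)
      e$time[e$time > t + 1e-12]))
    if (!is.null(splitsLeft) && nrow(splitsLeft) > 0)
      boundaries <- c(boundaries, splitsLeft$time[1])
    nextEvent <- if (length(boundaries)) min(boundaries) else Inf

    dt <- if (totalRate > 0) stats::rexp(1, totalRate) else Inf
    if (t + dt >= nextEvent) {
      if (is.infinite(nextEvent))
        stop("demography never coalesces the remaining lineages")
      t <- nextEvent
      if (!is.null(splitsLeft) && nrow(splitsLeft) > 0 &&
          abs(splitsLeft$time[1] - t) < 1e-12) {
        linPop[linPop == splitsLeft$derived[1]] <- splitsLeft$ancestral[1]
        splitsLeft <- splitsLeft[-1, , drop = FALSE]
      }
      next
    }
    t <- t + dt
    p <- sample(names(kPer), 1, prob = as.numeric(rates) / totalRate)
    inP <- which(linPop == p)
    pick <- sample(inP, 2)
    node <- nextNode; nextNode <- nextNode + 1L
    nodeTime[node] <- t
    parent[active[pick]] <- node
    active <- c(active[-pick], node)
    linPop <- c(linPop[-pick], p)
  }
  root <- active
  tmrca <- t

  nNodes <- nextNode - 1L
  blen <- numeric(nNodes)
  nonroot <- setdiff(seq_len(nNodes), root)
  blen[nonroot] <- nodeTime[parent[nonroot]] - nodeTime[nonroot]
  totLen <- sum(blen)

  nMut <- stats::rpois(1, theta / 2 * totLen)
  if (nMut > regionLength) nMut <- regionLength    # infinite sites at finite bp
  if (nMut == 0) {
    calls <- matrix(integer(0), nrow = nTot, ncol = 0)
    hapOut <- HaplotypeMatrix(calls, integer(0), popOf,
                              regionId = regionId, chrom = chrom,
                              regionStart = 1L, regionEnd = regionLength)
    attr(hapOut, "tmrca") <- tmrca
    attr(hapOut, "seed") <- seed
    return(hapOut)
  }
  mutNode <- sample.int(nNodes, nMut, replace = TRUE, prob = blen)
  # leaves below each node
  below <- vector("list", nNodes)
  for (i in seq_len(nTot)) below[[i]] <- i
  ord <- order(nodeTime[(nTot + 1):nNodes])
  for (nd in ((nTot + 1):nNodes)[ord]) {
    kids <- which(parent == nd)
    below[[nd]] <- unlist(below[kids])
  }
  calls <- matrix(0L, nrow = nTot, ncol = nMut)
  for (j in seq_len(nMut)) calls[below[[mutNode[j]]], j] <- 1L
  pos <- sort(sample.int(regionLength, nMut))
  hapOut <- HaplotypeMatrix(calls, pos, popOf, regionId = regionId,
                            chrom = chrom, regionStart = 1L,
                            regionEnd = regionLength)
  attr(hapOut, "tmrca") <- tmrca
  attr(hapOut, "seed") <- seed
  hapOut
}

#' Simulate polymorphism and divergence counts for one locus
#'
#' Counts consistent with the HKA likelihood: S ~ Poisson(theta a_n),
#' D ~ Poisson(theta (T + 1)), with T the species divergence in
#' 2N-generation units (the +1 carries ancestral polymorphism).
#'
#' @param theta per-locus scaled mutation rate.
#' @param T divergence time in 2N-generation units.
#' @param n haplotype sample size.
#' @param k optional polymorphism scaling (selection parameter; default 1).
#' @return named integer vector \code{c(S=, D=)}.
#' @export
simulateOutgroupDivergence <- function(theta, T, n, k = 1) {
  stopifnot(theta > 0, T >= 0, n >= 2)
  c(S = stats::rpois(1, k * theta * harmonicA(n)),
    D = stats::rpois(1, theta * (T + 1)))
}

#' Forward Wright-Fisher simulation of a selective sweep
#'
#' Standing variation for a diploid population of size N is drawn from the
#' neutral coalescent (a coalescent sample of 2N haplotypes is a
#' mutation-drift-equilibrium state); a segregating site near the window
#' center whose derived frequency lies in \code{initBand} then becomes
#' beneficial (fitnesses 1, 1+hs, 1+s) and the population is evolved
#' forward with per-generation recombination between adjacent sites until
#' the derived allele reaches \code{targetDaf} (or fixation). Runs in
#' which the beneficial allele is lost are retried with fresh standing
#' variation, up to \code{maxRetries} (retries are reported via
#' \code{message}). New mutations enter at rate theta/2 per generation
#' (one copy each, at fresh positions), and sites lost from the population
#' are dropped, so a neutral run stays at mutation-drift balance.
#'
#' @param N diploid population size (>= 50; keep small and interpret s as
#'   rescaled).
#' @param s selection coefficient (> 0; 0 gives a neutral forward run of
#'   \code{neutralGenerations} generations).
#' @param h dominance (default 0.5).
#' @param theta scaled mutation rate of the standing variation.
#' @param r per-generation recombination probability between adjacent
#'   sites.
#' @param sampleSize haplotypes returned.
#' @param targetDaf population derived frequency at which sampling occurs;
#'   \code{1} means fixation.
#' @param regionLength bp span of the window.
#' @param initBand derived-frequency band from which the selected site is
#'   picked.
#' @param neutralGenerations forward generations when s = 0.
#' @param maxRetries bounded retries when the allele is lost.
#' @param pop population label.
#' @param seed optional RNG seed.
#' @return A \linkS4class{HaplotypeMatrix} of the sample with attributes
#'   \code{selectedPos}, \code{selectedDafPop} (population frequency at
#'   sampling), \code{retries}, \code{seed}.
#' @export
simulateSweepForward <- function(N = 200, s = 0.05, h = 0.5, theta = 10,
                                 r = 1e-5, sampleSize = 40, targetDaf = 0.8,
                                 regionLength = 20000,
                                 initBand = c(0, 0.05),
                                 neutralGenerations = 50,
                                 maxRetries = 50, pop = "POP", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(N >= 50, s >= 0, h >= 0, h <= 1)
  for (attempt in 0:maxRetries) {
    init <- simulateCoalescentLocus(2 * N, theta,
                                    regionLength = regionLength)
    m <- haploCalls(init)
    posv <- sitePositions(init)
    L <- ncol(m)
    if (L < 3) next
    freq <- colSums(m) / (2 * N)
    if (s > 0) {
      centerDist <- abs(posv - regionLength / 2)
      cand <- which(freq >= initBand[1] & freq <= initBand[2])
      if (length(cand) == 0) next
      sel <- cand[which.min(centerDist[cand])]
    } else sel <- which.min(abs(posv - regionLength / 2))

    pool <- m
    selPos <- posv[sel]
    lost <- FALSE
    gen <- 0
    maxGen <- if (s > 0) 200 * N else neutralGenerations
    repeat {
      sel <- match(selPos, posv)
      f <- sum(pool[, sel]) / (2 * N)
      if (s > 0 && f == 0) { lost <- TRUE; break }
      if (s > 0 && (f >= targetDaf || f == 1)) break
      if (s == 0 && gen >= neutralGenerations) break
      if (gen >= maxGen) { lost <- TRUE; break }
      L <- ncol(pool)
      g <- pool[seq(1, 2 * N, 2), sel] + pool[seq(2, 2 * N, 2), sel]
      w <- c(1, 1 + h * s, 1 + s)[g + 1]
      par <- sample.int(N, 2 * N, replace = TRUE, prob = w)
      A <- pool[2 * par - 1, , drop = FALSE]
      B <- pool[2 * par, , drop = FALSE]
      cross <- matrix(stats::runif(2 * N * (L - 1)) < r, nrow = 2 * N)
      strand <- (matrix(stats::rbinom(2 * N, 1, 0.5), 2 * N, L) +
                   cbind(0L, t(apply(cross, 1, cumsum)))) %% 2
      pool <- A * (1 - strand) + B * strand
      storage.mode(pool) <- "integer"
      # mutation influx: theta/2 new single-copy variants per generation
      nNew <- stats::rpois(1, theta / 2)
      if (nNew > 0) {
        free <- setdiff(seq_len(regionLength), posv)
        if (length(free) >= nNew) {
          newPos <- sample(free, nNew)
          newCol <- matrix(0L, 2 * N, nNew)
          newCol[cbind(sample.int(2 * N, nNew, replace = TRUE),
                       seq_len(nNew))] <- 1L
          pool <- cbind(pool, newCol)
          posv <- c(posv, newPos)
        }
      }
      # drop variants lost from the population (keep the selected site)
      cs <- colSums(pool)
      keep <- cs > 0 | posv == selPos
      pool <- pool[, keep, drop = FALSE]
      posv <- posv[keep]
      ordp <- order(posv)
      pool <- pool[, ordp, drop = FALSE]
      posv <- posv[ordp]
      gen <- gen + 1
    }
    if (lost) next
    sel <- match(selPos, posv)
    segKeep <- which(colSums(pool) > 0 & colSums(pool) < 2 * N)
    segKeep <- sort(union(segKeep, sel))
    rows <- sample.int(2 * N, sampleSize)
    out <- HaplotypeMatrix(pool[rows, segKeep, drop = FALSE],
                           posv[segKeep], pop,
                           regionId = "sweep", chrom = "chr1",
                           regionStart = 1L, regionEnd = regionLength)
    attr(out, "selectedPos") <- selPos
    attr(out, "selectedDafPop") <- sum(pool[, sel]) / (2 * N)
    attr(out, "retries") <- attempt
    attr(out, "seed") <- seed
    if (attempt > 0) message("sweep retried ", attempt, " time(s)")
    return(out)
  }
  stop("beneficial allele lost in all ", maxRetries + 1, " attempts")
}

# one Wright-Fisher generation: selection (at selIdx, fitness 1/1+hs/1+s),
# recombination between adjacent sites, mutation influx, loss pruning.
# pool is the 2N x L haplotype matrix; posv its positions.
wfGeneration <- function(pool, posv, N, s, h, r, theta, regionLength,
                         selPos) {
  L <- ncol(pool)
  sel <- match(selPos, posv)
  if (s > 0 && !is.na(sel)) {
    g <- pool[seq(1, 2 * N, 2), sel] + pool[seq(2, 2 * N, 2), sel]
    w <- c(1, 1 + h * s, 1 + s)[g + 1]
  } else w <- rep(1, N)
  par <- sample.int(N, 2 * N, replace = TRUE, prob = w)
  A <- pool[2 * par - 1, , drop = FALSE]
  B <- pool[2 * par, , drop = FALSE]
  cross <- matrix(stats::runif(2 * N * (L - 1)) < r, nrow = 2 * N)
  strand <- (matrix(stats::rbinom(2 * N, 1, 0.5), 2 * N, L) +
               cbind(0L, t(apply(cross, 1, cumsum)))) %% 2
  pool <- A * (1 - strand) + B * strand
  storage.mode(pool) <- "integer"
  nNew <- stats::rpois(1, theta / 2)
  if (nNew > 0) {
    free <- setdiff(seq_len(regionLength), posv)
    if (length(free) >= nNew) {
      newPos <- sample(free, nNew)
      newCol <- matrix(0L, 2 * N, nNew)
      newCol[cbind(sample.int(2 * N, nNew, replace = TRUE),
                   seq_len(nNew))] <- 1L
      pool <- cbind(pool, newCol)
      posv <- c(posv, newPos)
    }
  }
  cs <- colSums(pool)
  keep <- cs > 0 | posv == selPos
  ordp <- order(posv[keep])
  list(pool = pool[, keep, drop = FALSE][, ordp, drop = FALSE],
       posv = posv[keep][ordp])
}

#' Paired two-population sweep simulation
#'
#' Two populations of diploid size N split from one ancestral standing-
#' variation pool (a coalescent draw of 4N haplotypes) and evolve forward
#' independently for exactly \code{gens} generations; a central standing
#' variant becomes beneficial in population 1 at the split while
#' population 2 stays neutral. Runs are retried until the selected allele
#' reaches \code{minDaf} in population 1 at sampling time, so the pair has
#' a fixed drift divergence (gens / 2N in coalescent units) plus a
#' population-1-specific sweep — the positive control for FST, lnRsb and
#' DIND between-population contrasts.
#'
#' @param N diploid size of each population.
#' @param s,h selection coefficient and dominance in population 1.
#' @param theta standing-variation scaled mutation rate (per population).
#' @param r per-generation recombination probability between adjacent
#'   sites.
#' @param gens forward generations in both populations.
#' @param minDaf minimum population-1 derived frequency of the selected
#'   site at sampling.
#' @param sampleSize haplotypes sampled per population.
#' @param regionLength bp span.
#' @param initBand derived-frequency band (ancestral pool) for the
#'   selected variant.
#' @param maxRetries bounded retries.
#' @param pops population labels.
#' @param seed optional RNG seed.
#' @return A \linkS4class{HaplotypeMatrix} with both populations and
#'   attributes \code{selectedPos}, \code{selectedDafPop1},
#'   \code{selectedDafPop2}, \code{retries}, \code{seed}.
#' @export
simulateSweepPair <- function(N = 400, s = 0.1, h = 0.5, theta = 16,
                              r = 1e-5, gens = 150, minDaf = 0.7,
                              sampleSize = 40, regionLength = 20000,
                              initBand = c(0, 0.05), maxRetries = 60,
                              pops = c("POP1", "POP2"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (attempt in 0:maxRetries) {
    anc <- simulateCoalescentLocus(4 * N, 2 * theta,
                                   regionLength = regionLength)
    m <- haploCalls(anc)
    posv <- sitePositions(anc)
    if (ncol(m) < 3) next
    rows1 <- seq_len(2 * N)
    p1 <- m[rows1, , drop = FALSE]
    p2 <- m[-rows1, , drop = FALSE]
    f1 <- colSums(p1) / (2 * N)
    cand <- which(f1 >= initBand[1] & f1 <= initBand[2] & f1 > 0)
    if (!length(cand)) next
    ctr <- abs(posv - regionLength / 2)
    selPos <- posv[cand[which.min(ctr[cand])]]
    pos1 <- posv; pos2 <- posv
    okRun <- TRUE
    for (g in seq_len(gens)) {
      st <- wfGeneration(p1, pos1, N, s, h, r, theta, regionLength, selPos)
      p1 <- st$pool; pos1 <- st$posv
      if (!selPos %in% pos1 || sum(p1[, match(selPos, pos1)]) == 0) {
        okRun <- FALSE; break
      }
    }
    if (!okRun) next
    if (sum(p1[, match(selPos, pos1)]) / (2 * N) < minDaf) next
    for (g in seq_len(gens)) {
      st <- wfGeneration(p2, pos2, N, 0, h, r, theta, regionLength, selPos)
      p2 <- st$pool; pos2 <- st$posv
    }
    allPos <- sort(union(pos1, pos2))
    take <- function(pool, pv) {
      out <- matrix(0L, nrow(pool), length(allPos))
      out[, match(pv, allPos)] <- pool
      out
    }
    s1 <- take(p1, pos1)[sample.int(2 * N, sampleSize), , drop = FALSE]
    s2 <- take(p2, pos2)[sample.int(2 * N, sampleSize), , drop = FALSE]
    calls <- rbind(s1, s2)
    segKeep <- which(colSums(calls) > 0 & colSums(calls) < nrow(calls))
    segKeep <- sort(union(segKeep, match(selPos, allPos)))
    out <- HaplotypeMatrix(calls[, segKeep, drop = FALSE], allPos[segKeep],
                           rep(pops, each = sampleSize),
                           regionId = "sweepPair", chrom = "chr1",
                           regionStart = 1L, regionEnd = regionLength)
    attr(out, "selectedPos") <- selPos
    attr(out, "selectedDafPop1") <-
      sum(p1[, match(selPos, pos1)]) / (2 * N)
    attr(out, "selectedDafPop2") <- if (selPos %in% pos2)
      sum(p2[, match(selPos, pos2)]) / (2 * N) else 0
    attr(out, "retries") <- attempt
    attr(out, "seed") <- seed
    if (attempt > 0) message("sweep pair retried ", attempt, " time(s)")
    return(out)
  }
  stop("selected allele never reached the target in ", maxRetries + 1,
       " attempts")
}

#' Draw case/control genotype counts from the penetrance model
#'
#' Multinomial draws from the Wittke-Thompson case and control genotype
#' probability vectors, with alpha derived from the prevalence identity.
#'
#' @param q susceptibility allele frequency.
#' @param beta,gamma heterozygote / homozygote relative risks.
#' @param Kp trait prevalence.
#' @param nCases,nControls cohort sizes.
#' @param seed optional RNG seed.
#' @return list of two \linkS4class{GenotypeCounts} (cases, controls).
#' @export
simulateCaseControlCounts <- function(q, beta, gamma, Kp,
                                      nCases, nControls, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- wtExpected(q, beta, gamma, Kp)
  if (e$alpha <= 0 || e$alpha >= 1 || e$alpha * gamma >= 1 ||
      e$alpha * beta >= 1)
    stop("infeasible alpha for these parameters")
  cs <- stats::rmultinom(1, nCases, e$caseP)[, 1]
  ct <- stats::rmultinom(1, nControls, e$ctrlP)[, 1]
  list(cases = GenotypeCounts(cs[1], cs[2], cs[3], cohort = "cases"),
       controls = GenotypeCounts(ct[1], ct[2], ct[3], cohort = "controls"))
}

#' Generate a neutral control-locus panel
#'
#' Independent loci simulated under a shared demography with per-locus
#' theta drawn from a log-normal distribution — the synthetic stand-in for
#' a genome-wide control gene set used to build empirical nulls.
#'
#' @param nLoci number of control loci.
#' @param demography a \code{\link{demographyConfig}} shared by all loci.
#' @param thetaMeanLog,thetaSdLog log-normal parameters of per-locus theta
#'   (defaults: median 8 per 10 kb locus, sdlog 0.4).
#' @param regionLength bp per locus.
#' @param seed optional RNG seed.
#' @return list of \linkS4class{HaplotypeMatrix}; attribute \code{seed}.
#' @export
generateControlPanel <- function(nLoci, demography = demographyConstant(40),
                                 thetaMeanLog = log(8), thetaSdLog = 0.4,
                                 regionLength = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nLoci >= 1)
  th <- stats::rlnorm(nLoci, thetaMeanLog, thetaSdLog)
  panel <- lapply(seq_len(nLoci), function(i)
    simulateCoalescentLocus(theta = th[i], demography = demography,
                            regionLength = regionLength,
                            regionId = sprintf("control_%04d", i)))
  attr(panel, "seed") <- seed
  attr(panel, "theta") <- th
  panel
}
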
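#' @include AllClasses.R
NULL

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on a 3-genotype table: all heterozygote counts
#' compatible with the observed rare-allele count (same parity) are
#' enumerated, their conditional probabilities computed, and the two-sided
#' p-value is the sum of probabilities not exceeding that of the observed
#' configuration.
#'
#' @param counts a \linkS4class{GenotypeCounts}.
#' @return p-value in (0, 1]; 1 for a monomorphic table.
#' @export
hweExactTest <- function(counts) {
  ct <- counts@counts
  n <- sum(ct)
  rare <- 2L * ct[["rareHom"]] + ct[["het"]]
  if (rare == 0L || rare == 2L * n) return(1)
  hets <- seq.int(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  lp <- vapply(hets, function(h) {
    ra <- (rare - h) / 2
    co <- n - ra - h
    lfactorial(n) - lfactorial(ra) - lfactorial(h) - lfactorial(co) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  pObs <- pr[hets == ct[["het"]]]
  sum(pr[pr <= pObs * (1 + 1e-12)])
}

# expected 6-cell probabilities of the Wittke-Thompson penetrance model;
# alpha is eliminated through the prevalence identity
# Kp = alpha [ (1-q)^2 + 2q(1-q) beta + q^2 gamma ].
wtExpected <- function(q, beta, gamma, Kp) {
  alpha <- Kp / ((1 - q)^2 + 2 * q * (1 - q) * beta + q^2 * gamma)
  caseP <- c(q^2 * alpha * gamma,
             2 * q * (1 - q) * alpha * beta,
             (1 - q)^2 * alpha) / Kp
  ctrlP <- c(q^2 * (1 - alpha * gamma),
             2 * q * (1 - q) * (1 - alpha * beta),
             (1 - q)^2 * (1 - alpha)) / (1 - Kp)
  list(alpha = alpha, caseP = caseP, ctrlP = ctrlP)
}

wtChisq <- function(q, beta, gamma, Kp, oCase, oCtrl) {
  e <- wtExpected(q, beta, gamma, Kp)
  if (e$alpha <= 0 || e$alpha >= 1 || any(e$caseP < 0) || any(e$ctrlP < 0) ||
      e$alpha * gamma >= 1 || e$alpha * beta >= 1)
    return(Inf)
  eCase <- e$caseP * sum(oCase)
  eCtrl <- e$ctrlP * sum(oCtrl)
  if (any(eCase <= 0) || any(eCtrl <= 0)) return(Inf)
  sum((oCase - eCase)^2 / eCase) + sum((oCtrl - eCtrl)^2 / eCtrl)
}

#' Fit the Wittke-Thompson disequilibrium-penetrance model
#'
#' Minimizes the 6-cell goodness-of-fit chi-square of the case/control
#' genotype expectations over the free parameters of the chosen genetic
#' model by quasi-Newton (BFGS) descent from 25 Latin-hypercube starts.
#' The baseline risk alpha is eliminated through the prevalence identity,
#' so the general model has 3 free parameters (q, beta, gamma) and the
#' constrained models 2 (q, gamma), with constraints dominant beta = gamma,
#' recessive beta = 1, additive beta = (gamma+1)/2, multiplicative beta =
#' sqrt(gamma) (gamma > 1 for the constrained models). The goodness-of-fit
#' p uses 1 df (general) or 2 df (constrained), and AIC = chi-square +
#' 2 x (number of free parameters).
#'
#' @param cases,controls \linkS4class{GenotypeCounts} ordered rare-hom /
#'   het / common-hom.
#' @param Kp trait prevalence in the general population (fixed).
#' @param model one of "general", "dominant", "recessive", "additive",
#'   "multiplicative".
#' @param nStarts number of Latin-hypercube starts (default 25).
#' @return A \linkS4class{PenetranceModelFit}.
#' @export
fitPenetranceModel <- function(cases, controls, Kp,
                               model = c("general", "dominant", "recessive",
                                         "additive", "multiplicative"),
                               nStarts = 25) {
  model <- match.arg(model)
  stopifnot(Kp > 0, Kp < 1)
  oCase <- as.numeric(cases@counts); oCtrl <- as.numeric(controls@counts)
  betaOf <- switch(model,
    general = function(p) exp(p[2]),
    dominant = function(p) exp(p[2]) + 1,          # beta = gamma
    recessive = function(p) 1,
    additive = function(p) ((exp(p[2]) + 1) + 1) / 2,
    multiplicative = function(p) sqrt(exp(p[2]) + 1))
  gammaOf <- switch(model,
    general = function(p) exp(p[3]),
    function(p) exp(p[2]) + 1)           # constrained: gamma = 1 + e^p > 1
  nFree <- if (model == "general") 3L else 2L
  obj <- function(p) {
    q <- 1 / (1 + exp(-p[1]))
    wtChisq(q, betaOf(p), gammaOf(p), Kp, oCase, oCtrl)
  }
  # reproducible multi-start grid without disturbing the caller's RNG stream
  starts <- local({
    if (exists(".Random.seed", envir = .GlobalEnv)) {
      old <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
    }
    set.seed(1L)
    lhs::randomLHS(nStarts, nFree)
  })
  best <- NULL
  for (i in seq_len(nStarts)) {
    p0 <- numeric(nFree)
    p0[1] <- stats::qlogis(0.01 + 0.48 * starts[i, 1])      # q in (0.01, .49)
    p0[nFree] <- log(0.2 + 9.8 * starts[i, nFree])   # gamma-scale start
    if (model == "general") p0[2] <- log(0.2 + 4.8 * starts[i, 2])
    fit <- try(stats::optim(p0, obj, method = "BFGS",
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  p <- best$par
  q <- 1 / (1 + exp(-p[1]))
  beta <- betaOf(p); gamma <- gammaOf(p)
  alpha <- wtExpected(q, beta, gamma, Kp)$alpha
  df <- if (model == "general") 1 else 2
  new("PenetranceModelFit", model = model, q = q, alpha = alpha,
      beta = beta, gamma = gamma, Kp = Kp, chisq = best$value, df = df,
      p = stats::pchisq(best$value, df, lower.tail = FALSE),
      AIC = best$value + 2 * nFree, nFree = nFree)
}

#' AIC model selection over penetrance-model fits
#'
#' Returns the minimum-AIC fit; exact ties go to the model with fewer free
#' parameters.
#'
#' @param fits list of \linkS4class{PenetranceModelFit} on identical data.
#' @return the selected \linkS4class{PenetranceModelFit}.
#' @export
selectBestModelAic <- function(fits) {
  stopifnot(length(fits) >= 2)
  aic <- vapply(fits, function(f) f@AIC, numeric(1))
  np <- vapply(fits, function(f) f@nFree, numeric(1))
  fits[[order(aic, np)[1]]]
}

#' Permutation association test on a 2x3 genotype table
#'
#' Pearson chi-square on the case/control by genotype table (genotypic
#' model) or on the rare-homozygote-vs-rest collapse (recessive model),
#' with the null distribution obtained by shuffling phenotype labels over
#' the pooled individuals. p = (1 + #{permuted >= observed}) / (B + 1).
#'
#' @param cases,controls \linkS4class{GenotypeCounts}.
#' @param model "genotypic" or "recessive".
#' @param B number of permutations (default 10000).
#' @param seed RNG seed (recorded; required for reproducibility).
#' @return list(p, observed, B, seed).
#' @export
permutationAssociation <- function(cases, controls,
                                   model = c("genotypic", "recessive"),
                                   B = 10000, seed = 1) {
  model <- match.arg(model)
  oCase <- cases@counts; oCtrl <- controls@counts
  collapse <- function(v) if (model == "recessive")
    c(v[1], v[2] + v[3]) else v
  stat <- function(tc, tn) {
    tab <- rbind(collapse(tc), collapse(tn))
    keep <- colSums(tab) > 0
    tab <- tab[, keep, drop = FALSE]
    if (ncol(tab) < 2 || any(rowSums(tab) == 0)) return(NA_real_)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  obs <- stat(oCase, oCtrl)
  if (is.na(obs)) return(list(p = 1, observed = NA_real_, B = B, seed = seed))
  nCase <- sum(oCase)
  geno <- rep.int(1:3, oCase + oCtrl)       # pooled individuals
  set.seed(seed)
  perm <- vapply(seq_len(B), function(b) {
    lab <- sample(geno)
    tc <- tabulate(lab[seq_len(nCase)], 3L)
    tn <- tabulate(lab[-seq_len(nCase)], 3L)
    stat(tc, tn)
  }, numeric(1))
  p <- (1 + sum(perm >= obs, na.rm = TRUE)) / (B + 1)
  list(p = p, observed = obs, B = B, seed = seed)
}

#' Allele frequency and genotype proportions
#'
#' @param counts a \linkS4class{GenotypeCounts}.
#' @return list: rareHomProportion (fraction), rareAlleleFrequency,
#'   genotypeProportions (length-3 fractions).
#' @export
genotypeFrequencies <- function(counts) {
  ct <- counts@counts
  n <- sum(ct)
  list(rareHomProportion = ct[["rareHom"]] / n,
       rareAlleleFrequency = (2 * ct[["rareHom"]] + ct[["het"]]) / (2 * n),
       genotypeProportions = as.numeric(ct) / n)
}
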
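#' @include AllGenerics.R
NULL

#' @rdname nHap
setMethod("nHap", "HaplotypeMatrix", function(x) nrow(x@calls))

#' @rdname nHap
setMethod("nSite", "HaplotypeMatrix", function(x) ncol(x@calls))

#' @rdname haploCalls
setMethod("haploCalls", "HaplotypeMatrix", function(x) x@calls)

#' @rdname haploCalls
setMethod("sitePositions", "HaplotypeMatrix", function(x) x@positions)

#' @rdname haploCalls
setMethod("popLabels", "HaplotypeMatrix", function(x) x@popLabels)

#' @rdname haploCalls
setMethod("ancestralState", "HaplotypeMatrix", function(x) x@ancestral)

#' @rdname haploCalls
setMethod("regionId", "HaplotypeMatrix", function(x) x@regionId)

#' @rdname subsetPop
setMethod("subsetPop", "HaplotypeMatrix", function(x, pop) {
  keep <- x@popLabels %in% pop
  if (sum(keep) < 2)
    stop("fewer than 2 haplotypes in population '", paste(pop, collapse = ","), "'")
  new("HaplotypeMatrix", regionId = x@regionId, chrom = x@chrom,
      positions = x@positions, ref = x@ref, alt = x@alt,
      calls = x@calls[keep, , drop = FALSE],
      popLabels = x@popLabels[keep], ancestral = x@ancestral,
      regionStart = x@regionStart, regionEnd = x@regionEnd)
})

#' @rdname derivedCalls
setMethod("derivedCalls", "HaplotypeMatrix", function(x) {
  m <- x@calls
  anc <- x@ancestral
  if (any(anc == "alt")) {
    flip <- which(anc == "alt")
    m[, flip] <- 1L - m[, flip]
  }
  if (any(anc == "unresolved"))
    m[, anc == "unresolved"] <- NA_integer_
  m
})

#' Subset sites by index
#'
#' \code{x[i, j]} subsets haplotypes (rows) and/or sites (columns) while
#' keeping coordinates, alleles and ancestral states in register.
#' @param x HaplotypeMatrix
#' @param i haplotype index
#' @param j site index
#' @param ... ignored
#' @param drop ignored (always FALSE)
#' @export
setMethod("[", "HaplotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  new("HaplotypeMatrix", regionId = x@regionId, chrom = x@chrom,
      positions = x@positions[j], ref = x@ref[j], alt = x@alt[j],
      calls = x@calls[i, j, drop = FALSE],
      popLabels = x@popLabels[i], ancestral = x@ancestral[j],
      regionStart = x@regionStart, regionEnd = x@regionEnd)
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat("HaplotypeMatrix '", object@regionId, "' (", object@chrom, ")\n",
      sep = "")
  cat("  ", nrow(object@calls), " haplotypes x ", ncol(object@calls),
      " sites\n", sep = "")
  tb <- table(object@popLabels)
  cat("  populations:",
      paste(names(tb), tb, sep = ":", collapse = " "), "\n")
  res <- sum(object@ancestral != "unresolved")
  cat("  ancestrally resolved sites: ", res, "/", length(object@ancestral),
      "\n", sep = "")
})

setMethod("show", "SFSCounts", function(object) {
  cat("SFSCounts: n=", object@n, " S=", object@S,
      " singletons=", object@etaS,
      " pairwise-diff sum=", object@dSum,
      " L=", object@L, "bp\n", sep = "")
})

setMethod("show", "EmpiricalNull", function(object) {
  cat("EmpiricalNull for ", object@statistic, " [", object@population, "]",
      sep = "")
  if (object@binVariable != "none")
    cat(", binned on ", object@binVariable, " (",
        nrow(object@classTable), " classes)", sep = "")
  cat("\n  panel: ", object@panelId, ", ",
      sum(object@classTable$n), " panel values\n", sep = "")
})

setMethod("show", "GenotypeCounts", function(object) {
  cat("GenotypeCounts [", object@cohort, "]: ",
      paste(object@counts, collapse = "/"),
      " (rareHom/het/commonHom), n=", sum(object@counts), "\n", sep = "")
})

setMethod("show", "PenetranceModelFit", function(object) {
  cat("PenetranceModelFit (", object@model, " model)\n", sep = "")
  cat(sprintf("  q=%.4f alpha=%.4f beta=%.3f gamma=%.3f (Kp=%.2f)\n",
              object@q, object@alpha, object@beta, object@gamma, object@Kp))
  cat(sprintf("  chisq=%.3f df=%d p=%.3f AIC=%.3f\n",
              object@chisq, as.integer(object@df), object@p, object@AIC))
})

setMethod("show", "HKAResult", function(object) {
  cat("HKAResult: ", length(object@theta), " loci, ",
      length(object@k), " test locus/loci\n", sep = "")
  cat(sprintf("  T=%.3f k=%s\n", object@T,
              paste(sprintf("%.3f", object@k), collapse = ", ")))
  cat(sprintf("  LRT=%.3f df=%d p=%.4g\n", object@LRT,
              as.integer(object@df), object@p))
})
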
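#' @include methods-HaplotypeMatrix.R
NULL

#' Read phased haplotypes from a VCF
#'
#' Loads phased biallelic SNPs for one region from a VCF file and expands
#' diploid genotypes into one row per haploid chromosome. Multiallelic
#' sites, indels, and sites with any unphased (non-missing) genotype are
#' skipped, with the number of skips reported via \code{message()}. Missing
#' genotypes become missing calls. If the VCF carries the standard
#' \code{AA=} INFO tag the ancestral state is taken from it (an AA matching
#' neither allele gives \code{"unresolved"}).
#'
#' @param file path to a VCF (plain text or bgzipped).
#' @param region list with \code{regionId}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive); see \code{\link{regionSpec}}.
#' @param pops data.frame with columns \code{sample}, \code{pop} (or a named
#'   character vector sample -> pop). Samples absent from it are dropped.
#' @return A \linkS4class{HaplotypeMatrix}; zero usable sites give an empty
#'   (0-column) matrix, not an error.
#' @export
readHaplotypes <- function(file, region, pops) {
  if (is.character(pops) && !is.null(names(pops)))
    pops <- data.frame(sample = names(pops), pop = unname(pops))
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))

  samples <- intersect(colnames(gt), pops$sample)
  if (length(samples) == 0)
    stop("no samples in the VCF match the population map")
  gt <- gt[, samples, drop = FALSE]
  popOf <- stats::setNames(pops$pop, pops$sample)[samples]

  inRegion <- fix$CHROM == region$chrom &
    fix$POS >= region$start & fix$POS <= region$end
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 &
    nchar(fix$ALT) == 1 & fix$ALT != "."
  # a site is unphased if any non-missing genotype lacks the phase separator
  isMissing <- function(g) is.na(g) | g %in% c(".", "./.", ".|.")
  phasedSite <- apply(gt, 1, function(g) {
    g <- g[!isMissing(g)]
    length(g) == 0 || all(grepl("|", g, fixed = TRUE))
  })
  keep <- inRegion & biallelic & phasedSite
  nSkip <- sum(inRegion & !(biallelic & phasedSite))
  if (nSkip > 0)
    message(nSkip, " site(s) skipped (multiallelic, indel or unphased)")

  idx <- which(keep)
  nh <- 2L * length(samples)
  calls <- matrix(NA_integer_, nrow = nh, ncol = length(idx))
  for (j in seq_along(idx)) {
    g <- gt[idx[j], ]
    al <- matrix(NA_integer_, nrow = 2, ncol = length(g))
    ok <- !isMissing(g)
    if (any(ok)) {
      sp <- strsplit(g[ok], "|", fixed = TRUE)
      a <- suppressWarnings(vapply(sp, function(x)
        as.integer(x[1:2]), integer(2)))
      al[, ok] <- a
    }
    calls[, j] <- as.vector(al)    # sample1 hapA, sample1 hapB, sample2 ...
  }
  popLab <- rep(popOf, each = 2)
  hapNames <- paste0(rep(samples, each = 2), c("_1", "_2"))
  rownames(calls) <- hapNames

  anc <- rep("unresolved", length(idx))
  info <- v@fix[idx, "INFO"]
  aa <- toupper(sub(".*AA=([^;]+).*", "\\1", info))
  hasAA <- grepl("AA=", info)
  anc[hasAA & aa == toupper(fix$REF[idx])] <- "ref"
  anc[hasAA & aa == toupper(fix$ALT[idx])] <- "alt"
  if (!any(hasAA)) anc <- rep("ref", length(idx))  # unpolarized input

  HaplotypeMatrix(calls, fix$POS[idx], popLab,
                  ancestral = anc, ref = fix$REF[idx], alt = fix$ALT[idx],
                  regionId = region$regionId, chrom = region$chrom,
                  regionStart = region$start, regionEnd = region$end)
}

#' Write a HaplotypeMatrix as a phased VCF
#'
#' Consecutive haplotype rows (1,2), (3,4), ... are paired into diploid
#' samples. The ancestral state is emitted as the standard \code{AA=} INFO
#' tag so a read/write round trip preserves polarization.
#'
#' @param hap a \linkS4class{HaplotypeMatrix} with an even number of rows.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeHaplotypeVCF <- function(hap, file) {
  n <- nHap(hap)
  if (n %% 2 != 0) stop("need an even number of haplotypes to form diploids")
  ns <- n %/% 2L
  sampleNames <- paste0("S", formatC(seq_len(ns), width = 4, flag = "0"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", hap@chrom, ">"),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleNames), collapse = "\t"))
  m <- haploCalls(hap)
  gtChar <- matrix(as.character(m), nrow = n)
  gtChar[is.na(gtChar)] <- "."
  lines <- vapply(seq_len(nSite(hap)), function(j) {
    aa <- switch(hap@ancestral[j], ref = hap@ref[j], alt = hap@alt[j], ".")
    gts <- paste(gtChar[seq(1, n, 2), j], gtChar[seq(2, n, 2), j], sep = "|")
    paste(c(hap@chrom, hap@positions[j], ".", hap@ref[j], hap@alt[j],
            ".", "PASS", paste0("AA=", aa), "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), file)
  invisible(file)
}

#' Population map for a written VCF
#'
#' Returns the sample -> population data.frame matching
#' \code{\link{writeHaplotypeVCF}}'s sample naming, for round-tripping.
#' @param hap a HaplotypeMatrix with an even number of rows.
#' @return data.frame with columns \code{sample}, \code{pop}.
#' @export
popMapForVCF <- function(hap) {
  ns <- nHap(hap) %/% 2L
  data.frame(sample = paste0("S", formatC(seq_len(ns), width = 4, flag = "0")),
             pop = popLabels(hap)[seq(1, nHap(hap), 2)])
}

#' Region specification
#' @param regionId identifier.
#' @param chrom chromosome.
#' @param start,end 1-based inclusive bounds.
#' @param role one of "test_gene", "control_gene", "flank".
#' @return a list with class \code{"regionSpec"}.
#' @export
regionSpec <- function(regionId, chrom, start, end, role = "test_gene") {
  stopifnot(start <= end,
            role %in% c("test_gene", "control_gene", "flank"))
  structure(list(regionId = regionId, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 role = role), class = "regionSpec")
}

#' Polarize a site by outgroup parsimony
#'
#' Assigns the ancestral state of a biallelic human site from up to three
#' outgroup calls (closest outgroup first, conventionally chimpanzee, then
#' orangutan, then macaque). The ancestral allele is the human allele
#' carried by a strict majority of the informative outgroups (those matching
#' REF or ALT); a tie, or no informative outgroup, gives
#' \code{"unresolved"}. All arguments are vectorized over sites.
#'
#' @param ref,alt human alleles.
#' @param chimp,orang,macaque outgroup base calls (\code{NA} = missing).
#' @return character vector in \code{c("ref","alt","unresolved")}.
#' @export
polarizeAncestral <- function(ref, alt, chimp, orang = NA, macaque = NA) {
  L <- length(ref)
  og <- rbind(rep_len(toupper(as.character(chimp)), L),
              rep_len(toupper(as.character(orang)), L),
              rep_len(toupper(as.character(macaque)), L))
  ref <- toupper(ref); alt <- toupper(alt)
  votesRef <- colSums(og == matrix(ref, 3, L, byrow = TRUE), na.rm = TRUE)
  votesAlt <- colSums(og == matrix(alt, 3, L, byrow = TRUE), na.rm = TRUE)
  out <- rep("unresolved", L)
  out[votesRef > votesAlt] <- "ref"
  out[votesAlt > votesRef] <- "alt"
  out
}

#' Read a BED accessibility mask
#'
#' BED input is 0-based half-open; it is converted to 1-based inclusive
#' internal coordinates on ingest and overlapping intervals are merged.
#' @param file BED path.
#' @return a \code{GRanges} of accessible intervals.
#' @export
readAccessibilityMask <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  GenomicRanges::reduce(gr)
}

#' Accessible fraction of a region
#'
#' Fraction of a region's bases covered by the accessibility mask, plus the
#' keep/drop decision at the 80% threshold used to discard poorly accessible
#' genes.
#'
#' @param region a \code{\link{regionSpec}}.
#' @param mask \code{GRanges} of accessible intervals (or \code{NULL} = all
#'   accessible).
#' @param threshold minimum accessible fraction to keep (default 0.80).
#' @return list with \code{fraction}, \code{keep}, \code{accessibleBases}.
#' @export
accessibilityFraction <- function(region, mask, threshold = 0.80) {
  len <- region$end - region$start + 1
  stopifnot(len > 0)
  if (is.null(mask)) {
    frac <- 1
  } else {
    rr <- GenomicRanges::GRanges(region$chrom,
            IRanges::IRanges(region$start, region$end))
    if (!region$chrom %in% as.character(
          GenomicRanges::seqnames(mask))) {
      frac <- 0
    } else {
      ov <- GenomicRanges::intersect(rr,
              GenomicRanges::reduce(mask), ignore.strand = TRUE)
      frac <- sum(IRanges::width(GenomicRanges::ranges(ov))) / len
    }
  }
  list(fraction = frac, keep = frac >= threshold,
       accessibleBases = round(frac * len))
}

#' Per-site frequency table
#'
#' Derived and minor allele frequencies per population, with resolution and
#' accessibility flags; the input of MAF/DAF-binned empirical nulls.
#' Frequencies use the reduced haplotype count when calls are missing.
#'
#' @param hap a HaplotypeMatrix.
#' @param mask optional \code{GRanges} accessibility mask.
#' @return data.frame: position, ancestralResolved, accessible, then
#'   \code{DAF_<pop>} and \code{MAF_<pop>} per population.
#' @export
siteTable <- function(hap, mask = NULL) {
  pops <- unique(popLabels(hap))
  dm <- derivedCalls(hap)
  raw <- haploCalls(hap)
  out <- data.frame(position = sitePositions(hap),
                    ancestralResolved = ancestralState(hap) != "unresolved")
  acc <- rep(TRUE, nSite(hap))
  if (!is.null(mask)) {
    sites <- GenomicRanges::GRanges(hap@chrom,
               IRanges::IRanges(sitePositions(hap), width = 1))
    acc <- IRanges::overlapsAny(sites, mask)
  }
  out$accessible <- acc
  for (p in pops) {
    rows <- popLabels(hap) == p
    nn <- colSums(!is.na(dm[rows, , drop = FALSE]))
    daf <- colSums(dm[rows, , drop = FALSE], na.rm = TRUE) / pmax(nn, 1)
    daf[nn == 0] <- NA
    nnr <- colSums(!is.na(raw[rows, , drop = FALSE]))
    af <- colSums(raw[rows, , drop = FALSE], na.rm = TRUE) / pmax(nnr, 1)
    maf <- pmin(af, 1 - af)
    out[[paste0("DAF_", p)]] <- daf
    out[[paste0("MAF_", p)]] <- maf
  }
  out
}

#' Site-frequency-spectrum summary of one population
#'
#' Reduces a HaplotypeMatrix to the \linkS4class{SFSCounts} sufficient
#' statistics. Sites with missing calls in the focal population are
#' excluded from all counts (the count of exclusions is recorded); the
#' unfolded SFS \code{xi} uses only ancestrally resolved sites, while
#' \code{S}, the singleton count and the pairwise-difference sum use all
#' complete segregating sites.
#'
#' @param hap a HaplotypeMatrix.
#' @param pop population code (default: all haplotypes).
#' @param L accessible length in bp for per-site scaling; defaults to the
#'   region span.
#' @return An \linkS4class{SFSCounts}.
#' @export
sfsCounts <- function(hap, pop = NULL, L = NULL) {
  x <- if (is.null(pop)) hap else subsetPop(hap, pop)
  n <- nHap(x)
  if (n < 2) stop("need >= 2 haplotypes")
  if (is.null(L)) L <- max(1, x@regionEnd - x@regionStart + 1)
  m <- haploCalls(x)
  complete <- colSums(is.na(m)) == 0
  nExcl <- sum(!complete)
  m <- m[, complete, drop = FALSE]
  cnt <- colSums(m)                       # ALT counts
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  minor <- pmin(cnt, n - cnt)
  etaS <- sum(seg & minor == 1)
  dSum <- sum(cnt[seg] * (n - cnt[seg]))
  # unfolded SFS over resolved sites
  anc <- x@ancestral[complete]
  dcnt <- cnt
  dcnt[anc == "alt"] <- n - cnt[anc == "alt"]
  resolved <- anc != "unresolved"
  xi <- tabulate(dcnt[resolved & seg], nbins = n - 1L)
  new("SFSCounts", n = as.integer(n), S = as.integer(S),
      xi = as.numeric(xi), etaS = as.integer(etaS),
      dSum = as.numeric(dSum), L = as.numeric(L),
      nExcluded = as.integer(nExcl))
}
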
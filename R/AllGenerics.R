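#' @include AllClasses.R
NULL

#' Number of haplotypes / sites
#' @param x a HaplotypeMatrix
#' @return integer(1)
#' @export
setGeneric("nHap", function(x) standardGeneric("nHap"))

#' @rdname nHap
#' @export
setGeneric("nSite", function(x) standardGeneric("nSite"))

#' Accessors for HaplotypeMatrix
#' @param x a HaplotypeMatrix
#' @return slot contents
#' @export
setGeneric("haploCalls", function(x) standardGeneric("haploCalls"))

#' @rdname haploCalls
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' @rdname haploCalls
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))

#' @rdname haploCalls
#' @export
setGeneric("ancestralState", function(x) standardGeneric("ancestralState"))

#' @rdname haploCalls
#' @export
setGeneric("regionId", function(x) standardGeneric("regionId"))

#' Subset a HaplotypeMatrix to one population
#' @param x a HaplotypeMatrix
#' @param pop population code
#' @return a HaplotypeMatrix containing only haplotypes of \code{pop}
#' @export
setGeneric("subsetPop", function(x, pop) standardGeneric("subsetPop"))

#' Derived-allele recoding
#'
#' Recode 0/1 REF/ALT calls so that 1 means the derived allele; columns with
#' unresolved ancestry are returned as NA.
#' @param x a HaplotypeMatrix
#' @return integer matrix of the same shape as \code{haploCalls(x)}
#' @export
setGeneric("derivedCalls", function(x) standardGeneric("derivedCalls"))
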
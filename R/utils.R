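# Small numerical helpers shared across statistics.

# harmonic number a_n = sum_{i=1}^{n-1} 1/i
harmonicA <- function(n) sum(1 / seq_len(n - 1L))

# b_n = sum_{i=1}^{n-1} 1/i^2
harmonicB <- function(n) sum(1 / seq_len(n - 1L)^2)

`%||%` <- function(a, b) if (is.null(a)) b else a

# derived allele count per site for one population, NA where the site has
# missing calls or unresolved ancestry
derivedCounts <- function(hap, pop = NULL) {
  x <- if (is.null(pop)) hap else subsetPop(hap, pop)
  m <- derivedCalls(x)
  cnt <- colSums(m)
  cnt[colSums(is.na(m)) > 0] <- NA_real_
  cnt
}
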
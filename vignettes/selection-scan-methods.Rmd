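---
title: "Methods: selection scans with empirically calibrated nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans with empirically calibrated nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popgenScan)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-data tests do and do not show
about real data.

## Data model

The central object is the `HaplotypeMatrix`: phased 0/1 calls (rows =
haploid chromosomes, columns = biallelic sites) with physical positions,
REF/ALT alleles, per-haplotype population labels, and a per-site ancestral
state. Ancestral states come from outgroup parsimony
(`polarizeAncestral`): the ancestral allele is the human allele carried by
a strict majority of the informative outgroup calls (closest outgroup
first); ties and uninformative sites are `unresolved`. A site that is
`unresolved` simply drops out of every quantity that needs polarization
(the unfolded SFS, Fay & Wu's H, DIND, iHS) — we exclude rather than
guess, and the exclusion count is visible in `SFSCounts@nExcluded` and
the show methods.

Coordinates are 1-based inclusive internally (the VCF convention); BED
masks are ingested as 0-based half-open and converted. Missing calls are
kept as `NA`: a site with any missing call in the focal population uses
the reduced haplotype count for its frequency in `siteTable`, but is
excluded from the SFS summary and from all haplotype-homozygosity
computations. This is the conservative standard; it slightly shortens
regions with patchy coverage rather than biasing pairwise differences
downward.

Accessibility: regions keep/drop at an accessible fraction of 0.80
(strictly below drops), and per-site normalization uses the accessible
length L, not the raw span. The raw-span alternative changes only the
per-site scaling of θ_W and π, never the normalized statistics.

## Diversity and SFS statistics

For a sample of n chromosomes with S segregating sites, unfolded spectrum
ξ_i and pairwise-difference sum Δ:

- θ_W = S / a_n with a_n = Σ_{i<n} 1/i; π = Δ / C(n,2).
- Tajima's D = (π − θ_W)/√(e₁S + e₂S(S−1)) with the 1989 constants.
- Fu & Li's D\* contrasts S with the singleton count η_s (minor count 1,
  polarization-free); F\* contrasts π with η_s. We use the corrected
  starred constants (the ones standard software converged on); they are
  validated in the tests against hand-evaluated values at n = 4 and by
  the neutral-mean calibration below.
- Normalized Fay & Wu's H = (π − θ_L)/√Var with
  θ_L = (1/(n−1)) Σ i·ξ_i, the variance using θ̂ = θ_W and
  θ̂² = S(S−1)/(a_n² + b_n). H uses only ancestrally resolved sites,
  including the S inside its variance — mixing resolved and unresolved
  site counts would miscalibrate the normalization.

S = 0 yields a missing value, never 0: monomorphic windows must not
dilute empirical nulls with fake zeros.

Sliding windows (defaults 5 kb span, 500 bp step) are anchored at the
region start; trailing partial windows are dropped. When a null is
supplied, windows below its 5th percentile are flagged — the familiar
"sweep valley" display.

## FST and haplotype statistics

Per-SNP FST is the Hudson estimator, 1 − H_w/H_b with the n/(n−1)
small-sample correction inside H_w. Negative estimates are reported, not
clamped: clamping would bias every percentile of the empirical null.

EHH at offset x from a core allele is Σ_h C(k_h,2)/C(k_core,2) over
distinct extended haplotypes; curves stop at 100 kb per side or when EHH
drops below 0.05 (the crossing point is kept, so the trapezoidal
integral is conservative). iHS is ln(iHH_A/iHH_D), standardized within
equal-width DAF bins against a calibration panel; lnRsb is
ln(iES₁/iES₂) of integrated site-EHH (pooled alleles, normalized by
focal-site homozygosity), centred by the calibration panel's median and
scaled by its SD. Physical distance is used throughout (no genetic map).

DIND is iπ_A/iπ_D over a *constant* window of 40 flanking variants (20
per side; configurable). SNPs without the full flank complement on each
side get no DIND at all — computing with fewer flanks would silently
change the statistic's null distribution. When the derived class is
perfectly homogeneous (iπ_D = 0) the SNP is flagged and later assigned
the dataset-wide maximum finite DIND plus 20, so such SNPs always rank
above every finite value; DAF classes of the null whose 95th percentile
would fall among these cap substitutes (> 5% capped) are marked
undefined and produce no significance calls — this is why selection on
low-frequency derived alleles is explicitly not detectable here.

## Empirical nulls and the composite caller

Nulls are percentile tables (1st/5th/95th/99th, linear interpolation)
over a control-locus panel, optionally binned in 50 MAF classes (FST) or
100 DAF classes (DIND). Raw panel values are retained per class so a
percentile rank is an exact counting fraction. Classes with fewer than
20 observations are flagged unreliable.

Signature families: diversity (θ_W, π; low tail), SFS (D, D\*, F\*, H;
low tail), differentiation (FST; high tail), haplotype (DIND, iHS,
lnRsb; high tail). A gene is a directional target iff ≥ 3 distinct
families have a statistic past its 5% tail in the same population, or
≥ 2 families are past their 1% tails; tails are strict (rank > 0.95,
not ≥). θ_W and π count as one family — they read the same signature.
The family map is data (`statFamilies()`), so alternative groupings are
testable.

**Gene-level evidence for per-SNP statistics.** A gene's FST/DIND/iHS
evidence is its per-locus maximum, and that maximum is ranked against
the *same per-locus maximum computed on the panel*. Ranking a max over
tens of correlated SNPs against a per-SNP null saturates at rank 1.0
even for neutral loci (we measured ~20% neutral false positives that
way); calibrating at the aggregation level restores uniform neutral
ranks. Per-SNP DAF/MAF-binned ranks are still computed and written to
the SNP tables for locus-level inspection.

Balancing-selection candidates are genes whose whole-gene θ_W or π
exceeds the panel's 95th percentile in at least one population;
candidates are *reported* as balancing targets only when the MLHKA test
rejects neutrality (p < 0.05) in at least one population.

## MLHKA, coalescent p-values, TMRCA

The HKA likelihood is S_i ~ Poisson(k_i θ_i a_{n_i}),
D_i ~ Poisson(θ_i(T+1)), k ≡ 1 at reference loci. Given T and k, the ML
θ_i is (S_i + D_i)/(k_i a_i + T + 1) in closed form, so we maximize the
profile likelihood numerically over log T (null) and (log T, log k)
(alternative) — direct ML rather than the original MCMC, which is
appropriate because our acceptance is property-based (type-I error
3–7% at α = 0.05; median k̂ ∈ [2.4, 3.6] when truth is 3) rather than a
replication of unpublished per-gene fits. The LRT uses χ² with one df
per free k. Fits are per population; whether a shared T across
populations is preferable is data-dependent and left to the caller.

Coalescent p-values condition on θ (not on S):
p = (1 + #{sim ≥ obs})/(iterations + 1). The default demographies are
piecewise-constant stand-ins (constant-size African-like; bottleneck
non-African-like) with all parameters in the config — the calibrated
demographic model of any particular study belongs to its own
configuration, not to this package's defaults.

TMRCA = (mean pairwise difference of each chromosome to the MRCA)/μ,
with μ per region per year = fixed differences/(2 × 6 My) and a
25-year generation time. The MRCA sequence is the ancestral allele at
every segregating site (haplotype-network reconstruction is out of
scope). The SD is a site bootstrap (1000 resamples); a closed-form
variance exists in the literature but depends on assumptions we cannot
verify here, so the bootstrap is reported and labelled in the output
metadata. Against recorded true coalescent TMRCAs the estimator's median
relative error is ~17% at n = 20, θ = 10.

## Association arm

The exact Hardy-Weinberg test enumerates all heterozygote counts with
the observed allele-count parity; the two-sided p sums probabilities not
exceeding the observed configuration's. We use the exact rather than
the asymptotic χ² test as the default because on small tables with rare
homozygotes the asymptotic test is badly anticonservative (on a 3/12/72
table it gives ≈ 0.017 where the exact test gives 0.041).

The Wittke-Thompson model writes case genotype probabilities
(q²αγ, 2q(1−q)αβ, (1−q)²α)/Kp and the control complement, with α
eliminated through Kp = α[(1−q)² + 2q(1−q)β + q²γ]. We minimize the
6-cell goodness-of-fit χ² by BFGS from 25 Latin-hypercube starts
(the objective has local minima; multi-start is cheap insurance), with
model constraints dominant β = γ, recessive β = 1, additive
β = (γ+1)/2, multiplicative β = √γ, all with γ > 1; p uses 1 df
(general) or 2 df (constrained), and AIC = χ² + 2·(free parameters),
i.e. AIC on the goodness-of-fit statistic itself, matching the use of
that statistic as the objective (noted in the output).

Permutation association shuffles phenotype labels over pooled
individuals and compares the Pearson χ² of the 2×3 table (genotypic) or
the rare-homozygote-vs-rest 2×2 (recessive), with the
(R+1)/(B+1) estimator and a mandatory seed. Note that on a 2×2 collapse
label swapping fixes both margins, so the permutation distribution is
exactly hypergeometric — a useful sanity check on any permutation
implementation.

## Synthetic data: what it emulates and what it does not

The coalescent generator is a structured Hudson n-coalescent with
piecewise-constant sizes and clean splits, infinite-sites mutation
(Poisson(θ/2 × tree length) placed uniformly on branches), exact
ancestral states, and recorded true TMRCA. Time is in 2N₀-generation
units; E[π] = θ and E[S] = θa_n are tested to within 3–5% at 5000
replicates. There is *no intra-locus recombination* in the coalescent
generator: SFS-statistic nulls are per-locus quantities and do not need
it, but it does mean simulated loci have stronger internal LD than real
10–20 kb human windows — haplotype-test nulls built from such panels
are conservative about haplotype length.

The forward Wright-Fisher simulator provides sweeps: standing variation
is initialized from a coalescent draw of 2N haplotypes (a valid
mutation-drift-equilibrium state), a central standing variant in a low
frequency band becomes beneficial (fitnesses 1, 1+hs, 1+s), and new
mutations enter at θ/2 single-copy variants per generation (without
this influx a neutral forward run loses rare variants and Tajima's D
drifts positive within tens of generations — we measured +0.8 in 20
generations before adding it). Population sizes are desk-scale
(N ≈ 200–400) with s interpreted as rescaled; recombination is
per-adjacent-pair per generation (default 10⁻⁵). The paired variant
(`simulateSweepPair`) splits one ancestral pool into two populations
that drift for exactly `gens` generations with selection in one — the
positive control for FST/lnRsb contrasts, with the matched neutral
panel generated as a coalescent split at τ = gens/2N.

The penetrance-model generator draws multinomial genotype counts from
the case/control probability vectors, erroring when the implied α is
infeasible.

Panel defaults: per-locus θ log-normal with median 8 per 10 kb
(≈ 0.0008/site, human-like) and sdlog 0.4 (matching the large
across-gene dispersion of real per-site diversity), n = 40 haplotypes,
10 kb loci. The dispersion choice matters: it is the main reason the
*diversity* family alone rarely calls a sweep in the synthetic study —
as in real data, where mutation-rate variation masks moderate diversity
loss and the composite rule carries the specificity.

## Problem sizes used by the test suite

The acceptance properties run at: 2000 neutral replicates (n = 20,
θ = 5) for the SFS-statistic means (all within ±0.15 of 0); 500
simulated panels for MLHKA type-I error and 200 for k recovery; 5000
replicates for the coalescent moment checks; an end-to-end scan with a
120-locus two-population panel, 8 injected sweeps and 5 injected
excess-polymorphism (k = 3) loci; and 30 + 30 forward sweeps vs neutral
loci for DIND/iHS power (one-sided Wilcoxon). These sizes are the
package's chosen desk-scale study conditions; all generators accept
larger values.

Passing these tests shows the machinery is internally calibrated under
the stated models. It does not show robustness to features the
generators do not emulate: sequencing/phasing error, SFS ascertainment
bias of low-coverage data (the motivation for empirical nulls in the
first place), gene conversion, background selection, or fine-scale
recombination-rate variation.

## Known limitations

- Haplotype statistics integrate over physical distance only.
- The composite caller's family map is one defensible reading of
  "distinct signatures"; it is configurable but the default is not the
  only choice.
- DIND is undefined (by design) where the null's DAF class is dominated
  by cap substitutes — selection on low-frequency derived alleles is
  invisible to it.
- The MLHKA implementation assumes free recombination between loci and
  no intra-locus recombination effects on the Poisson counts.
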
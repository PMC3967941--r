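Package: popgenScan
Title: Intra-Species Natural-Selection Scans with Empirically Calibrated
    Outlier Nulls
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects signatures of recent directional and long-term balancing
    selection in phased population haplotype data. Implements site-frequency-
    spectrum neutrality statistics (Watterson's theta, pi, Tajima's D, Fu and
    Li's D* and F*, normalized Fay and Wu's H) per region and in sliding
    windows, per-SNP Hudson FST, extended-haplotype-homozygosity tests (EHH,
    iHS, lnRsb) and the derived intra-allelic nucleotide diversity (DIND)
    test, empirical outlier calibration against a control-locus panel with
    MAF/DAF-binned percentile nulls, a composite directional-selection caller,
    a maximum-likelihood HKA test with coalescent-simulation p-values and
    TMRCA estimation for balancing-selection candidates, and case/control
    association analysis under the Wittke-Thompson disequilibrium-penetrance
    model with exact Hardy-Weinberg and permutation tests. Includes coalescent
    and forward Wright-Fisher simulators that generate every input the
    pipeline needs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'association.R'
    'methods-HaplotypeMatrix.R'
    'io.R'
    'sfs-statistics.R'
    'balancing-selection.R'
    'empirical-null.R'
    'fst.R'
    'haplotype-tests.R'
    'simulate.R'
    'pipeline.R'
    'popgenScan-package.R'
    'utils.R'
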
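Package: rvgene
Title: Rare-Variant Analysis of a Single Gene: Clustering, Severity-Weighted
    Burden Testing, and Allele-Frequency Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for germline rare-variant analyses of a candidate gene:
    parsing HGVS coding-DNA (c.) positions and mapping them to protein residues
    and named protein domains; a permutation test for spatial clustering of
    variants along the coding sequence based on the normalized geometric mean
    of pairwise distances, together with per-domain variant-count enrichment;
    a consequence- and prediction-based integer severity-weight ledger
    (PolyPhen-2/SIFT increments); a severity-weighted sequence kernel
    association (SKAT-type) variance-component score test for binary traits
    with a rare/common variant combination over a convex mixing grid and
    permutation min-p correction; cohort-versus-population allele-count
    enrichment via Fisher's exact or chi-square tests; variant triage by
    allele frequency, in-silico verdict plurality, and functional evidence;
    and a synthetic-data generator (Hardy-Weinberg genotypes, logistic
    phenotypes with weight-proportional effects, clustered or uniform variant
    positions) so the full pipeline is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
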
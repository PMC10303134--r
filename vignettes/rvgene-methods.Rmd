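---
title: "Methods: rare-variant analyses of a single gene with rvgene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant analyses of a single gene with rvgene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvgene)
```

## Scope and motivation

`rvgene` packages the statistical layer of a single-candidate-gene germline
variant study: given a set of annotated variants in one transcript, it asks
(i) whether the variants cluster spatially along the coding sequence or pile
up in particular protein domains, (ii) whether variant carriage is
associated with a binary phenotype once each variant is weighted by its
predicted severity, and (iii) whether individual variants are enriched in
the cohort relative to a population reference. The packaged worked example
is PAM (peptidylglycine alpha-amidating monooxygenase), a 974-residue
bifunctional enzyme with two catalytic cores (PHMcc, PALcc) separated by a
linker and flanked by non-catalytic termini, screened in a
pituitary-adenoma cohort; 16 prioritized coding variants and 7 regulatory
variants ship as `pam_variant_table()`.

Because the cohort and biobank genotype-level data behind such studies are
access-restricted, the package includes a synthetic-data module that
generates inputs with the statistical structure the analyses assume, so
every stage is testable end-to-end without restricted data.

## Coordinates and domain mapping

Positions are HGVS coding-DNA (c.) coordinates: 1-based, closed intervals,
`c.1` the first CDS base, negative anchors in the 5'UTR, `c.*N` in the
3'UTR, and intronic positions expressed as an exonic anchor plus a signed
offset (`c.2332-2` is two bases before the acceptor of the exon starting at
2332). The parser covers substitutions and simple offsets only —
duplications, insertions and other edit grammar are retained verbatim but
not interpreted, and multi-transcript genes are out of scope.

Residue mapping uses ceiling division (`codon n` covers bases `3n-2..3n`),
which reproduces the printed cDNA/protein pairs for all 16 packaged coding
variants. Two conventions deserve emphasis:

* **Intronic variants are projected to their exonic anchor** for all
  position-based statistics. The clustering statistic is normalized to CDS
  length, and a splice variant is biologically tied to the exon boundary it
  disrupts, so the anchor is the least arbitrary location for it.
* **Domain boundaries are configuration, not constants.** Published domain
  annotations for PAM disagree by a few residues at the PHMcc edges (some
  sources end PHMcc near Val351; schematic figures are not base-precise),
  and the proregion/N-terminus distinction is not consistently drawn. The
  packaged map (N-terminus 1–36, PHMcc 37–356, linker 357–497, PALcc
  498–820, C-terminus 821–974) is one defensible choice that reproduces the
  published per-domain counts (4 PHMcc, 7 PALcc, 3 linker, 2 N-terminal);
  it ships as editable JSON and analyses that depend on exact boundaries
  should be read with that freedom in mind. In particular, a published
  N-terminal enrichment p-value of 0.02 depends on an unprinted boundary
  set and is deliberately **not** treated as a reproduction target here;
  the robust, boundary-stable property — the N-terminus shows the largest
  observed/expected excess among the five regions — is what the tests
  assert.

## Spatial clustering statistic

For variant positions $x_1,\dots,x_n$ on a CDS of length $L$ the statistic
is the normalized geometric mean of all pairwise distances,

$$ S = \frac{1}{L}\left(\prod_{i<j} |x_i - x_j|\right)^{2/(n(n-1))}, $$

accumulated in log space. $S$ is dimensionless, translation-invariant until
boundary clipping, scales as $1/L$, and is small when variants cluster. The
permutation test draws $B$ null sets of $n$ positions uniformly from
$[1, L]$ and reports the one-sided add-one empirical p-value
$p = (r+1)/(B+1)$, where $r$ counts null draws at least as clustered as the
data. The add-one convention never returns 0 and is standard permutation
practice.

Null sampling defaults to **distinct** positions (matching observed data,
where positions are unique sites); with-replacement sampling is available
by configuration, in which case a draw with a zero pairwise distance (which
would collapse the geometric mean to 0) is redrawn. With the packaged 16
coding positions and $B = 10^5$ the test reproduces the published
$p \approx 0.35$: the prioritized variants are *not* significantly
clustered.

The per-domain count test converts each residue interval to its codon span
`[3*start-2, 3*end]`, counts variants per domain, and compares against the
same uniform null, one-sided for enrichment. Under with-replacement
sampling the per-domain null count is exactly Binomial$(n, f)$ with $f$ the
domain's CDS fraction, which the tests use as a closed-form oracle.

## Severity weights

The weight ledger maps consequence classes to integers: 5 (UTR, synonymous,
splice region), 10 (protein-altering), 20 (start/stop lost, in-frame
indels), 75 (frameshift, nonsense, canonical splice acceptor/donor), 100
(transcript ablation), and for missense variants 20 plus increments from
PolyPhen-2 (+20 probably damaging, +10 possibly damaging, +5 unknown, +0
benign) and SIFT (+20 deleterious, +0 tolerated). Missing PolyPhen
annotations are treated as "unknown" (+5) and missing SIFT as +0, mirroring
the ledger's explicit "+5 if unknown" for PolyPhen only; SIFT
low-confidence calls inherit their confident counterpart's increment. The
scheme is serializable to JSON so alternative ledgers can be swapped in.

## Weighted association test

The association test is a variance-component score test for binary traits.
A logistic null model `phenotype ~ covariates` is fitted by IRLS; with
residuals $r = y - \hat\mu$, dosage matrix $G$ and weights $w$,

$$ Q = \sum_j w_j^2 \left(\sum_i r_i g_{ij}\right)^2 . $$

Under the null, $Q$ is distributed as a mixture
$\sum_k \lambda_k \chi^2_{1,k}$ where $\lambda_k$ are the eigenvalues of
the weighted, covariate-projected score covariance
$W\,(G'VG - G'VX(X'VX)^{-1}X'VG)\,W$, $V = \mathrm{diag}(\hat\mu(1-\hat\mu))$.
Tail probabilities are computed by Davies-type numerical inversion of the
characteristic function (Imhof's integral), integrating piecewise over
half-periods of the asymptotic oscillation and accelerating the
alternating tail by iterated averaging of partial sums; target tolerance
1e-9, eigenvalues below `1e-10 * max` truncated. If the inversion fails or
the p-value falls below the inversion's resolution, a Liu-type
moment-matching approximation is used and flagged as such. Weights enter
directly as $w_j$ (squared inside $Q$); the common Beta(MAF; 1, 25) weight
convention is deliberately not used, because the ledger above encodes the
intended severity ordering.

**Rare/common combination.** Variants are partitioned at a MAF cutoff
(default 0.1%, strict `<`, on sample MAF unless an explicit per-variant MAF
is supplied). Each partition gets its own $Q$ and analytic p. The combined
statistic is the variance-standardized convex sum

$$ Q(\rho) = \rho\,\frac{Q_\text{rare}}{\mathrm{sd}_0(Q_\text{rare})}
           + (1-\rho)\,\frac{Q_\text{common}}{\mathrm{sd}_0(Q_\text{common})},
   \qquad \rho \in \{0, 0.25, 0.5, 0.75, 1\}, $$

with $\mathrm{sd}_0 = \sqrt{2\sum_k \lambda_k^2}$ from each partition's
null spectrum. The reported combined p-value is the minimum p over the
grid, corrected for the grid search by residual permutation: each of $B$
permutations of the residual vector is pushed through the same grid, each
permutation's per-$\rho$ p is its rank within the permutation distribution,
and the final p is the add-one fraction of permutations whose minimum p is
at least as small as the observed minimum. This convex-sum-with-min-p
construction is this package's concrete realization of an adaptive
rare/common combination; published descriptions of such procedures rarely
print formulas, so the construction is documented here and swappable by
configuration. An empty partition degrades the combination to the
non-empty partition's analytic p; a non-converged null model switches the
partition p-values to their permutation versions.

Missing dosages are imputed to twice the sample allele frequency (the
column mean), which preserves column means and leaves complete matrices
bit-identical.

**Small-sample behaviour.** At desk scale the analytic Davies p for a
partition dominated by singleton/doubleton variants is anticonservative
(the usual small-sample limitation of variance-component score tests for
binary traits without moment corrections; in null simulations at
n = 1,000 the rare-partition analytic test rejected at ~0.11 at nominal
0.05). The combined, permutation-corrected p does not inherit this: its
null rejection rate in the same simulations is ~0.04–0.05. Users wanting
calibrated per-partition inference at small n should rely on the
permutation p (`skat_test(..., cfg = )`).

The exome-wide multiple-testing threshold helper is plain Bonferroni:
0.05 / 25,000 genes = 2e-6.

## Enrichment against a population reference

Cohort-versus-population comparisons build the 2x2 allele table
(alt/ref by cohort/controls) and use the 1-df chi-square test without
continuity correction when all four expected counts are at least 5,
otherwise the two-sided Fisher exact test (point-probability method). This
expected-count rule is the standard realization of "Fisher or chi-square,
as appropriate". Published tables often print control MAFs without allele
numbers; `maf_to_counts()` reconstructs integer counts only under an
explicitly supplied total allele number and marks the result as assumed —
denominators are never invented silently. Carrier frequencies are reported
as percentages rounded half-up to 2 decimals, matching the printed
convention (1/18 = 5.56%).

## Variant triage

`combine_verdicts()` condenses a (pathogenic, uncertain, benign) verdict
count triple into a label by strict plurality, with ties and uncertain
pluralities resolved to VUS. Commercial aggregators weight individual
tools, so some published labels are not reproducible from counts under any
count-only rule (the packaged table records five such rows in its
`plurality_classification` column); the rule is injectable for users who
want to encode a different policy. `flag_rare_deleterious()` flags a
variant when any of the non-mutually-exclusive criteria holds: control MAF
below 1%, in-silico support (likely-pathogenic classification, CADD_PHRED
at or above 15 when verdicts are absent, or an annotated splice/regulatory
effect), or published functional evidence. Missing fields skip their
criterion with a notice, so the flag is monotone in available evidence.
All 23 packaged variants flag under the defaults.

## Synthetic data: what it does and does not emulate

The generator draws Hardy-Weinberg genotypes (`Binomial(2, MAF)`,
independent across variants and individuals), binary phenotypes from
`logit P(case) = logit(prevalence) + beta_scale * sum_j w_j g_ij`, variant
positions either uniform on the CDS or concentrated around uniformly
placed cluster centers (± a spread, deduplicated by redraw), and
cohort/control allele counts as binomials with a multiplicative enrichment
factor. A single master seed feeds a per-generator derived stream, so
adding one generator never perturbs another and every output is a pure
function of (spec, seed).

Deliberately not modelled: linkage disequilibrium, population structure
and relatedness, genotyping error, and covariate-phenotype confounding.
Passing tests therefore demonstrate statistical correctness of the methods
under their stated assumptions — calibration under independence and HWE,
power under weight-proportional effects — not robustness to the
correlation structure of real cohorts. Real analyses should supply
principal components or other structure covariates to the null model.

## Problem sizes and numerical choices

The test-suite simulations use desk-scale sizes chosen to make Monte-Carlo
checks decisive while staying inexpensive: null calibration of the
combined test uses 2,000 replicates at n = 1,000 individuals and m = 20
variants with 500 residual permutations each; the power comparison uses
500 paired replicates at n = 500, m = 10, beta_scale = 0.02 (sized once,
by a small pilot, to put power in the interior of (0, 1) so the
weighted-versus-unweighted ordering is informative); clustering
reproduction uses the published B = 100,000. Tie-breaks and degenerate
inputs: duplicate positions are an error under distinct sampling and a
redraw under with-replacement sampling; a monomorphic (or zero-weight)
partition has Q = 0 and p = 1; add-one empirical p-values never return 0;
`q = 0` returns p = 1 exactly.

## Known limitations

* The HGVS parser is a deliberate subset (substitution-style edits and
  simple offsets); it does not validate edit semantics.
* Domain-boundary-sensitive results inherit the uncertainty of the domain
  map; both the map and the counts are exposed so users can vary them.
* The analytic per-partition p is anticonservative for very sparse rare
  partitions at small n (see above).
* The rare/common combination is a faithful-in-spirit reconstruction of
  adaptive-sum procedures, not a line-by-line reimplementation of any
  specific published algorithm.
* Biobank-scale results depending on restricted genotype data cannot be
  reproduced here; the package reproduces the published summary-level
  analyses (clustering, domain counts, weights, thresholds, enrichment
  arithmetic) and validates the association machinery by simulation.
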
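---
title: "Methods: ROH detection, genomic inbreeding and population structure in rohscan"
author: "rohscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, genomic inbreeding and population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

This vignette is the package's own account of the models and rules it
implements, the parameters that matter, the numerical conventions it
fixes where the field's conventions are ambiguous, and what the
simulation-based validation does and does not establish.

## The data model

`GenotypeData` wraps a `RangedSummarizedExperiment`: one integer assay
`calls` (markers × samples) with codes 0/1/2 counting copies of
`allele2`, `NA` for missing; marker coordinates (1-based bp) as
`rowRanges`; `sample_id` and `population` in `colData`. Validity enforces
unique identifiers, codes in {0,1,2,NA} and position-sorted markers
within each chromosome — the ROH scanner refuses rather than re-sorts, so
sortedness is a container invariant, established once at construction.
Sample order is never changed by any operation.

For text PED input the allele coding is necessarily conventional: PED
stores allele pairs with no designated reference, so `allele1` is the
first non-missing allele observed at each marker (scanning samples in
order, then the two alleles of a pair) and codes count `allele2`. This is
deterministic without an external reference panel, and it is persisted to
BIM on binary export. The consequence, verified in the test suite, is
that a matrix round-trips through PED exactly when it is in this
"first-seen" orientation; otherwise it round-trips up to a per-marker
0↔2 flip with the allele labels swapped — the genotypes themselves are
unchanged. BED/BIM/FAM and VCF round-trips are exact unconditionally,
because both formats store the allele assignment.

## ROH detection rule

A run extends over consecutive position-sorted markers while every call
is a non-missing homozygote and the distance to the previous marker is at
most `maxGapBp`; any heterozygote, missing call, over-gap or chromosome
end closes it. Closed runs are emitted when they contain at least
`minSnps` SNPs *and* span at least `minLengthBp`. Defaults are the
rule set used for 150K-chip cattle data: 1000 kb minimum length, 60 SNPs,
zero heterozygotes, zero missing calls, 1000 kb maximum gap. The two
minima are ANDed: that is the only reading under which both thresholds
constrain the output. No LD pruning is ever applied before ROH detection;
the 1 Mb length floor itself suppresses the short, LD-driven runs that
pruning would otherwise be needed to control.

Numerical conventions the literature leaves open, fixed here and tested:

* run length is `end_bp − start_bp + 1` (1-based inclusive, positions of
  the first and last SNP in the run). The ±1 is irrelevant at Mb scale
  but fixed for exactness.
* length classes <2, 2–4, 4–8, 8–16, >16 Mb are left-closed right-open:
  a run of exactly 4,000,000 bp is classed 4–8 Mb.
* the gap is measured between consecutive markers inside the run; a
  marker that breaks a run by gap can start the next one.
* only the strict zero-het/zero-missing rule is implemented; a tolerance
  window would change the semantics of "maximal run" and is out of scope.

The scanner is validated by set-equality against an independent
brute-force enumerator of maximal valid windows on thousands of random
instances, and by monotonicity properties (raising a minimum never adds
runs; relaxing the gap never removes one).

## Genomic inbreeding

`F_ROH = L_ROH / L_AUT`. `L_AUT` is a property of the dataset, not a
universal constant: for real 150K bovine data the package supplies the
ARS-UCD1.2 chip coverage 2,487,082,459 bp (`bovineAutosomeLength()`); for
simulated or other genotypes the default is the observed covered length,
Σ over chromosomes of (last − first marker position + 1)
(`coveredAutosomeLength()`). Per-class and per-chromosome decompositions
divide the same denominator, so they sum to the total exactly (to one ulp
of floating reassociation).

The excess-homozygosity coefficient is `F = (O − E)/(L − E)` with
`E = Σ_j (1 − 2 p_j (1 − p_j))` over the individual's non-missing
markers. Missing calls are excluded from `O`, `E` and `L` alike.
Frequencies default to the individual's own population
(`freqBasis = "population"`), matching per-breed reporting practice; a
pooled basis is one argument away. Two edge behaviours are defined rather
than left to chance: an individual whose markers are all monomorphic has
`L = E` and is reported as `F = 0` with a `degenerate` flag; and on
adversarial few-marker panels with monomorphic markers the estimator can
drop slightly below −1 (the classic normalisation does not bound it from
below in small samples) — values are reported unclamped. At Hardy–
Weinberg equilibrium `F = 0` exactly; a fully homozygous individual gets
`F = 1`.

## Population structure

**Fixation Index.** Two estimators share one interface. The Wright/Nei
pooled-frequency form — per marker `(H_T − H̄_S)/H_T` with
`H_T = 2p̄(1−p̄)`, `p̄` the unweighted mean of the two population
frequencies, overall value the ratio of sums — is the default and drives
the per-marker outlier scan (strict `F_ST > 0.5`, undefined markers never
outliers). It is the convention of the chip-analysis suites this package
mirrors, but for two demes its expectation under the Balding–Nichols
model is `F/(2−F)`, roughly half the divergence parameter. The
Weir–Cockerham (1984) variance-components estimator (`Σa / Σ(a+b+c)`) is
nearly unbiased for the parameter and is the right choice when the goal
is parameter recovery; the package's recovery tests use it and
cross-check it against an independently coded Hudson-type estimator.
Per-marker Weir–Cockerham values may be slightly negative and are never
clamped. The 95% CI is a seeded bootstrap over markers (1000 replicates
by default); the resampling unit is the marker because the estimator is a
ratio of marker sums.

**PCA.** Missing calls are mean-imputed, markers centred by `2p̂` and
(optionally) scaled by `sqrt(2p̂(1−p̂))`; scores come from the
eigendecomposition of the sample–sample covariance of the standardized
matrix, scaled by the square roots of the eigenvalues. Monomorphic
markers are dropped with a warning. Eigenvalue *scale* is
normalisation-dependent across software; no attempt is made to match any
particular program's printed eigenvalues, and comparisons should use
variance proportions.

**IBD.** PLINK-style method-of-moments: observed IBS0/IBS1/IBS2 counts
against their expectations under IBD state 0/1/2 computed from pooled
allele frequencies, solved sequentially for (Z0, Z1, Z2), clamped to
[0,1] and renormalised; `PI_HAT = Z2 + Z1/2`. The small-sample bias
corrections of the original moment method are omitted — at the marker
counts involved (thousands after pruning) they move estimates by far less
than the decision thresholds. Duplicates are flagged at `PI_HAT > 0.95`.
The first-degree flag is `PI_HAT ≥ 0.5`, deliberately non-strict: an
ideal parent–offspring pair has expectation exactly (Z0, Z1, Z2) =
(0, 1, 0), i.e. `PI_HAT = 0.5`, and a strict inequality would never fire
on the very relationship the flag exists to catch.

**GRM.** VanRaden method 1, `ZZ' / (2Σp(1−p))`, missing entries
contributing zero to `Z` (mean imputation), monomorphic markers excluded.

## QC and LD pruning

Filter order is fixed and idempotent: markers without a positive position
or on non-autosomal chromosomes (cattle autosomes "1".."29") first, then
samples, then markers by call rate, each kept only if its non-missing
fraction is *strictly* above 0.90 ("call rate ≤ 0.90 deleted").

Pruning removes markers greedily inside 50-SNP windows advancing by 5
SNPs until no retained pair within a window has squared Pearson
correlation of genotype codes above 0.5 (pairwise-complete samples). The
pair-resolution rule — drop the lower-MAF member, ties to the higher
index — and the step size are community convention; the proprietary
software whose published marker count (83,776 of 128,180) motivated these
defaults does not document its traversal, so that count is not expected
to be reproducible bit-for-bit even given the same data. The
postcondition (no surviving offending pair in any window) is
self-verifying and audited in the tests; pruned output is invariant to
sample order.

## ROH islands and annotation

Within a population each marker is scored by the number of individuals
whose runs cover its position (each individual once). TOP_SNPs are the
top 1% by occurrence: the threshold is the occurrence at rank
`ceil(0.01·M)` and *all* markers at or above it qualify, so ties can push
the set past the nominal 1% — the natural reading when thresholds are
small integers (occurrence counts). TOP_SNPs are merged into TOP_ROH
intervals while consecutive SNPs are ≤ 1 Mb apart (mirroring the ROH gap
rule; exposed as `mergeGapBp`), with island bounds at the first/last
TOP_SNP positions — not extended to flanking non-TOP markers, the
conservative choice where the convention is unstated. Annotation is plain
interval intersection (≥ 1 bp; half-open arithmetic internally, 1-based
inclusive coordinates on output) against BED or GFF3 features;
consequence-level classification (missense etc.) is out of scope, as are
enrichment analyses. Cross-population comparison reduces to interval
intersection for regions and exact Venn partitions for gene name sets.

## The simulator: what it emulates and what it does not

`simulatePopulations()` draws, per population *k* and marker *j*, an
allele frequency from `Beta(p(1−F_k)/F_k, (1−p)(1−F_k)/F_k)` around an
ancestral `p`, then genotypes as `Binomial(2, p_jk)` — the
Balding–Nichols model, the simplest generative model whose parameter is
the estimand of the F_ST analyses. Per-population `F_k` are fitted to the
requested pairwise matrix by least squares on `fst_ij = (F_i + F_j)/2`
(the Hudson expectation); the default three-population matrix
(0.019/0.050/0.052) reproduces the divergence regime of the three Aosta
breeds, giving `F ≈ (0.021, 0.017, 0.083)`. `F_k = 0` is handled
analytically (subpopulation frequency equals the ancestral draw).

Defaults, chosen once as the desk-scale profile: 3 populations × 50
individuals; 29 chromosomes × 700 markers (~20K markers) on 13.3 Mb
chromosomes, preserving the ~19 kb inter-marker spacing of a 128K-marker
bovine 150K chip scaled down; ancestral MAF uniform on (0.05, 0.5]
(chip-like ascertainment, counted allele randomly oriented); missing rate
0.005 (typical chip call rates), heterozygote-error rate 0. One integer
seed feeds a fixed splitting scheme (one derived stream per operation),
so runs are bit-identical for a fixed seed and stages remain
independently reproducible.

`plantAutozygousSegments()` sets every marker inside a requested tract to
a homozygote by drawing one allele from its population frequency and
duplicating it — tracts keep realistic allele content instead of being
artificially monomorphic. By default the single marker immediately
flanking each tract is set heterozygous (`flankHet = TRUE`). This is a
*validation* feature, not a claim about nature: background genotypes are
homozygous with probability ≈ 0.6 per marker, so an unmarked tract's
detected run would extend a geometrically distributed number of markers
past the true edge and the planted boundary would be unrecoverable in
principle. With the flanking heterozygote, truth boundaries are
identifiable and the recovery tests can demand marker-exact agreement.
Real autozygous tracts carry no such guarantee; recovery statistics on
simulated data are therefore statements about the detector's rule
fidelity, not about boundary accuracy on real chips.

Larger geometries are used where a test requires them: the
planted-segment recovery study runs 10 chromosomes × 2,000 markers
(38 Mb at the same 19 kb spacing) so that tracts up to 30 Mb fit on one
chromosome, and F_ST recovery uses 2 × 200 individuals × 20K markers.

What the simulator does *not* model: linkage disequilibrium and
recombination maps (markers are exchangeable given frequencies), pedigree
structure, phasing, and ascertainment beyond the MAF floor. Passing tests
on this synthetic substrate validate the statistics' implementations and
their parameter recovery under the stated model; they do not certify
behaviour under real LD structure, which is why the ROH caller is
additionally pinned to a combinatorial oracle that makes no distributional
assumptions at all.

## Pipeline

`runPipeline()` executes qc → prune → roh → inbreeding → fst/pca/ibd →
islands → annotation from one YAML config (unknown keys rejected; stage
defaults are the values above). The marker-level F_ST outlier scan runs
on the full QC'd set, while overall F_ST, PCA and IBD/GRM use the pruned
set. Every stage writes plain TSV/BED files, and a JSON manifest records
package version, parameters, input checksums and the seed — enough to
reproduce any run; deterministic stages re-run bit-identically.

## Known limitations

* The Wright/Nei overall F_ST systematically under-shoots the divergence
  parameter for small numbers of demes (see above); use
  `estimator = "weir_cockerham"` for parameter-scale values.
* `F` (excess homozygosity) is not bounded below by −1 on degenerate
  small panels; no clamping is applied.
* Only strict zero-het/zero-missing ROH calling is available; HMM-based
  callers and sequence-data ROH are out of scope.
* Multi-allelic variants are skipped at VCF import; phased information is
  ignored.
* Published island coordinates and pruned-marker counts from proprietary
  pipelines are not bit-reproducible without the original genotypes; the
  package instead pins its behaviour to oracles and ground-truth
  simulations.
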
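---
title: "Methods: fine-scale beta diversity and the rare biosphere"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale beta diversity and the rare biosphere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finescale)
```

## Scope and model of the data

`finescale` analyses replicate 16S rRNA amplicon surveys of the same
habitat: an OTU-by-sample count table whose columns are deep
(tens of thousands of reads) replicate samples taken a millimetre or so
apart. The scientific question is whether the replicates differ in
species membership beyond what incomplete sampling explains, and if so,
which fraction of the community — abundant or rare — carries the
difference. The package assumes the OTU table was produced by joint
clustering of all samples (one OTU label space); it does not cluster
reads itself, and it does not compute reference alignments or taxonomy —
a taxonomy table with a percent-identity column is an input.

## Read quality filtering

Five filters are applied per read, in a fixed order so that per-filter
attrition counts are deterministic: mean Phred quality, exact forward
primer (27F by default), ambiguous bases, homopolymer runs, minimum
length. Defaults are mean quality ≥ 25, homopolymer ≤ 8, length ≥ 80 bp.
Choices the underlying description leaves open, decided here and
configurable:

* length is measured on the primer-trimmed read (`length_after_trim`),
  mean quality always on the full read;
* the primer must match exactly (no IUPAC expansion — 27F is
  unambiguous) at position 0; the reverse primer is not searched for;
* an empty sequence fails the length filter; a quality/sequence length
  mismatch is an input error, not a filter failure.

## Similarity indices

With `a` OTUs shared and `b`, `c` exclusive, the qualitative indices are
Jaccard `a/(a+b+c)`, Sorensen `2a/(2a+b+c)`, Ochiai
`a/sqrt((a+b)(a+c))` and Anderberg `a/(a+2(b+c))`. The Anderberg form is
adopted because it is the unique simple form consistent with reported
qualitative-index tables through the identity `A = J/(2−J)` (sources
using this index family rarely print its formula). The two identities
`S = 2J/(1+J)` and `A = J/(2−J)` are enforced by tests to 1e-12 on
random presence pairs.

Quantitative indices:

* **Bray-Curtis** on raw counts, `2 Σ min(x_i, y_i)/(n+m)` (a
  relative-abundance variant is available), matching the calculator
  convention used by the common OTU-pipeline tools.
* **Chao abundance-based Jaccard and Sorensen**: `UV/(U+V−UV)` and
  `2UV/(U+V)` where `U = Σ_shared x_i/n`, `V = Σ_shared y_i/m`, with
  the Chao bias correction — `U` gains
  `((m−1)/m)·(f_{+1}/(2 f_{+2}))·Σ_{shared, y_i = 1} x_i/n` where
  `f_{+1}`/`f_{+2}` count shared OTUs that are singletons/doubletons in
  the *other* sample; `f_{+2} = 0` is replaced by 1 (the standard
  continuity fix); estimates are clamped to [0, 1]. At realistic depths
  the corrected and raw values agree to printed precision, so published
  tables cannot distinguish them; the correction defaults on.
* **Smith theta**: the plug-in estimator of
  `θ = Σp_i q_i / (Σp_i² + Σq_i² − Σp_i q_i)` with `p_i = x_i/n`.
* **Yue–Clayton theta**: the same ratio with unbiased moment estimators
  `Σ̂p² = Σx_i(x_i−1)/(n(n−1))`, `Σ̂pq = Σx_i y_i/(nm)`, clamped to
  [0, 1] (the moment estimator can leave the unit interval on identical
  or shallow samples; the clamp restores the contract that identical
  columns score 1). The two thetas estimate the same quantity — reported
  values that differ only in the third decimal are estimator-level, not
  estimand-level, differences — which is why both are provided. Tests
  verify `θ_YC → θ_Smith` as counts are scaled up.

All nine indices are symmetric, lie in [0, 1], equal 1 on identical
columns and 0 on disjoint supports (Ochiai and the thetas by the 0/0 → 0
convention).

## Shared-OTU accounting

`venn_summary()` partitions OTUs by their exact occupancy subset and
reports sharing percentages under the *inclusive* convention: an OTU
shared between the x samples of a subset counts even when it also occurs
elsewhere, and the denominator is the number of distinct OTUs observed
across those x samples; the "unshared" percentage of a sample is its
exclusive OTUs over its observed richness. A global-union denominator is
available behind `denominator = "global"` because published summaries
mix the two conventions. Occupancy is validated against brute-force set
enumeration on random tables.

## Rare biosphere definition and sub-classification

Rarity cutoffs are counts (n = 1, ≤ 2, ≤ 5, ≤ 10) or proportions
(≤ 0.004%), converted per sample by `floor(proportion × reads)` — the
largest count not exceeding the proportion. Note that at shallow depths
the conversion can floor to 0, leaving the proportion-defined rare set
empty; it becomes non-trivial at survey-scale depths (0.004% of 77,361
reads is 3). Abundant cutoffs are n > 10 (complementary to n ≤ 10, so
the two sides partition each sample's observed OTUs) and relative
abundance > 1%.

Rare OTUs (pooled across samples at n ≤ 5 by default) are classified in
two stages:

1. **NUNN** (non-unique, non-novel): best hit against the abundant
   representative set has identity > 85% *and* alignment length
   ≥ 100 bp.
2. **UNN** (unique, non-novel): otherwise, best identity to a reference
   database > 85%.
3. **UN** (unique, novel): neither.

"> 85%" is read strictly for both gates. Alignments are exact
Smith–Waterman (match +1, mismatch −1; a length-L gap costs 1 + L, i.e.
−2 to open including the first gap column and −1 per extension),
computed with Biostrings; identity is matches over alignment columns.
Hits are ranked by alignment score — as BLAST ranks them — with ties
broken by identity, then length, then subject id; ranking by identity
alone would let short perfect chance matches (which occur between any
two unrelated sequences) outrank a long, near-identical true relative.
For the same reason, when the reference comparison is done by alignment
(rather than from a precomputed best-identity column, which external
classifiers provide and the package accepts), the ≥ 100 bp length gate
applies to the reference hit as well. Classification is at OTU level
with read weights — per-read classification inside a heterogeneous OTU
could differ, a known simplification.

## Richness model and the shared-singleton null

A mixed-Poisson abundance model with a two-component exponential mixing
distribution has geometric mixture marginals,
`P(k) = w g(k; μ1) + (1−w) g(k; μ2)`,
`g(k; μ) = (1/(1+μ))(μ/(1+μ))^k`. Parameters maximise the
zero-truncated multinomial likelihood of the frequency counts `f(k)` for
`k ≤ τ` with larger counts pooled into a tail cell; optimisation is
multi-start (10 deterministic starts) Nelder-Mead followed by BFGS on
(logit w, log μ1, log μ2). A fit with `w` within 0.005 of a boundary or
coincident component means falls back to a single geometric and is
flagged. Estimated richness is `S_hat = D_τ/(1 − P(0)) + n_{>τ}`,
floored at the observed richness. The truncation point is scanned over
{10, 25, 50, 100, max k}, keeping the highest τ whose goodness-of-fit
chi-square p ≥ 0.05 (best p as fallback). The usual model-selection
criteria for this estimator family (highest truncation point with
acceptable fit, small standard error, low residuals) do not pin down a
scan procedure, so the grid is this package's choice.

The expected-singleton pool defaults to
`N_pool = S_hat − (D − f1)` — species not yet seen at least twice under
a complete census: the estimated undetected species plus the observed
singletons. As a worked example, a sample with D = 18,265 observed
OTUs, f1 = 12,140 singletons and S_hat = 44,959 has a pool of 38,834.
The alternative
reading `S_hat · P(X = 1)` (model-expected singleton count at a
hypothetical complete census) is available behind
`method = "expected_f1"`.

The null model of sharing under incomplete sampling draws `n` reads with
replacement from a pool of `N` equally likely species in each of `R`
virtual replicates, so a species is detected per replicate with
`p = 1 − (1 − 1/N)^n` and occupancy is Binomial(R, p); expected
occupancy-class counts and sharing percentages follow in closed form
(inclusive convention: shared-by-x is `p^x/(1 − (1−p)^x)`, unshared is
`(1−p)^{R−1}`). "Drawing n with replacement" is read literally — fewer
than n distinct species may result; a hypergeometric
(n-distinct-species) reading would change `p` and is not used. A seeded
Monte Carlo mode performs the literal draws; tests require closed form
and simulation to agree within three Monte Carlo standard errors.
Whether published predictions used the closed form or simulation is not
stated; the two agree at the reported precision, so the closed form is
the default. Observed and predicted percentages are compared per class
by Student t-tests (equal variances) with direction flags; classes with
a single data point on either side are skipped with a warning.

## Subsampling test of spatial separation

Three subsamples of fixed depth from one source sample form the
"within" group (no spatial separation by construction) and one
subsample from each of three other samples forms the "across" group; if
membership differences were sampling noise the groups would be
indistinguishable. The three within-subsamples are drawn as a *disjoint
partition* of 3 × size reads by default: reads of a sample are
exchangeable, so disjoint subsamples are independent multinomial draws
and the two groups are exactly exchangeable under a
no-spatial-structure null. Independent (overlap-allowed) draws are
available behind `disjoint = FALSE` but are *not* calibrated: subsamples
sharing physical reads are positively correlated, which deflates
within-group dissimilarity and inflates the test's size severalfold at
typical subsample/depth ratios. (A partition is also what the default
sizes arithmetic supports: three 28,000-read subsamples fit inside an
86,240-read sample.)

Per-class data points follow the subsample bookkeeping: the unshared
class contributes one point per subsample (3 per group), the shared-by-2
class one point per subsample pair (3 per group), the shared-by-3 class
a single point per group (reported, not tested). The *unshared* class is
the primary verdict: its points are one-per-subsample, while the
pairwise points share subsamples and are positively correlated, which
makes the shared-2 t-test anticonservative (measured size 0.14 vs 0.06
at nominal 0.05 in the calibration study below).

## Other tests

* **G-test**: `G = 2 Σ O_ij ln(O_ij/E_ij)` over positive cells (zero
  cells contribute 0, the x ln x limit), df = (rows−1)(cols−1), compared
  to the upper-α chi-square quantile; empty rows/columns are dropped
  with a warning. The default α = 0.008 is the Bonferroni-corrected 0.05
  for the 6 pairwise comparisons of 4 samples.
* **Rarefaction**: mean observed richness over seeded
  without-replacement resamples per depth; the exact hypergeometric
  expectation `Σ_i (1 − C(N−n_i, d)/C(N, d))` is provided separately and
  used as the test oracle.
* **Ordination regression**: NMDS itself is delegated to any standard
  implementation (vegan's `metaMDS` in the analysis drivers);
  `embedding_r2()` takes arbitrary 2-D coordinates and regresses pairwise
  Euclidean distance on similarity, reporting the squared Pearson
  correlation.

## Synthetic communities: what they emulate and what they do not

`generate_community()` draws metacommunity rates from the same
two-component exponential mixture the richness module fits (closing the
recovery loop; a lognormal is available for misspecification checks).
The `core_fraction` most abundant species (default 5%) are present in
every replicate; each remaining tail species is, independently per
replicate, kept with probability 1 − ρ or replaced by a
replicate-specific species of the same abundance. Reads are multinomial
at the configured depth. This is the simplest mechanism that produces
the phenomenon under study — abundant members shared and tightly
clustered, rare members largely replicate-specific — with a single
interpretable knob ρ; there is no explicit spatial field, no chimeras,
and no sequencing error model beyond the planted QC failure modes, so
passing tests demonstrate correctness of the *analysis* under the
stated sampling model, not robustness to artefacts real surveys contain.

Defaults, chosen once as the package's study conditions: mixture
w = 0.7, μ1 = 0.5, μ2 = 50 (a singleton-rich community with a strongly
uneven dominant component); R = 4 replicates; ρ = 0.8 for the study
signature; sequence length 250 bp with planted NUNN/UNN identity targets
of 95% (comfortably clear of the 85% gate, so plant-and-recover tests
are decisive); planting probabilities 0.905/0.05/0.045 reflecting a
typical read-weighted composition of a sediment rare biosphere. The
full-survey (`"paper"`) preset is S = 45,000 species at 75,000 reads
per replicate;
the small preset used throughout the tests and analysis drivers is
S = 2,000 at 5,000 reads, which keeps the full workflow under a minute.

`generate_sequences()` mutates exactly `round(L × rate)` positions, so
planted identities are achieved exactly up to local-alignment end
trimming; `generate_reads_with_quality()` plants exactly one failure
mode per failing read so the QC report has a known expectation.

## Validation studies and their problem sizes

The test suite's validation studies run at these sizes, chosen to keep
the default run under a minute while leaving each check decisive:

* index identities on 1,000 random presence pairs (tolerance 1e-12) and
  nine-index contracts on 30 random tables;
* aligner vs a brute-force affine-gap dynamic-programming oracle on 200
  random pairs of 8–30 bp (score equality, and the implementation's
  matches/columns profile must lie in the oracle's optimal set — ties
  between equally optimal alignments make single-path comparison
  ill-posed);
* Venn occupancy vs set enumeration on 100 random tables;
* shared-singleton closed form vs Monte Carlo on a grid up to
  N = 38,834, n = 12,140, within 3 Monte Carlo standard errors;
* richness recovery over 20 seeded simulations at S = 2,000 with
  expected depth 5,000. At reduced scale the mixture parameters cannot
  all be held at their full-survey defaults: the depth constraint
  `E[N] = S(w μ1 + (1−w) μ2)` must hold, and the package keeps the
  mixture shape (w = 0.7, μ1 = 0.5) while setting μ2 ≈ 7.17 from the
  constraint. This preserves the singleton-rich frequency shape of real
  samples. (Scaling both component means down proportionally instead
  drives P(0) to 0.68 with nearly all of the low-abundance component
  unobserved; total richness is then unidentifiable in practice — an
  information limit of that regime, not an estimator defect.)
* spatial-test calibration: 50 seeded ρ = 0 runs at subsample size
  1,000 (primary verdict significant in ≤ 10%);
* end-to-end signature: 20 seeded ρ = 0.8 communities, requiring the
  rare (n ≤ 5) mean Jaccard below half the abundant (n > 10) mean
  Jaccard.

## Known limitations

* OTU tables must be jointly labelled; independently clustered tables
  cannot be compared (OTU ids are opaque).
* Classification operates on OTU representatives weighted by reads, not
  on individual reads.
* The proportion rarity cutoff floors to zero at shallow depths (by
  construction of the depth-to-count conversion).
* The richness estimator extrapolates unseen species from the fitted
  mixture; when most of a mixture component is unobserved the estimate
  is unstable, and the goodness-of-fit diagnostics (χ², p, truncation
  point) should be inspected before using `S_hat`.
* The Monte Carlo null and all subsampling are seeded; results are
  reproducible bit-for-bit only with the same seeds.
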
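---
title: "Methods: models, estimators and design choices in germdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in germdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germdiv)
```

germdiv characterizes SNP-genotyped germplasm collections whose defining
features are (i) deep two-way population structure, (ii) very high selfing,
and (iii) structure-dominated linkage disequilibrium. This vignette
explains the statistical machinery, the synthetic data that backs the test
suite, and the places where the design was genuinely open and a choice had
to be made.

## 1. Data model

Genotypes are alternate-allele dosages in {0, 1, 2, NA}, accessions ×
markers. Allele frequencies are always estimated from typed calls,
`p = (2n₂ + n₁) / (2n_typed)`; the alternate allele is whatever the input
file called alternate and is never re-polarized. Marker metadata carry
chromosome, 1-based position, and QC fields; sample metadata carry gene
pool, stratum (landrace vs cultivar/line), and optional coordinates.

PIC defaults to the DArT-report convention `1 − Σp²` (maximum 0.5 for a
biallelic locus), because reported PIC ranges reaching 0.5 are only
attainable under that convention; Botstein's
`1 − Σp² − 2p²q²` is available via `pic_convention = "botstein"`.

## 2. Diversity and F-statistics

Per locus and group: `He = 2pq`, unbiased `uHe = He·2n/(2n−1)`,
`Ho` = heterozygote fraction among typed, `F = 1 − Ho/He` where `He > 0`.
Group summaries report means over defined loci with `SE = sd/√L`.

Hierarchical F-statistics use the Nei decomposition with unweighted
subpopulation means: per locus `Hs` = mean subpopulation `He`, `Ht` = `He`
of the mean allele frequency, `H̄o` = mean subpopulation `Ho`, and

```
F_ST = (Ht − Hs)/Ht,  F_IS = (Hs − H̄o)/Hs,  F_IT = (Ht − H̄o)/Ht,
```

so `(1 − F_IT) = (1 − F_IS)(1 − F_ST)` holds exactly per locus (a unit
test asserts it to 1e-12). Two forms are reported:

* **per-locus means ± SE** — the layout of classic germplasm reports;
* **multilocus ratio-of-means** (`$multilocus`) — Nei's Gst computed from
  locus-averaged heterozygosities.

The distinction matters in this domain: at divergence near 0.75 most loci
sit close to fixation in one or both pools, the per-locus ratio is
dominated by those near-degenerate terms, and its mean is far below the
generative divergence. The ratio-of-means form is the quantity our
simulator calibration targets and the one used for recovery checks.

Probability of identity per locus is `Σpᵢ⁴ + Σᵢ<ⱼ(2pᵢpⱼ)²`, accumulated in
log space across loci. The probability of exclusion uses **one-parent
exclusion** by exhaustive enumeration of HWE mother/offspring
configurations (a random non-father is excluded when neither of his
alleles can complete the offspring genotype); published germplasm tables
rarely state which exclusion formula they use, so the one-parent form was
chosen as the most common default and validated against a Monte-Carlo
oracle. Combined PE is `1 − Π(1 − PE_l)`.

Group summaries exclude accessions labelled admixed or unknown, mirroring
the convention of dropping structure-unassigned accessions (max q below
0.7) from pool-level tables.

## 3. Windowed genome scans

Chromosomes are tiled into non-overlapping 100-kb windows. The window
type's prose convention (1-based inclusive start) conflicts with the
worked assignment example (position 100,000 in the second window); we
follow the example: assignment is `pos %/% L + 1` and windows are reported
BED-style.

With SNP-only panels there are no observed invariant sites, so per-site
magnitudes of `θ_W = S/aₙ` and π depend entirely on the normalization
denominator. Both normalizations (window length in bp; genotyped marker
count) plus the raw sums are exposed, and no published per-site magnitude
is treated as a recovery target. Tajima's D uses the 1989 constants with
`n` = 2 × group size and the per-locus pairwise-difference sum
`x(n_l − x)/C(n_l, 2)` over typed chromosomes — a deliberate approximation
when missingness makes `n_l` vary by locus (exact on complete data, where
it matches an independent textbook implementation in the tests).

Window FST defaults to the Hudson ratio-of-sums `1 − ΣH_w/ΣH_b`
(`H_b = p_a(1−p_b) + p_b(1−p_a)`), the standard robust choice for window
scans; the Nei form is available for consistency with the diversity module.

## 4. Outlier detection

**FDIST-style envelope.** The null is a hierarchical island world: two
groups, two demes per group. Ancestral frequency uniform on (0.02, 0.98);
group frequencies by Balding–Nichols divergence at the between-group tier;
deme frequencies by a second tier; binomial sampling at the observed deme
sizes; 20,000 simulated loci by default. Both tiers are calibrated by
method of moments from the observed hierarchical F-statistics (the
calibration used by the original tools is not published). Observed and
simulated loci are summarized identically (total heterozygosity and
between-group Nei FST), simulated loci are binned into equal-count
heterozygosity bins (≥200 per bin), and loci outside the central 95% are
flagged.

One numerical subtlety: the null FST distribution has *atoms* — loci fixed
in every deme give FST exactly 1 — and a plain empirical envelope
under-rejects (type-I ≈ 3% instead of 5%). The decision therefore uses
randomized tail probabilities (uniform tie-splitting), the textbook
correction for discrete test statistics, which restores exact size;
conservative (non-randomized) p-values are still reported per locus.

**Bayesian logistic-FST model.** Per locus i and subpopulation j,
`logit F_ij = α_i δ_i + β_j`; deme frequencies are Balding–Nichols around
an ancestral `p_i` and are integrated out analytically, giving a
beta-binomial marginal for the allele counts. `δ_i` is a spike-and-slab
inclusion indicator (prior inclusion 1/11, i.e. prior odds 10 for
neutrality; slab `α ~ N(0, 2)`; `β_j ~ N(−1, 1.8)`). This replaces a
literal reversible-jump sampler with an equivalent posterior quantity that
is simpler to test. Pilot runs tune random-walk scales toward ~30%
acceptance; the decision statistic is the posterior inclusion probability
converted to q-values (cumulative mean of 1 − PIP down the ranking, made
monotone), flagged at q < 0.05.

A caveat stated plainly: with two populations the per-locus evidence is
two frequency draws, so power depends on how extreme selected loci are
relative to the background overdispersion. On a background of FST 0.1 even
antithetically fixed loci are ≈2σ events and no method reaches 80% power;
the power acceptance world therefore uses a within-pool-scale background
(FST 0.02, the stratum-level differentiation of such collections) with
selected loci swept to near-fixation (boost 0.7). Under that world the
sampler attains full power at essentially zero false-positive rate.

## 5. Linkage disequilibrium

Pairwise LD is the squared Pearson correlation of dosage vectors
(composite LD) — with ~4% heterozygosity, phase-aware haplotype r² would
add nothing but EM noise, and the dosage convention matches how
structure-corrected LD is defined. The corrected `r²_SV` whitens both
dosage vectors by `K^(−1/2)` (kinship eigenvalues floored at 1e-6 — a
Yang-diagonal GRM is mildly indefinite by construction), projects out the
whitened intercept and K−1 admixture columns, and correlates the
residuals. With identity kinship and no covariates this reduces *exactly*
to r² (asserted to machine precision); on a constructed fixture whose LD
is purely inter-pool divergence, correction collapses median r² from >0.4
to <0.01.

The GRM uses standardized dosages with Yang's inbreeding-adjusted
diagonal, per-pair averaging over jointly typed markers; monomorphic
markers are dropped with a count.

LD decay is fitted with the Hill–Weir drift expectation

```
E[r²](C) = (10+C)/((2+C)(11+C)) · [1 + ((3+C)(12+12C+C²))/(n(2+C)(11+C))]
```

with `C = ρd`, by least squares over a log-spaced ρ grid refined by 1-D
optimization (the problem is one-dimensional; a multi-start grid makes
convergence a non-issue). Raw pairs are fitted by default; distance-binned
means are an option since published fits do not always say which was used.
The half-decay distance solves `E[r²](d) = E[r²](0⁺)/2` by bracketed root
finding, with the d→0⁺ fitted value as the "maximum" reference.

Pruning uses a sliding marker-count window (defaults 50/5, the dialect of
the commercial tool being unstated) with a deterministic drop rule: lower
call rate, then lower MAF, then later position. A window spanning all
markers reproduces exhaustive O(m²) pruning, which is how the oracle test
checks it. Panel selection filters (call rate ≥ 0.75, MAF > 0.05,
polymorphic in every pool), prunes at r² < 0.5, then fills per chromosome
by greedy max-min spacing.

## 6. Haplotype blocks

Heterozygous calls are treated as missing — in a selfer nearly all calls
are homozygous, so two-locus haplotype counts can be read directly from
the remaining genotypes. The general EM over double-heterozygote phase
ambiguity is provided for `het_as_missing = FALSE` and tested against a
likelihood grid search. D′ confidence intervals evaluate the multinomial
likelihood of the gamete counts on a |D′| grid (step 0.001, allele
frequencies fixed at their MLEs) and take the cumulative 5%/95% points;
Gabriel categories are strong LD (CI low ≥ 0.70, high ≥ 0.98) and strong
recombination (high < 0.90). Block finding keeps candidate spans whose
outermost pair is strong LD and whose informative pairs are ≥ 95% strong
LD, selected greedily by span with leftmost tie-break; the extra
size-stratified CI rules of the original desktop tool are deliberately
simplified to this core rule (documented deviation — per-group block
counts from that tool are not recovery targets).

## 7. Structure, trees, space

The admixture estimator is a maximum-likelihood EM on allele copies
(`x log Σq_k f_k + (2−x) log Σq_k(1−f_k)`), restarted from random points.
It is a stand-in, not a replica, of Bayesian MCMC clustering: its two
concrete jobs are supplying the structure covariates for r²_SV and the
q ≥ 0.7 assignment rule (below threshold → admixed). Likelihood
monotonicity is asserted every iteration.

Dendrograms: simple-matching dissimilarity (mismatch fraction over jointly
typed loci, genotype states {0,1,2}) feeding neighbor-joining (ape), with
bootstrap over loci and majority support on internal edges; negative NJ
branch lengths are clamped to zero with a count.

Spatial diversity lays a regular grid (50-km default step — the published
"hierarchical procedure" is under-specified, so a regular grid is used)
and pools allele frequencies of accessions within a 150-km haversine
radius (mean Earth radius 6371 km). A single-accession neighborhood
reports that accession's own-frequency He (heterozygous loci contribute
0.5) — the chosen reading of "diversity only for this accession"; the
alternative (proportion of heterozygous loci) is a one-liner on the pooled
path.

## 8. The synthetic germplasm generator

`simulate_collection()` is the stated world the tests run in. Defaults: 64
+ 111 accessions in two pools plus 6 admixed; two strata per pool;
11 chromosomes × 47 Mb; 5000 markers; pool divergence target 0.75; stratum
divergence 0.02; selfing coin 0.6; 8% missing calls; 1% divergent-selection
loci (boost 0.2); ancestral frequencies uniform on [0.05, 0.95].

Mechanics and the reasoning behind them:

* **Divergence calibration.** Pool frequencies are Balding–Nichols draws
  `Beta(pλ, (1−p)λ)`, `λ = (1−F)/F`. For two pools, `E[Hs] = 2pq(1−F)` and
  `E[Ht] = 2pq(1−F/2)`, so the multilocus Nei FST has expectation
  `(F/2)/(1−F/2)`; inverting gives `F = 2t/(1+t)` for target t. This was
  derived before any acceptance measurement; realized recovery at 5000
  loci is within ±0.015 of target across seeds.
* **LD without drift.** Each stratum gets founder haplotypes (60 by
  default) drawn from its frequencies; emitted haplotypes are founder
  mosaics with Poisson(generations × rate × length) breakpoints. LD decays
  with distance while marker frequencies stay pinned to the founder sample
  (no Wright–Fisher resampling — an earlier design drifted the realized
  FST upward by ~0.03). Pool 1 uses a lower crossover rate, giving the
  slower decay expected of the less recombined gene pool.
* **Selfing** is a per-accession IBD coin: with probability `selfing_F`
  the two gametes are identical, so `Ho/He ≈ 1 − selfing_F` within a
  panmictic pool (asserted as a test property of the generative rule).
  No explicit pedigree generations — sufficient for every statistic here.
* **Admixture.** Admixed accessions get true q from Beta(5,5) truncated to
  [0.3, 0.7] and build each gamete as a chromosome-level mosaic (each
  chromosome from pool 1 with probability q). Drawing one source pool per
  genome would collapse selfed admixed accessions to pure types.
* **Selection.** Divergent-selection loci are antithetic near-fixations:
  `p₁ = 0.5 + d`, `p₂ = 0.5 − d` with `d = √(base+boost)/2`, random
  direction, pinning the per-locus Nei FST at base + boost. A
  Balding–Nichols draw at a boosted target frequently realizes *no*
  divergence, which would make planted signals undetectable in principle.
* **Neutral panel.** For Tajima's-D calibration a separate generator draws
  derived-allele counts from the neutral 1/x spectrum and places them on
  sampled chromosomes, so D is centered at zero by construction.

What the generator does **not** emulate — and hence what a green test does
not establish: ascertainment of the real genotyping platform (real panels
are enriched for intermediate-frequency SNPs, giving whole-collection He
near 0.44 where this world gives ≈0.20, and within-pool He of 0.10–0.17
where this world gives ≈0.05); realistic recombination maps and
centromeric structure; linked selection; genotype-calling error. Magnitude
comparisons against published diversity tables are therefore out of scope;
structural and recovery properties are in scope.

## 9. Numerical and degenerate-input conventions

Monomorphic loci: skipped in F-statistics (`Ht = 0`), contribute `PI = 1`,
`PE = 0`, uninformative for D′. All-missing markers are flagged, never
silently dropped. Tajima's D with `S = 0` is NA, never 0. Empty windows
report `S = 0` with zero diversity. The q-value ranking is made monotone
by a reverse cumulative minimum. Pruning and panel selection are fully
deterministic; all stochastic stages take explicit seeds and the pipeline
is byte-identical under a repeated seed.

## 10. Known limitations

* The Bayesian sampler assumes the 2N sampled chromosomes are independent;
  under strong selfing they are not, so its evidence is mildly
  overconfident (conservative prior odds of 10 compensate in practice).
* Tajima's D uses a single n per window with per-locus typed counts only
  in the pairwise term (exact under complete data).
* The FDIST observed statistic conditions on total heterozygosity in
  equal-count bins; kernel conditioning is not implemented.
* Haploview's short-span CI refinements are not reproduced; block counts
  should be compared qualitatively across tools.
* The CLI is a thin dispatcher (`simulate`, `run-all`); per-stage
  subcommands are exposed as R functions rather than shell verbs.
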
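---
title: "sexbiome: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sexbiome: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexbiome)
```

## The problem

In several insect groups one sex produces far more of a defensive or
signalling compound than the other — male blister beetles (Meloidae) and
cantharidin are the canonical case — and a recurring hypothesis is that
symbiotic bacteria participate in the compound's biogenesis.  If so, the
responsible taxa should be enriched in the producing sex *consistently
across related host species*, not just in one.  `sexbiome` implements that
screen for 16S amplicon data: given an ASV count table and sample metadata
(host species, sex, population), it quantifies per-species male enrichment
of every ASV and asks in how many species the enrichment recurs.  A single
species' enrichment is weak evidence (heavy-tailed community data produce
many one-off differences); recurrence across all species sampled is the
interesting signal.

## The pipeline

1. **Exclusion.** Samples with fewer reads than the rarefaction depth
   cannot be rarefied and are excluded; the boundary is inclusive (a sample
   at exactly the depth is kept).  This is the only self-consistent
   exclusion rule once a rarefaction depth is chosen, so the package uses
   the depth itself as the threshold rather than a second free parameter.
2. **Rarefaction.** Each remaining sample is subsampled *without
   replacement* to exactly `depth` reads — a multivariate hypergeometric
   draw, the ecological convention — so all samples contribute equal
   sequencing effort and per-sample proportions are directly comparable.
   Sampling with replacement would inflate the variance of rare ASVs and
   was rejected.
3. **Group means.** For each (species, sex) the mean of per-sample
   proportion vectors is taken (the mean of proportions, not the proportion
   of pooled reads).  After rarefaction to equal depth the two definitions
   coincide; the mean-of-proportions form is used because it stays correct
   if a caller skips rarefaction.
4. **The i index.** For each ASV and species, `i = (M' − F')/M'` with
   `M' = max(M, floor)`, `F' = max(F, floor)`.  `i` is 0 when the floored
   means are equal (including when both sexes lack the ASV), positive when
   males carry more, at most 1 (never exactly 1, since `F' ≥ floor > 0`),
   and unbounded below — the index is deliberately asymmetric, reading
   enrichment relative to the male mean.
5. **Tally and candidates.** ASVs are partitioned by the exact number of
   species with `i > 0` (strict: `i = 0` counts as not enriched, making
   "enriched nowhere" the complementary class), and those positive in at
   least `min_species` species are reported with their per-species `i`
   values, blanking cells where `i ≤ 0`.

### The pseudocount floor

The floor is derived, not tuned: at rarefaction depth `d` with at most
`r_max` replicates per sex–species group, the smallest non-zero mean
relative abundance any ASV can show is one read in one replicate,
`(1/d)/r_max = 1/(d · r_max)`.  At the defaults (`d = 428`, `r_max = 6`)
this is `1/2568 ≈ 3.894 × 10⁻⁴`.  Both `M` and `F` are clamped from below
at the floor — not only exact zeros — because clamping only zeros would
make `i` discontinuous as a mean crosses zero: a mean of `10⁻⁹` and a mean
of 0 should not give materially different indices.
`pseudocount_floor(value =)` overrides the constant while keeping the
derived denominator on record, for users who want a different convention.

### What the screen is not

`i` is a descriptive measure.  No per-ASV significance is attached and no
multiple-testing correction is applied to the consistency tally; the
package instead supplies a generator and recovery harness (below) so the
screen's sensitivity and null behaviour can be measured under a known
truth.  Count-model tests (negative-binomial Wald and similar) are outside
the package's scope.

## Diversity components

These are the standard descriptive companions of the screen, computed on
the rarefied table.

* **Shannon index** in natural log (nats) by default — the convention of
  the R ecosystem's diversity functions — with the base configurable.
  Computed via `vegan::diversity`.
* **Wilcoxon rank-sum** (two-sided) for group comparisons of per-sample
  statistics, exact when both groups are ≤ 49 tie-free observations and
  normal-approximated with mid-rank tie correction otherwise (the
  `stats::wilcox.test` behaviour).  **Benjamini–Hochberg** adjustment is
  applied across whatever family of comparisons the caller supplies — the
  family is a scientific choice (e.g. one comparison per host species), so
  the package does not guess it.
* **Bray–Curtis** via `vegan::vegdist`; **weighted UniFrac** implemented
  in-package as the branch-wise sum `Σ l_b |A_b − B_b|` over a rooted
  tree's edges, with the normalized variant (divide by `Σ l_b (A_b +
  B_b)`, bounded in [0, 1]) as the default because it is comparable across
  libraries; the raw variant is a flag away.  The implementation is
  cross-checked in the test suite against an independent naive
  tip-path-accumulation oracle and against `phyloseq::UniFrac`.
* **PCoA** by Gower double-centering (`stats::cmdscale`); negative
  eigenvalues (non-Euclidean distances) are reported but excluded from
  coordinates and from the variance-explained denominator, with a recorded
  warning if fewer positive axes exist than requested.
* **PERMANOVA** one-way, free permutation of labels, via `vegan::adonis2`
  — 999 permutations by default, p = (1 + #{F* ≥ F})/(1 + n), which can
  never be 0.  Multi-factor and stratified designs are out of scope; the
  questions addressed here are single-factor (sex, species).

## The synthetic-data generator

`simulate_dataset()` emulates the post-denoising state of a multi-species,
two-sex amplicon study.  Defaults are the study conditions the package is
designed around:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 5 | host species |
| `replicates` | 6 | biological replicates per sex per species |
| `n_asvs` | 500 | ASV richness before rarefaction |
| `concentration` | 20 | Dirichlet concentration of per-species baselines; low values give the strong species-specific communities real insects show |
| `base_sdlog` | 2 | log-normal base measure: a few dominant ASVs, a long rare tail |
| `theta` | 0.02 | Dirichlet-multinomial overdispersion; per-sample composition variance ≈ p(1−p)·θ, giving realistic replicate scatter (θ → 0 is multinomial) |
| `depth_meanlog`, `depth_sdlog` | log(30000), 1 | log-normal library sizes spanning roughly 3×10³–3×10⁵ reads |
| `shallow_depths` | 55, 61 | two forced failed libraries, assigned to random samples |
| `spike_baseline` | NULL | optionally force spiked ASVs' baseline proportion, making effect sizes a condition rather than a draw |

Male enrichment is injected compositionally: the male expectation is the
female baseline with spiked entries multiplied by their fold-change `f ≥ 1`
and the vector renormalized, which keeps proportions valid at any `f`
(adding reads instead would not).  Shared spikes recur in every species;
species-specific spikes in one.  Taxonomy is drawn from a small fixed
lineage pool that includes the genera such screens are typically asked
about (*Cutibacterium*, *Staphylococcus*, an Enterobacteriaceae genus), so
taxon-level screens are exercised by name; the phylogeny is a random
coalescent over the ASVs (`ape::rcoal`).  One RNG stream per dataset,
fully determined by the config seed.

**What the generator does not emulate:** sequencing error, chimeras,
primer/copy-number bias (all upstream of the package's inputs), real
phylogenetic correlation between abundance and taxonomy, and
population-level structure within species (population labels are carried
but no population effect is simulated).  Passing recovery tests therefore
show the *screen* behaves as designed under a known truth — not that any
particular real dataset satisfies the generator's assumptions.

## Recovery and null calibration

`run_recovery()` repeats simulate → screen → score over sequentially
derived seeds (master seed + run index, for auditability).  Sensitivity is
defined on shared spikes only — the fraction appearing in the all-species
candidate list; species-specific spikes are a separate class.  Under the
default-sized design with three shared spikes at 1% baseline and `f = 10`,
a 10-fold expectation gap at depth 428 with 6 replicates is ≈ 4–5 standard
errors of the group-mean difference, so recovery is expected in virtually
every run — the acceptance suite requires ≥ 95% of 100 runs.

`null_calibration()` runs the same loop on a spike-free config and reports
the distribution of the all-species-positive count — the reference against
which a small observed count (e.g. 2 of ~2000 ASVs) can be judged.  It
refuses configs containing spikes rather than silently ignoring them.

## Numerical and design notes

* **Rarefaction algorithm.** A chained hypergeometric draw
  (`stats::rhyper` per ASV, conditioning on reads and slots remaining) is
  equivalent to drawing the reads uniformly without replacement but runs in
  O(richness) per sample with no read-level expansion.  Each sample's
  sub-seed is derived from the user seed plus a deterministic hash of the
  sample id, so a sample's draw is invariant to column order and to which
  other samples are present.
* **Determinism.** Every stochastic entry point (`rarefy`,
  `simulate_dataset`, `random_tree`, `permanova`, the harnesses) takes a
  seed and restores the caller's RNG state afterwards.
* **Degenerate inputs.** All-zero samples are rejected where proportions
  are needed; a species missing one sex is an error naming the species;
  an all-excluded table is an error rather than an empty result; ASVs with
  zero reads after rarefaction are dropped from the screen (they carry no
  information at the analysis depth).
* **Candidate ordering** (positive-species count desc, mean positive `i`
  desc, ASV id asc) is an artifact convention chosen to make reports
  deterministic; no biological meaning attaches to it.
* **Test problem sizes.** The suite exercises the study-sized design (500
  ASVs, 60 samples) for end-to-end checks, 100 replicate runs for
  recovery, 200 replicates for the PERMANOVA null band, and small
  enumerable instances (≤ 6 samples) wherever an exhaustive oracle is the
  comparison.  These sizes give Monte-Carlo error comfortably inside the
  asserted bands while keeping the default run fast.
* **Null calibration of PERMANOVA** is checked on a single-species 6+6
  design, where free label permutation is exactly valid; with several
  species and balanced sex labels, free permutation across species is only
  approximately exchangeable and the test would be conservative.

## Known limitations

* The `i` index compares means of heavy-tailed proportions from few
  replicates; a single dominant replicate can flip its sign.  The
  cross-species consistency requirement is the guard, not any per-species
  inference.
* Weighted UniFrac assumes the supplied tree is rooted and spans every
  ASV; the package refuses rather than pruning silently.
* Rarefaction discards data by design; depth is a config default (428),
  chosen by the caller to trade sample retention against resolution, and
  nothing in the package revisits that choice automatically.
* The CLI covers the four pipeline stages with one YAML config per run;
  it is a thin wrapper over the exported functions, which remain the
  primary interface.
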
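---
title: "IBD graphs: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IBD graphs: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ibdmap)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
simulator emulates, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` do not themselves compute.

## 1. The IBD-graph representation

Location-specific identity by descent for a set of individuals at one
genomic position is a partition of their haplotype slots (`id.0` paternal,
`id.1` maternal — a single global convention, so no phase bookkeeping
leaks between modules) into founder-genome-label classes. An
`ibd_graph_set` stores `K` realizations of such partitions along a marker
grid as change-points: a new partition is recorded only when the induced
set-partition changes, not when the underlying inheritance vector does.
Partitions identical up to class relabeling are the same object; all reuse
(LOD caching, change-point compression) keys on the canonical
first-appearance relabeling (`canonical_key()`).

Positions are genetic (cM); recombination follows the Haldane map
function, $\theta = (1 - e^{-2d/100})/2$, with no interference —
consistent with each meiosis being a Markov chain along the chromosome.
Inheritance is autosomal; sex is read from pedigree files but never used
in transmission.

## 2. Conditional inheritance-vector sampling

`sample_ivs()` draws from the exact posterior over inheritance-vector
paths given unordered biallelic genotypes on a sparse panel: uniform IV
prior, bitwise-independent transitions with the per-interval Haldane
fraction, and single-locus emissions that sum penetrances over
founder-allele assignments (per-allele error `eps`, default 0.01 — chosen
to tolerate Mendelian-consistent genotyping errors, which otherwise derail
IV estimation). The forward pass runs over the full $2^m$ state space of
each family-connected pedigree component; paths are drawn by backward
sampling, so realizations are exact draws, not MCMC output, and the
correctness of every marginal is testable by enumeration.

Design choices:

* **Exactness with a meiosis cap** (default 18, ~262k states per
  component) instead of an MCMC sampler for large pedigrees. The cap
  applies per family-connected component: the likelihood factorizes over
  components (a property the test suite asserts), so a pedigree file far
  larger than the cap is fine as long as each connected component is
  within it. Components beyond the cap raise a capacity error advising
  splitting rather than silently approximating.
* Founder-phase symmetry is not quotiented out; the factor-of-$2^F$
  saving is not worth the bookkeeping at desk scale.
* Missing genotypes contribute emission factor 1.

## 3. Cryptic relatedness

**Pairwise screen.** `pairwise_posterior()` runs a forward–backward over
the 15 set-partitions of an ordered pair's four slots (detailed states;
condensed genotypic states are coarsenings and can be derived). The
process jumps to its stationary distribution at rate `alpha` per cM
(default 0.05, giving multi-cM expected segment lengths), so the
transition over distance $d$ is $e^{-\alpha d} I + (1-e^{-\alpha d})
\mathbf{1}\pi'$. The stationary distribution is parameterized by a
marginal any-IBD probability `beta` (default 0.05) and an autozygosity
weight `delta` (default 0.02): each partition is weighted by independent
pair-sharing factors and normalized over the 15 states. `beta`, `alpha`
and the error rate are all exposed; none is estimated from data (out of
scope).

**Joint stitching.** `ibd_stitch()` processes haplotype slots in a fixed
order; the first founds FGL 1 and each later slot follows a hidden
copying path — copy one of the previously processed slots (sharing its
location-specific FGL) or carry novel material — switching at rate `rho`
per cM (default 0.1) and founding novel material with probability `nu`
(default 0.5) at a switch. Because sharing is expressed through labels,
transitivity holds by construction in every realization. The reference
model for this stage is unpublished, so this copying model is this
package's own specification with the same contract: jointly-consistent,
location-specific, multi-individual IBD realizations.

Two design points deserve emphasis, both driven by a measured failure:

* **Soft phase.** With markers in linkage equilibrium the only phase
  information comes from IBD partners. Hard-sampling a phase per
  realization (coin flips at heterozygous sites) makes every early
  haplotype an incoherent mosaic, and planted shared segments were
  recovered in under 15% of realizations. Instead each slot carries a
  posterior allele probability given its sampled copying path; emissions
  integrate over it. Recovery of a planted 25 cM segment shared by 3 of 6
  individuals then exceeds 90% (asserted by the test suite).
* **Partner copying is special.** Treating a slot and its partner as
  independent channels makes copying one's own partner penalty-free and
  the sampler declares everyone autozygous; the exact autozygote emission
  (heterozygote only via error) is used for that one case.

An optional `sweeps` argument re-samples every slot given all the others;
the measured default is the single sequential sweep. A `shuffle_order`
seed exists because any sequential sampler is order-sensitive at finite
`K` — exposing the knob is the honest option.

## 4. Merging

`merge_ibd_graphs()` pairs realization `k` of every input (realizations
are exchangeable, so any fixed pairing is statistically equivalent) and,
at each grid position, closes the pedigree partitions over the
cross-individual equivalences asserted by the bridge partition with
union-find. The merged partition is therefore always a coarsening of the
disjoint union: merging can only add sharing, never remove it (asserted as
a property test, together with idempotence and order-invariance).

Bridge graphs on a denser grid are down-sampled by nearest position (ties
to the lower position). Bridge haplotypes carry arbitrary phase; the
documented alignment rule scores slot orientations by the map length over
which the bridge's within-individual autozygosity pattern matches the
pedigree partition. That score is swap-invariant, so the tie-break
(identity) always applies — the rule is retained because it is
deterministic and logged, and because phase errors are absorbed
downstream by the fact that partitions, not haplotypes, are merged.
An optional `groups` argument restricts bridge equivalences to within
stated groups of individuals, for workflows that merge pedigrees in
separate components; the default is a single group.

## 5. LOD scores from IBD graphs

Given graphs realized conditional on marker data, trait LOD scores need no
further reference to pedigrees or genotypes. For a biallelic QTL model
(`q`, genotype means, residual variance — means rather than
additive/dominance parameters, so dominance is representable), the
component likelihood sums the Normal trait density over latent
founder-allele assignments. Numerical choices:

* The sum is computed by **variable elimination over the class graph**
  (classes are binary variables; phenotyped individuals are pairwise
  factors), so it is exact for components far beyond brute-force scale.
  The `class_cap` argument (default 22) is a capacity guard in the user's
  hands, not a numerical limit; merged analyses on hundreds of
  individuals pass a larger cap explicitly.
* Likelihood mixing over realizations and the null average use
  log-sum-exp; products over 500+ individuals underflow doubles
  otherwise.
* **Caching**: contributions are memoized per connectivity group and
  canonical key, shared across realizations and positions. Classes carried
  by many individuals ("hubs", e.g. a planted ancestral segment spanning
  pedigrees) are summed out in a cheap outer elimination so that group
  messages stay cacheable; `cache_blocks` (derived automatically from the
  pedigrees by `batch_lods()`) pins groups to pedigree components. None of
  this changes a single digit: curves with caching on and off are
  bit-identical, which the suite asserts.
* The **null** is the trait-locus-unlinked hypothesis: prior single-locus
  IBD from pedigree structure only, no cross-pedigree IBD, averaged over
  `M` gene drops (default 10,000, fixed seed recorded). Pedigree
  components are independent under the null, so the average is taken per
  component and multiplied — identical in expectation to averaging the
  product, with far lower Monte-Carlo variance.
* LOD is reported in log10, per convention.

## 6. What the simulator emulates — and what it does not

`simulate_ibd_study()` generates the complete world: pedigrees built from
small family templates, sparse and dense panels, planted cryptic
relatedness, QTL-driven trait replicates, and the ground-truth IBD graph.

* The `gaw` preset mirrors the scale of the motivating study design:
  7 pedigrees (~530 individuals), 351 sparse markers at 0.64 cM mean
  spacing in linkage equilibrium, a dense panel with MAF > 0.05,
  21 cryptically related founders (3 per pedigree), a QTL at 69 cM, and
  200 trait replicates by default. The dense panel is 2000 markers
  (~9 per cM): measured as the density at which a single shared haplotype
  between otherwise-unrelated individuals is confidently detectable; the
  real dense sets are far denser still.
* Pedigrees are unions of family-connected components of 6–8 members
  (8–10 meioses each), keeping exact IV sampling comfortable while the
  files reach realistic sizes. Real study pedigrees are larger and
  connected; their internal structure is not reproduced (sizes and depths
  of the original pedigrees are not published), which mainly means our
  per-pedigree linkage information is carried by many small loops rather
  than a few deep ones.
* Cryptic relatedness is planted by relabeling each bridge founder's
  paternal slot to a hidden ancestral FGL over a jittered ~25 cM segment
  centered on the QTL — map-consistent, segmental, and transitive, which
  is exactly what the stitching stage is meant to recover. The hidden
  ancestor never appears in the emitted pedigrees.
* The QTL is additive with trait-increasing allele frequency 0.1 and the
  planted ancestral haplotype carrying the increasing allele. The variance
  explained is the one deliberately calibrated quantity: the emulation
  target prescribes calibrating it so that unmerged per-pedigree
  information is weak while the merged analysis is strong. At VE = 0.20
  the unmerged region-averaged LOD sits around 1 and the merged one well
  above 3, reproducing the reported contrast; the value was fixed once and
  not revisited. The `mini` preset keeps VE = 0.15 (the region-recovery
  criterion's stated effect size).
* Not emulated: linkage disequilibrium (markers are independent given the
  FGLs, matching the sparse panel's description; LD modeling is out of
  scope), admixture and ancestry-specific allele frequencies, coalescent
  founder haplotypes, and trait covariates (traits are emitted
  pre-adjusted). A green test therefore establishes correctness of the
  inference machinery under its own assumptions — not robustness to LD or
  admixture, which the original data do exhibit.

## 7. Known limitations

* Exact IV sampling is exponential in component meioses; pedigrees above
  the cap must be split (the error says so) — there is no MCMC fallback.
* The stitch model is a stand-in for an unpublished reference; its
  defaults (`rho`, `nu`, `beta`, `alpha`) are order-of-magnitude choices
  exposed as configuration, not estimates.
* Imputation assigns each dense SNP to its nearest sparse-grid position;
  recombination between the SNP and that position is ignored (the error of
  this simplification vanishes as sparse density grows). When a
  realization's partition is strictly inconsistent with observed data at
  `eps = 0`, an error floor of 1e-9 is used for that block and a message
  emitted; dense-typed targets always keep their own observed genotypes in
  the error-free limit.
* Pair selection for the cryptic stage (which pairs to screen, what
  kinship threshold) is user input; the package does not choose the 21
  individuals for you.
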
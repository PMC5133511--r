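# ibdmap

Identity-by-descent (IBD) graphs for pedigree linkage mapping and
family-based genotype imputation.

`ibdmap` is for statistical geneticists working with multi-pedigree study
samples in which some of the "unrelated" founders are in fact cryptically
related. It realizes location-specific IBD within pedigrees conditional on a
sparse marker panel, infers jointly-consistent IBD among cryptically related
individuals from a dense panel, merges the two into combined IBD graphs, and
computes quantitative-trait LOD scores directly from the graphs. It also
performs GIGI-style family-based genotype imputation with correlation-based
accuracy metrics, and ships a simulator that generates complete synthetic
studies (pedigrees, panels, planted cryptic relatedness, QTL-driven traits,
ground-truth IBD) so every stage can be exercised end to end.

## The model in brief

At a genomic position x, location-specific IBD for a set of individuals is a
partition of their haplotype slots into founder-genome-label (FGL) classes:
slots in one class descend from a single founder haplotype. A set of K such
partitions along a marker grid — an *IBD graph set* — is the central object.

* **Within pedigrees** (`sample_ivs`): inheritance vectors v(x) (one bit per
  meiosis) are drawn from the exact Lander–Green posterior
  P(v(·) | sparse genotypes) by a forward pass over the 2^m IV states of
  each pedigree component and backward sampling. Inter-marker transitions
  flip each bit independently with the Haldane recombination fraction
  θ = (1 − e^(−2d/100))/2; emissions sum genotype penetrances (per-allele
  error ε) over founder-allele assignments.
* **Between pedigrees** (`pairwise_posterior`, `ibd_stitch`): a 15-state HMM
  over the set-partitions of a pair's four slots screens pairs for sharing;
  a sequential haplotype-copying sampler then realizes jointly-consistent
  IBD over all cryptically related individuals at once — transitivity holds
  by construction because sharing is expressed through labels.
* **Merging** (`merge_ibd_graphs`): realization k of each sampler is
  combined by union-find closure at every grid position, so the merged
  partition is always a coarsening of the disjoint union.
* **LOD mapping** (`lod_curve`, `batch_lods`): for a biallelic QTL model
  (allele frequency q, genotype means μ0, μ1, μ2, residual variance σ²),

      LOD(x) = log10[ (1/K) Σ_k Π_components L(G_k(x)) ] − log10 L0,

  where L sums the Normal trait likelihood over the 2^c latent allele
  assignments of a component's c classes (computed exactly by variable
  elimination over the class graph) and L0 is the unlinked null from prior
  single-locus gene dropping within pedigrees. Identical component
  contributions across realizations *and* positions are recognised by
  canonical graph equivalence and computed once.
* **Imputation** (`impute_genotypes`, `imputation_accuracy`): dense-panel
  SNPs are imputed into untyped individuals through the realized IBD;
  accuracy is reported as ρ1 = Σ cor / #SNPe and ρ2 = Σ cor / #SNPs (per-SNP
  correlation of true genotype with imputed dosage; #SNPe = SNPs imputed as
  polymorphic, #SNPs = reference-polymorphic SNPs), overall and in MAF bins
  (0,0.01], (0.01,0.15], (0.15,0.5].

## Worked example

```r
library(ibdmap)

cfg   <- sim_preset("mini", n_traits = 20)      # 3 pedigrees, 60 individuals
study <- simulate_ibd_study(cfg, seed = 1)
study
#> <sim_dataset> 3 pedigrees / 60 individuals; 60 sparse + 720 dense markers;
#>   QTL at 40 cM (VE 0.150); 6 bridge founders; 20 trait replicates

ped_graphs <- lapply(seq_along(study$pedigrees), function(i)
  sample_ivs(study$pedigrees[[i]], study$sparse_panel, K = 50, seed = 100 + i))
bridge <- ibd_stitch(study$dense_panel, study$bridge$id, K = 50, seed = 7)
merged <- merge_ibd_graphs(ped_graphs, bridge)
merged
#> <ibd_graph_set> 60 individuals, 60 positions (0.00-88.50 cM), K = 50
#>   (mean 49.8 change-points) [merged]

lods <- batch_lods(merged, study$pedigrees, study$traits, study$qtl,
                   null_M = 5000, null_seed = 1, class_cap = 300)
lods
#> <lod_result> 60 positions, 20 replicate(s), K = 50; max average LOD 1.010 at 40.50 cM
autoplot(lods)    # per-replicate curves with the average emphasised
```

The average curve peaks at 40.5 cM — next to the simulated QTL at 40 cM.
Dropping the merge step and summing the per-pedigree curves instead
(`batch_lods(ped_graphs, ...)`) collapses the signal: in this run the mean
LOD over the 27.5–52.5 cM trait region is 0.78 with merging against 0.03
without — the cryptic relatedness carries most of the mapping information.

A command-line front end wrapping the same functions (subcommands
`simulate`, `sample-ivs`, `pairwise-ibd`, `stitch`, `merge`, `lod`,
`impute`, `accuracy`) is installed at
`system.file("cli", "ibdmap", package = "ibdmap")`.

## Acceptance script

`scripts/acceptance.R` re-runs the full workflow at the emulation scale
(7 pedigrees, ~530 individuals, 351 sparse markers, 21 cryptically related
founders sharing a planted ~25 cM segment around a QTL at 69 cM; K = 100,
50 trait replicates) and writes the two region-averaged LOD levels — merged
graphs versus the unmerged per-pedigree total — as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/ibd-graph-mapping.Rmd`) documents the
models, their assumptions, all tunable parameters and defaults, what the
simulator does and does not emulate, and the numerical design choices.
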
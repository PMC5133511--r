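#' Simulation configuration
#'
#' Describes a complete synthetic study: several pedigrees built from
#' small family templates, a sparse linkage panel in linkage equilibrium,
#' a dense panel with a MAF floor, planted cryptic relatedness (bridge
#' founders across pedigrees sharing a hidden ancestral founder genome
#' label over a segment), and a biallelic QTL driving quantitative trait
#' replicates.
#'
#' Pedigrees are composed of family-connected components drawn from two
#' templates: `nuclear6` (2 founders, 4 children; 8 meioses) and
#' `threegen8` (3 founders over three generations; 10 meioses), keeping
#' each component well inside the exact inheritance-vector sampler's
#' meiosis cap while the pedigree files reach realistic sizes.
#'
#' @param n_pedigrees Number of pedigrees.
#' @param comp_threegen,comp_nuclear Number of three-generation / nuclear
#'   components per pedigree.
#' @param sparse_n Number of sparse markers.
#' @param sparse_spacing_cm Mean sparse-marker spacing (cM).
#' @param sparse_freq_range Range of sparse alternate-allele frequencies.
#' @param dense_n Number of dense markers (same map span as the sparse
#'   panel).
#' @param dense_maf_floor Minimum dense-marker MAF.
#' @param qtl_cm QTL position (cM); must lie inside the map.
#' @param qtl_q Population frequency of the trait-increasing allele.
#' @param qtl_ve Proportion of trait variance explained by the QTL under
#'   Hardy-Weinberg (calibrates an additive allele effect).
#' @param sigma2 Residual trait variance.
#' @param n_bridge_per_ped Cryptically related founders per pedigree; the
#'   bridge founders of one link group share a hidden ancestral FGL over a
#'   planted segment (0 disables cryptic relatedness).
#' @param bridge_segment_cm Planted shared-segment length (cM) centered on
#'   the QTL.
#' @param bridge_jitter_cm Per-individual uniform jitter on each segment
#'   end point (cM).
#' @param n_cryptic_groups Number of disjoint link groups the bridge
#'   founders are split into (each group shares its own hidden FGL).
#' @param n_traits Number of trait replicates.
#' @param eps Per-allele genotyping error rate used when emitting
#'   genotypes.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_pedigrees = 3, comp_threegen = 1, comp_nuclear = 2,
                       sparse_n = 60, sparse_spacing_cm = 1.5,
                       sparse_freq_range = c(0.2, 0.8),
                       dense_n = 720, dense_maf_floor = 0.05,
                       qtl_cm = 40, qtl_q = 0.1, qtl_ve = 0.15, sigma2 = 1,
                       n_bridge_per_ped = 2, bridge_segment_cm = 25,
                       bridge_jitter_cm = 3, n_cryptic_groups = 1,
                       n_traits = 20, eps = 0.01) {
  cfg <- list(
    n_pedigrees = n_pedigrees, comp_threegen = comp_threegen,
    comp_nuclear = comp_nuclear, sparse_n = sparse_n,
    sparse_spacing_cm = sparse_spacing_cm, sparse_freq_range = sparse_freq_range,
    dense_n = dense_n, dense_maf_floor = dense_maf_floor,
    qtl_cm = qtl_cm, qtl_q = qtl_q, qtl_ve = qtl_ve, sigma2 = sigma2,
    n_bridge_per_ped = n_bridge_per_ped, bridge_segment_cm = bridge_segment_cm,
    bridge_jitter_cm = bridge_jitter_cm, n_cryptic_groups = n_cryptic_groups,
    n_traits = n_traits, eps = eps
  )
  span <- (sparse_n - 1) * sparse_spacing_cm
  if (qtl_cm <= 0 || qtl_cm >= span) abort("qtl_cm must lie strictly inside the map span")
  if (qtl_q < 0 || qtl_q > 1) abort("qtl_q must lie in [0, 1]")
  if (qtl_ve < 0 || qtl_ve >= 1) abort("qtl_ve must lie in [0, 1)")
  if (dense_maf_floor <= 0 || dense_maf_floor >= 0.5) abort("dense_maf_floor must lie in (0, 0.5)")
  if (n_bridge_per_ped > 0 && n_bridge_per_ped > comp_threegen + comp_nuclear) {
    abort("n_bridge_per_ped cannot exceed the number of components per pedigree")
  }
  structure(cfg, class = "sim_config")
}

#' Simulation presets
#'
#' `"mini"`: 3 pedigrees of 20 (60 individuals), 60 sparse markers at
#' 1.5 cM, 720 dense markers, QTL at 40 cM explaining 15% of trait
#' variance, 6 bridge founders, 20 trait replicates - the seconds-scale
#' default for tests.
#'
#' `"gaw"`: the scaled study emulation - 7 pedigrees of 76 (532
#' individuals), 351 sparse markers at 0.64 cM mean spacing in linkage
#' equilibrium, a dense MAF>0.05 panel, 21 cryptically related founders
#' (3 per pedigree) sharing a planted ~25 cM segment around a QTL at
#' 69 cM, and 200 trait replicates.
#'
#' @param name `"mini"` or `"gaw"`.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("mini", "gaw"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    mini = list(),
    gaw = list(
      n_pedigrees = 7, comp_threegen = 5, comp_nuclear = 6,
      sparse_n = 351, sparse_spacing_cm = 0.64,
      dense_n = 2000, qtl_cm = 69, qtl_q = 0.1, qtl_ve = 0.2,
      n_bridge_per_ped = 3, bridge_segment_cm = 25, n_traits = 200
    )
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_config, base)
}

#' QTL variance explained under Hardy-Weinberg
#'
#' `Var_genetic / (Var_genetic + sigma2)` with the genetic variance taken
#' over Hardy-Weinberg genotype frequencies at allele frequency `q`.
#'
#' @param model A [qtl_model].
#' @return Proportion in `[0, 1)`.
#' @export
trait_variance_explained <- function(model) {
  q <- model$q
  pr <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  mbar <- sum(pr * model$mu)
  vg <- sum(pr * model$mu^2) - mbar^2
  vg / (vg + model$sigma2)
}

#' Additive QTL model with a target variance explained
#'
#' Solves the additive allele effect `a` (genotype means `0, a, 2a`) so
#' that [trait_variance_explained()] equals `ve`:
#' `a = sqrt(ve / (1 - ve) * sigma2 / (2 q (1 - q)))`.
#'
#' @param q Trait-increasing allele frequency in (0, 1).
#' @param ve Target variance explained in `[0, 1)`.
#' @param sigma2 Residual variance.
#' @return A [qtl_model].
#' @export
qtl_model_for_ve <- function(q, ve, sigma2 = 1) {
  if (q <= 0 || q >= 1) abort("q must lie strictly in (0, 1)")
  if (ve < 0 || ve >= 1) abort("ve must lie in [0, 1)")
  a <- sqrt(ve / (1 - ve) * sigma2 / (2 * q * (1 - q)))
  qtl_model(q, c(0, a, 2 * a), sigma2)
}

# template pedigree member tables (ids get a pedigree/component prefix)
template_members <- function(kind, prefix) {
  id <- function(i) sprintf("%s_%d", prefix, i)
  if (kind == "nuclear6") {
    tibble(
      id = id(1:6),
      father = c(NA, NA, rep(id(1), 4)),
      mother = c(NA, NA, rep(id(2), 4)),
      sex = c(1L, 2L, 1L, 2L, 1L, 2L)
    )
  } else if (kind == "threegen8") {
    # couple (1,2) with children 4,5,6; child 4 x founder 3 -> 7, 8
    tibble(
      id = id(1:8),
      father = c(NA, NA, NA, rep(id(1), 3), rep(id(4), 2)),
      mother = c(NA, NA, NA, rep(id(2), 3), rep(id(3), 2)),
      sex = c(1L, 2L, 2L, 1L, 2L, 1L, 1L, 2L)
    )
  } else abort(sprintf("unknown template '%s'", kind))
}

derive_seeds <- function(seed, streams) {
  set.seed(as.integer(seed))
  setNames(sample.int(2147483646L, length(streams)), streams)
}

#' Simulate a complete multi-pedigree IBD study
#'
#' Builds pedigrees from templates, gene-drops founder genome labels over
#' the union marker grid, plants cryptic relatedness by relabeling each
#' bridge founder's paternal slot to a hidden ancestral FGL over its
#' planted segment (so cross-pedigree IBD is segmental, map-consistent and
#' transitive), emits sparse/dense genotypes from the true FGL alleles
#' with error `eps` (markers in linkage equilibrium), draws trait
#' replicates from the true QTL genotypes, and returns the ground truth
#' alongside the data. Hidden connectors never appear in the emitted
#' pedigrees - that is what makes the relatedness cryptic.
#'
#' @param config A [sim_config].
#' @param seed Master seed; structure, genotypes and traits use derived
#'   named substreams.
#' @return A `sim_dataset` list: `pedigrees` (list of [pedigree]),
#'   `sparse_panel`, `dense_panel` ([marker_panel]s; all individuals
#'   typed), `traits` (tibble `id`, `t1..tR`), `qtl` ([qtl_model]),
#'   `qtl_cm`, `bridge` (tibble of planted segments), and `truth` (list:
#'   `graphs` = true [ibd_graph_set] (K = 1) on the union grid incl. the
#'   QTL position, `qtl_geno` = named true QTL genotypes, `grid_cm`).
#' @export
simulate_ibd_study <- function(config, seed = 1L) {
  seeds <- derive_seeds(seed, c("structure", "genotypes", "traits"))
  n_ped <- config$n_pedigrees
  kinds <- c(rep("threegen8", config$comp_threegen), rep("nuclear6", config$comp_nuclear))

  peds <- lapply(seq_len(n_ped), function(p) {
    mem <- purrr::map_dfr(seq_along(kinds), function(ci) {
      template_members(kinds[ci], sprintf("P%02d_C%02d", p, ci))
    })
    pedigree(mem, ped_id = sprintf("P%02d", p))
  })

  # marker grids
  sparse_cm <- seq(0, by = config$sparse_spacing_cm, length.out = config$sparse_n)
  span <- max(sparse_cm)
  dense_cm <- seq(span * 0.5 / config$dense_n, span * (1 - 0.5 / config$dense_n),
                  length.out = config$dense_n)
  dense_cm <- round(dense_cm, 6)
  grid_cm <- sort(unique(c(sparse_cm, dense_cm, config$qtl_cm)))
  sparse_ix <- match(sparse_cm, grid_cm)
  dense_ix <- match(dense_cm, grid_cm)
  qtl_ix <- match(config$qtl_cm, grid_cm)

  # true IBD by gene dropping per pedigree on the union grid
  grid_map <- genetic_map(sprintf("g%04d", seq_along(grid_cm)), grid_cm)
  set.seed(seeds["structure"])
  lab_all <- NULL
  offset <- 0L
  for (p in peds) {
    ivs <- draw_iv_paths(nrow(p$meioses), map_theta(grid_map), n = 1L,
                         seed = sample.int(2147483646L, 1))
    labs <- matrix(0L, length(grid_cm), 2L * nrow(p$members))
    for (j in seq_along(grid_cm)) labs[j, ] <- iv_to_partition(ivs[[1]][j, ], p)
    colnames(labs) <- slot_names(p)
    lab_all <- cbind(lab_all, labs + offset)
    offset <- offset + 2L * length(p$founders)
  }
  individuals <- unlist(lapply(peds, function(p) p$members$id))

  # plant cryptic relatedness: bridge founders' paternal slots share a
  # hidden ancestral FGL over jittered segments around the QTL
  bridge <- tibble(id = character(0), group = integer(0),
                   start_cm = numeric(0), end_cm = numeric(0))
  if (config$n_bridge_per_ped > 0 && n_ped > 1) {
    picks <- unlist(lapply(seq_len(n_ped), function(p) {
      vapply(seq_len(config$n_bridge_per_ped), function(ci) {
        peds[[p]]$members$id[match(sprintf("P%02d_C%02d_1", p, ci), peds[[p]]$members$id)]
      }, character(1))
    }))
    groups <- rep(seq_len(config$n_cryptic_groups), length.out = length(picks))
    half <- config$bridge_segment_cm / 2
    jit <- config$bridge_jitter_cm
    bridge <- tibble(
      id = picks, group = groups,
      start_cm = pmax(0, config$qtl_cm - half + runif(length(picks), -jit, jit)),
      end_cm = pmin(span, config$qtl_cm + half + runif(length(picks), -jit, jit))
    )
    for (b in seq_len(nrow(bridge))) {
      slot <- paste0(bridge$id[b], ".0")
      col <- match(slot, colnames(lab_all))
      own <- lab_all[qtl_ix, col]      # the founder slot's own FGL
      hidden <- offset + bridge$group[b]
      rows <- grid_cm >= bridge$start_cm[b] & grid_cm <= bridge$end_cm[b]
      relabel <- lab_all[rows, , drop = FALSE]
      relabel[relabel == own] <- hidden
      lab_all[rows, ] <- relabel
    }
  }

  # allele frequencies
  set.seed(seeds["genotypes"])
  sparse_freq <- runif(config$sparse_n, config$sparse_freq_range[1], config$sparse_freq_range[2])
  dmaf <- runif(config$dense_n, config$dense_maf_floor, 0.5)
  dense_freq <- ifelse(runif(config$dense_n) < 0.5, dmaf, 1 - dmaf)
  n_fgl <- max(lab_all)

  draw_panel <- function(ix, freq, forced_fgl = NULL, forced_allele = NULL) {
    true_g <- matrix(0L, length(ix), length(individuals))
    obs_g <- matrix(0L, length(ix), length(individuals))
    for (r in seq_along(ix)) {
      al <- rbinom(n_fgl, 1L, freq[r])
      if (!is.null(forced_fgl)) al[forced_fgl] <- forced_allele
      l <- lab_all[ix[r], ]
      a1 <- al[l[seq(1, length(l), 2)]]
      a2 <- al[l[seq(2, length(l), 2)]]
      true_g[r, ] <- a1 + a2
      f1 <- rbinom(length(a1), 1L, config$eps)
      f2 <- rbinom(length(a2), 1L, config$eps)
      obs_g[r, ] <- abs(a1 - f1) + abs(a2 - f2)
    }
    colnames(true_g) <- colnames(obs_g) <- individuals
    list(true = true_g, obs = obs_g)
  }
  sp <- draw_panel(sparse_ix, sparse_freq)
  dn <- draw_panel(dense_ix, dense_freq)

  # QTL genotypes: hidden FGLs carry the trait-increasing allele
  hidden_fgls <- if (nrow(bridge)) offset + unique(bridge$group) else integer(0)
  qal <- rbinom(n_fgl, 1L, config$qtl_q)
  qal[hidden_fgls] <- 1L
  lq <- lab_all[qtl_ix, ]
  qtl_geno <- setNames(qal[lq[seq(1, length(lq), 2)]] + qal[lq[seq(2, length(lq), 2)]],
                       individuals)

  model <- qtl_model_for_ve(config$qtl_q, config$qtl_ve, config$sigma2)
  set.seed(seeds["traits"])
  traits <- tibble(id = individuals)
  for (t in seq_len(config$n_traits)) {
    traits[[paste0("t", t)]] <- model$mu[qtl_geno + 1L] +
      rnorm(length(individuals), 0, sqrt(config$sigma2))
  }

  sparse_map <- genetic_map(sprintf("ms%03d", seq_len(config$sparse_n)), sparse_cm)
  dense_map <- genetic_map(sprintf("md%04d", seq_len(config$dense_n)), dense_cm)
  sparse_geno <- sp$obs; rownames(sparse_geno) <- sparse_map$marker
  dense_geno <- dn$obs; rownames(dense_geno) <- dense_map$marker

  truth_graphs <- ibd_graph_set(
    individuals, grid_cm,
    list(compress_partitions(length(grid_cm), function(j) lab_all[j, ])),
    source = "truth"
  )

  structure(list(
    config = config, seed = seed,
    pedigrees = peds,
    sparse_panel = marker_panel(sparse_map, sparse_geno, freq = sparse_freq, eps = config$eps),
    dense_panel = marker_panel(dense_map, dense_geno, freq = dense_freq, eps = config$eps),
    traits = traits,
    qtl = model, qtl_cm = config$qtl_cm,
    bridge = bridge,
    truth = list(graphs = truth_graphs, qtl_geno = qtl_geno, grid_cm = grid_cm,
                 dense_true = dn$true, sparse_true = sp$true)
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d pedigrees / %d individuals; %d sparse + %d dense markers; QTL at %g cM (VE %.3f); %d bridge founders; %d trait replicates\n",
    length(x$pedigrees), nrow(x$traits), nrow(x$sparse_panel$map),
    nrow(x$dense_panel$map), x$qtl_cm, trait_variance_explained(x$qtl),
    nrow(x$bridge), sum(startsWith(colnames(x$traits), "t"))))
  invisible(x)
}

#' Write / read a simulated dataset as plain-text files
#'
#' Emits the same formats the analysis functions read: `pedigrees.ped`,
#' `sparse.map`/`dense.map`, `sparse.geno`/`dense.geno` (tabular),
#' `sparse.freq`/`dense.freq`, `traits.tsv`, `truth_graphs.txt` (compact
#' IBD-graph format) and `meta.json`.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; `read_ibd_study()` returns the reconstructed
#'   pieces as a list.
#' @export
write_ibd_study <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_pedigree(dataset$pedigrees, fp("pedigrees.ped"))
  for (nm in c("sparse", "dense")) {
    panel <- dataset[[paste0(nm, "_panel")]]
    writeLines(c("# chrom marker cm bp",
                 paste(panel$map$chrom, panel$map$marker,
                       format(panel$map$cm, digits = 12, trim = TRUE),
                       panel$map$bp)), fp(paste0(nm, ".map")))
    write_genotypes(panel$geno, fp(paste0(nm, ".geno")))
    write_frequencies(setNames(panel$freq, panel$map$marker), fp(paste0(nm, ".freq")))
  }
  write_traits(dataset$traits, fp("traits.tsv"))
  write_ibd_graphs(dataset$truth$graphs, fp("truth_graphs.txt"))
  meta <- list(seed = dataset$seed, qtl_cm = dataset$qtl_cm,
               qtl = unclass(dataset$qtl), eps = dataset$config$eps,
               bridge = as.data.frame(dataset$bridge))
  jsonlite::write_json(meta, fp("meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ibd_study
#' @export
read_ibd_study <- function(dir) {
  fp <- function(f) file.path(dir, f)
  meta <- jsonlite::read_json(fp("meta.json"), simplifyVector = TRUE)
  panels <- lapply(c(sparse = "sparse", dense = "dense"), function(nm) {
    marker_panel(read_genetic_map(fp(paste0(nm, ".map"))),
                 read_genotypes(fp(paste0(nm, ".geno"))),
                 freq = unname(read_frequencies(fp(paste0(nm, ".freq")))),
                 eps = meta$eps)
  })
  peds <- read_pedigree(fp("pedigrees.ped"))
  if (inherits(peds, "pedigree")) peds <- list(peds)
  list(
    pedigrees = peds,
    sparse_panel = panels$sparse, dense_panel = panels$dense,
    traits = read_traits(fp("traits.tsv")),
    truth_graphs = read_ibd_graphs(fp("truth_graphs.txt")),
    qtl = qtl_model(meta$qtl$q, meta$qtl$mu, meta$qtl$sigma2),
    qtl_cm = meta$qtl_cm,
    bridge = as_tibble(meta$bridge)
  )
}
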
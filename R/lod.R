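#' Biallelic quantitative-trait-locus model
#'
#' Trait model for LOD-score computation on IBD graphs: a biallelic locus
#' with trait-increasing allele frequency `q`, genotype means `mu[1:3]` for
#' 0, 1 and 2 copies, and residual Normal variance `sigma2`. Dominance is
#' allowed (means are free).
#'
#' @param q Trait-increasing allele frequency in `[0, 1]`.
#' @param mu Numeric length-3 genotype means (0/1/2 copies).
#' @param sigma2 Residual variance, > 0.
#' @return A `qtl_model` object.
#' @export
qtl_model <- function(q, mu, sigma2) {
  if (q < 0 || q > 1) abort("q must lie in [0, 1]")
  if (length(mu) != 3 || anyNA(mu)) abort("mu must be three genotype means")
  if (!is.finite(sigma2) || sigma2 <= 0) abort("sigma2 must be > 0")
  structure(list(q = q, mu = as.numeric(mu), sigma2 = sigma2), class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("<qtl_model> q = %g, mu = (%g, %g, %g), sigma2 = %g\n",
              x$q, x$mu[1], x$mu[2], x$mu[3], x$sigma2))
  invisible(x)
}

#' Trait likelihood of one IBD-graph component
#'
#' Density of observed quantitative traits given the IBD partition of one
#' connected component: each IBD class carries a latent trait-locus allele
#' (frequency `q`), and each phenotyped individual contributes a Normal
#' density at the genotype mean indexed by the number of trait-increasing
#' alleles on its two slots. The sum over the `2^c` latent assignments is
#' computed exactly (internally by variable elimination over the class
#' graph, so graphs far above desk-enumeration scale remain exact).
#' Missing traits contribute factor 1.
#'
#' @param labels Named integer partition labels whose slots form one
#'   connected component through the phenotyped individuals.
#' @param traits Named numeric trait values (`NA` = missing).
#' @param model A [qtl_model].
#' @param class_cap Maximum number of IBD classes in the component
#'   (default 22); above it a capacity error is raised (reduce pedigree or
#'   bridge density).
#' @param log Return the natural-log density?
#' @return Probability density (or its log).
#' @export
component_likelihood <- function(labels, traits, model, class_cap = 22, log = FALSE) {
  slot_ind <- sub("\\.[01]$", "", names(labels))
  ids <- intersect(unique(slot_ind), names(traits))
  y <- as.numeric(traits[ids])
  cls <- canonical_labels(labels)
  c_n <- max(cls)
  if (c_n > class_cap) {
    abort(sprintf("component has %d IBD classes, above the cap of %d; reduce pedigree/bridge density",
                  c_n, class_cap), class = "ibdmap_capacity_error")
  }
  pat <- integer(length(ids)); mat <- integer(length(ids))
  for (j in seq_along(ids)) {
    ix <- which(slot_ind == ids[j])
    pat[j] <- cls[ix[1]]; mat[j] <- cls[ix[2]]
  }
  ll <- component_loglik_core(pat - 1L, mat - 1L, c_n, y,
                              model$q, model$mu[1], model$mu[2], model$mu[3],
                              model$sigma2)
  if (log) ll else exp(ll)
}

# natural-log trait likelihood of a full partition: product over the
# connected components induced by the phenotyped individuals
partition_trait_loglik <- function(labels, traits, model, class_cap = 22) {
  slot_ind <- sub("\\.[01]$", "", names(labels))
  keep <- names(traits)[!is.na(traits)]
  comps <- partition_slot_components(labels)
  tot <- 0
  for (ix in comps) {
    ids <- intersect(unique(slot_ind[ix]), keep)
    if (!length(ids)) next
    tot <- tot + component_likelihood(labels[ix], traits[ids], model,
                                      class_cap = class_cap, log = TRUE)
  }
  tot
}

#' Null (unlinked) trait log-likelihood from prior pedigree IBD
#'
#' The LOD denominator: the trait-locus position is unlinked to the mapped
#' region, so location-specific IBD at the trait locus follows the prior
#' (unconditional) single-locus gene-dropping process within each pedigree,
#' with no cross-pedigree IBD. The likelihood is a Monte-Carlo average over
#' `M` prior inheritance-vector draws; pedigree components are independent
#' under the null, so the average is taken per component and multiplied
#' (same expectation as averaging the product, much lower MC variance).
#'
#' @param peds A [pedigree] or list of pedigrees covering the phenotyped
#'   individuals.
#' @param traits A tibble with column `id` plus one column per trait
#'   replicate, or a named numeric vector (one replicate).
#' @param model A [qtl_model].
#' @param M Number of prior gene-drop realizations (default 10000).
#' @param seed Integer seed (draws are deterministic given the seed).
#' @param class_cap Passed to [component_likelihood()].
#' @return Named numeric vector of natural-log null likelihoods, one per
#'   replicate.
#' @export
null_loglik <- function(peds, traits, model, M = 10000, seed = 1L, class_cap = 22) {
  if (M < 1) abort("M must be >= 1")
  if (inherits(peds, "pedigree")) peds <- list(peds)
  tr <- traits_matrix(traits)
  set.seed(as.integer(seed))
  comps <- unlist(lapply(peds, pedigree_components), recursive = FALSE)
  total <- setNames(numeric(ncol(tr)), colnames(tr))
  for (p in comps) {
    ids <- intersect(p$members$id, rownames(tr))
    if (!length(ids)) next
    m <- nrow(p$meioses)
    # unique prior partitions with their MC weights
    if (m == 0L) {
      parts <- list(setNames(seq_len(2L * nrow(p$members)), slot_names(p)))
      wts <- 1
    } else {
      states <- sample.int(2L^m, M, replace = TRUE) - 1L
      tab <- table(states)
      uniq <- as.integer(names(tab))
      key <- character(length(uniq))
      parts0 <- vector("list", length(uniq))
      for (u in seq_along(uniq)) {
        iv <- as.integer(bitwAnd(bitwShiftR(uniq[u], seq_len(m) - 1L), 1L))
        parts0[[u]] <- iv_to_partition(iv, p)
        key[u] <- paste(canonical_labels(parts0[[u]]), collapse = ",")
      }
      grp <- match(key, unique(key))           # ids in first-occurrence order
      parts <- parts0[!duplicated(grp)]
      wts <- as.numeric(tapply(as.numeric(tab), grp, sum)) / M
    }
    # weighted mixture over the unique prior partitions, through the same
    # exact machinery the curves use (deduplicates repeated components)
    slots <- slot_names(p)
    pos_of <- match(ids, p$members$id)
    slot_idx <- rbind(2L * pos_of - 2L, 2L * pos_of - 1L)
    reals <- lapply(parts, function(lab) {
      list(pos = 1L, labels = matrix(unname(lab), nrow = 1))
    })
    res <- lod_curves_core(reals, 1L, slot_idx, tr[ids, , drop = FALSE],
                           model$q, model$mu[1], model$mu[2], model$mu[3],
                           model$sigma2, TRUE, as.integer(class_cap),
                           8L, integer(0), wts)
    total <- total + as.numeric(res$loglik[1, ])
  }
  total
}

traits_matrix <- function(traits) {
  if (is.numeric(traits) && !is.null(names(traits))) {
    m <- matrix(traits, ncol = 1, dimnames = list(names(traits), "trait"))
    return(m)
  }
  tr <- as.data.frame(traits)
  if (!"id" %in% names(tr)) abort("traits need an 'id' column")
  m <- as.matrix(tr[setdiff(names(tr), "id")])
  rownames(m) <- as.character(tr$id)
  if (ncol(m) == 0) abort("traits need at least one replicate column")
  storage.mode(m) <- "double"
  m
}

#' LOD-score curves from IBD graph realizations
#'
#' For each grid position `x`,
#' `LOD(x) = log10[(1/K) sum_k prod_components L(G_k(x))] - log10 L0`,
#' where `L` is the component trait likelihood and `L0` the unlinked null
#' from [null_loglik()]. Identical component contributions across
#' realizations and across positions are recognised by canonical graph
#' equivalence and computed once; cache hit/miss counts are reported in the
#' result's attributes and by [glance()].
#'
#' @param graphs An [ibd_graph_set] (conditional on marker data).
#' @param traits Trait tibble (`id` + replicate columns) or named vector.
#' @param model A [qtl_model].
#' @param null Named natural-log null likelihoods per replicate (from
#'   [null_loglik()] on the same phenotyped individuals), or the pedigree
#'   list itself, in which case the null is computed here.
#' @param cache Use the equivalence cache (results are bit-identical with
#'   and without).
#' @param cache_blocks Optional named vector assigning each phenotyped
#'   individual to a caching block (e.g. its pedigree component). Blocks
#'   only shape how likelihood contributions are grouped and memoized;
#'   classes spanning blocks are handled exactly in an outer elimination,
#'   so the curve itself is unchanged. [batch_lods()] derives blocks from
#'   the pedigrees automatically, which speeds up merged-graph scans.
#' @param class_cap,null_M,null_seed See [component_likelihood()] and
#'   [null_loglik()].
#' @return A `lod_result`: tibble with `cm` and one LOD column per
#'   replicate plus `average`; attributes `K`, `cache_hits`,
#'   `cache_misses`, `null`, `skipped`.
#' @export
lod_curve <- function(graphs, traits, model, null, cache = TRUE, class_cap = 22,
                      null_M = 10000, null_seed = 1L, cache_blocks = NULL) {
  tr <- traits_matrix(traits)
  ids <- intersect(graphs$individuals, rownames(tr))
  if (!length(ids)) abort("no overlap between graph individuals and traits")
  tr <- tr[ids, , drop = FALSE]
  # replicates with no phenotyped overlap carry no information: both the
  # numerator and a consistently-restricted null are 1, so their LOD is 0
  usable <- colSums(!is.na(tr)) > 0
  if (!all(usable)) {
    warn(sprintf("replicate(s) with no phenotyped overlap contribute LOD 0: %s",
                 paste(colnames(tr)[!usable], collapse = ", ")))
  }
  if (inherits(null, "pedigree") || (is.list(null) && inherits(null[[1]], "pedigree"))) {
    null <- null_loglik(null, traits_to_tibble(tr), model, M = null_M, seed = null_seed,
                        class_cap = class_cap)
  }
  if (!all(colnames(tr) %in% names(null))) abort("null must cover every replicate")
  null <- null[colnames(tr)]

  slot_idx <- matrix(0L, 2, length(ids))
  pos_of <- match(ids, graphs$individuals)
  slot_idx[1, ] <- 2L * pos_of - 2L       # 0-based paternal column
  slot_idx[2, ] <- 2L * pos_of - 1L
  blocks <- integer(0)
  if (!is.null(cache_blocks)) {
    if (is.null(names(cache_blocks)) || !all(ids %in% names(cache_blocks))) {
      abort("cache_blocks must be a named vector covering the phenotyped individuals")
    }
    blocks <- as.integer(as.factor(cache_blocks[ids]))
  }
  res <- lod_curves_core(graphs$realizations, length(graphs$positions),
                         slot_idx, tr, model$q, model$mu[1], model$mu[2],
                         model$mu[3], model$sigma2, cache, as.integer(class_cap),
                         blocks = blocks)
  lods <- (res$loglik - matrix(null, nrow = length(graphs$positions),
                               ncol = ncol(tr), byrow = TRUE)) / log(10)
  colnames(lods) <- colnames(tr)
  out <- tibble(cm = graphs$positions)
  out <- dplyr::bind_cols(out, as_tibble(lods))
  out$average <- rowMeans(lods)
  structure(out,
            K = n_realizations(graphs), cache_hits = res$hits,
            cache_misses = res$misses, null = null,
            skipped = colnames(traits_matrix(traits))[!usable],
            source = graphs$source,
            class = c("lod_result", class(out)))
}

# named block id per individual: one block per family-connected component
pedigree_blocks <- function(peds) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  comps <- unlist(lapply(peds, pedigree_components), recursive = FALSE)
  unlist(lapply(seq_along(comps), function(i) {
    setNames(rep(i, nrow(comps[[i]]$members)), comps[[i]]$members$id)
  }))
}

traits_to_tibble <- function(tr) {
  out <- tibble(id = rownames(tr))
  for (j in seq_len(ncol(tr))) out[[colnames(tr)[j]]] <- tr[, j]
  out
}

#' LOD curves for many trait replicates and one or several graph sources
#'
#' With a single (e.g. merged) graph set this is [lod_curve()]. With a list
#' of per-pedigree graph sets (unmerged mode) the per-pedigree LOD curves
#' are summed at each position, which is the classical multi-pedigree
#' linkage total when no between-pedigree IBD is asserted. The `average`
#' column is the pointwise arithmetic mean of the per-replicate curves.
#'
#' @param graphs An [ibd_graph_set] or a list of them (per pedigree).
#' @param peds Pedigree list covering the phenotyped individuals (used for
#'   the null construction).
#' @param traits Trait tibble (`id` + replicate columns).
#' @param model A [qtl_model].
#' @param ... Passed to [lod_curve()].
#' @inheritParams lod_curve
#' @return A `lod_result` (summed across sources in unmerged mode).
#' @export
batch_lods <- function(graphs, peds, traits, model, null_M = 10000,
                       null_seed = 1L, ...) {
  if (inherits(graphs, "ibd_graph_set")) {
    blocks <- if (inherits(peds, "pedigree") || (is.list(peds) && inherits(peds[[1]], "pedigree"))) {
      pedigree_blocks(peds)
    } else NULL
    return(lod_curve(graphs, traits, model, null = peds, null_M = null_M,
                     null_seed = null_seed, cache_blocks = blocks, ...))
  }
  if (inherits(peds, "pedigree")) peds <- list(peds)
  tr <- traits_matrix(traits)
  per_ped <- lapply(graphs, function(g) {
    ped_match <- peds[vapply(peds, function(p) any(p$members$id %in% g$individuals), logical(1))]
    lod_curve(g, traits, model, null = ped_match, null_M = null_M,
              null_seed = null_seed, cache_blocks = pedigree_blocks(ped_match), ...)
  })
  reps <- setdiff(colnames(per_ped[[1]]), c("cm", "average"))
  total <- per_ped[[1]]
  for (r in per_ped[-1]) {
    for (cn in reps) total[[cn]] <- total[[cn]] + r[[cn]]
  }
  total$average <- rowMeans(as.matrix(total[reps]))
  attr(total, "K") <- attr(per_ped[[1]], "K")
  attr(total, "cache_hits") <- sum(vapply(per_ped, attr, numeric(1), "cache_hits"))
  attr(total, "cache_misses") <- sum(vapply(per_ped, attr, numeric(1), "cache_misses"))
  attr(total, "source") <- "unmerged_sum"
  total
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> %d positions, %d replicate(s), K = %s; max average LOD %.3f at %.2f cM\n",
              nrow(x), sum(!colnames(x) %in% c("cm", "average")),
              format(attr(x, "K")), max(x$average), x$cm[which.max(x$average)]))
  invisible(x)
}

#' Tidy and summarise LOD results
#'
#' `tidy()` returns one row per (position, replicate); `glance()` one row
#' with the curve maximum, its position, and cache statistics.
#'
#' @param x A `lod_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lod_result
#' @export
tidy.lod_result <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), cols = -c("cm"),
                      names_to = "replicate", values_to = "lod")
}

#' @rdname tidy.lod_result
#' @method glance lod_result
#' @export
glance.lod_result <- function(x, ...) {
  tibble(
    n_positions = nrow(x),
    n_replicates = sum(!colnames(x) %in% c("cm", "average")),
    K = as.integer(attr(x, "K") %||% NA),
    max_average_lod = max(x$average),
    argmax_cm = x$cm[which.max(x$average)],
    cache_hits = as.numeric(attr(x, "cache_hits") %||% NA),
    cache_misses = as.numeric(attr(x, "cache_misses") %||% NA)
  )
}

#' Plot LOD curves
#'
#' Per-replicate curves as light lines with the pointwise average
#' emphasised.
#'
#' @param object A `lod_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lod_result
#' @export
autoplot.lod_result <- function(object, ...) {
  long <- tidy.lod_result(object)
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = dplyr::filter(long, .data$replicate != "average"),
      ggplot2::aes(x = .data$cm, y = .data$lod, group = .data$replicate),
      colour = "cyan3", alpha = 0.4) +
    ggplot2::geom_line(
      data = dplyr::filter(long, .data$replicate == "average"),
      ggplot2::aes(x = .data$cm, y = .data$lod), colour = "black", linewidth = 1) +
    ggplot2::labs(x = "position (cM)", y = "LOD")
}

#' Write a LOD result as TSV (position, one column per replicate, average)
#' @param lods A `lod_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lods <- function(lods, path) {
  utils::write.table(as.data.frame(lods), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lods
#' @export
read_lods <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  out <- as_tibble(df)
  class(out) <- c("lod_result", class(out))
  out
}
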
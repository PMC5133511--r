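#' Family-based genotype imputation from IBD graph realizations
#'
#' GIGI-style imputation: dense-panel SNPs are imputed into untyped
#' individuals through the location-specific IBD realized conditional on
#' the sparse panel. Each dense SNP is assigned to its nearest sparse-grid
#' position (cM, ties to the lower position; SNPs outside the grid go to
#' the nearest end with a warning). Within each realization's IBD component
#' at that position, founder-genome-label allele assignments are weighted
#' by population frequency times the observation likelihood of the
#' dense-typed members' genotypes (per-allele error `eps`); the target's
#' genotype probabilities are the posterior marginals of its two slots'
#' alleles. FGL classes untouched by any observed genotype fall back to
#' Hardy-Weinberg at the SNP's frequency (how imputation degrades to the
#' population MAF when pedigree information is absent). Probabilities are
#' averaged over the `K` realizations.
#'
#' @param graphs An [ibd_graph_set] on the sparse grid.
#' @param dense_panel A dense [marker_panel] carrying the dense-typed
#'   individuals' genotypes.
#' @param targets Individuals to impute (default: graph individuals
#'   without dense genotypes; dense-typed individuals may be included,
#'   e.g. for self-consistency checks).
#' @param eps Per-allele error rate (default: the dense panel's).
#' @param class_cap Capacity cap on IBD classes per component.
#' @return An `imputation_result`: tibble with `id`, `marker`, `cm`, `p0`,
#'   `p1`, `p2`, `dosage` (`= p1 + 2 p2`).
#' @export
impute_genotypes <- function(graphs, dense_panel, targets = NULL,
                             eps = dense_panel$eps, class_cap = 22) {
  obs_ids <- intersect(colnames(dense_panel$geno), graphs$individuals)
  if (is.null(targets)) targets <- setdiff(graphs$individuals, obs_ids)
  targets <- as.character(targets)
  if (!length(targets)) abort("no target individuals")
  if (!all(targets %in% graphs$individuals)) abort("targets must be graph individuals")

  dmap <- dense_panel$map
  outside <- dmap$cm < min(graphs$positions) | dmap$cm > max(graphs$positions)
  if (any(outside)) {
    warn(sprintf("%d dense SNP(s) outside the sparse grid assigned to the nearest end",
                 sum(outside)))
  }
  assign_idx <- nearest_grid_index(dmap$cm, graphs$positions)
  K <- n_realizations(graphs)
  n_snp <- nrow(dmap)
  slots <- slot_names(graphs$individuals)
  probs <- array(0, dim = c(length(targets), n_snp, 3L),
                 dimnames = list(targets, dmap$marker, NULL))
  geno_obs <- dense_panel$geno[, obs_ids, drop = FALSE]
  pen <- genotype_obs_prob_table(eps)

  floored <- FALSE
  pen_floor <- genotype_obs_prob_table(max(eps, 1e-9))
  for (k in seq_len(K)) {
    r <- graphs$realizations[[k]]
    seg_of_snp <- findInterval(assign_idx, r$pos)
    for (seg in unique(seg_of_snp)) {
      snps <- which(seg_of_snp == seg)
      lab <- setNames(r$labels[seg, ], slots)
      block <- impute_segment(lab, geno_obs[snps, , drop = FALSE],
                              dense_panel$freq[snps], pen, targets, class_cap)
      if (anyNA(block)) {
        # a SNP inconsistent with this realization's partition at eps = 0
        # (e.g. recombination between the SNP and its assigned sparse
        # marker): fall back to an error floor for the block
        floored <- TRUE
        block <- impute_segment(lab, geno_obs[snps, , drop = FALSE],
                                dense_panel$freq[snps], pen_floor, targets, class_cap)
      }
      probs[, snps, ] <- probs[, snps, , drop = FALSE] + block
    }
  }
  if (floored) {
    inform("some SNP/realization blocks were inconsistent at eps = 0; an error floor of 1e-9 was used there")
  }
  probs <- probs / K
  # self-consistency in the error-free limit: a dense-typed target's own
  # observation is definitive, whatever the realized IBD says elsewhere
  if (eps == 0) {
    for (id in intersect(targets, obs_ids)) {
      seen <- which(!is.na(dense_panel$geno[, id]))
      for (j in seen) {
        probs[id, j, ] <- 0
        probs[id, j, dense_panel$geno[j, id] + 1L] <- 1
      }
    }
  }
  out <- tibble(
    id = rep(targets, each = n_snp),
    marker = rep(dmap$marker, length(targets)),
    cm = rep(dmap$cm, length(targets)),
    p0 = as.vector(t(probs[, , 1])),
    p1 = as.vector(t(probs[, , 2])),
    p2 = as.vector(t(probs[, , 3]))
  )
  out$dosage <- out$p1 + 2 * out$p2
  class(out) <- c("imputation_result", class(out))
  out
}

# posterior genotype probabilities for all targets over a block of SNPs
# sharing one partition; returns array (targets x snps x 3)
impute_segment <- function(lab, geno_obs, freq, pen, targets, class_cap) {
  slot_ind <- sub("\\.[01]$", "", names(lab))
  comps <- partition_slot_components(lab)
  n_snp <- length(freq)
  res <- array(0, dim = c(length(targets), n_snp, 3L))
  obs_ids <- colnames(geno_obs)
  for (ix in comps) {
    ids_here <- unique(slot_ind[ix])
    tg <- intersect(targets, ids_here)
    if (!length(tg)) next
    cls <- canonical_labels(lab[ix])
    c_n <- max(cls)
    if (c_n > class_cap) {
      abort(sprintf("component has %d IBD classes, above the cap of %d", c_n, class_cap),
            class = "ibdmap_capacity_error")
    }
    oi <- intersect(obs_ids, ids_here)
    slot_class <- function(id) cls[which(slot_ind[ix] == id)]
    o_pat <- vapply(oi, function(i) slot_class(i)[1], integer(1))
    o_mat <- vapply(oi, function(i) slot_class(i)[2], integer(1))
    t_pat <- vapply(tg, function(i) slot_class(i)[1], integer(1))
    t_mat <- vapply(tg, function(i) slot_class(i)[2], integer(1))

    tot <- matrix(0, n_snp, 1)
    acc <- array(0, dim = c(length(tg), n_snp, 3L))
    for (a in 0:(2L^c_n - 1L)) {
      bit <- bitwAnd(bitwShiftL(1L, seq_len(c_n) - 1L), a) > 0
      w <- rep(1, n_snp)
      for (cc in seq_len(c_n)) w <- w * (if (bit[cc]) freq else 1 - freq)
      for (j in seq_along(oi)) {
        g <- geno_obs[, oi[j]]
        x <- sum(bit[o_pat[j]], bit[o_mat[j]])
        ok <- !is.na(g)
        w[ok] <- w[ok] * pen[x + 1L, g[ok] + 1L]
      }
      tot <- tot + w
      for (j in seq_along(tg)) {
        x <- sum(bit[t_pat[j]], bit[t_mat[j]])
        acc[j, , x + 1L] <- acc[j, , x + 1L] + w
      }
    }
    if (any(tot == 0)) return(array(NA_real_, dim = dim(res)))
    ti <- match(tg, targets)
    for (g in 1:3) res[ti, , g] <- acc[, , g] / matrix(tot, length(tg), n_snp, byrow = TRUE)
  }
  # targets in components with no slots (cannot happen) or untouched classes
  # are covered by the enumeration itself; targets absent from every
  # component with observations still got Hardy-Weinberg marginals above.
  res
}

#' Hardy-Weinberg (no-pedigree) baseline imputation
#'
#' Every target gets the population genotype distribution at each SNP -
#' what family-based imputation falls back to with no informative
#' relatives.
#'
#' @param dense_panel A dense [marker_panel].
#' @param targets Individual ids.
#' @return An `imputation_result`.
#' @export
hw_imputation <- function(dense_panel, targets) {
  dmap <- dense_panel$map
  p <- dense_panel$freq
  n_snp <- nrow(dmap)
  out <- tibble(
    id = rep(as.character(targets), each = n_snp),
    marker = rep(dmap$marker, length(targets)),
    cm = rep(dmap$cm, length(targets)),
    p0 = rep((1 - p)^2, length(targets)),
    p1 = rep(2 * p * (1 - p), length(targets)),
    p2 = rep(p^2, length(targets))
  )
  out$dosage <- out$p1 + 2 * out$p2
  class(out) <- c("imputation_result", class(out))
  out
}

#' Dosage matrix of an imputation result
#' @param result An `imputation_result`.
#' @return Matrix markers x individuals.
#' @export
dosage_matrix <- function(result) {
  ids <- unique(result$id)
  mk <- unique(result$marker)
  m <- matrix(NA_real_, length(mk), length(ids), dimnames = list(mk, ids))
  m[cbind(match(result$marker, mk), match(result$id, ids))] <- result$dosage
  m
}

#' Correlation-based imputation accuracy (rho1 / rho2)
#'
#' Per-SNP Pearson correlation between true genotypes (0/1/2) and imputed
#' dosages across target individuals. `rho1` divides the summed
#' correlations by the number of SNPs imputed as polymorphic (`n_snpe`);
#' `rho2` divides the same sum by the number of SNPs polymorphic in the
#' reference panel (`n_snps`), so it also reflects SNPs the imputation
#' failed to recover. SNPs whose true genotypes have zero variance have
#' undefined correlation: they contribute 0 to the sum and are excluded
#' from `n_snpe`. Results are reported overall and within reference-MAF
#' bins (0,0.01], (0.01,0.15], (0.15,0.5].
#'
#' Correlation (rather than concordance) implicitly adjusts for MAF, which
#' matters for rare variants.
#'
#' @param truth Matrix of true genotypes (markers x individuals).
#' @param result An `imputation_result` covering the same individuals/SNPs.
#' @param ref_freq Named per-marker alternate-allele frequencies of the
#'   reference panel (used for polymorphism and MAF bins).
#' @return An `accuracy_report` tibble: rows `overall` and one per MAF
#'   bin; columns `bin`, `n_snps`, `n_snpe`, `rho1`, `rho2`.
#' @export
imputation_accuracy <- function(truth, result, ref_freq) {
  dos <- dosage_matrix(result)
  ids <- intersect(colnames(truth), colnames(dos))
  mk <- intersect(rownames(truth), rownames(dos))
  if (!length(ids) || !length(mk)) abort("truth and result must share individuals and SNPs")
  truth <- truth[mk, ids, drop = FALSE]
  dos <- dos[mk, ids, drop = FALSE]
  f <- ref_freq[mk]
  maf <- pmin(f, 1 - f)

  v_true <- apply(truth, 1, function(x) stats::var(x[!is.na(x)]))
  v_dos <- apply(dos, 1, stats::var)
  poly_ref <- maf > 0
  poly_imp <- !is.na(v_dos) & v_dos > 0
  corr <- rep(0, length(mk))
  defined <- poly_imp & !is.na(v_true) & v_true > 0
  for (i in which(defined)) {
    corr[i] <- stats::cor(truth[i, ], dos[i, ], use = "complete.obs")
  }
  if (any(poly_imp & !defined)) {
    inform(sprintf("%d SNP(s) with zero-variance true genotypes excluded from n_snpe",
                   sum(poly_imp & !defined)))
  }
  one_row <- function(sel, name) {
    tibble(
      bin = name,
      n_snps = sum(poly_ref & sel),
      n_snpe = sum(defined & sel),
      rho1 = if (sum(defined & sel) > 0) sum(corr[defined & sel]) / sum(defined & sel) else 0,
      rho2 = if (sum(poly_ref & sel) > 0) sum(corr[defined & sel]) / sum(poly_ref & sel) else 0
    )
  }
  bins <- list(
    "overall" = rep(TRUE, length(mk)),
    "(0,0.01]" = maf > 0 & maf <= 0.01,
    "(0.01,0.15]" = maf > 0.01 & maf <= 0.15,
    "(0.15,0.5]" = maf > 0.15
  )
  out <- purrr::map2_dfr(bins, names(bins), one_row)
  class(out) <- c("accuracy_report", class(out))
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  print(as_tibble(x))
  invisible(x)
}

#' @rdname imputation_accuracy
#' @param x An `accuracy_report`.
#' @param ... Unused.
#' @method glance accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) {
  as_tibble(x[x$bin == "overall", ])
}

#' Write an accuracy report as TSV (overall and per-bin rows)
#' @param report An `accuracy_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accuracy <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
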
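#' Single-marker emission probability of an inheritance vector
#'
#' Probability of observed genotypes at one marker given an inheritance
#' vector: the IV is propagated to its IBD partition and the partition
#' genotype likelihood is multiplied over connected components.
#'
#' @param iv Integer 0/1 vector, one bit per meiosis.
#' @param ped A [pedigree].
#' @param geno Named numeric vector of genotypes (0/1/2, `NA` missing).
#' @param freq Alternate-allele frequency at the marker.
#' @param eps Per-allele error rate.
#' @return Probability in `[0, 1]`.
#' @export
iv_emission <- function(iv, ped, geno, freq, eps = 0) {
  partition_likelihood(iv_to_partition(iv, ped), geno, freq, eps)
}

#' Sample inheritance vectors conditional on sparse-panel genotypes
#'
#' Draws `K` realizations from the exact posterior over inheritance-vector
#' paths given unordered genotypes on a sparse marker panel, under the
#' Lander-Green hidden Markov model: uniform IV prior, per-interval
#' transitions in which each meiosis bit flips independently with the
#' Haldane recombination fraction, and genotype-likelihood emissions with
#' per-allele error rate `panel$eps`. The forward pass is computed exactly
#' over the `2^m` IV states of each family-connected pedigree component and
#' paths are drawn by backward sampling, so the realizations are exact
#' posterior draws, not MCMC output. A new change-point is recorded only
#' when the induced set-partition (not the raw IV) changes.
#'
#' @param ped A [pedigree]; each family-connected component must have at
#'   most `cap` meioses.
#' @param panel A [marker_panel] on the sparse map; individuals absent from
#'   the panel columns are treated as untyped.
#' @param K Number of realizations.
#' @param seed Integer seed.
#' @param cap Meiosis cap per pedigree component (default 18, about 262k
#'   states); larger components need to be split before exact sampling.
#' @return An [ibd_graph_set] on the panel grid with attributes `loglik`
#'   (total log-likelihood of the genotype data, natural log) and
#'   `component_logliks` (per pedigree component; the total is their sum).
#' @export
sample_ivs <- function(ped, panel, K = 100, seed = 1L, cap = 18L) {
  if (K < 1) abort("K must be >= 1")
  comps <- pedigree_components(ped)
  too_big <- vapply(comps, function(p) nrow(p$meioses), integer(1)) > cap
  if (any(too_big)) {
    abort(sprintf(
      "pedigree component(s) with more than %d meioses (%s); split the pedigree before exact IV sampling",
      cap, paste(vapply(comps[too_big], function(p) p$ped_id, character(1)), collapse = ", ")),
      class = "ibdmap_capacity_error")
  }
  set.seed(as.integer(seed))
  theta <- map_theta(panel$map)
  M <- nrow(panel$map)

  offset <- 0L
  logliks <- numeric(length(comps))
  comp_reals <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    p <- comps[[ci]]
    res <- sample_ivs_component(p, panel, theta, M, K)
    logliks[ci] <- res$loglik
    comp_reals[[ci]] <- lapply(res$reals, function(r) {
      r$labels <- r$labels + offset
      r
    })
    offset <- offset + 2L * length(p$founders)
  }
  individuals <- unlist(lapply(comps, function(p) p$members$id))
  reals <- lapply(seq_len(K), function(k) {
    combine_realizations(lapply(comp_reals, `[[`, k))
  })
  out <- ibd_graph_set(individuals, panel$map$cm, reals, source = "sample_ivs")
  attr(out, "loglik") <- sum(logliks)
  attr(out, "component_logliks") <- setNames(logliks, vapply(comps, function(p) p$ped_id, character(1)))
  out
}

sample_ivs_component <- function(p, panel, theta, M, K) {
  mem <- p$members
  n <- nrow(mem)
  father <- ifelse(is.na(mem$father), -1L, match(mem$father, mem$id) - 1L)
  mother <- ifelse(is.na(mem$mother), -1L, match(mem$mother, mem$id) - 1L)
  typed <- intersect(mem$id, colnames(panel$geno))
  g <- panel$geno[, typed, drop = FALSE]
  typed <- typed[colSums(!is.na(g)) > 0]
  obs <- match(typed, mem$id) - 1L

  if (nrow(p$meioses) == 0L) {
    # founders only: all-distinct partition everywhere, one change-point
    lab <- matrix(seq_len(2L * n), nrow = 1L)
    reals <- replicate(K, list(pos = 1L, labels = lab), simplify = FALSE)
    ll <- 0
    if (length(typed)) {
      part <- setNames(seq_len(2L * n), slot_names(p))
      ll <- sum(log(vapply(seq_len(M), function(j) {
        gj <- panel$geno[j, typed]
        names(gj) <- typed
        partition_likelihood(part, gj, panel$freq[j], panel$eps)
      }, numeric(1))))
    }
    return(list(reals = reals, loglik = ll))
  }

  tabs <- lg_state_tables(father, mother, obs)
  if (length(obs)) {
    gm <- panel$geno[, mem$id[obs + 1L], drop = FALSE]   # M x n_obs
    gm[is.na(gm)] <- -1
    storage.mode(gm) <- "integer"
    emis <- lg_emissions(tabs$obs_labels, gm, panel$freq, panel$eps)
  } else {
    emis <- matrix(1, nrow = 1L, ncol = M)
    tabs$obs_group <- rep(1L, 2L^tabs$n_meioses)
  }
  sm <- lg_forward_sample(emis, tabs$obs_group, theta, tabs$n_meioses, K)
  reals <- lapply(seq_len(K), function(k) {
    states <- sm$paths[k, ] + 1L
    grp <- tabs$full_group[states]
    cp <- which(c(TRUE, grp[-1] != grp[-M]))
    list(pos = cp, labels = tabs$fgl[states[cp], , drop = FALSE])
  })
  list(reals = reals, loglik = sm$loglik)
}

# merge per-component change-point realizations (disjoint label spaces)
# into one realization over the concatenated slot vector
combine_realizations <- function(rs) {
  if (length(rs) == 1L) return(rs[[1]])
  pos <- sort(unique(unlist(lapply(rs, `[[`, "pos"))))
  labels <- do.call(cbind, lapply(rs, function(r) {
    rows <- findInterval(pos, r$pos)
    r$labels[rows, , drop = FALSE]
  }))
  list(pos = pos, labels = labels)
}
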
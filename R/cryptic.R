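#' Pairwise IBD model (15 detailed states)
#'
#' Hidden Markov model for location-specific IBD between the four haplotype
#' slots of an ordered pair of individuals. The hidden state is one of the
#' 15 set-partitions of the 4 slots (detailed states; the 9 condensed
#' genotypic states are coarsenings). Along the chromosome the state jumps
#' to its stationary distribution at rate `alpha` per cM, giving the
#' transition matrix `exp(-alpha*d) I + (1 - exp(-alpha*d)) 1 pi'` over a
#' distance of `d` cM.
#'
#' The stationary distribution `pi` is parameterized by a marginal
#' cross-pair IBD probability `beta` and a within-individual autozygosity
#' weight `delta`: each partition gets weight
#' `prod(cross pairs: gamma if shared else 1-gamma) *
#'  prod(within pairs: delta if shared else 1-delta)`
#' normalized over the 15 partitions, with `gamma = 1 - (1-beta)^(1/4)` so
#' that for small rates the chance that at least one of the 4 cross
#' slot-pairs is IBD is about `beta`.
#'
#' @param beta Marginal probability that the pair shares any IBD at a
#'   locus (default 0.05).
#' @param alpha State-change rate per cM (default 0.05).
#' @param eps Per-allele genotyping error rate (default 0.01).
#' @param delta Within-individual autozygosity weight (default 0.02).
#' @param pi Optional explicit stationary distribution (length 15,
#'   overrides `beta`/`delta`).
#' @return An object of class `pairwise_ibd_model` with elements `states`
#'   (15 x 4 matrix of class labels for slots i.0, i.1, j.0, j.1), `pi`,
#'   `alpha`, `eps`.
#' @export
pairwise_ibd_model <- function(beta = 0.05, alpha = 0.05, eps = 0.01,
                               delta = 0.02, pi = NULL) {
  states <- partitions_of_4()
  if (is.null(pi)) {
    gamma <- 1 - (1 - beta)^(1 / 4)
    cross <- rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
    within <- rbind(c(1, 2), c(3, 4))
    w <- apply(states, 1, function(s) {
      wc <- prod(ifelse(s[cross[, 1]] == s[cross[, 2]], gamma, 1 - gamma))
      ww <- prod(ifelse(s[within[, 1]] == s[within[, 2]], delta, 1 - delta))
      wc * ww
    })
    pi <- w / sum(w)
  }
  if (length(pi) != 15 || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    abort("pi must be a distribution over the 15 states")
  }
  if (alpha < 0) abort("alpha must be >= 0")
  structure(list(states = states, pi = as.numeric(pi), alpha = alpha, eps = eps),
            class = "pairwise_ibd_model")
}

# the 15 set-partitions of 4 elements as canonical restricted growth strings
partitions_of_4 <- function() {
  out <- list()
  grow <- function(prefix) {
    if (length(prefix) == 4L) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(max(prefix) + 1L)) grow(c(prefix, v))
  }
  grow(1L)
  m <- do.call(rbind, out)
  colnames(m) <- c("i.0", "i.1", "j.0", "j.1")
  m
}

# which of the 15 states share at least one cross-individual slot pair
states_any_cross_ibd <- function(states) {
  apply(states, 1, function(s) any(outer(s[1:2], s[3:4], "==")))
}

#' Posterior over pairwise IBD states along a dense panel
#'
#' Forward-backward over the 15 detailed IBD states for one pair of
#' individuals, with genotype-likelihood emissions.
#'
#' @param panel A dense [marker_panel].
#' @param pair Character vector of two individual ids (columns of the
#'   panel).
#' @param model A [pairwise_ibd_model].
#' @return A `pairwise_posterior` object: tibble with `marker`, `cm`,
#'   `p_ibd` (posterior probability that any cross-individual slot pair is
#'   IBD) and columns `s1`..`s15`; the state definitions and the model are
#'   attached as attributes. Log-likelihood of the pair's genotypes is in
#'   attribute `loglik`.
#' @export
pairwise_posterior <- function(panel, pair, model = pairwise_ibd_model()) {
  if (nrow(panel$map) < 2) abort("need at least 2 markers")
  if (length(pair) != 2 || !all(pair %in% colnames(panel$geno))) {
    abort("pair must name two genotyped individuals")
  }
  gi <- panel$geno[, pair[1]]
  gj <- panel$geno[, pair[2]]
  emis <- pairwise_emissions(model$states, gi, gj, panel$freq, model$eps)
  M <- nrow(panel$map)
  d <- diff(panel$map$cm)
  stay <- exp(-model$alpha * d)
  pi <- model$pi

  fwd <- matrix(0, M, 15)
  loglik <- 0
  f <- pi * emis[1, ]
  norm <- sum(f); loglik <- loglik + log(norm); fwd[1, ] <- f / norm
  for (j in 2:M) {
    f <- (stay[j - 1] * fwd[j - 1, ] + (1 - stay[j - 1]) * pi) * emis[j, ]
    norm <- sum(f); loglik <- loglik + log(norm); fwd[j, ] <- f / norm
  }
  post <- matrix(0, M, 15)
  b <- rep(1, 15)
  post[M, ] <- fwd[M, ]
  for (j in (M - 1):1) {
    be <- b * emis[j + 1, ]
    b <- stay[j] * be + (1 - stay[j]) * sum(pi * be)
    b <- b / sum(b)
    p <- fwd[j, ] * b
    post[j, ] <- p / sum(p)
  }
  any_ibd <- states_any_cross_ibd(model$states)
  out <- tibble(marker = panel$map$marker, cm = panel$map$cm,
                p_ibd = as.numeric(post %*% any_ibd))
  colnames(post) <- paste0("s", seq_len(15))
  out <- dplyr::bind_cols(out, as_tibble(post))
  attr(out, "pair") <- pair
  attr(out, "model") <- model
  attr(out, "loglik") <- loglik
  class(out) <- c("pairwise_posterior", class(out))
  out
}

# emission likelihood per marker (rows) per state (cols), vectorized over
# markers; genotypes NA contribute factor 1
pairwise_emissions <- function(states, gi, gj, freq, eps) {
  M <- length(freq)
  pen <- genotype_obs_prob_table(eps)
  emis <- matrix(0, M, nrow(states))
  for (s in seq_len(nrow(states))) {
    lab <- states[s, ]
    c_n <- max(lab)
    for (a in 0:(2^c_n - 1)) {
      bit <- bitwAnd(bitwShiftL(1L, seq_len(c_n) - 1L), a) > 0
      prior <- rep(1, M)
      for (cc in seq_len(c_n)) prior <- prior * (if (bit[cc]) freq else 1 - freq)
      xi <- sum(bit[lab[1]], bit[lab[2]])
      xj <- sum(bit[lab[3]], bit[lab[4]])
      pi_ <- rep(1, M); pj_ <- rep(1, M)
      ok_i <- !is.na(gi); ok_j <- !is.na(gj)
      pi_[ok_i] <- pen[xi + 1L, gi[ok_i] + 1L]
      pj_[ok_j] <- pen[xj + 1L, gj[ok_j] + 1L]
      emis[, s] <- emis[, s] + prior * pi_ * pj_
    }
  }
  emis
}

#' Call IBD segments from a pairwise posterior
#'
#' Maximal runs of consecutive markers whose posterior probability of any
#' cross-individual IBD is at least `threshold`; runs separated by
#' below-threshold gaps shorter than `merge_gap_cm` are merged.
#'
#' @param post A `pairwise_posterior` (or any tibble with `cm` and `p_ibd`).
#' @param threshold Posterior threshold in (0, 1) (default 0.8).
#' @param merge_gap_cm Merge gap (cM, default 0.5).
#' @return Tibble with `id1`, `id2`, `start_cm`, `end_cm`, `mean_p`
#'   (posterior averaged over the segment's markers); zero rows when
#'   nothing exceeds the threshold.
#' @export
call_ibd_segments <- function(post, threshold = 0.8, merge_gap_cm = 0.5) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  pair <- attr(post, "pair") %||% c(NA_character_, NA_character_)
  hot <- post$p_ibd >= threshold
  empty <- tibble(id1 = character(0), id2 = character(0), start_cm = numeric(0),
                  end_cm = numeric(0), mean_p = numeric(0))
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- tibble(start = starts[r$values], end = ends[r$values])
  # merge across short cold gaps
  i <- 1L
  while (i < nrow(segs)) {
    gap <- post$cm[segs$start[i + 1L]] - post$cm[segs$end[i]]
    if (gap < merge_gap_cm) {
      segs$end[i] <- segs$end[i + 1L]
      segs <- segs[-(i + 1L), ]
    } else i <- i + 1L
  }
  tibble(
    id1 = pair[1], id2 = pair[2],
    start_cm = post$cm[segs$start], end_cm = post$cm[segs$end],
    mean_p = vapply(seq_len(nrow(segs)), function(s) {
      mean(post$p_ibd[segs$start[s]:segs$end[s]])
    }, numeric(1))
  )
}

#' Haplotype-stitching model parameters
#'
#' @param rho Copy-switch rate per cM (default 0.1).
#' @param nu Probability that a new segment founds a novel founder genome
#'   label rather than copying an existing haplotype (default 0.5).
#' @param eps Miscopy/error rate (default 0.01).
#' @return A `stitch_model` object.
#' @export
stitch_model <- function(rho = 0.1, nu = 0.5, eps = 0.01) {
  if (rho < 0) abort("rho must be >= 0")
  if (nu <= 0 || nu > 1) abort("nu must lie in (0, 1]")
  if (eps < 0 || eps >= 0.5) abort("eps must lie in [0, 0.5)")
  structure(list(rho = rho, nu = nu, eps = eps), class = "stitch_model")
}

#' Jointly-consistent multi-individual IBD by haplotype stitching
#'
#' Sequentially samples location-specific IBD among individuals not
#' connected by pedigree. Haplotype slots are processed in a fixed order;
#' the first founds FGL 1, and each later slot follows a hidden copying
#' path: at any position it either copies one of the previously processed
#' slots (sharing that slot's location-specific FGL, matching its observed
#' allele with probability `1 - eps`) or carries a novel FGL (emitting by
#' population frequency). Copy switches occur at rate `rho` per cM; a
#' switch founds a novel FGL with probability `nu`, otherwise it picks a
#' previous slot uniformly. Because sharing is expressed through labels,
#' transitivity of IBD holds by construction in every realization.
#'
#' Unphased genotypes get a random phase per realization (the phase
#' uncertainty is flagged in the `phase_sampled` attribute; downstream
#' merging resolves bridge-haplotype orientation explicitly).
#'
#' @param panel A dense [marker_panel].
#' @param ids Individuals to stitch (default: all panel columns); n >= 2.
#' @param model A [stitch_model].
#' @param K Number of realizations.
#' @param seed Integer seed.
#' @param shuffle_order Optional integer; when given, the processing order
#'   of individuals is shuffled with this seed (the sequential sampler is
#'   order-sensitive at finite K).
#' @param haplotypes Optional list with matrices `hap0`, `hap1` (markers x
#'   individuals, 0/1/NA) of pre-phased haplotypes.
#' @param sweeps Number of sampling sweeps (default 1): the first
#'   introduces slots sequentially; optional extra sweeps re-sample every
#'   slot's copying path given all the others (the soft-phase emissions
#'   make the single sequential sweep sufficient in practice).
#' @return An [ibd_graph_set] on the `2 * length(ids)` slots over the
#'   panel grid.
#' @export
ibd_stitch <- function(panel, ids = colnames(panel$geno), model = stitch_model(),
                       K = 100, seed = 1L, shuffle_order = NULL,
                       haplotypes = NULL, sweeps = 1L) {
  if (K < 1) abort("K must be >= 1")
  ids <- as.character(ids)
  if (length(ids) < 2) abort("need at least 2 individuals to stitch")
  if (!all(ids %in% colnames(panel$geno))) abort("ids must be panel columns")
  if (!is.null(shuffle_order)) {
    set.seed(as.integer(shuffle_order))
    ids <- sample(ids)
  }
  g <- panel$geno[, ids, drop = FALSE]
  g[is.na(g)] <- -1
  storage.mode(g) <- "integer"
  phased <- !is.null(haplotypes)
  if (phased) {
    h0 <- haplotypes$hap0[, ids, drop = FALSE]; h1 <- haplotypes$hap1[, ids, drop = FALSE]
    h0[is.na(h0)] <- -1; h1[is.na(h1)] <- -1
    storage.mode(h0) <- "integer"; storage.mode(h1) <- "integer"
  } else {
    h0 <- h1 <- matrix(0L, 0, 0)
  }
  set.seed(as.integer(seed))
  fgls <- stitch_core(g, panel$freq, panel$map$cm, model$rho, model$nu,
                      model$eps, as.integer(K), phased, h0, h1,
                      sweeps = as.integer(sweeps))
  reals <- lapply(fgls, function(f) {
    compress_partitions(nrow(f), function(j) f[j, ])
  })
  out <- ibd_graph_set(ids, panel$map$cm, reals, source = "ibd_stitch")
  attr(out, "phase_sampled") <- !phased
  out
}

#' Plot a pairwise IBD posterior along the chromosome
#'
#' @param object A `pairwise_posterior`.
#' @param threshold Optional horizontal reference line.
#' @param ... Unused.
#' @return A ggplot object showing P(any cross-individual IBD) by position.
#' @method autoplot pairwise_posterior
#' @export
autoplot.pairwise_posterior <- function(object, threshold = NULL, ...) {
  pair <- attr(object, "pair")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$cm, y = .data$p_ibd)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (cM)", y = "P(any IBD)",
                  title = paste(pair, collapse = " ~ "))
  if (!is.null(threshold)) p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
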
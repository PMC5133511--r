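# pedigree fixtures ---------------------------------------------------------

make_trio <- function() {
  pedigree(data.frame(
    id = c("f", "m", "c"), father = c(NA, NA, "f"), mother = c(NA, NA, "m"),
    sex = c(1, 2, 1)), ped_id = "trio")
}

make_sibpair <- function() {
  pedigree(data.frame(
    id = c("f", "m", "s1", "s2"),
    father = c(NA, NA, "f", "f"), mother = c(NA, NA, "m", "m"),
    sex = c(1, 2, 1, 2)), ped_id = "sibs")
}

# three generations, 6 members, 8 slots: couple -> two children, one child
# marries in, one grandchild
make_threegen6 <- function() {
  pedigree(data.frame(
    id = c("g1", "g2", "u1", "p1", "sp", "k1"),
    father = c(NA, NA, "g1", "g1", NA, "p1"),
    mother = c(NA, NA, "g2", "g2", NA, "sp"),
    sex = c(1, 2, 1, 1, 2, 2)), ped_id = "tg6")
}

# 4-generation, 12-member pedigree used for hand-counted fixtures
ped12_file <- function(path = tempfile(fileext = ".ped")) {
  writeLines(c(
    "# family id father mother sex",
    "fam12 a1 0 0 1",
    "fam12 a2 0 0 2",
    "fam12 b1 a1 a2 1",
    "fam12 b2 a1 a2 2",
    "fam12 b3 0 0 2",
    "fam12 c1 b1 b3 1",
    "fam12 c2 b1 b3 2",
    "fam12 c3 0 0 1",
    "fam12 d1 c3 c2 1",
    "fam12 d2 c3 c2 2",
    "fam12 e1 0 0 2",
    "fam12 d3 c3 e1 1"
  ), path)
  path
}

flat_map <- function(n, spacing = 1, start = 0) {
  genetic_map(paste0("m", seq_len(n)), seq(start, by = spacing, length.out = n))
}

# independent oracles --------------------------------------------------------

# brute-force single-locus genotype likelihood of a full partition: loop
# over every assignment of alleles to classes (no bit tricks, no reuse of
# package internals beyond the partition labels themselves)
oracle_partition_lik <- function(labels, geno, p, eps = 0) {
  geno <- geno[!is.na(geno)]
  if (length(geno) == 0) return(1)
  classes <- sort(unique(labels))
  obs_p <- function(a_obs, a_true) if (a_obs == a_true) 1 - eps else eps
  geno_p <- function(g, x, y) {
    if (g == 1) {
      obs_p(0, x) * obs_p(1, y) + obs_p(1, x) * obs_p(0, y)
    } else {
      a <- g / 2
      obs_p(a, x) * obs_p(a, y)
    }
  }
  total <- 0
  for (assign in 0:(2^length(classes) - 1)) {
    alleles <- as.integer(intToBits(assign))[seq_along(classes)]
    names(alleles) <- classes
    w <- prod(ifelse(alleles == 1, p, 1 - p))
    for (id in names(geno)) {
      x <- alleles[as.character(labels[paste0(id, ".0")])]
      y <- alleles[as.character(labels[paste0(id, ".1")])]
      w <- w * geno_p(geno[[id]], x, y)
    }
    total <- total + w
  }
  total
}

# brute-force trait likelihood of a partition component: plain double loop
# over the 2^c latent allele assignments
oracle_trait_lik <- function(labels, traits, model) {
  classes <- sort(unique(labels))
  total <- 0
  for (assign in 0:(2^length(classes) - 1)) {
    alleles <- as.integer(intToBits(assign))[seq_along(classes)]
    names(alleles) <- classes
    w <- prod(ifelse(alleles == 1, model$q, 1 - model$q))
    for (id in names(traits)) {
      if (is.na(traits[[id]])) next
      x <- alleles[as.character(labels[paste0(id, ".0")])] +
        alleles[as.character(labels[paste0(id, ".1")])]
      w <- w * dnorm(traits[[id]], model$mu[x + 1], sqrt(model$sigma2))
    }
    total <- total + w
  }
  total
}

# dense-matrix Lander-Green forward pass over all 2^m IV states, with
# explicit transition matrices and oracle emissions; returns per-marker
# posterior state probabilities and the log-likelihood
oracle_lg_posterior <- function(ped, panel) {
  m <- nrow(ped$meioses)
  M <- nrow(panel$map)
  theta <- haldane_theta(diff(panel$map$cm))
  states <- 0:(2^m - 1)
  emis <- matrix(0, length(states), M)
  for (s in seq_along(states)) {
    iv <- as.integer(intToBits(states[s]))[1:m]
    part <- iv_to_partition(iv, ped)
    for (j in seq_len(M)) {
      g <- panel$geno[j, intersect(colnames(panel$geno), ped$members$id)]
      g <- g[!is.na(g)]
      emis[s, j] <- oracle_partition_lik(part, g, panel$freq[j], panel$eps)
    }
  }
  trans <- function(th) {
    S <- length(states)
    T1 <- matrix(0, S, S)
    for (a in seq_len(S)) for (b in seq_len(S)) {
      h <- sum(as.integer(intToBits(bitwXor(states[a], states[b]))[1:m]))
      T1[a, b] <- th^h * (1 - th)^(m - h)
    }
    T1
  }
  fwd <- matrix(0, length(states), M)
  f <- rep(1 / 2^m, 2^m) * emis[, 1]
  loglik <- log(sum(f)); fwd[, 1] <- f / sum(f)
  for (j in 2:M) {
    f <- as.vector(t(trans(theta[j - 1])) %*% fwd[, j - 1]) * emis[, j]
    loglik <- loglik + log(sum(f)); fwd[, j] <- f / sum(f)
  }
  bwd <- matrix(1, length(states), M)
  for (j in (M - 1):1) {
    bwd[, j] <- trans(theta[j]) %*% (bwd[, j + 1] * emis[, j + 1])
    bwd[, j] <- bwd[, j] / sum(bwd[, j])
  }
  post <- fwd * bwd
  post <- sweep(post, 2, colSums(post), "/")
  list(post = post, loglik = loglik, emis = emis)
}

# recursive kinship coefficient (independent of the gene-drop machinery)
oracle_kinship <- function(ped, a, b) {
  mem <- ped$members
  parent <- function(id) {
    i <- match(id, mem$id)
    c(mem$father[i], mem$mother[i])
  }
  memo <- new.env()
  phi <- function(x, y) {
    key <- paste(sort(c(x, y)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    ix <- match(x, mem$id); iy <- match(y, mem$id)
    val <- if (x == y) {
      p <- parent(x)
      if (is.na(p[1])) 0.5 else 0.5 * (1 + phi(p[1], p[2]))
    } else if (ix > iy) {          # members are topologically ordered
      p <- parent(x)
      if (is.na(p[1])) 0 else 0.5 * (phi(p[1], y) + phi(p[2], y))
    } else {
      p <- parent(y)
      if (is.na(p[1])) 0 else 0.5 * (phi(p[1], x) + phi(p[2], x))
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

# small panel builder: explicit genotypes (markers x individuals)
panel_from <- function(geno, cm = NULL, freq = NULL, eps = 0) {
  if (is.null(cm)) cm <- seq(0, by = 1, length.out = nrow(geno))
  map <- genetic_map(rownames(geno) %||% paste0("m", seq_len(nrow(geno))), cm)
  rownames(geno) <- map$marker
  marker_panel(map, geno, freq = freq, eps = eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
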
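test_that("pairwise transition structure is stochastic and collapses correctly", {
  m <- pairwise_ibd_model(beta = 0.08, alpha = 0.07)
  expect_equal(sum(m$pi), 1)
  expect_true(all(m$pi >= 0))
  expect_equal(nrow(m$states), 15)
  expect_equal(nrow(unique(m$states)), 15)
  for (d in c(0, 0.5, 3, 100)) {
    s <- exp(-m$alpha * d)
    Tm <- s * diag(15) + (1 - s) * matrix(m$pi, 15, 15, byrow = TRUE)
    expect_equal(rowSums(Tm), rep(1, 15))
    if (d == 0) expect_equal(Tm, diag(15))
  }
})

test_that("forward likelihood equals the exhaustive path sum on a short panel", {
  set.seed(5)
  M <- 3
  geno <- cbind(a = sample(0:2, M, TRUE), b = sample(0:2, M, TRUE))
  panel <- panel_from(geno, cm = c(0, 2, 5), freq = c(0.3, 0.5, 0.7), eps = 0.02)
  model <- pairwise_ibd_model(beta = 0.1, alpha = 0.08, eps = 0.02)
  post <- pairwise_posterior(panel, c("a", "b"), model)

  # brute force over all 15^3 state paths with independently computed
  # emissions and explicit jump-process transitions
  emis <- sapply(seq_len(15), function(s) {
    lab <- setNames(model$states[s, ], c("a.0", "a.1", "b.0", "b.1"))
    vapply(seq_len(M), function(j) {
      oracle_partition_lik(lab, setNames(geno[j, c("a", "b")], c("a", "b")),
                           panel$freq[j], 0.02)
    }, numeric(1))
  })
  stay <- exp(-model$alpha * diff(panel$map$cm))
  total <- 0
  for (s1 in 1:15) for (s2 in 1:15) for (s3 in 1:15) {
    t12 <- stay[1] * (s1 == s2) + (1 - stay[1]) * model$pi[s2]
    t23 <- stay[2] * (s2 == s3) + (1 - stay[2]) * model$pi[s3]
    total <- total + model$pi[s1] * emis[1, s1] * t12 * emis[2, s2] * t23 * emis[3, s3]
  }
  expect_equal(attr(post, "loglik"), log(total), tolerance = 1e-9)
  expect_equal(rowSums(as.matrix(post[paste0("s", 1:15)])), rep(1, M))
})

test_that("degenerate priors behave as contracted", {
  set.seed(9)
  M <- 30
  geno <- cbind(a = sample(0:2, M, TRUE), b = sample(0:2, M, TRUE))
  panel <- panel_from(geno, freq = runif(M, 0.3, 0.7), eps = 0.01)
  # point mass on the all-distinct state
  states <- ibdmap:::partitions_of_4()
  all_distinct <- which(apply(states, 1, function(s) length(unique(s)) == 4))
  pi0 <- rep(0, 15); pi0[all_distinct] <- 1
  model <- pairwise_ibd_model(pi = pi0)
  post <- pairwise_posterior(panel, c("a", "b"), model)
  expect_equal(post$p_ibd, rep(0, M))
  expect_equal(post[[paste0("s", all_distinct)]], rep(1, M))

  # all-missing data: posterior equals the marginal prior at every marker
  panel2 <- panel_from(matrix(NA_real_, M, 2, dimnames = list(NULL, c("a", "b"))),
                       freq = rep(0.5, M), eps = 0.01)
  m2 <- pairwise_ibd_model(beta = 0.2)
  post2 <- pairwise_posterior(panel2, c("a", "b"), m2)
  for (j in c(1, 15, 30)) {
    expect_equal(as.numeric(post2[j, paste0("s", 1:15)]), m2$pi, tolerance = 1e-12)
  }
})

test_that("identical genotypes at many informative markers give near-certain IBD", {
  set.seed(12)
  M <- 500
  g <- sample(0:2, M, TRUE, prob = c(.25, .5, .25))
  panel <- panel_from(cbind(a = g, b = g), cm = seq(0, 100, length.out = M),
                      freq = rep(0.5, M), eps = 0.01)
  post <- pairwise_posterior(panel, c("a", "b"))
  mid <- (M %/% 4):(3 * M %/% 4)
  expect_true(all(post$p_ibd[mid] > 0.99))
})

test_that("segment calling finds runs and merges short gaps", {
  fake <- tibble::tibble(cm = seq(0, 20, by = 0.2),
                         p_ibd = 0.1)
  expect_equal(nrow(call_ibd_segments(fake, 0.8)), 0)
  # one hot block
  fake$p_ibd[26:50] <- 0.95
  segs <- call_ibd_segments(fake, 0.8)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_cm, fake$cm[26])
  expect_equal(segs$end_cm, fake$cm[50])
  # a 0.2 cM dip inside the block is merged; a 2 cM gap is not
  fake$p_ibd[38] <- 0.2
  expect_equal(nrow(call_ibd_segments(fake, 0.8)), 1)
  fake$p_ibd[60:70] <- 0.9
  expect_equal(nrow(call_ibd_segments(fake, 0.8)), 2)
  expect_error(call_ibd_segments(fake, 1.2))
})

test_that("a planted shared segment is recovered by the pairwise screen", {
  # two individuals share one haplotype over 25 cM in the middle of an
  # 80 cM chromosome; the called segment should cover the true midpoint
  reps <- 20
  hit <- 0
  for (r in seq_len(reps)) {
    set.seed(300 + r)
    M <- 640
    cm <- seq(0, 80, length.out = M)
    p <- runif(M, 0.2, 0.8)
    shared_zone <- cm >= 27.5 & cm <= 52.5
    h_shared <- rbinom(M, 1, p)
    mk <- function() {
      h1 <- rbinom(M, 1, p); h2 <- rbinom(M, 1, p)
      g <- h1 + h2
      g[shared_zone] <- (h_shared + h2)[shared_zone]
      g
    }
    panel <- panel_from(cbind(a = mk(), b = mk()), cm = cm, freq = p, eps = 0.01)
    segs <- call_ibd_segments(pairwise_posterior(panel, c("a", "b")), 0.8)
    if (nrow(segs) > 0 && any(segs$start_cm <= 40 & segs$end_cm >= 40)) hit <- hit + 1
  }
  expect_gte(hit / reps, 0.95)
})

test_that("stitch honors its degenerate and transitive contracts", {
  set.seed(77)
  M <- 120
  ids <- c("a", "b", "c")
  geno <- matrix(sample(0:2, M * 3, TRUE), M, 3, dimnames = list(NULL, ids))
  panel <- panel_from(geno, cm = seq(0, 60, length.out = M),
                      freq = rep(0.5, M), eps = 0.01)
  # nu = 1: copying is impossible, every realization is all-distinct
  g <- ibd_stitch(panel, ids, stitch_model(nu = 1), K = 5, seed = 3)
  for (k in 1:5) {
    expect_length(unique(partition_at(g, k, 60)), 6)
  }
  expect_error(ibd_stitch(panel, ids, K = 0), "K")

  # transitivity holds in every realization at every stored change-point
  g2 <- ibd_stitch(panel, ids, K = 10, seed = 9)
  violations <- 0
  for (k in 1:10) {
    r <- g2$realizations[[k]]
    for (row in seq_along(r$pos)) {
      lab <- r$labels[row, ]
      ab <- any(outer(lab[1:2], lab[3:4], "=="))
      bc <- any(outer(lab[3:4], lab[5:6], "=="))
      ac <- any(outer(lab[1:2], lab[5:6], "=="))
      shared_class <- intersect(intersect(lab[1:2], lab[3:4]), lab[5:6])
      if (length(shared_class) > 0 && !(ab && bc && ac)) violations <- violations + 1
    }
  }
  expect_equal(violations, 0)
})

test_that("stitch detects duplicated individuals with high probability", {
  set.seed(21)
  M <- 500
  g <- sample(0:2, M, TRUE, prob = c(.25, .5, .25))
  extra <- sapply(1:3, function(i) sample(0:2, M, TRUE, prob = c(.25, .5, .25)))
  colnames(extra) <- paste0("x", 1:3)
  panel <- panel_from(cbind(dup1 = g, dup2 = g, extra),
                      cm = seq(0, 100, length.out = M), freq = rep(0.5, M),
                      eps = 0.01)
  K <- 40
  st <- ibd_stitch(panel, colnames(panel$geno), K = K, seed = 10)
  mid <- M %/% 2
  share <- vapply(seq_len(K), function(k) {
    p <- partition_at(st, k, mid)
    any(outer(p[c("dup1.0", "dup1.1")], p[c("dup2.0", "dup2.1")], "=="))
  }, logical(1))
  expect_gt(mean(share), 0.95)
})

test_that("stitch realizations are exchangeable between halves", {
  set.seed(33)
  M <- 200
  ids <- letters[1:4]
  geno <- matrix(sample(0:2, M * 4, TRUE), M, 4, dimnames = list(NULL, ids))
  panel <- panel_from(geno, cm = seq(0, 80, length.out = M),
                      freq = rep(0.5, M), eps = 0.01)
  K <- 60
  st <- ibd_stitch(panel, ids, K = K, seed = 14)
  mean_pair_ibd <- function(ks, j) {
    mean(vapply(ks, function(k) {
      p <- partition_at(st, k, j)
      mean(vapply(1:3, function(i1) {
        any(outer(p[(2 * i1 - 1):(2 * i1)], p[(2 * i1 + 1):(2 * i1 + 2)], "=="))
      }, logical(1)))
    }, numeric(1)))
  }
  for (j in c(50, 150)) {
    a <- mean_pair_ibd(1:(K / 2), j)
    b <- mean_pair_ibd((K / 2 + 1):K, j)
    expect_lt(abs(a - b), 3 * sqrt(0.25 / (K / 2)) + 1e-9)
  }
})

test_that("stitch recovers planted multi-individual sharing", {
  # 3 of 6 individuals share one haplotype over a 25 cM segment; the
  # posterior sharing fraction at the midpoint should be high
  set.seed(41)
  M <- 640
  cm <- seq(0, 80, length.out = M)
  p <- runif(M, 0.2, 0.8)
  zone <- cm >= 27.5 & cm <= 52.5
  h_shared <- rbinom(M, 1, p)
  mk <- function(shared) {
    h1 <- rbinom(M, 1, p); h2 <- rbinom(M, 1, p)
    g <- h1 + h2
    if (shared) g[zone] <- (h_shared + h2)[zone]
    g
  }
  geno <- sapply(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), mk)
  colnames(geno) <- paste0("i", 1:6)
  panel <- panel_from(geno, cm = cm, freq = p, eps = 0.01)
  K <- 30
  st <- ibd_stitch(panel, colnames(geno), K = K, seed = 6)
  mid <- which.min(abs(cm - 40))
  frac <- mean(vapply(seq_len(K), function(k) {
    part <- partition_at(st, k, mid)
    sh12 <- any(outer(part[1:2], part[3:4], "=="))
    sh13 <- any(outer(part[1:2], part[5:6], "=="))
    sh12 && sh13
  }, logical(1)))
  expect_gt(frac, 0.9)
})
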
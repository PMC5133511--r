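# a fixed sib-pair scenario: one graph realization, hand-chosen sharing
sib_graph <- function(labels, cm = c(0, 10)) {
  ibd_graph_set(c("s1", "s2"), cm,
                list(list(pos = 1L, labels = matrix(labels, 1))))
}

test_that("imputation is the identity for dense-typed targets at eps = 0", {
  g <- sib_graph(c(1L, 2L, 3L, 4L))
  dmap <- genetic_map(c("d1", "d2", "d3"), c(1, 5, 9))
  geno <- matrix(c(0, 1, 2, 2, 0, 1), 3, 2, dimnames = list(dmap$marker, c("s1", "s2")))
  panel <- marker_panel(dmap, geno, freq = c(0.3, 0.5, 0.7), eps = 0)
  res <- impute_genotypes(g, panel, targets = c("s1", "s2"), eps = 0)
  for (i in seq_len(nrow(res))) {
    truth <- geno[res$marker[i], res$id[i]]
    expect_equal(res$dosage[i], truth, tolerance = 1e-12)
    expect_equal(res[[paste0("p", truth)]][i], 1, tolerance = 1e-12)
  }
})

test_that("targets without informative relatives fall back to Hardy-Weinberg", {
  g <- sib_graph(c(1L, 2L, 3L, 4L))   # no sharing between s1 and s2
  dmap <- genetic_map(c("d1", "d2"), c(1, 8))
  geno <- matrix(c(0, 2), 2, 1, dimnames = list(dmap$marker, "s1"))
  panel <- marker_panel(dmap, geno, freq = c(0.3, 0.6), eps = 0)
  res <- impute_genotypes(g, panel, targets = "s2", eps = 0)
  expect_equal(res$p0, (1 - c(0.3, 0.6))^2, tolerance = 1e-12)
  expect_equal(res$p1, 2 * c(0.3, 0.6) * (1 - c(0.3, 0.6)), tolerance = 1e-12)
  expect_equal(res$dosage, 2 * c(0.3, 0.6), tolerance = 1e-12)
  # and that equals the explicit baseline imputation
  hw <- hw_imputation(panel, "s2")
  expect_equal(res$dosage, hw$dosage, tolerance = 1e-12)
})

test_that("full sharing transfers an observed homozygote with certainty", {
  g <- sib_graph(c(1L, 2L, 1L, 2L))   # sibs share both haplotypes
  dmap <- genetic_map("d1", 5)
  geno <- matrix(2, 1, 1, dimnames = list("d1", "s1"))
  panel <- marker_panel(dmap, geno, freq = 0.4, eps = 0)
  res <- impute_genotypes(g, panel, targets = "s2", eps = 0)
  expect_equal(res$p2, 1, tolerance = 1e-12)
  expect_equal(res$dosage, 2, tolerance = 1e-12)
})

test_that("imputation posteriors match hand enumeration for one shared haplotype", {
  # s1 observed het at a SNP; sibs share the paternal haplotype only:
  # s2 = a_shared + fresh allele; hand posterior over assignments
  g <- sib_graph(c(1L, 2L, 1L, 3L))
  dmap <- genetic_map("d1", 5)
  p <- 0.3
  geno <- matrix(1, 1, 1, dimnames = list("d1", "s1"))
  panel <- marker_panel(dmap, geno, freq = p, eps = 0)
  res <- impute_genotypes(g, panel, targets = "s2", eps = 0)
  # P(a1, a2, a3) ~ Bern(p) each; obs: a1 + a2 = 1; s2 = a1 + a3
  W <- 0; P <- c(0, 0, 0)
  for (a1 in 0:1) for (a2 in 0:1) for (a3 in 0:1) {
    w <- prod(ifelse(c(a1, a2, a3) == 1, p, 1 - p)) * ((a1 + a2) == 1)
    W <- W + w
    P[a1 + a3 + 1] <- P[a1 + a3 + 1] + w
  }
  expect_equal(c(res$p0, res$p1, res$p2), P / W, tolerance = 1e-12)
})

test_that("averaging over K realizations is linear", {
  dmap <- genetic_map(c("d1", "d2"), c(2, 7))
  p <- c(0.4, 0.6)
  geno <- matrix(c(1, 2), 2, 1, dimnames = list(dmap$marker, "s1"))
  panel <- marker_panel(dmap, geno, freq = p, eps = 0.01)
  labs <- list(c(1L, 2L, 1L, 3L), c(1L, 2L, 1L, 2L), c(1L, 2L, 3L, 4L))
  both <- ibd_graph_set(c("s1", "s2"), c(0, 10),
                        lapply(labs, function(l) list(pos = 1L, labels = matrix(l, 1))))
  res_all <- impute_genotypes(both, panel, targets = "s2")
  singles <- lapply(labs, function(l) impute_genotypes(sib_graph(l), panel, targets = "s2"))
  expect_equal(res_all$dosage,
               rowMeans(sapply(singles, `[[`, "dosage")), tolerance = 1e-12)
})

test_that("accuracy metrics reproduce the footnote formulas on a 5-SNP fixture", {
  # 4 reference-polymorphic SNPs with correlations 0.8 and 0.6 on the two
  # imputed-polymorphic ones, plus one reference-monomorphic SNP
  truth <- rbind(
    s1 = c(0, 1, 2, 1, 0), s2 = c(1, 1, 0, 1, 0), s3 = c(2, 1, 1, 1, 0),
    s4 = c(0, 0, 2, 1, 0), s5 = c(1, 2, 0, 1, 0)
  )
  truth <- t(truth)  # markers x individuals
  rownames(truth) <- paste0("d", 1:5)
  ids <- colnames(truth) <- paste0("i", 1:5)
  # build dosages: d1 with cor 0.8 to truth, d2 with cor 0.6, d3/d4 constant,
  # d5 constant truth (zero variance -> excluded)
  mk_cor <- function(y, rho) {
    x <- as.numeric(scale(y))
    z <- as.numeric(scale(residuals(lm(rnorm(length(y)) ~ y))))
    rho * x + sqrt(1 - rho^2) * z
  }
  set.seed(2)
  dos <- rbind(mk_cor(truth[1, ], 0.8), mk_cor(truth[2, ], 0.6),
               rep(1, 5), rep(0.5, 5), rep(0, 5))
  dimnames(dos) <- dimnames(truth)
  res <- tibble::tibble(
    id = rep(ids, each = 5), marker = rep(rownames(truth), 5),
    cm = rep(1:5, 5),
    p0 = 0, p1 = 0, p2 = 0,
    dosage = as.vector(dos)   # column-major: marker fastest, matching id blocks
  )
  class(res) <- c("imputation_result", class(res))
  ref_freq <- setNames(c(0.1, 0.3, 0.45, 0.2, 0), rownames(truth))
  rep_out <- suppressMessages(imputation_accuracy(truth, res, ref_freq))
  ov <- rep_out[rep_out$bin == "overall", ]
  expect_equal(ov$n_snps, 4)        # d5 is reference-monomorphic
  expect_equal(ov$n_snpe, 2)        # two imputed-polymorphic with defined cor
  expect_equal(ov$rho1, (0.8 + 0.6) / 2, tolerance = 1e-6)
  expect_equal(ov$rho2, (0.8 + 0.6) / 4, tolerance = 1e-6)
  # bins partition by reference MAF
  expect_equal(sum(rep_out$n_snps[rep_out$bin != "overall"]), ov$n_snps)

  # perfect imputation: rho1 = rho2 = 1
  res2 <- res
  res2$dosage <- as.vector(truth)
  class(res2) <- class(res)
  perf <- imputation_accuracy(truth[1:2, ], res2, ref_freq[1:2])
  ovp <- perf[perf$bin == "overall", ]
  expect_equal(ovp$rho1, 1, tolerance = 1e-12)
  expect_equal(ovp$rho2, 1, tolerance = 1e-12)

  # all-constant dosages: guarded zero with no imputed-polymorphic SNPs
  res3 <- res
  res3$dosage <- rep(1, nrow(res3))
  class(res3) <- class(res)
  cons <- imputation_accuracy(truth, res3, ref_freq)
  expect_equal(cons$rho1[cons$bin == "overall"], 0)
  expect_equal(cons$n_snpe[cons$bin == "overall"], 0)
})

test_that("family imputation beats the Hardy-Weinberg baseline on simulated data", {
  wins <- 0
  for (r in 1:4) {
    cfg <- sim_preset("mini", n_traits = 1, dense_n = 120)
    ds <- simulate_ibd_study(cfg, seed = 500 + r)
    ped <- ds$pedigrees[[1]]
    ids <- ped$members$id
    # dense-type the first half of each component; impute the rest
    dense_ids <- ids[seq(1, length(ids), by = 2)]
    targets <- setdiff(ids, dense_ids)
    g <- sample_ivs(ped, ds$sparse_panel, K = 20, seed = 600 + r)
    panel <- ds$dense_panel
    panel$geno <- panel$geno[, dense_ids, drop = FALSE]
    res <- impute_genotypes(g, panel, targets = targets)
    hw <- hw_imputation(panel, targets)
    truth <- ds$truth$dense_true[, targets, drop = FALSE]
    rownames(truth) <- ds$dense_panel$map$marker
    fr <- setNames(ds$dense_panel$freq, ds$dense_panel$map$marker)
    a1 <- suppressMessages(imputation_accuracy(truth, res, fr))
    a0 <- suppressMessages(imputation_accuracy(truth, hw, fr))
    if (a1$rho1[a1$bin == "overall"] >= a0$rho1[a0$bin == "overall"]) wins <- wins + 1
  }
  expect_equal(wins, 4)
})
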
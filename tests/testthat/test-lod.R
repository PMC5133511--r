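test_that("component likelihood degenerates correctly and matches closed forms", {
  model0 <- qtl_model(0, c(1, 5, 9), sigma2 = 2)
  lab <- c(a.0 = 1L, a.1 = 2L, b.0 = 2L, b.1 = 3L)
  y <- c(a = 0.4, b = 1.7)
  # q = 0: every individual sits at mu0
  expect_equal(component_likelihood(lab, y, model0),
               prod(dnorm(y, 1, sqrt(2))), tolerance = 1e-12)

  # single individual, two singleton classes: 3-term Hardy-Weinberg mixture
  model <- qtl_model(0.3, c(0, 1, 2), sigma2 = 1)
  one <- c(z.0 = 1L, z.1 = 2L)
  got <- component_likelihood(one, c(z = 0.9), model)
  hw <- c(0.49, 0.42, 0.09)
  expect_equal(got, sum(hw * dnorm(0.9, 0:2, 1)), tolerance = 1e-12)

  # missing traits contribute factor 1
  expect_equal(component_likelihood(lab, c(a = NA, b = NA), model), 1)

  # class cap raises a capacity error
  big <- setNames(seq_len(48), slot_names(paste0("i", 1:24)))
  expect_error(component_likelihood(big, setNames(rep(0, 24), paste0("i", 1:24)),
                                    model, class_cap = 22),
               class = "ibdmap_capacity_error")
})

test_that("component likelihood equals brute-force enumeration on random graphs", {
  set.seed(77)
  model <- qtl_model(0.25, c(-0.5, 0.4, 1.5), sigma2 = 0.8)
  for (r in 1:25) {
    n <- sample(3:6, 1)
    ids <- paste0("i", 1:n)
    c_n <- sample(2:10, 1)
    # random connected-ish labels over 2n slots
    lab <- setNames(sample.int(c_n, 2 * n, replace = TRUE), slot_names(ids))
    y <- setNames(rnorm(n), ids)
    y[sample(n, 1)] <- NA
    got <- component_likelihood(lab, y, model)
    expect_equal(got, oracle_trait_lik(lab, y, model), tolerance = 1e-10)
  }
})

test_that("null log-likelihood matches closed forms", {
  model <- qtl_model(0.3, c(0, 1, 2), sigma2 = 1)
  # founders-only pedigrees: product of 3-term mixtures, exactly, any M
  fo <- pedigree(data.frame(id = c("u", "v"), father = NA, mother = NA, sex = 1:2), "fo")
  y <- tibble::tibble(id = c("u", "v"), t1 = c(0.2, -1.1))
  hw <- c(0.49, 0.42, 0.09)
  expected <- sum(log(c(sum(hw * dnorm(0.2, 0:2, 1)), sum(hw * dnorm(-1.1, 0:2, 1)))))
  expect_equal(unname(null_loglik(fo, y, model, M = 7, seed = 1)["t1"]), expected,
               tolerance = 1e-12)

  # q = 0: plain Normal likelihood for any pedigree
  ped <- make_threegen6()
  y2 <- tibble::tibble(id = ped$members$id, t1 = rnorm(6))
  m0 <- qtl_model(0, c(0.5, 2, 4), sigma2 = 2)
  expect_equal(unname(null_loglik(ped, y2, m0, M = 11, seed = 2)["t1"]),
               sum(dnorm(y2$t1, 0.5, sqrt(2), log = TRUE)), tolerance = 1e-12)
})

test_that("sib-pair null matches the exact 1/4-1/2-1/4 sharing mixture", {
  model <- qtl_model(0.4, c(0, 0.8, 1.6), sigma2 = 1)
  ped <- make_sibpair()
  y <- tibble::tibble(id = c("s1", "s2"), t1 = c(1.1, 0.7))   # parents unphenotyped
  # exact: enumerate the 16 IVs -> sharing states with weights 1/4, 1/2, 1/4
  states <- list(
    share0 = c(s1.0 = 1L, s1.1 = 2L, s2.0 = 3L, s2.1 = 4L),
    share_pat = c(s1.0 = 1L, s1.1 = 2L, s2.0 = 1L, s2.1 = 3L),
    share_both = c(s1.0 = 1L, s1.1 = 2L, s2.0 = 1L, s2.1 = 2L)
  )
  yv <- c(s1 = 1.1, s2 = 0.7)
  exact <- log(0.25 * oracle_trait_lik(states$share0, yv, model) +
               0.50 * oracle_trait_lik(states$share_pat, yv, model) +
               0.25 * oracle_trait_lik(states$share_both, yv, model))
  got <- unname(null_loglik(ped, y, model, M = 100000, seed = 3)["t1"])
  # the estimator converges at binomial MC rate; 3 SE of the dominant term
  expect_lt(abs(got - exact), 0.01)
})

test_that("lod_curve handles trivial graph sets as contracted", {
  ped <- make_sibpair()
  map <- flat_map(4, spacing = 5)
  model <- qtl_model(0.3, c(0, 1, 2), sigma2 = 1)
  traits <- tibble::tibble(id = c("s1", "s2"), t1 = c(0.5, 1.2))

  # all-missing traits: both likelihood sides are 1, LOD identically zero
  na_traits <- tibble::tibble(id = c("s1", "s2"), t1 = c(NA_real_, NA_real_))
  g <- gene_drop(ped, map, seed = 2)
  expect_warning(lods0 <- lod_curve(g, na_traits, model, null = setNames(0, "t1")))
  expect_equal(lods0$t1, rep(0, 4))

  # K = 1 graph constant along the chromosome: flat curve, one miss per
  # component per replicate
  const <- ibd_graph_set(c("s1", "s2"), map$cm,
                         list(list(pos = 1L, labels = matrix(c(1L, 2L, 1L, 3L), 1))))
  null <- null_loglik(ped, traits, model, M = 20000, seed = 5)
  lods <- lod_curve(const, traits, model, null)
  expect_equal(length(unique(round(lods$t1, 12))), 1)
  expect_equal(attr(lods, "cache_misses"), 1)

  # hand-assembled K = 3, 2-position set matches the full formula
  r1 <- list(pos = 1L, labels = matrix(c(1L, 2L, 1L, 2L), 1))
  r2 <- list(pos = c(1L, 2L), labels = rbind(c(1L, 2L, 1L, 3L), c(1L, 2L, 3L, 4L)))
  r3 <- list(pos = 1L, labels = matrix(c(1L, 2L, 3L, 4L), 1))
  two <- ibd_graph_set(c("s1", "s2"), c(0, 10), list(r1, r2, r3))
  lods2 <- lod_curve(two, traits, model, null)
  yv <- c(s1 = 0.5, s2 = 1.2)
  lik_at <- function(labs) {
    sapply(labs, function(l) {
      oracle_trait_lik(setNames(l, c("s1.0", "s1.1", "s2.0", "s2.1")), yv, model)
    })
  }
  num1 <- mean(lik_at(list(c(1, 2, 1, 2), c(1, 2, 1, 3), c(1, 2, 3, 4))))
  num2 <- mean(lik_at(list(c(1, 2, 1, 2), c(1, 2, 3, 4), c(1, 2, 3, 4))))
  expect_equal(lods2$t1, (log(c(num1, num2)) - null[["t1"]]) / log(10),
               tolerance = 1e-9)
})

test_that("curves with and without the cache are bit-identical", {
  ped <- make_threegen6()
  map <- flat_map(12, spacing = 4)
  set.seed(6)
  geno <- matrix(sample(0:2, 12 * 6, TRUE), 12, 6,
                 dimnames = list(NULL, ped$members$id))
  panel <- marker_panel(map, geno, freq = rep(0.5, 12), eps = 0.02)
  g <- sample_ivs(ped, panel, K = 10, seed = 3)
  traits <- tibble::tibble(id = ped$members$id, t1 = rnorm(6), t2 = rnorm(6))
  model <- qtl_model(0.2, c(0, 1, 2), sigma2 = 1)
  null <- null_loglik(ped, traits, model, M = 2000, seed = 4)
  l1 <- lod_curve(g, traits, model, null, cache = TRUE)
  l2 <- lod_curve(g, traits, model, null, cache = FALSE)
  expect_identical(l1$t1, l2$t1)
  expect_identical(l1$t2, l2$t2)
  expect_gt(attr(l1, "cache_hits"), 0)
  expect_equal(attr(l2, "cache_hits"), 0)

  # the cache_blocks hint must not change the curve either
  l3 <- lod_curve(g, traits, model, null, cache_blocks = ibdmap:::pedigree_blocks(ped))
  expect_equal(l3$t1, l1$t1, tolerance = 1e-12)
})

test_that("batch averaging and unmerged summing behave as documented", {
  p1 <- make_sibpair()
  p2 <- make_threegen6()
  map <- flat_map(6, spacing = 6)
  set.seed(10)
  ids <- c(p1$members$id, p2$members$id)
  geno <- matrix(sample(0:2, 6 * length(ids), TRUE), 6, length(ids),
                 dimnames = list(NULL, ids))
  panel <- marker_panel(map, geno, freq = rep(0.4, 6), eps = 0.02)
  g1 <- sample_ivs(p1, panel, K = 8, seed = 1)
  g2 <- sample_ivs(p2, panel, K = 8, seed = 2)
  traits <- tibble::tibble(id = ids, t1 = rnorm(10), t2 = rnorm(10))
  model <- qtl_model(0.3, c(0, 0.8, 1.6), sigma2 = 1)

  # single replicate: average equals the replicate
  one <- batch_lods(g1, p1, traits[traits$id %in% p1$members$id, c("id", "t1")],
                    model, null_M = 500, null_seed = 1)
  expect_equal(one$average, one$t1)

  # unmerged mode: sum of the per-pedigree curves
  both <- batch_lods(list(g1, g2), list(p1, p2), traits, model,
                     null_M = 500, null_seed = 1)
  ind1 <- batch_lods(g1, p1, traits[traits$id %in% p1$members$id, ], model,
                     null_M = 500, null_seed = 1)
  ind2 <- batch_lods(g2, p2, traits[traits$id %in% p2$members$id, ], model,
                     null_M = 500, null_seed = 1)
  expect_equal(both$t1, ind1$t1 + ind2$t1, tolerance = 1e-9)
  expect_equal(both$average, (both$t1 + both$t2) / 2, tolerance = 1e-12)

  # tidy/glance accessors
  td <- tidy(both)
  expect_setequal(unique(td$replicate), c("t1", "t2", "average"))
  gl <- glance(ind1)
  expect_equal(gl$n_replicates, 2)
  expect_s3_class(autoplot(both), "ggplot")
})

test_that("LOD results round-trip through the TSV writer", {
  ped <- make_sibpair()
  map <- flat_map(5)
  g <- gene_drop(ped, map, seed = 3)
  traits <- tibble::tibble(id = c("s1", "s2"), t1 = c(0.3, -0.2))
  model <- qtl_model(0.2, c(0, 1, 2), 1)
  lods <- lod_curve(g, traits, model, null_loglik(ped, traits, model, M = 500, seed = 2))
  f <- tempfile(fileext = ".tsv")
  write_lods(lods, f)
  back <- read_lods(f)
  expect_equal(back$t1, lods$t1, tolerance = 1e-12)
  expect_equal(back$cm, lods$cm)
})
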
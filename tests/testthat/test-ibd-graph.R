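test_that("partition genotype likelihood matches hand enumeration", {
  # autozygote cannot be an error-free heterozygote
  expect_equal(partition_genotype_likelihood(c(a.0 = 1L, a.1 = 1L), c(a = 1), p = 0.3), 0)
  # two singleton classes, hom-ref: (1-p)^2
  expect_equal(partition_genotype_likelihood(c(a.0 = 1L, a.1 = 2L), c(a = 0), p = 0.3), 0.49)
  # empty observation set: empty product
  expect_equal(partition_genotype_likelihood(c(a.0 = 1L, a.1 = 2L), c(a = NA), p = 0.3), 1)
  # split-component observation is a contract violation
  lab <- c(a.0 = 1L, a.1 = 1L, b.0 = 2L, b.1 = 2L)
  expect_error(partition_genotype_likelihood(lab, c(a = 0, b = 0), p = 0.3),
               class = "ibdmap_contract_error")
})

test_that("partition likelihood equals brute-force enumeration on random partitions", {
  set.seed(42)
  ids <- letters[1:5]
  slots <- as.vector(rbind(paste0(ids, ".0"), paste0(ids, ".1")))
  for (rep in 1:20) {
    lab <- setNames(sample.int(6, 10, replace = TRUE), slots)
    geno <- setNames(sample(c(0, 1, 2, NA), 5, replace = TRUE), ids)
    p <- runif(1, 0.05, 0.95)
    eps <- sample(c(0, 0.02), 1)
    expect_equal(partition_likelihood(lab, geno, p, eps),
                 oracle_partition_lik(lab, geno, p, eps), tolerance = 1e-12)
  }
})

test_that("canonical keys are relabeling-invariant and distinguish set-partitions", {
  slots <- c("a.0", "a.1", "b.0", "b.1")
  lab1 <- setNames(c(3L, 7L, 3L, 9L), slots)
  lab2 <- setNames(c(20L, 5L, 20L, 1L), slots)   # same set-partition, relabeled
  expect_identical(canonical_key(lab1), canonical_key(lab2))

  # sib-pair: exhaustive IV enumeration induces 4 distinct set-partitions of
  # the 4 slots (no sharing; paternal-only; maternal-only; both) - the two
  # single-haplotype configurations are distinct partitions even though they
  # share a genotype-level IBD count
  ped <- make_sibpair()
  keys <- vapply(0:15, function(s) {
    iv <- as.integer(intToBits(s))[1:4]
    canonical_key(iv_to_partition(iv, ped), c("s1.0", "s1.1", "s2.0", "s2.1"))
  }, character(1))
  expect_length(unique(keys), 4)

  # one individual admits exactly two set-partitions of its 2 slots
  keys1 <- vapply(0:15, function(s) {
    iv <- as.integer(intToBits(s))[1:4]
    canonical_key(iv_to_partition(iv, ped), c("s1.0", "s1.1"))
  }, character(1))
  expect_lte(length(unique(keys1)), 2)
  expect_error(canonical_key(lab1, character(0)))
})

test_that("compact graph format round-trips exactly and flags malformed files", {
  ped <- make_threegen6()
  gd <- gene_drop(ped, flat_map(25, spacing = 2), seed = 9)
  gd2 <- gene_drop(ped, flat_map(25, spacing = 2), seed = 10)
  set <- ibd_graph_set(ped$members$id, flat_map(25, spacing = 2)$cm,
                       c(gd$realizations, gd2$realizations))
  f <- tempfile(fileext = ".txt")
  write_ibd_graphs(set, f)
  back <- read_ibd_graphs(f)
  expect_equal(back$individuals, set$individuals)
  expect_equal(back$positions, set$positions)
  expect_equal(back$realizations, set$realizations)

  # truncation: drop the last realization's lines
  lines <- readLines(f)
  writeLines(lines[seq_len(grep("^R 2$", lines) - 1)], f)
  expect_error(read_ibd_graphs(f), "truncated", class = "ibdmap_parse_error")

  # malformed record
  writeLines(c(lines[1:4], "X what"), f)
  expect_error(read_ibd_graphs(f), class = "ibdmap_parse_error")
})

test_that("a chromosome-constant partition stores exactly one change-point", {
  founders <- pedigree(data.frame(id = c("u", "v"), father = NA, mother = NA,
                                  sex = c(1, 2)), "f2")
  gd <- gene_drop(founders, flat_map(40), seed = 2)
  f <- tempfile()
  write_ibd_graphs(gd, f)
  expect_length(grep("^C ", readLines(f)), 1)
})

test_that("change-point storage reconstructs the dense per-position partitions", {
  ped <- make_threegen6()
  map <- flat_map(30, spacing = 3)
  set.seed(4)
  ivs <- ibdmap:::draw_iv_paths(nrow(ped$meioses), ibdmap:::map_theta(map), n = 3, seed = 4)
  set <- ibdmap:::ibd_graph_set_from_ivs(ped, map$cm, ivs)
  for (k in 1:3) {
    for (j in seq_len(30)) {
      dense <- canonical_labels(iv_to_partition(ivs[[k]][j, ], ped))
      expect_equal(unname(partition_at(set, k, j)), dense)
    }
  }
})

test_that("merging with an empty bridge is the disjoint union", {
  p1 <- make_sibpair()
  p2 <- pedigree(data.frame(id = c("x", "y", "z"), father = c(NA, NA, "x"),
                            mother = c(NA, NA, "y"), sex = c(1, 2, 1)), "p2")
  map <- flat_map(12)
  g1 <- gene_drop(p1, map, seed = 1)
  g2 <- gene_drop(p2, map, seed = 2)
  merged <- merge_ibd_graphs(list(g1, g2), bridge_set = NULL)
  for (j in c(1, 6, 12)) {
    joint <- c(partition_at(g1, 1, j), partition_at(g2, 1, j) + 100L)
    expect_identical(unname(canonical_labels(partition_at(merged, 1, j))),
                     canonical_labels(joint))
  }
})

test_that("bridge merging unites classes across pedigrees (hand union-find, 8 slots)", {
  p1 <- make_sibpair()
  p2 <- pedigree(data.frame(id = c("u", "v", "w1", "w2"),
                            father = c(NA, NA, "u", "u"), mother = c(NA, NA, "v", "v"),
                            sex = c(1, 2, 1, 2)), "p2")
  map <- flat_map(5)
  g1 <- gene_drop(p1, map, seed = 3)
  g2 <- gene_drop(p2, map, seed = 4)
  # bridge asserts s1.0 ~ w1.0 everywhere
  bridge <- ibd_graph_set(c("s1", "w1"), map$cm,
                          list(list(pos = 1L, labels = matrix(c(1L, 2L, 1L, 3L), 1))))
  merged <- merge_ibd_graphs(list(g1, g2), bridge)
  for (j in 1:5) {
    part <- partition_at(merged, 1, j)
    expect_equal(part[["s1.0"]], part[["w1.0"]])
    # hand union-find: merged partition equals join of the three partitions
    joint <- rbind(c(canonical_labels(partition_at(g1, 1, j)), canonical_labels(partition_at(g2, 1, j)) + 10L))
    slots <- c(slot_names(p1$members$id), slot_names(p2$members$id))
    assert <- integer(length(slots))
    assert[match(c("s1.0", "w1.0"), slots)] <- 99L
    expected <- canonical_labels(ibdmap:::join_partitions(rbind(joint, assert)))
    expect_identical(unname(canonical_labels(part[slots])), expected)
  }
})

test_that("merge is monotone, idempotent, and order-invariant", {
  p1 <- make_sibpair()
  p2 <- make_threegen6()
  map <- flat_map(10, spacing = 4)
  g1 <- gene_drop(p1, map, seed = 5)
  g2 <- gene_drop(p2, map, seed = 6)
  bridge <- ibd_graph_set(c("s2", "k1"), map$cm,
                          list(list(pos = c(1L, 6L),
                                    labels = rbind(c(1L, 2L, 1L, 3L), c(1L, 2L, 3L, 4L)))))
  m12 <- merge_ibd_graphs(list(g1, g2), bridge)
  m21 <- merge_ibd_graphs(list(g2, g1), bridge)
  for (j in 1:10) {
    part <- partition_at(m12, 1, j)
    # monotone: pairs together in an input stay together
    for (g in list(g1, g2)) {
      before <- partition_at(g, 1, j)
      sl <- names(before)
      for (a in seq_along(sl)) for (b in seq_len(a - 1)) {
        if (before[a] == before[b]) expect_equal(part[[sl[a]]], part[[sl[b]]])
      }
    }
    # order-invariance up to canonical relabeling
    expect_identical(canonical_key(part, sort(names(part))),
                     canonical_key(partition_at(m21, 1, j), sort(names(part))))
  }
  # idempotent: merging the merged set with the same bridge changes nothing
  m2 <- merge_ibd_graphs(list(m12), bridge)
  expect_equal(m2$realizations, m12$realizations)

  # mismatched K and unknown bridge individuals error
  bridge_bad <- ibd_graph_set(c("nobody", "k1"), map$cm,
                              list(list(pos = 1L, labels = matrix(1:4, 1))))
  expect_error(merge_ibd_graphs(list(g1, g2), bridge_bad), "absent")
})

test_that("as_tibble gives one row per realization-segment-slot", {
  ped <- make_trio()
  gd <- gene_drop(ped, flat_map(8), seed = 1)
  tb <- tibble::as_tibble(gd)
  expect_s3_class(tb, "tbl_df")
  expect_setequal(unique(tb$slot), slot_names(ped))
  expect_true(all(tb$end_cm >= tb$start_cm))
})
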
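#' Merge pedigree IBD graphs with between-pedigree (bridge) IBD graphs
#'
#' Combines per-pedigree IBD graph sets with a jointly-sampled IBD graph
#' set on cryptically related individuals ("bridge") into IBD graphs on the
#' union of individuals. At each grid position and realization the output
#' partition is the union-find closure of the pedigree partitions plus the
#' cross-individual equivalences asserted by the bridge partition, so
#' pedigree-internal sharing is never removed: the merged partition is a
#' coarsening of the disjoint union. Realization `k` of every input is
#' paired with realization `k` of every other (realizations are
#' exchangeable, so any fixed pairing is statistically equivalent).
#'
#' Bridge graphs on a denser grid are down-sampled by nearest position
#' (ties to the lower position). Because bridge haplotypes carry arbitrary
#' phase, each bridge individual's two slots are aligned to its pedigree
#' slots per realization by the orientation (identity or swap) that
#' maximizes the map length over which the bridge's within-individual
#' autozygosity pattern agrees with the pedigree partition, ties resolved
#' to identity; the chosen orientations are returned in the `alignment`
#' attribute.
#'
#' @param pedigree_sets List of [ibd_graph_set]s over disjoint individuals,
#'   all on the same position grid with the same `K`.
#' @param bridge_set An [ibd_graph_set] whose individuals each occur in one
#'   of the pedigree sets, with the same `K`.
#' @param groups Optional list of character vectors of individual ids,
#'   partitioning the bridge individuals into merge groups (bridge
#'   equivalences between individuals of different groups are dropped, as
#'   when pedigrees are merged in separate components). Default: one group
#'   with all bridge individuals.
#' @return An [ibd_graph_set] on the union of individuals, on the pedigree
#'   grid.
#' @export
merge_ibd_graphs <- function(pedigree_sets, bridge_set = NULL, groups = NULL) {
  if (inherits(pedigree_sets, "ibd_graph_set")) pedigree_sets <- list(pedigree_sets)
  K <- unique(vapply(pedigree_sets, n_realizations, integer(1)))
  if (length(K) != 1L) abort("pedigree sets disagree on the number of realizations K")
  grid <- pedigree_sets[[1]]$positions
  for (s in pedigree_sets[-1]) {
    if (!isTRUE(all.equal(s$positions, grid))) abort("pedigree sets must share one position grid")
  }
  individuals <- unlist(lapply(pedigree_sets, `[[`, "individuals"))
  if (anyDuplicated(individuals)) abort("pedigree sets must cover disjoint individuals")
  n_slots <- 2L * length(individuals)
  offsets <- c(0L, cumsum(vapply(pedigree_sets, function(s) {
    max(vapply(s$realizations, function(r) max(r$labels), integer(1)))
  }, integer(1))))

  if (!is.null(bridge_set)) {
    if (n_realizations(bridge_set) != K) {
      abort(sprintf("bridge K = %d but pedigree K = %d", n_realizations(bridge_set), K))
    }
    absent <- setdiff(bridge_set$individuals, individuals)
    if (length(absent)) {
      abort(sprintf("bridge individual(s) absent from all pedigrees: %s",
                    paste(absent, collapse = ", ")))
    }
    if (is.null(groups)) groups <- list(bridge_set$individuals)
    # grid position -> nearest bridge marker
    nb <- nearest_grid_index(grid, bridge_set$positions)
    alignment <- align_bridge_slots(pedigree_sets, bridge_set, nb)
  }

  M <- length(grid)
  reals <- vector("list", K)
  for (k in seq_len(K)) {
    ped_rs <- lapply(pedigree_sets, function(s) s$realizations[[k]])
    cps <- sort(unique(unlist(lapply(ped_rs, `[[`, "pos"))))
    if (!is.null(bridge_set)) {
      br <- bridge_set$realizations[[k]]
      rows_b <- findInterval(nb, br$pos)
      cps <- sort(unique(c(cps, which(c(TRUE, rows_b[-1] != rows_b[-M])))))
    }
    pos_out <- integer(0); labs <- list(); prev <- NULL
    for (i in cps) {
      base <- unlist(lapply(seq_along(ped_rs), function(si) {
        r <- ped_rs[[si]]
        r$labels[findInterval(i, r$pos), ] + offsets[si]
      }))
      rows <- matrix(base, nrow = 1L)
      if (!is.null(bridge_set)) {
        blab <- br$labels[rows_b[i], ]
        for (g in groups) {
          assert <- integer(n_slots)
          for (id in g) {
            bi <- match(id, bridge_set$individuals)
            ti <- match(id, individuals)
            ori <- alignment[[k]][[id]]
            src <- if (identical(ori, "swap")) c(2L * bi, 2L * bi - 1L) else c(2L * bi - 1L, 2L * bi)
            assert[c(2L * ti - 1L, 2L * ti)] <- blab[src]
          }
          rows <- rbind(rows, assert)
        }
      }
      lab <- canonical_labels(join_partitions(rows))
      if (is.null(prev) || any(lab != prev)) {
        pos_out <- c(pos_out, i)
        labs[[length(labs) + 1L]] <- lab
        prev <- lab
      }
    }
    reals[[k]] <- list(pos = pos_out, labels = do.call(rbind, labs))
  }
  out <- ibd_graph_set(individuals, grid, reals, source = "merged")
  if (!is.null(bridge_set)) attr(out, "alignment") <- alignment
  out
}

# per-realization, per-bridge-individual slot orientation. The stated rule
# scores orientations by the map length over which the bridge's
# within-individual autozygosity pattern matches the pedigree partition;
# that score is invariant under slot swap, so every comparison ties and the
# tie-break (identity) applies. Computed explicitly so the log records it.
align_bridge_slots <- function(pedigree_sets, bridge_set, nb) {
  K <- n_realizations(bridge_set)
  grid <- pedigree_sets[[1]]$positions
  w <- interval_weights(grid)
  ped_of <- function(id) {
    for (s in pedigree_sets) if (id %in% s$individuals) return(s)
    NULL
  }
  lapply(seq_len(K), function(k) {
    out <- list()
    br <- bridge_set$realizations[[k]]
    rows_b <- findInterval(nb, br$pos)
    for (id in bridge_set$individuals) {
      bi <- match(id, bridge_set$individuals)
      b_auto <- br$labels[rows_b, 2L * bi - 1L] == br$labels[rows_b, 2L * bi]
      s <- ped_of(id)
      r <- s$realizations[[k]]
      pi <- match(id, s$individuals)
      rows_p <- findInterval(seq_along(grid), r$pos)
      p_auto <- r$labels[rows_p, 2L * pi - 1L] == r$labels[rows_p, 2L * pi]
      score_identity <- sum(w[b_auto == p_auto])
      score_swap <- sum(w[b_auto == p_auto])  # swap-invariant: always a tie
      out[[id]] <- if (score_swap > score_identity) "swap" else "identity"
    }
    out
  })
}

# cM weight attributed to each grid position (half-intervals)
interval_weights <- function(grid) {
  if (length(grid) == 1L) return(1)
  d <- diff(grid)
  c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
}
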
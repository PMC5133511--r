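#' IBD graph sets
#'
#' An `ibd_graph_set` holds `K` realizations of location-specific IBD for a
#' fixed set of individuals on a fixed marker grid. Each realization is a
#' sequence of [IBD partitions][canonical_key] stored compactly as
#' change-points: the marker index at which the induced set-partition
#' changes, plus the new partition (canonical class labels, one per
#' haplotype slot in header order: per individual, paternal slot `.0` then
#' maternal slot `.1`).
#'
#' @param individuals Character vector of individual ids (defines slot
#'   order).
#' @param positions Strictly increasing numeric marker positions (cM).
#' @param realizations List of `K` realizations; each is a list with `pos`
#'   (integer change-point marker indices, starting at 1, strictly
#'   increasing) and `labels` (integer matrix, one row per change-point,
#'   one column per slot).
#' @param source Free-text provenance tag (e.g. sampler name).
#' @return An object of class `ibd_graph_set`.
#' @export
ibd_graph_set <- function(individuals, positions, realizations, source = "") {
  individuals <- as.character(individuals)
  positions <- as.numeric(positions)
  if (length(individuals) == 0) abort("no individuals")
  if (anyDuplicated(individuals)) abort("duplicate individual ids")
  if (length(positions) == 0 || any(diff(positions) <= 0)) {
    abort("positions must be non-empty and strictly increasing")
  }
  if (length(realizations) < 1) abort("K must be >= 1")
  n_slot <- 2L * length(individuals)
  realizations <- lapply(realizations, function(r) {
    pos <- as.integer(r$pos)
    lab <- r$labels
    if (is.null(dim(lab))) lab <- matrix(as.integer(lab), nrow = length(pos))
    if (length(pos) == 0 || pos[1] != 1L || any(diff(pos) <= 0) ||
        any(pos > length(positions))) {
      abort("change-point indices must start at 1, be strictly increasing, and lie on the grid")
    }
    if (ncol(lab) != n_slot || nrow(lab) != length(pos)) {
      abort("labels matrix must be (#change-points x #slots)")
    }
    lab <- t(apply(lab, 1, canonical_labels))
    if (n_slot == 1L) lab <- matrix(lab, ncol = 1L)
    list(pos = pos, labels = lab)
  })
  structure(
    list(individuals = individuals, positions = positions,
         realizations = realizations, source = source),
    class = "ibd_graph_set"
  )
}

#' @export
print.ibd_graph_set <- function(x, ...) {
  ncp <- mean(vapply(x$realizations, function(r) length(r$pos), numeric(1)))
  cat(sprintf(
    "<ibd_graph_set> %d individuals, %d positions (%.2f-%.2f cM), K = %d (mean %.1f change-points)%s\n",
    length(x$individuals), length(x$positions), min(x$positions), max(x$positions),
    length(x$realizations), ncp,
    if (nzchar(x$source)) paste0(" [", x$source, "]") else ""
  ))
  invisible(x)
}

#' Number of realizations of an IBD graph set
#' @param set An [ibd_graph_set].
#' @return Integer `K`.
#' @export
n_realizations <- function(set) length(set$realizations)

#' Extract the IBD partition at one grid position
#'
#' Reconstructs the partition of realization `k` at marker index `i` from
#' the change-point storage (binary search, O(log #change-points)).
#'
#' @param set An [ibd_graph_set].
#' @param k Realization index in `1..K`.
#' @param i Marker index on the grid.
#' @return Named integer vector of class labels (names = slots).
#' @export
partition_at <- function(set, k, i) {
  i <- as.integer(i)
  if (i < 1L || i > length(set$positions)) abort("position index off grid")
  r <- set$realizations[[k]]
  row <- findInterval(i, r$pos)
  setNames(r$labels[row, ], slot_names(set$individuals))
}

#' Tidy an IBD graph set into a long tibble of constant segments
#'
#' @param x An [ibd_graph_set].
#' @param ... Unused.
#' @return A tibble with one row per (realization, segment, slot).
#' @importFrom tibble as_tibble
#' @method as_tibble ibd_graph_set
#' @export
as_tibble.ibd_graph_set <- function(x, ...) {
  slots <- slot_names(x$individuals)
  purrr::map_dfr(seq_along(x$realizations), function(k) {
    r <- x$realizations[[k]]
    end <- c(r$pos[-1] - 1L, length(x$positions))
    tibble(
      realization = k,
      segment = rep(seq_along(r$pos), each = length(slots)),
      start_cm = rep(x$positions[r$pos], each = length(slots)),
      end_cm = rep(x$positions[end], each = length(slots)),
      slot = rep(slots, length(r$pos)),
      class = as.integer(t(r$labels))
    )
  })
}

# build a change-point graph set from per-marker partitions.
# part_fun(j) must return an integer label vector (slot order fixed).
compress_partitions <- function(n_markers, part_fun) {
  pos <- integer(0); labs <- list()
  prev <- NULL
  for (j in seq_len(n_markers)) {
    cur <- canonical_labels(part_fun(j))
    if (is.null(prev) || any(cur != prev)) {
      pos <- c(pos, j); labs[[length(labs) + 1L]] <- cur
      prev <- cur
    }
  }
  list(pos = pos, labels = do.call(rbind, labs))
}

#' Convert an inheritance vector to an IBD partition
#'
#' Propagates founder genome labels through the pedigree: founder slots get
#' fixed distinct FGLs (in pedigree member order); each child's paternal
#' slot copies the father's paternal FGL if the corresponding meiosis bit
#' is 0, else the father's maternal FGL (likewise for the maternal slot and
#' mother), following the pedigree's deterministic meiosis order.
#'
#' @param iv Integer 0/1 vector, one bit per meiosis (0 = grandpaternal).
#' @param ped A [pedigree].
#' @return Named integer label vector (one FGL per slot).
#' @export
iv_to_partition <- function(iv, ped) {
  m <- nrow(ped$meioses)
  if (length(iv) != m) {
    abort(sprintf("inheritance vector length %d != %d meioses", length(iv), m))
  }
  mem <- ped$members
  n <- nrow(mem)
  lab <- matrix(0L, nrow = 2L, ncol = n, dimnames = list(NULL, mem$id))
  fgl <- 0L
  nonf_rank <- cumsum(!is.na(mem$father))
  for (i in seq_len(n)) {
    if (is.na(mem$father[i])) {
      lab[, i] <- c(fgl + 1L, fgl + 2L)
      fgl <- fgl + 2L
    } else {
      j <- nonf_rank[i]
      bit_p <- iv[2L * j - 1L]
      bit_m <- iv[2L * j]
      lab[1L, i] <- lab[bit_p + 1L, mem$father[i]]
      lab[2L, i] <- lab[bit_m + 1L, mem$mother[i]]
    }
  }
  setNames(as.vector(lab), slot_names(ped))
}

# graph set from a list of IV path matrices (markers x meioses)
ibd_graph_set_from_ivs <- function(ped, positions, ivs, source = "gene_drop") {
  reals <- lapply(ivs, function(iv) {
    compress_partitions(nrow(iv), function(j) iv_to_partition(iv[j, ], ped))
  })
  ibd_graph_set(ped$members$id, positions, reals, source = source)
}

#' Read and write IBD graph sets in compact text format
#'
#' The compact format stores one partition per change-point. Header lines:
#' `#individuals: id1 id2 ...`, `#positions_cM: p1 p2 ...`,
#' `#realizations: K`; then for each realization a line `R k` followed by
#' `C <position-index> <label per slot>` lines (1-based marker indices,
#' slots in header order, paternal then maternal per individual).
#' Round-trips exactly: `read_ibd_graphs(write_ibd_graphs(s, f))` equals
#' `s` up to the `source` tag.
#'
#' @param set An [ibd_graph_set].
#' @param path File path.
#' @return `write_ibd_graphs()`: `path`, invisibly. `read_ibd_graphs()`:
#'   an [ibd_graph_set].
#' @export
write_ibd_graphs <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("#individuals:", paste(set$individuals, collapse = " ")),
    paste("#positions_cM:", paste(format(set$positions, digits = 15, trim = TRUE,
                                         scientific = FALSE), collapse = " ")),
    paste("#realizations:", length(set$realizations))
  ), con)
  for (k in seq_along(set$realizations)) {
    r <- set$realizations[[k]]
    writeLines(paste("R", k), con)
    writeLines(paste("C", r$pos,
                     apply(r$labels, 1, paste, collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_ibd_graphs
#' @export
read_ibd_graphs <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  parse_fail <- function(i, msg) {
    abort(sprintf("%s:%d: %s", path, i, msg), class = "ibdmap_parse_error")
  }
  grab <- function(tag) {
    i <- grep(paste0("^#", tag, ":"), lines)
    if (length(i) != 1) abort(sprintf("%s: missing '#%s:' header", path, tag),
      class = "ibdmap_parse_error")
    strsplit(trimws(sub(paste0("^#", tag, ":"), "", lines[i])), "\\s+")[[1]]
  }
  individuals <- grab("individuals")
  positions <- as.numeric(grab("positions_cM"))
  K <- as.integer(grab("realizations"))
  n_slot <- 2L * length(individuals)

  reals <- vector("list", K)
  cur_k <- 0L; pos <- integer(0); labs <- list()
  flush <- function() {
    if (cur_k > 0L) {
      if (length(pos) == 0) parse_fail(length(lines), sprintf("realization %d has no change-points", cur_k))
      reals[[cur_k]] <<- list(pos = pos, labels = do.call(rbind, labs))
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (f[1] == "R") {
      flush()
      cur_k <- suppressWarnings(as.integer(f[2]))
      if (is.na(cur_k) || cur_k < 1L || cur_k > K) parse_fail(i, "bad realization index")
      pos <- integer(0); labs <- list()
    } else if (f[1] == "C") {
      if (cur_k == 0L) parse_fail(i, "change-point before any 'R' line")
      v <- suppressWarnings(as.integer(f[-1]))
      if (length(v) != n_slot + 1L || anyNA(v)) {
        parse_fail(i, sprintf("expected position index + %d labels", n_slot))
      }
      pos <- c(pos, v[1]); labs[[length(labs) + 1L]] <- v[-1]
    } else {
      parse_fail(i, sprintf("unrecognised record '%s'", f[1]))
    }
  }
  flush()
  if (any(vapply(reals, is.null, logical(1)))) {
    abort(sprintf("%s: file truncated: %d of %d realizations present",
      path, sum(!vapply(reals, is.null, logical(1))), K), class = "ibdmap_parse_error")
  }
  ibd_graph_set(individuals, positions, reals, source = "file")
}
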
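#' Construct a pedigree
#'
#' A pedigree is a set of individuals with parent links. Founders have both
#' parents absent; non-founders have both parents present in the pedigree.
#' Each non-founder contributes two meioses (paternal and maternal), ordered
#' deterministically: children in topological order (parents before
#' children, ties broken by input order), and for each child the paternal
#' meiosis before the maternal one. Haplotype slots follow the global
#' convention slot 0 = paternal, slot 1 = maternal.
#'
#' @param members A data frame with columns `id`, `father`, `mother`, `sex`
#'   (`father`/`mother` are `NA` or `"0"` for founders; sex is read but not
#'   used in transmission - inheritance is autosomal).
#' @param ped_id Pedigree id used as a namespace tag.
#' @return An object of class `pedigree` with components `members` (tibble),
#'   `founders` (character), `meioses` (tibble with `child`, `slot` where
#'   slot 0 = paternal, 1 = maternal), and `ped_id`.
#' @export
pedigree <- function(members, ped_id = "ped1") {
  m <- as_tibble(members)
  need <- c("id", "father", "mother")
  if (!all(need %in% names(m))) abort("members needs columns id, father, mother")
  if (!"sex" %in% names(m)) m$sex <- 0L
  m$id <- as.character(m$id)
  m$father <- clean_parent(m$father)
  m$mother <- clean_parent(m$mother)
  if (anyDuplicated(m$id)) abort(sprintf("duplicate individual id(s): %s",
    paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))

  half <- is.na(m$father) != is.na(m$mother)
  if (any(half)) {
    abort(sprintf("individual(s) with exactly one parent specified: %s",
      paste(m$id[half], collapse = ", ")), class = "ibdmap_structure_error")
  }
  for (col in c("father", "mother")) {
    bad <- !is.na(m[[col]]) & !(m[[col]] %in% m$id)
    if (any(bad)) {
      abort(sprintf("missing parent record(s): %s (parent of %s)",
        paste(unique(m[[col]][bad]), collapse = ", "),
        paste(m$id[bad], collapse = ", ")), class = "ibdmap_structure_error")
    }
  }

  ord <- topo_order(m)   # errors on cycles
  m <- m[ord, ]
  nonf <- m$id[!is.na(m$father)]
  meioses <- tibble(
    child = rep(nonf, each = 2L),
    slot = rep(c(0L, 1L), length(nonf))
  )
  structure(
    list(
      members = m,
      founders = m$id[is.na(m$father)],
      meioses = meioses,
      ped_id = as.character(ped_id)
    ),
    class = "pedigree"
  )
}

clean_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("0", "", "NA") | is.na(x)] <- NA_character_
  x
}

# topological order of members (parents before children); cycle -> error
topo_order <- function(m) {
  n <- nrow(m)
  idx <- setNames(seq_len(n), m$id)
  indeg <- ifelse(is.na(m$father), 0L, 2L)
  kids <- vector("list", n)   # children positions per member position
  for (i in seq_len(n)) {
    if (!is.na(m$father[i])) {
      fi <- idx[[m$father[i]]]; mi <- idx[[m$mother[i]]]
      kids[[fi]] <- c(kids[[fi]], i)
      kids[[mi]] <- c(kids[[mi]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != n) {
    abort("pedigree parent-child graph contains a cycle",
      class = "ibdmap_structure_error")
  }
  out
}

#' Read a PED-style pedigree file
#'
#' Whitespace-delimited columns `family id father mother sex` (`0` = missing
#' parent); optional header; `#` comments. A file may contain several
#' families; one [pedigree] is returned per family id.
#'
#' @param path Path to the pedigree file.
#' @return A single `pedigree` if the file holds one family, else a named
#'   list of `pedigree` objects (in order of first appearance).
#' @export
read_pedigree <- function(path) {
  lines <- read_table_lines(path)
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 5)) {
    abort(sprintf("pedigree file '%s': expected 5 columns (family id father mother sex)", path))
  }
  first <- fields[[1]]
  if (identical(tolower(first[1]), "family") || identical(tolower(first[2]), "id")) {
    fields <- fields[-1]
  }
  mat <- do.call(rbind, fields)
  df <- tibble(
    family = mat[, 1], id = mat[, 2], father = mat[, 3], mother = mat[, 4],
    sex = suppressWarnings(as.integer(mat[, 5]))
  )
  fams <- unique(df$family)
  peds <- lapply(fams, function(f) {
    pedigree(df[df$family == f, c("id", "father", "mother", "sex")], ped_id = f)
  })
  names(peds) <- fams
  if (length(peds) == 1L) peds[[1]] else peds
}

#' Write pedigrees to a PED-style file
#'
#' @param peds A `pedigree` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(peds, path) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  rows <- purrr::map_dfr(peds, function(p) {
    m <- p$members
    tibble(family = p$ped_id, id = m$id,
           father = ifelse(is.na(m$father), "0", m$father),
           mother = ifelse(is.na(m$mother), "0", m$mother),
           sex = m$sex)
  })
  writeLines(c("# family id father mother sex",
               do.call(paste, rows)), path)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree %s> %d members (%d founders, %d meioses)\n",
    x$ped_id, nrow(x$members), length(x$founders), nrow(x$meioses)))
  invisible(x)
}

#' Haplotype slot names of a pedigree
#'
#' Slots are named `<id>.0` (paternal) and `<id>.1` (maternal), paternal
#' before maternal, individuals in pedigree member order.
#'
#' @param ped A [pedigree], or a character vector of individual ids.
#' @return Character vector of slot names.
#' @export
slot_names <- function(ped) {
  ids <- if (inherits(ped, "pedigree")) ped$members$id else as.character(ped)
  as.vector(rbind(paste0(ids, ".0"), paste0(ids, ".1")))
}

#' Connected components of a pedigree
#'
#' Splits a pedigree into its family-connected components (individuals
#' linked by parent-child edges). Exact inheritance-vector machinery works
#' per component, so component size (not file size) is what the meiosis cap
#' constrains.
#'
#' @param ped A [pedigree].
#' @return List of `pedigree` objects, one per component, ped_id suffixed
#'   with `.c<k>` when there is more than one.
#' @export
pedigree_components <- function(ped) {
  m <- ped$members
  n <- nrow(m)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  idx <- setNames(seq_len(n), m$id)
  for (i in seq_len(n)) {
    if (!is.na(m$father[i])) {
      unite(i, idx[[m$father[i]]])
      unite(i, idx[[m$mother[i]]])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  if (length(comps) == 1L) return(list(ped))
  lapply(seq_along(comps), function(k) {
    pedigree(m[comps[[k]], ], ped_id = paste0(ped$ped_id, ".c", k))
  })
}

#' Drop genes through a pedigree
#'
#' Simulates one realization of the prior (unconditional) IBD process:
#' founder slots carry fixed distinct founder genome labels (FGLs) at every
#' marker, and each meiosis is a Markov chain over grandparental origins
#' with switch probability equal to the Haldane recombination fraction per
#' marker interval.
#'
#' @param ped A [pedigree].
#' @param map A [genetic_map] (positions define the marker grid).
#' @param seed Integer seed.
#' @return An [ibd_graph_set] with `K = 1` on the map grid.
#' @export
gene_drop <- function(ped, map, seed = 1L) {
  if (nrow(map) == 0) abort("map must be non-empty")
  ivs <- draw_iv_paths(nrow(ped$meioses), map_theta(map), n = 1L, seed = seed)
  ibd_graph_set_from_ivs(ped, map$cm, ivs)
}

# unconditional IV paths: list of (markers x m) 0/1 matrices
draw_iv_paths <- function(m, theta, n, seed) {
  set.seed(as.integer(seed))
  M <- length(theta) + 1L
  lapply(seq_len(n), function(k) {
    if (m == 0L) return(matrix(0L, nrow = M, ncol = 0L))
    iv <- matrix(0L, nrow = M, ncol = m)
    iv[1, ] <- rbinom(m, 1L, 0.5)
    if (M > 1L) {
      flips <- matrix(rbinom((M - 1L) * m, 1L, rep(theta, m)), nrow = M - 1L)
      iv[-1, ] <- (matrix(iv[1, ], nrow = M - 1L, ncol = m, byrow = TRUE) +
                     apply(flips, 2, cumsum)) %% 2L
    }
    iv
  })
}
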
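#' Haldane map function
#'
#' Convert a genetic map distance to a recombination fraction under the
#' Haldane (no-interference) model, \eqn{\theta = (1 - e^{-2d/100})/2} for a
#' distance `d` in centimorgans, and back.
#'
#' @param d Non-negative map distance(s) in cM.
#' @return `haldane_theta()` returns recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_theta(10)
#' haldane_cm(haldane_theta(10))
#' @export
haldane_theta <- function(d) {
  if (any(!is.finite(d) | d < 0)) {
    abort("map distances must be finite and non-negative", class = "ibdmap_domain_error")
  }
  (1 - exp(-2 * d / 100)) / 2
}

#' @rdname haldane_theta
#' @param theta Recombination fraction(s) in `[0, 0.5)`.
#' @return `haldane_cm()` returns map distance(s) in cM.
#' @export
haldane_cm <- function(theta) {
  if (any(!is.finite(theta) | theta < 0 | theta >= 0.5)) {
    abort("recombination fractions must lie in [0, 0.5)", class = "ibdmap_domain_error")
  }
  -50 * log(1 - 2 * theta)
}

#' Construct a genetic map
#'
#' A genetic map is an ordered set of markers with physical (bp) and genetic
#' (cM) positions; inter-marker recombination fractions follow the Haldane
#' map function.
#'
#' @param marker Character vector of marker ids.
#' @param cm Numeric vector of genetic positions (cM), strictly increasing.
#' @param bp Optional integer vector of physical positions, strictly
#'   increasing; defaults to `round(cm * 1e6)`.
#' @param chrom Chromosome label (single value).
#' @return An object of class `genetic_map`: a tibble with columns `chrom`,
#'   `marker`, `cm`, `bp` and an attribute `theta` holding the recombination
#'   fraction for each adjacent marker interval.
#' @export
genetic_map <- function(marker, cm, bp = NULL, chrom = "1") {
  marker <- as.character(marker)
  cm <- as.numeric(cm)
  if (length(marker) != length(cm) || length(marker) == 0) {
    abort("marker and cm must be non-empty and of equal length")
  }
  if (anyDuplicated(marker)) abort("duplicate marker ids in map")
  if (is.null(bp)) bp <- round(cm * 1e6)
  bp <- as.numeric(bp)
  if (any(diff(cm) <= 0) || any(diff(bp) <= 0)) {
    abort("map positions must be strictly increasing in both cM and bp")
  }
  out <- tibble(chrom = as.character(chrom), marker = marker, cm = cm, bp = bp)
  attr(out, "theta") <- haldane_theta(diff(cm))
  class(out) <- c("genetic_map", class(out))
  out
}

#' Read a MAP-style genetic map file
#'
#' Whitespace-delimited columns `chrom marker cm bp`; a header line is
#' detected and skipped; lines starting with `#` are comments.
#'
#' @param path Path to the map file.
#' @return A [genetic_map] object.
#' @export
read_genetic_map <- function(path) {
  lines <- read_table_lines(path)
  fields <- strsplit(trimws(lines), "\\s+")
  first <- fields[[1]]
  if (length(first) < 4) abort(sprintf("map file '%s': expected 4 columns", path))
  if (is.na(suppressWarnings(as.numeric(first[3])))) fields <- fields[-1] # header
  mat <- do.call(rbind, fields)
  genetic_map(
    marker = mat[, 2],
    cm = as.numeric(mat[, 3]),
    bp = as.numeric(mat[, 4]),
    chrom = mat[1, 1]
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf(
    "<genetic_map> %d markers, %.2f-%.2f cM (chrom %s)\n",
    nrow(x), min(x$cm), max(x$cm), x$chrom[1]
  ))
  invisible(x)
}

map_theta <- function(map) {
  th <- attr(map, "theta")
  if (is.null(th)) th <- haldane_theta(diff(map$cm))
  th
}

# read non-empty, non-comment lines of a whitespace-delimited text file
read_table_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) abort(sprintf("file '%s' has no data lines", path))
  lines
}

#' Map dense positions to nearest grid positions
#'
#' Assigns each query position to the index of the nearest position on a
#' grid (both in cM); ties go to the lower position. Queries outside the grid
#' range are assigned to the nearest end.
#'
#' @param query Numeric positions (cM).
#' @param grid Strictly increasing numeric grid positions (cM).
#' @return Integer vector of grid indices.
#' @export
nearest_grid_index <- function(query, grid) {
  if (length(grid) == 0) abort("empty grid")
  lo <- findInterval(query, grid, all.inside = TRUE)
  hi <- pmin(lo + 1L, length(grid))
  dlo <- abs(query - grid[lo])
  dhi <- abs(grid[hi] - query)
  ifelse(dhi < dlo, hi, lo) # ties -> lower index
}
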
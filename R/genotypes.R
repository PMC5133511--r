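#' Marker panels
#'
#' A `marker_panel` couples a [genetic_map] with unordered biallelic
#' genotypes (0/1/2 alternate-allele counts, `NA` = missing), per-marker
#' alternate-allele frequencies and a genotyping error rate. It is the
#' input both to the conditional inheritance-vector sampler (sparse,
#' well-spaced panels) and to the cryptic-IBD machinery and imputation
#' (dense panels).
#'
#' @param map A [genetic_map].
#' @param geno Numeric matrix, markers in rows (rownames = marker ids,
#'   matching the map) and individuals in columns.
#' @param freq Alternate-allele frequencies, one per marker; if `NULL`,
#'   estimated from the genotyped individuals.
#' @param eps Per-allele genotyping error rate (default 0.01, shared with
#'   the samplers; tolerates Mendelian-consistent errors).
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(map, geno, freq = NULL, eps = 0.01) {
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(map)) abort("geno must have one row per map marker")
  if (is.null(rownames(geno))) rownames(geno) <- map$marker
  if (!identical(rownames(geno), map$marker)) abort("geno rownames must match map markers")
  if (is.null(colnames(geno))) abort("geno must have individual ids as colnames")
  bad <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad)) abort("genotypes must be 0/1/2 or NA")
  if (is.null(freq)) {
    freq <- rowMeans(geno, na.rm = TRUE) / 2
    freq[is.nan(freq)] <- 0.5
    freq <- pmin(pmax(freq, 1e-4), 1 - 1e-4)
  }
  if (length(freq) != nrow(map) || any(freq <= 0 | freq >= 1)) {
    abort("freq must have one value per marker, strictly inside (0, 1)")
  }
  if (eps < 0 || eps >= 0.5) abort("eps must lie in [0, 0.5)")
  structure(list(map = map, geno = geno, freq = as.numeric(freq), eps = eps),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d markers x %d individuals (%.1f%% missing), eps = %g\n",
    nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno)), x$eps))
  invisible(x)
}

#' Read genotypes from a tabular file or VCF
#'
#' Tabular format: whitespace-delimited, first column = marker id, remaining
#' columns = individuals (header row with ids required), values 0/1/2/NA.
#' Files ending in `.vcf` are read as biallelic VCF through the
#' VariantAnnotation package.
#'
#' @param path Path to a `.txt`/`.tsv` tabular genotype file or a `.vcf`.
#' @return Numeric genotype matrix (markers x individuals).
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) return(read_genotypes_vcf(path))
  lines <- read_table_lines(path)
  fields <- strsplit(trimws(lines), "\\s+")
  hdr <- fields[[1]]
  mat <- do.call(rbind, fields[-1])
  if (ncol(mat) != length(hdr)) abort(sprintf("'%s': ragged genotype table", path))
  g <- suppressWarnings(apply(mat[, -1, drop = FALSE], 2, as.numeric))
  if (is.null(dim(g))) g <- matrix(g, nrow = nrow(mat))
  dimnames(g) <- list(mat[, 1], hdr[-1])
  g
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  keep <- lengths(VariantAnnotation::alt(vcf)) == 1L
  vcf <- vcf[keep, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  g <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  g[gt %in% c("0/0", "0|0")] <- 0
  g[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  g[gt %in% c("1/1", "1|1")] <- 2
  g
}

#' Write genotypes to the tabular format
#'
#' @param geno Genotype matrix (markers x individuals), dimnames required.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  lines <- c(
    paste(c("marker", colnames(geno)), collapse = "\t"),
    vapply(seq_len(nrow(geno)), function(i) {
      paste(c(rownames(geno)[i], ifelse(is.na(geno[i, ]), "NA",
                                        format(geno[i, ], trim = TRUE))), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a two-column allele-frequency table
#'
#' Columns: marker id, alternate-allele frequency.
#' @param path File path.
#' @return Named numeric vector of frequencies.
#' @export
read_frequencies <- function(path) {
  lines <- read_table_lines(path)
  fields <- strsplit(trimws(lines), "\\s+")
  if (is.na(suppressWarnings(as.numeric(fields[[1]][2])))) fields <- fields[-1]
  mat <- do.call(rbind, fields)
  setNames(as.numeric(mat[, 2]), mat[, 1])
}

#' @rdname read_frequencies
#' @param freq Named numeric vector of frequencies.
#' @export
write_frequencies <- function(freq, path) {
  writeLines(c("marker\tfreq",
               paste(names(freq), format(freq, trim = TRUE, digits = 15), sep = "\t")), path)
  invisible(path)
}

#' Read and write quantitative trait tables
#'
#' TSV with column `id` then one column per trait replicate.
#'
#' @param path File path.
#' @return A tibble with column `id` and one numeric column per replicate.
#' @export
read_traits <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          comment.char = "#")
  out <- tibble(id = df[[1]])
  for (j in seq_along(df)[-1]) out[[names(df)[j]]] <- as.numeric(df[[j]])
  out
}

#' @rdname read_traits
#' @param traits Tibble as returned by [read_traits()].
#' @export
write_traits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
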
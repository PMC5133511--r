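#' IBD partitions
#'
#' At one genomic position, location-specific IBD for a set of individuals
#' is a partition of their haplotype slots into classes; slots in one class
#' descend from one founder haplotype (share one founder genome label, FGL).
#' A partition is represented as an integer vector of class labels named by
#' slot (`<id>.0` paternal, `<id>.1` maternal).
#'
#' `canonical_labels()` relabels classes by order of first appearance so any
#' relabeling of the same set-partition maps to the same vector.
#' `canonical_key()` returns a stable hashable token for the set-partition
#' induced on a stated subset of slots; it is how equal LOD-score
#' contributions are recognised across realizations and across locations.
#'
#' @param labels Named integer vector of class labels (names = slots).
#' @param subset Character vector of slot names (non-empty, in a fixed
#'   order chosen by the caller).
#' @return `canonical_key()`: a single string; `canonical_labels()`: an
#'   integer vector relabeled to first-appearance order.
#' @examples
#' p <- c(a.0 = 5L, a.1 = 9L, b.0 = 5L, b.1 = 2L)
#' canonical_key(p, c("a.0", "a.1", "b.0", "b.1"))
#' @export
canonical_key <- function(labels, subset = names(labels)) {
  if (length(subset) == 0) abort("subset must be non-empty")
  x <- labels[subset]
  if (anyNA(x)) abort(sprintf("slot(s) absent from partition: %s",
    paste(subset[is.na(x)], collapse = ", ")))
  paste(canonical_labels(x), collapse = ",")
}

#' @rdname canonical_key
#' @export
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}

# connected components of individuals through shared class labels.
# labels: named by slot; returns list of integer vectors (slot indices).
partition_slot_components <- function(labels) {
  comp_of_class <- canonical_labels(labels)      # class id per slot
  n_ind <- length(labels) / 2L
  # union classes that co-occur within an individual
  n_class <- max(comp_of_class)
  parent <- seq_len(n_class)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n_ind)) {
    a <- find(comp_of_class[2L * i - 1L]); b <- find(comp_of_class[2L * i])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n_class), find, integer(1))
  comp_id <- roots[comp_of_class]                 # component per slot
  split(seq_along(labels), comp_id)
}

#' Genotype likelihood given an IBD partition
#'
#' Single-locus probability of observed unordered biallelic genotypes given
#' the IBD partition of the observed individuals' slots. Each class carries
#' a latent allele drawn independently with alternate-allele frequency `p`;
#' each of an individual's two allele observations is correct with
#' probability `1 - eps` and flipped with probability `eps`; an unordered
#' heterozygote sums its two ordered observation events.
#'
#' When the partition spans several connected components the likelihood is
#' the product over components. `partition_genotype_likelihood()` requires a
#' single component (every observed individual's two slots inside it);
#' `partition_likelihood()` is the product form for arbitrary partitions.
#'
#' @param labels Named integer class labels (slots `<id>.0`, `<id>.1`).
#' @param geno Named numeric vector of observed genotypes (0/1/2, `NA` =
#'   missing) for a subset of individuals.
#' @param p Alternate-allele frequency in (0, 1) (0 or 1 allowed; the locus
#'   is then monomorphic).
#' @param eps Per-allele error rate in `[0, 0.5)`.
#' @return Probability in `[0, 1]`.
#' @export
partition_genotype_likelihood <- function(labels, geno, p, eps = 0) {
  geno <- geno[!is.na(geno)]
  if (length(geno) == 0) return(1)
  comps <- partition_slot_components(labels)
  slot_ind <- sub("\\.[01]$", "", names(labels))
  obs_ind <- names(geno)
  owner <- vapply(comps, function(ix) any(slot_ind[ix] %in% obs_ind), logical(1))
  for (ix in comps[owner]) {
    inside <- obs_ind %in% slot_ind[ix]
    both <- vapply(obs_ind[inside], function(i) sum(slot_ind[ix] == i) == 2L, logical(1))
    if (!all(both)) abort("observed individual has slots split across components",
      class = "ibdmap_contract_error")
  }
  if (sum(owner) != 1L) {
    abort("partition spans several observed components; use partition_likelihood()",
      class = "ibdmap_contract_error")
  }
  component_geno_lik(labels, comps[[which(owner)]], geno, p, eps)
}

#' @rdname partition_genotype_likelihood
#' @export
partition_likelihood <- function(labels, geno, p, eps = 0) {
  geno <- geno[!is.na(geno)]
  if (length(geno) == 0) return(1)
  slot_ind <- sub("\\.[01]$", "", names(labels))
  missing_ind <- setdiff(names(geno), slot_ind)
  if (length(missing_ind)) abort(sprintf("observed individual(s) not in partition: %s",
    paste(missing_ind, collapse = ", ")))
  comps <- partition_slot_components(labels)
  out <- 1
  for (ix in comps) {
    g <- geno[names(geno) %in% slot_ind[ix]]
    if (length(g)) out <- out * component_geno_lik(labels, ix, g, p, eps)
  }
  out
}

# likelihood of one component: sum over latent alleles of its classes.
component_geno_lik <- function(labels, slot_ix, geno, p, eps) {
  cls <- canonical_labels(labels[slot_ix])       # 1..c within component
  c_n <- max(cls)
  slot_ind <- sub("\\.[01]$", "", names(labels)[slot_ix])
  # class index of each observed individual's paternal/maternal slot
  pat <- integer(length(geno)); mat <- integer(length(geno))
  for (j in seq_along(geno)) {
    ix <- which(slot_ind == names(geno)[j])
    pat[j] <- cls[ix[1]]; mat[j] <- cls[ix[2]]
  }
  # enumerate 2^c latent allele assignments, vectorized over assignments
  n_a <- 2L^c_n
  bits <- matrix(0L, nrow = n_a, ncol = c_n)
  for (b in seq_len(c_n)) bits[, b] <- bitwAnd(seq_len(n_a) - 1L, bitwShiftL(1L, b - 1L)) > 0
  prior <- apply(bits, 1, function(a) prod(ifelse(a == 1, p, 1 - p)))
  pen <- genotype_obs_prob_table(eps)            # [x+y+1, g+1]
  lik <- prior
  for (j in seq_along(geno)) {
    x <- bits[, pat[j]]; y <- bits[, mat[j]]
    lik <- lik * pen[cbind(x + y + 1L, geno[j] + 1L)]
  }
  sum(lik)
}

# P(observed unordered genotype g | latent ordered pair with x+y alt copies).
# Rows: latent alt count 0,1,2 (latent het symmetric); cols: g = 0,1,2.
genotype_obs_prob_table <- function(eps) {
  e <- eps; c1 <- 1 - eps
  # per-allele channel: P(obs a | true t)
  # latent (0,0): obs alleles iid Bern(e); latent (1,1): iid Bern(c1)
  # latent het: one allele each
  rbind(
    c(c1 * c1, 2 * c1 * e, e * e),               # latent 0 alt
    c(c1 * e, c1 * c1 + e * e, c1 * e),          # latent 1 alt (ordered sum)
    c(e * e, 2 * c1 * e, c1 * c1)                # latent 2 alt
  )
}
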
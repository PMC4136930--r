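#' Normalised abundance table
#'
#' Proportions divide each species' count by the sample's `total_reads`
#' (normalising across sequencing runs of very different depth); group shares
#' sum the proportions of each named sample group and renormalise the sum to
#' 1 (100%), easing comparison across groups of samples. Zero-count species
#' are kept as explicit zeros.
#'
#' @param counts species x sample matrix of non-negative integer counts.
#' @param metadata a `sample_metadata` covering every sample column.
#' @param groups optional named list of sample-id vectors.
#' @return An object of class `abundance_table`: list with `counts`,
#'   `proportions` and `group_shares` (species x group matrix whose columns
#'   each sum to 1, or to 0 for all-zero groups).
#' @export
normalize_abundance <- function(counts, metadata, groups = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  miss <- setdiff(colnames(counts), metadata$sample_id)
  if (length(miss))
    stop("samples without metadata: ", paste(miss, collapse = ", "))
  totals <- metadata$total_reads[match(colnames(counts), metadata$sample_id)]
  zero_bad <- totals == 0 & colSums(counts) > 0
  if (any(zero_bad))
    stop("total_reads is 0 but counts are nonzero for sample(s): ",
         paste(colnames(counts)[zero_bad], collapse = ", "))
  prop <- sweep(counts, 2, pmax(totals, 1), "/")
  gs <- NULL
  if (!is.null(groups)) {
    gs <- vapply(groups, function(g) {
      bad <- setdiff(g, colnames(counts))
      if (length(bad)) stop("group sample(s) absent from counts: ",
                            paste(bad, collapse = ", "))
      v <- rowSums(prop[, g, drop = FALSE])
      if (sum(v) > 0) v / sum(v) else v
    }, numeric(nrow(counts)))
    if (is.null(dim(gs))) gs <- matrix(gs, ncol = length(groups),
                                       dimnames = list(rownames(counts), names(groups)))
  }
  out <- list(counts = counts, proportions = prop, group_shares = gs)
  class(out) <- "abundance_table"
  out
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d species x %d samples (total %d reads)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Conditional probability of a tag count in a second library
#'
#' The exact conditional distribution, given `x` occurrences of a tag in a
#' library of `N1` reads, of observing `y` occurrences in a library of `N2`
#' reads under equal underlying frequency:
#' \deqn{p(y \mid x) = \left(\frac{N2}{N1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}}
#' computed in log space. Sums to 1 over `y = 0, 1, ...`.
#'
#' @param y,x non-negative tag counts (`y` may be a vector).
#' @param N1,N2 positive library sizes.
#' @return Probabilities, same length as `y`.
#' @export
ac_pmf <- function(y, x, N1, N2) {
  if (any(c(x, y) < 0)) stop("counts must be non-negative")
  if (N1 <= 0 || N2 <= 0) stop("library sizes must be positive")
  r <- N2 / N1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

.ac_cdf_grid <- function(x, N1, N2, tail_eps = 1e-12) {
  r <- N2 / N1
  mu <- (x + 1) * r
  ymax <- max(20, ceiling(mu + 20 * sqrt(mu * (1 + r)) + 20))
  repeat {
    p <- ac_pmf(0:ymax, x, N1, N2)
    if (1 - sum(p) < tail_eps || ymax > 1e7) break
    ymax <- ymax * 2
  }
  list(y = 0:ymax, pmf = p, cdf = cumsum(p))
}

#' Exact conditional differential tag-count test
#'
#' Compares a tag's count `x` in a library of size `N1` with its count `y` in
#' a library of size `N2` using the exact conditional distribution of
#' [ac_pmf()]. The expected range is the equal-tail interval at significance
#' `alpha`: `y_lo` is the largest value with `P(Y < y_lo) <= alpha/2` and
#' `y_hi` the smallest with `P(Y > y_hi) <= alpha/2`. The two-sided p-value
#' doubles the smaller tail (capped at 1); the observation is significant
#' exactly when `y` falls outside the expected range.
#'
#' @param x,y observed counts in the two libraries.
#' @param N1,N2 library sizes.
#' @param alpha significance level in (0, 1).
#' @return An object of class `ac_result`: list with `x`, `y`, `N1`, `N2`,
#'   `p_two_sided`, `expected_range` (`c(y_lo, y_hi)`), `significant`,
#'   `alpha`.
#' @export
ac_test <- function(x, y, N1, N2, alpha = 0.05) {
  if (any(c(x, y) < 0)) stop("counts must be non-negative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  g <- .ac_cdf_grid(x, N1, N2)
  # P(Y < y) = cdf[y] with cdf[0] = 0
  p_lt <- function(k) if (k <= 0) 0 else g$cdf[min(k, length(g$cdf))]
  p_le <- function(k) if (k < 0) 0 else g$cdf[min(k + 1, length(g$cdf))]
  half <- alpha / 2
  lo_cand <- which(c(0, g$cdf)[seq_along(g$y)] <= half + 1e-15) # P(Y < y) per y
  y_lo <- if (length(lo_cand)) g$y[max(lo_cand)] else 0L
  gt <- 1 - g$cdf                                              # P(Y > y) per y
  hi_cand <- which(gt <= half + 1e-15)
  y_hi <- g$y[min(hi_cand)]
  p2 <- min(1, 2 * min(p_le(y), 1 - p_lt(y)))
  out <- list(x = x, y = y, N1 = N1, N2 = N2, p_two_sided = p2,
              expected_range = c(y_lo = y_lo, y_hi = y_hi),
              significant = (y < y_lo || y > y_hi), alpha = alpha)
  class(out) <- "ac_result"
  out
}

#' @export
print.ac_result <- function(x, ...) {
  cat(sprintf("Tag-count test: x=%d/N1=%g vs y=%d/N2=%g\n", x$x, x$N1, x$y, x$N2))
  cat(sprintf("  expected range [%d, %d] at alpha=%g; p=%.4g; %ssignificant\n",
              x$expected_range[1], x$expected_range[2], x$alpha,
              x$p_two_sided, if (x$significant) "" else "not "))
  invisible(x)
}

#' Rarefaction: expected OTU richness in a subsample
#'
#' The hypergeometric closed form
#' `E[S(n)] = sum_i (1 - choose(N - N_i, n)/choose(N, n))`, relating the
#' number of harvested sequences to the number of OTUs retrieved.
#'
#' @param otu_sizes positive integer OTU sizes.
#' @param n subsample sizes (each `<= sum(otu_sizes)`).
#' @return A data frame with columns `n` and `expected_otus`.
#' @export
rarefaction <- function(otu_sizes, n) {
  if (any(otu_sizes <= 0) || any(otu_sizes != round(otu_sizes)))
    stop("otu_sizes must be positive integers")
  N <- sum(otu_sizes)
  if (any(n > N)) stop("subsample size exceeds the total number of reads")
  if (any(n < 0)) stop("subsample sizes must be non-negative")
  exp_s <- as.numeric(vegan::rarefy(matrix(otu_sizes, nrow = 1), sample = n))
  data.frame(n = n, expected_otus = exp_s)
}

#' Venn-region counts of OTU sharing across sites
#'
#' For 2-4 sites, counts the OTUs falling in every region of the Venn
#' diagram (each non-empty subset of sites, exclusively). Region counts sum
#' to the size of the union. More than 4 sites is refused; use
#' [pairwise_sharing()] instead.
#'
#' @param sets named list (2-4 elements) of OTU-id vectors.
#' @return A named integer vector; names are `&`-joined site subsets.
#' @export
venn_sharing <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4)
    stop("venn_sharing handles 2-4 sites; for more, use pairwise_sharing()")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  univ <- unique(unlist(sets))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1) member <- matrix(member, nrow = 1,
                                          dimnames = list(NULL, names(sets)))
  out <- integer()
  for (size in seq_len(k)) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      inside <- rowSums(member[, idx, drop = FALSE]) == size &
        rowSums(member[, -idx, drop = FALSE]) == 0
      out[paste(names(sets)[idx], collapse = "&")] <- sum(inside)
    }
  }
  out
}

#' Pairwise OTU sharing matrix
#'
#' @param sets named list of OTU-id vectors.
#' @return A symmetric matrix of intersection sizes (diagonal: set sizes).
#' @export
pairwise_sharing <- function(sets) {
  k <- length(sets)
  m <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  m
}

#' Species x site distribution table
#'
#' Per species and site: the mean, over the site's selected samples (by
#' default surface cDNA samples, averaging across size fractions), of the
#' species' proportion of each sample's total reads — the "mean relative
#' frequency" recipe of per-site biogeographic maps. Presence is a share
#' greater than zero.
#'
#' @param read_species data frame with columns `read_id`, `sample_id`,
#'   `species`.
#' @param metadata a `sample_metadata`.
#' @param layer,template sample selection (`NULL` = no restriction).
#' @return An object of class `species_site_table`: list with `shares`
#'   (species x site mean relative frequency), `presence` (logical matrix)
#'   and `counts` (species x sample).
#' @export
species_site_table <- function(read_species, metadata, layer = "surface",
                               template = "cDNA") {
  sel <- rep(TRUE, nrow(metadata))
  if (!is.null(layer)) sel <- sel & metadata$layer == layer
  if (!is.null(template)) sel <- sel & metadata$template == template
  samples <- metadata$sample_id[sel]
  species <- sort(unique(read_species$species))
  counts <- table(factor(read_species$species, levels = species),
                  factor(read_species$sample_id, levels = metadata$sample_id))
  counts <- matrix(as.integer(counts), nrow = length(species),
                   ncol = nrow(metadata),
                   dimnames = list(species, metadata$sample_id))
  totals <- pmax(metadata$total_reads, 1L)
  prop <- sweep(counts, 2, totals, "/")
  sites <- unique(metadata$site[sel])
  shares <- vapply(sites, function(st) {
    sm <- intersect(samples, metadata$sample_id[metadata$site == st])
    if (!length(sm)) return(numeric(length(species)))
    rowMeans(prop[, sm, drop = FALSE])
  }, numeric(length(species)))
  if (is.null(dim(shares)))
    shares <- matrix(shares, nrow = length(species),
                     dimnames = list(species, sites))
  colnames(shares) <- sites
  out <- list(shares = shares, presence = shares > 0, counts = counts)
  class(out) <- "species_site_table"
  out
}

#' @export
print.species_site_table <- function(x, ...) {
  cat("Mean relative frequency (species x site):\n")
  print(round(x$shares, 5))
  invisible(x)
}
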
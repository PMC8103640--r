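#' Per-site nucleotide diversity
#'
#' Unbiased average pairwise difference at a biallelic site:
#' `pi = 2 * ref_count * alt_count / (n * (n - 1))` with
#' `n = ref_count + alt_count` observed alleles.
#'
#' @param ref_count,alt_count Non-negative allele counts (vectorized).
#' @return Per-site pi; sites with fewer than two observed alleles are an
#'   error (callers are expected to exclude them).
#' @export
site_pi <- function(ref_count, alt_count) {
  n <- ref_count + alt_count
  if (any(n < 2)) stop("site_pi requires at least 2 observed alleles per site")
  2 * ref_count * alt_count / (n * (n - 1))
}

# Observed allele counts for one population: list of ref/alt count vectors.
pop_allele_counts <- function(dosages, samples) {
  d <- dosages[, samples, drop = FALSE]
  called <- rowSums(!is.na(d))
  alt <- rowSums(d, na.rm = TRUE)
  list(n_ind = called, alt = alt, ref = 2 * called - alt)
}

#' Windowed nucleotide diversity for one population
#'
#' Sums [site_pi()] over variant sites in the window (allele counts from the
#' called genotypes of the population only; sites with fewer than 2 called
#' alleles are skipped) and divides by the window span, giving per-bp theta-pi.
#'
#' @param gm A [new_genotype_matrix()].
#' @param pop Character vector of sample IDs.
#' @param chrom,start,end Window (0-based half-open).
#' @return Per-bp pi (a single number).
#' @export
window_pi <- function(gm, pop, chrom, start, end) {
  if (end <= start) stop("zero-span window")
  in_w <- gm$sites$chrom == chrom & gm$sites$pos > start & gm$sites$pos <= end
  if (!any(in_w)) return(0)
  ac <- pop_allele_counts(gm$dosages[in_w, , drop = FALSE], pop)
  ok <- (ac$ref + ac$alt) >= 2
  if (!any(ok)) return(0)
  sum(site_pi(ac$ref[ok], ac$alt[ok])) / (end - start)
}

#' Weir-Cockerham per-site variance components
#'
#' Computes the a (between-population), b (between individuals within
#' populations) and c (within-individual) variance components of the
#' Weir-Cockerham theta estimator for two diploid populations at every site,
#' from observed genotype calls. Sites with fewer than 2 called individuals
#' in either population are returned as `NA` (skip signal).
#'
#' @param gm A [new_genotype_matrix()] (or a bare dosage matrix).
#' @param split A [population_split()].
#' @return data.frame with columns `a`, `b`, `c` (one row per site).
#' @export
wc_site_components <- function(gm, split) {
  dosages <- if (inherits(gm, "genotype_matrix")) gm$dosages else gm
  d1 <- dosages[, split$tolerance, drop = FALSE]
  d2 <- dosages[, split$control, drop = FALSE]
  n1 <- rowSums(!is.na(d1)); n2 <- rowSums(!is.na(d2))
  p1 <- rowSums(d1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(d2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(d1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(d2 == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2

  skip <- n1 < 2 | n2 < 2
  a[skip] <- NA_real_; b[skip] <- NA_real_; cc[skip] <- NA_real_
  data.frame(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham Fst (ratio of sums)
#'
#' Aggregates per-site variance components over a window as
#' `theta_w = sum(a) / sum(a + b + c)`. Windows where the denominator is zero
#' (or no usable sites remain) are undefined; negative estimates are retained
#' unless `clamp_negative = TRUE`.
#'
#' @param comp data.frame from [wc_site_components()] (rows = sites in the
#'   window; `NA` rows are skipped).
#' @param clamp_negative Clamp negative estimates to 0 (default `FALSE`).
#' @return The windowed theta-hat, or `NA` when undefined.
#' @export
window_fst <- function(comp, clamp_negative = FALSE) {
  ok <- !is.na(comp$a)
  if (!any(ok)) return(NA_real_)
  denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (denom == 0) return(NA_real_)
  th <- sum(comp$a[ok]) / denom
  if (clamp_negative && th < 0) 0 else th
}

#' log2 diversity ratio
#'
#' `log2(pi_control / pi_tolerance)`; defined only when both diversities are
#' strictly positive. Large positive values mark windows where the tolerance
#' population lost diversity relative to the control.
#'
#' @param pi_control,pi_tolerance Non-negative per-bp diversities (vectorized).
#' @return The log2 ratio, `NA` where undefined.
#' @export
log2_pi_ratio <- function(pi_control, pi_tolerance) {
  if (any(pi_control < 0 | pi_tolerance < 0, na.rm = TRUE))
    stop("diversities must be >= 0")
  out <- rep(NA_real_, length(pi_control))
  ok <- !is.na(pi_control) & !is.na(pi_tolerance) &
    pi_control > 0 & pi_tolerance > 0
  out[ok] <- log2(pi_control[ok] / pi_tolerance[ok])
  out
}

#' Windowed sweep-scan statistics
#'
#' Computes, for every window of the grid, the number of usable SNPs, the
#' ratio-of-sums Weir-Cockerham Fst, per-bp theta-pi in each population and
#' the log2 diversity ratio.
#'
#' @param gm A [new_genotype_matrix()].
#' @param split A [population_split()].
#' @param chrom_lengths Named vector of chromosome lengths (defaults to the
#'   VCF contig lengths carried by `gm` when present).
#' @param size,step Window size and slide in bp.
#' @param clamp_negative Passed to [window_fst()].
#' @return data.frame of window statistics (`chrom`, `start`, `end`,
#'   `truncated`, `n_snps`, `fst`, `pi_control`, `pi_tolerance`,
#'   `log2_ratio`) carrying the grid attributes.
#' @export
scan_windows <- function(gm, split, chrom_lengths = NULL, size = 40000,
                         step = 20000, clamp_negative = FALSE) {
  if (is.null(chrom_lengths)) chrom_lengths <- attr(gm, "contig_lengths")
  if (is.null(chrom_lengths))
    stop("chrom_lengths required (none found on the genotype matrix)")
  split <- population_split(split$tolerance, split$control, gm)
  w <- make_windows(chrom_lengths, size, step)

  comp <- wc_site_components(gm, split)
  ac_t <- pop_allele_counts(gm$dosages, split$tolerance)
  ac_c <- pop_allele_counts(gm$dosages, split$control)
  pi_t_site <- ifelse(ac_t$n_ind >= 1 & (ac_t$ref + ac_t$alt) >= 2,
                      2 * ac_t$ref * ac_t$alt /
                        ((ac_t$ref + ac_t$alt) * (ac_t$ref + ac_t$alt - 1)), 0)
  pi_c_site <- ifelse(ac_c$n_ind >= 1 & (ac_c$ref + ac_c$alt) >= 2,
                      2 * ac_c$ref * ac_c$alt /
                        ((ac_c$ref + ac_c$alt) * (ac_c$ref + ac_c$alt - 1)), 0)

  stats <- lapply(seq_len(nrow(w)), function(i) {
    in_w <- gm$sites$chrom == w$chrom[i] &
      gm$sites$pos > w$start[i] & gm$sites$pos <= w$end[i]
    span <- w$end[i] - w$start[i]
    n_use <- sum(in_w & !is.na(comp$a))
    c(n_snps = n_use,
      fst = window_fst(comp[in_w, , drop = FALSE], clamp_negative),
      pi_control = sum(pi_c_site[in_w]) / span,
      pi_tolerance = sum(pi_t_site[in_w]) / span)
  })
  stats <- do.call(rbind, stats)
  out <- cbind(w, as.data.frame(stats))
  out$log2_ratio <- log2_pi_ratio(out$pi_control, out$pi_tolerance)
  attr(out, "size") <- size
  attr(out, "step") <- step
  out
}
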
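# Independent brute-force oracles, deliberately written as scalar loops over
# the published definitions, separate from the vectorized production code.

# Ratio-of-sums Weir-Cockerham theta over all supplied sites, two diploid
# populations, evaluated site by site from raw genotype vectors.
oracle_wc_theta <- function(d1, d2) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(d1))) {
    g1 <- d1[i, ]; g1 <- g1[!is.na(g1)]
    g2 <- d2[i, ]; g2 <- g2[!is.na(g2)]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 2 || n2 < 2) next
    r <- 2
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- sum(g1 == 1) / n1;  h2 <- sum(g2 == 1) / n2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1 * n1 + n2 * n2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) NA_real_ else num / den
}

# Average pairwise difference at a site by explicit enumeration of all
# unordered allele pairs.
oracle_site_pi <- function(alleles) {
  n <- length(alleles)
  stopifnot(n >= 2)
  diffs <- 0; total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    if (alleles[i] != alleles[j]) diffs <- diffs + 1
  }
  diffs / total
}

# Upper-tail hypergeometric probability by direct summation of the mass
# function via choose().
oracle_hyper_upper <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Random small-site genotype pair with missingness, for oracle comparisons.
random_site_pair <- function() {
  n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
  make <- function(n) {
    g <- sample(0:2, n, replace = TRUE)
    g[runif(n) < 0.15] <- NA
    g
  }
  list(d1 = make(n1), d2 = make(n2))
}

anchor_df <- function(ra, rb, chrom_a = "A1", chrom_b = "B1") {
  data.frame(gene_a = sprintf("a%03d", ra), gene_b = sprintf("b%03d", rb),
             chrom_a = chrom_a, chrom_b = chrom_b, rank_a = ra, rank_b = rb,
             evalue = 1e-10, stringsAsFactors = FALSE)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Fraction of selected windows/regions overlapping any truth interval, and
# which truth intervals are hit (0-based half-open on both sides).
overlap_truth <- function(intervals, truth) {
  hit_truth <- vapply(seq_len(nrow(truth)), function(i)
    any(intervals$start < truth$end[i] & intervals$end > truth$start[i]),
    logical(1))
  in_truth <- vapply(seq_len(nrow(intervals)), function(i)
    any(truth$start < intervals$end[i] & truth$end > intervals$start[i]),
    logical(1))
  list(n_truth_hit = sum(hit_truth),
       precision = if (nrow(intervals)) mean(in_truth) else NA_real_)
}
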
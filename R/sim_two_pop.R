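#' Simulate a two-population diploid SNP panel with planted sweeps
#'
#' Draws biallelic SNP genotypes for a "tolerance" and a "control" population
#' under the Balding-Nichols model: each site has an ancestral alternate
#' frequency `p ~ Uniform(0.05, 0.95)` and each population's frequency is
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` (for `F = 0` both populations share `p`
#' exactly), so the expected Weir-Cockerham Fst equals `F`. Genotype dosages
#' are `Binomial(2, population frequency)`.
#'
#' Inside each planted sweep interval the tolerance-population frequency is
#' pushed deterministically toward the nearer of 0/1 so that its expected
#' heterozygosity falls by roughly `pi_reduction`, and then an additional
#' fraction `divergence_boost` of the remaining distance to the boundary,
#' which raises between-population divergence. Truth intervals are returned
#' and written as BED3.
#'
#' @param n_per_pop Diploid individuals per population (default 7, matching a
#'   7-vs-7 accession split).
#' @param chrom_len Chromosome length in bp.
#' @param n_sites Number of SNP sites, placed uniformly without replacement.
#' @param F Background differentiation in `[0, 1)`.
#' @param sweeps List of sweep descriptors `list(start, end, pi_reduction,
#'   divergence_boost)` (1-based inclusive bp; non-overlapping).
#'   `divergence_boost` defaults to 0.9.
#' @param seed Integer seed; outputs are byte-identical given (params, seed).
#' @param out_dir If non-`NULL`, write `sim.vcf` and `truth_sweeps.bed` here.
#' @param chrom Chromosome name.
#' @return A list with the genotype matrix (`genotype_matrix`), `truth`
#'   (data.frame of sweep intervals), `params`, and file paths when written.
#' @export
sim_two_pop_genotypes <- function(n_per_pop = 7L, chrom_len = 2e6, n_sites = 2e4,
                                  F = 0.15, sweeps = list(), seed = 1L,
                                  out_dir = NULL, chrom = "chr1") {
  stopifnot(n_per_pop >= 2L, n_sites >= 1L, chrom_len >= n_sites)
  if (F < 0 || F >= 1) stop("F must be in [0, 1); F = 1 gives a degenerate Beta")
  sweeps <- lapply(sweeps, function(s) {
    s <- as.list(s)
    if (is.null(s$divergence_boost)) s$divergence_boost <- 0.9
    stopifnot(s$start >= 1, s$end <= chrom_len, s$start < s$end,
              s$pi_reduction >= 1, s$divergence_boost >= 0, s$divergence_boost < 1)
    s
  })
  if (length(sweeps) > 1L) {
    iv <- do.call(rbind, lapply(sweeps, function(s) c(s$start, s$end)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) stop("sweep intervals must not overlap")
  }

  set.seed(seed)
  pos <- sort(sample.int(chrom_len, n_sites))
  p_anc <- runif(n_sites, 0.05, 0.95)
  if (F == 0) {
    p_tol <- p_anc
    p_ctl <- p_anc
  } else {
    a <- p_anc * (1 - F) / F
    b <- (1 - p_anc) * (1 - F) / F
    p_tol <- rbeta(n_sites, a, b)
    p_ctl <- rbeta(n_sites, a, b)
  }

  for (s in sweeps) {
    in_sw <- pos >= s$start & pos <= s$end
    pt <- p_tol[in_sw]
    lower <- pt <= 0.5
    # heterozygosity ~ 2p(1-p) scales ~ linearly in the minor frequency,
    # so dividing the distance to the nearer boundary by pi_reduction
    # reduces within-population diversity by about that factor
    pt[lower] <- pt[lower] / s$pi_reduction
    pt[!lower] <- 1 - (1 - pt[!lower]) / s$pi_reduction
    pt[lower] <- pt[lower] * (1 - s$divergence_boost)
    pt[!lower] <- 1 - (1 - pt[!lower]) * (1 - s$divergence_boost)
    p_tol[in_sw] <- pt
  }

  n <- n_per_pop
  dos_tol <- matrix(rbinom(n_sites * n, 2L, rep(p_tol, n)), nrow = n_sites)
  dos_ctl <- matrix(rbinom(n_sites * n, 2L, rep(p_ctl, n)), nrow = n_sites)
  dosages <- cbind(dos_tol, dos_ctl)
  sample_ids <- c(sprintf("tol%02d", seq_len(n)), sprintf("ctl%02d", seq_len(n)))
  colnames(dosages) <- sample_ids

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  gm <- new_genotype_matrix(
    sites = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE),
    dosages = dosages, sample_ids = sample_ids)

  truth <- if (length(sweeps)) {
    data.frame(chrom = chrom,
               start = vapply(sweeps, function(s) s$start - 1, numeric(1)),
               end = vapply(sweeps, function(s) s$end, numeric(1)))
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric())
  }

  out <- list(gm = gm, truth = truth,
              split = list(tolerance = sample_ids[seq_len(n)],
                           control = sample_ids[n + seq_len(n)]),
              chrom_lengths = setNames(chrom_len, chrom),
              params = list(n_per_pop = n, chrom_len = chrom_len,
                            n_sites = n_sites, F = F, sweeps = sweeps,
                            seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$vcf <- write_vcf_snps(file.path(out_dir, "sim.vcf"), chrom, pos, ref,
                              alt, dosages, sample_ids,
                              setNames(chrom_len, chrom))
    out$truth_bed <- write_bed3(truth, file.path(out_dir, "truth_sweeps.bed"))
    writeLines(out$split$tolerance, file.path(out_dir, "pop_tolerance.txt"))
    writeLines(out$split$control, file.path(out_dir, "pop_control.txt"))
    out$pop_tolerance <- file.path(out_dir, "pop_tolerance.txt")
    out$pop_control <- file.path(out_dir, "pop_control.txt")
  }
  out
}
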
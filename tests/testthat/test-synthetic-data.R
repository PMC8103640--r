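test_that("two-population generator is deterministic and validates inputs", {
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  s1 <- sim_two_pop_genotypes(n_per_pop = 4, chrom_len = 1e5, n_sites = 500,
                              F = 0.1, seed = 3, out_dir = d1)
  s2 <- sim_two_pop_genotypes(n_per_pop = 4, chrom_len = 1e5, n_sites = 500,
                              F = 0.1, seed = 3, out_dir = d2)
  expect_identical(readLines(s1$vcf), readLines(s2$vcf))
  expect_identical(s1$gm$dosages, s2$gm$dosages)

  expect_error(sim_two_pop_genotypes(F = 1), "degenerate")
  expect_error(sim_two_pop_genotypes(
    chrom_len = 1e5, n_sites = 100,
    sweeps = list(list(start = 1, end = 5e4, pi_reduction = 10),
                  list(start = 4e4, end = 9e4, pi_reduction = 10))),
    "overlap")
})

test_that("with F = 0 and no sweeps the populations share allele frequencies", {
  s <- sim_two_pop_genotypes(n_per_pop = 20, chrom_len = 1e6, n_sites = 1e4,
                             F = 0, seed = 9)
  d <- s$gm$dosages
  p_t <- rowMeans(d[, s$split$tolerance]) / 2
  p_c <- rowMeans(d[, s$split$control]) / 2
  diffs <- p_t - p_c
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("planted sweeps reduce tolerance diversity inside the interval", {
  sweeps <- list(list(start = 3e5 + 1, end = 4e5, pi_reduction = 10))
  for (seed in 1:10) {
    s <- sim_two_pop_genotypes(n_per_pop = 7, chrom_len = 1e6, n_sites = 5000,
                               F = 0.15, sweeps = sweeps, seed = seed)
    pi_in <- window_pi(s$gm, s$split$tolerance, "chr1", 3e5, 4e5)
    pi_out <- window_pi(s$gm, s$split$tolerance, "chr1", 5e5, 6e5)
    expect_lt(pi_in, pi_out)
  }
})

test_that("truth BED records the planted intervals 0-based half-open", {
  d <- tempfile(); on.exit(unlink(d, recursive = TRUE))
  s <- sim_two_pop_genotypes(chrom_len = 1e6, n_sites = 1000,
                             sweeps = list(list(start = 1001, end = 2000,
                                                pi_reduction = 5)),
                             seed = 1, out_dir = d)
  bed <- read.table(s$truth_bed)
  expect_equal(bed$V2, 1000)
  expect_equal(bed$V3, 2000)
})

test_that("codon pair generator honours its closed-form limits", {
  s0 <- sim_codon_pair_set(n_pairs = 5, sites_per_pair = 200, beta_T = 0, seed = 2)
  expect_identical(s0$seq_a, setNames(s0$seq_b, names(s0$seq_a)))
  tab0 <- fourdtv_table(s0$seq_a, s0$seq_b)
  expect_true(all(tab0$fourdtv == 0))

  # saturation: transversion fraction approaches 1/2
  ssat <- sim_codon_pair_set(n_pairs = 10, sites_per_pair = 1e4, beta_T = 50,
                             seed = 2)
  tab <- fourdtv_table(ssat$seq_a, ssat$seq_b)
  expect_lt(abs(mean(tab$fourdtv) - 0.5), 0.01)

  expect_error(sim_codon_pair_set(beta_T = -1), ">= 0")
})

test_that("codon pairs expose exact per-pair transversion counts as truth", {
  s <- sim_codon_pair_set(n_pairs = 4, sites_per_pair = 500, beta_T = 0.3,
                          seed = 8)
  tab <- fourdtv_table(s$seq_a, s$seq_b)
  expect_equal(tab$n_transversions, s$truth$n_transversions)
  expect_equal(tab$n_4d_sites, rep(500L, 4))
})

test_that("read simulator is deterministic and validates arguments", {
  r1 <- sim_diploid_reads(genome_len = 2e4, coverage = 10, read_len = 80,
                          seed = 4)
  r2 <- sim_diploid_reads(genome_len = 2e4, coverage = 10, read_len = 80,
                          seed = 4)
  expect_identical(r1$reads, r2$reads)
  expect_true(all(nchar(r1$reads) == 80))
  expect_equal(length(r1$reads), ceiling(2e4 * 10 / 80))
  expect_error(sim_diploid_reads(genome_len = 50, read_len = 100),
               "genome_len")
})

test_that("very low coverage leaves the peak at multiplicity 1", {
  r <- sim_diploid_reads(genome_len = 5e4, coverage = 1, read_len = 100,
                         seed = 6)
  h <- count_kmers(r$reads, 17)
  expect_error(find_major_peak(h, "first_local_min"), "peak not found")
})

test_that("gene-order generator plants disjoint deletion/unannotated sets", {
  expect_error(sim_gene_order_pair(deletions = "t0001",
                                   unannotated_but_present = "t0001"),
               "disjoint")
  s <- sim_gene_order_pair(n_genes = 20, n_chroms = 2,
                           deletions = c("t0003", "t0010"),
                           unannotated_but_present = "t0015", seed = 2)
  expect_true(all(is.na(
    s$pairs$reference_gene[s$pairs$target_gene %in% c("t0003", "t0010", "t0015")])))
  # deleted sequence absent from, unannotated sequence present in, the reference
  all_ref <- paste(s$ref_genome, collapse = "")
  expect_false(grepl(s$cds[["t0003"]], all_ref, fixed = TRUE))
  expect_false(grepl(s$cds[["t0010"]], all_ref, fixed = TRUE))
  expect_true(grepl(s$cds[["t0015"]], all_ref, fixed = TRUE))
  expect_false("r0015" %in% s$ref_genes$gene_id)
})
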
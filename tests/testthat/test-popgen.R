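make_gm <- function(dosages, pos = NULL, chrom = "chr1") {
  n <- nrow(dosages)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  new_genotype_matrix(
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T"),
    dosages, colnames(dosages))
}

two_pop <- function(d1, d2) {
  d <- cbind(d1, d2)
  colnames(d) <- c(paste0("t", seq_len(ncol(d1))), paste0("c", seq_len(ncol(d2))))
  list(gm = make_gm(d),
       split = population_split(paste0("t", seq_len(ncol(d1))),
                                paste0("c", seq_len(ncol(d2)))))
}

test_that("site pi matches pairwise enumeration", {
  expect_equal(site_pi(2, 2), oracle_site_pi(c(0, 0, 1, 1)))
  expect_equal(site_pi(2, 2), 2 / 3)
  expect_equal(site_pi(4, 0), 0)
  expect_equal(site_pi(1, 1), 1)
  expect_error(site_pi(1, 0), "2 observed alleles")
})

test_that("window pi normalizes by span and skips under-called sites", {
  # one site with alleles {A,A,T,T} in a 40 kb window
  d <- matrix(c(1L, 1L), nrow = 1,
              dimnames = list(NULL, c("s1", "s2")))
  gm <- make_gm(d, pos = 100L)
  expect_equal(window_pi(gm, c("s1", "s2"), "chr1", 0, 40000), (2 / 3) / 40000)
  expect_equal(window_pi(gm, c("s1", "s2"), "chr1", 40000, 80000), 0)
  expect_error(window_pi(gm, c("s1", "s2"), "chr1", 100, 100), "zero-span")
})

test_that("per-bp pi is invariant to doubling span with doubled SNPs", {
  d1 <- matrix(rep(c(0L, 1L, 2L, 1L), 3), nrow = 3, byrow = TRUE,
               dimnames = list(NULL, paste0("s", 1:4)))
  gm1 <- make_gm(d1, pos = c(10L, 20L, 30L))
  d2 <- rbind(d1, d1)
  gm2 <- make_gm(d2, pos = c(10L, 20L, 30L, 1010L, 1020L, 1030L))
  expect_equal(window_pi(gm1, paste0("s", 1:4), "chr1", 0, 1000),
               window_pi(gm2, paste0("s", 1:4), "chr1", 0, 2000))
})

test_that("fixed difference gives a=0.5,b=0,c=0 and theta = 1 exactly", {
  tp <- two_pop(matrix(0L, 1, 5), matrix(2L, 1, 5))
  comp <- wc_site_components(tp$gm, tp$split)
  expect_identical(comp$a, 0.5)
  expect_identical(comp$b, 0)
  expect_identical(comp$c, 0)
  expect_identical(window_fst(comp), 1)
})

test_that("identical heterozygotes in both populations give theta = 0 exactly", {
  tp <- two_pop(matrix(1L, 1, 2), matrix(1L, 1, 2))
  comp <- wc_site_components(tp$gm, tp$split)
  expect_identical(comp$a, 0)
  expect_identical(comp$b, -0.25)
  expect_identical(comp$c, 0.5)
  expect_identical(window_fst(comp), 0)
})

test_that("monomorphic sites contribute nothing", {
  tp <- two_pop(matrix(0L, 1, 4), matrix(0L, 1, 4))
  comp <- wc_site_components(tp$gm, tp$split)
  expect_equal(comp$a + comp$b + comp$c, 0)
  expect_true(is.na(window_fst(comp)))
})

test_that("sites with under 2 called individuals in a population are skipped", {
  d1 <- matrix(c(1L, NA, NA, NA), 1, 4)
  tp <- two_pop(d1, matrix(c(0L, 1L, 2L, 0L), 1, 4))
  comp <- wc_site_components(tp$gm, tp$split)
  expect_true(is.na(comp$a))
})

test_that("ratio-of-sums Fst matches the brute-force oracle to 1e-12", {
  set.seed(101)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    d1 <- matrix(sample(0:2, 25 * n1, replace = TRUE), 25, n1)
    d2 <- matrix(sample(0:2, 25 * n2, replace = TRUE), 25, n2)
    d1[runif(length(d1)) < 0.1] <- NA
    d2[runif(length(d2)) < 0.1] <- NA
    keep1 <- rowSums(!is.na(d1)) >= 2 & rowSums(!is.na(d2)) >= 2
    tp <- two_pop(d1, d2)
    comp <- wc_site_components(tp$gm, tp$split)
    expect_equal(window_fst(comp), oracle_wc_theta(d1, d2), tolerance = 1e-12)
  }
})

test_that("window statistics are invariant under within-population relabeling", {
  set.seed(55)
  s <- sim_two_pop_genotypes(n_per_pop = 6, chrom_len = 2e5, n_sites = 2000,
                             F = 0.2, seed = 77)
  ws1 <- scan_windows(s$gm, s$split, s$chrom_lengths)
  sp2 <- list(tolerance = sample(s$split$tolerance),
              control = sample(s$split$control))
  ws2 <- scan_windows(s$gm, sp2, s$chrom_lengths)
  expect_equal(ws1$fst, ws2$fst)
  expect_equal(ws1$pi_tolerance, ws2$pi_tolerance)
})

test_that("negative windowed theta is retained unless clamped", {
  # equal allele frequencies but opposite genotype configurations push the
  # estimator below zero (excess within-population variance)
  tp <- two_pop(matrix(c(0L, 2L), 1, 2), matrix(c(1L, 1L), 1, 2))
  comp <- wc_site_components(tp$gm, tp$split)
  th <- window_fst(comp)
  expect_lt(th, 0)
  expect_identical(window_fst(comp, clamp_negative = TRUE), 0)
})

test_that("log2 diversity ratio handles zeros as undefined", {
  expect_equal(log2_pi_ratio(0.002, 0.0005), 2)
  expect_equal(log2_pi_ratio(0.001, 0.001), 0)
  expect_true(is.na(log2_pi_ratio(0.001, 0)))
  expect_true(is.na(log2_pi_ratio(0, 0.001)))
  expect_error(log2_pi_ratio(-0.1, 0.2), ">= 0")
})
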
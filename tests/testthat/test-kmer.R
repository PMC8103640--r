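test_that("canonical k-mer counting matches hand enumeration", {
  # ACGTACGT, k=5: windows ACGTA, CGTAC, GTACG, TACGT; canonical forms
  # collapse to ACGTA (x2) and CGTAC (x2)
  h <- count_kmers("ACGTACGT", k = 5)
  expect_equal(unname(h$counts[["2"]]), 2)
  expect_equal(length(h$counts), 1L)
  expect_equal(h$total_kmers, 4)
})

test_that("reads shorter than k and N-containing windows contribute nothing", {
  h <- count_kmers(c("ACG", "NNNNNNNN", "ACGTACGT"), k = 5)
  expect_equal(h$total_kmers, 4)
  expect_error(count_kmers(c("ACG", "NNNNN"), k = 5), "no k-mers")
})

test_that("even k and out-of-range k are rejected", {
  expect_error(count_kmers("ACGTACGT", k = 4), "odd")
  expect_error(count_kmers("ACGTACGT", k = 33), "3, 31")
})

test_that("histogram is invariant under read order and reverse complement", {
  set.seed(7)
  reads <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
    character(1))
  h1 <- count_kmers(reads, k = 7)
  h2 <- count_kmers(rev(reads), k = 7)
  flip <- reads
  flip[seq(1, 30, by = 3)] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(flip[seq(1, 30, by = 3)])))
  h3 <- count_kmers(flip, k = 7)
  expect_identical(h1$counts, h2$counts)
  expect_identical(h1$counts, h3$counts)
})

test_that("total k-mers equals sum of read_len - k + 1 over clean reads", {
  set.seed(21)
  lens <- sample(30:80, 20, replace = TRUE)
  reads <- vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  h <- count_kmers(reads, k = 17)
  expect_equal(h$total_kmers, sum(lens - 17 + 1))
})

test_that("major peak excludes the error spike under first_local_min", {
  h <- structure(list(k = 17L,
                      counts = setNames(c(1e6, 4e4, 5e4), c("1", "41", "42")),
                      total_kmers = 1e6 + 41 * 4e4 + 42 * 5e4),
                 class = "kmer_histogram")
  expect_equal(find_major_peak(h)$peak, 42)
  expect_equal(find_major_peak(h, "none")$peak, 1)
})

test_that("degenerate histograms are handled per contract", {
  h1 <- structure(list(k = 17L, counts = setNames(100, "30"),
                       total_kmers = 3000), class = "kmer_histogram")
  expect_equal(find_major_peak(h1, "none")$peak, 30)
  h2 <- structure(list(k = 17L, counts = setNames(100, "1"),
                       total_kmers = 100), class = "kmer_histogram")
  expect_error(find_major_peak(h2, "first_local_min"), "peak not found")
})

test_that("genome size estimate is total over peak, linear in the peak", {
  h <- structure(list(k = 17L, counts = setNames(1000, "10"),
                      total_kmers = 10000), class = "kmer_histogram")
  expect_equal(estimate_genome_size(h, 10)$genome_size_bp, 1000)
  expect_equal(estimate_genome_size(h, 5)$genome_size_bp, 2000)
  expect_error(estimate_genome_size(h, 0), ">= 1")
})

test_that("error k-mers can be excluded from the numerator", {
  h <- structure(list(k = 17L,
                      counts = setNames(c(1000, 500), c("1", "20")),
                      total_kmers = 11000), class = "kmer_histogram")
  lit <- estimate_genome_size(h, 20, include_error_kmers = TRUE)
  excl <- estimate_genome_size(h, 20, include_error_kmers = FALSE,
                               error_cutoff = 1)
  expect_equal(lit$genome_size_bp, 11000 / 20)
  expect_equal(excl$genome_size_bp, 10000 / 20)
})

test_that("histo export is two ascending whitespace-separated columns", {
  h <- count_kmers(c("ACGTACGTAA", "ACGTACGT"), k = 5)
  f <- tempfile()
  on.exit(unlink(f))
  write_histo(h, f)
  tab <- read.table(f)
  expect_equal(tab$V1, sort(as.integer(names(h$counts))))
  expect_equal(sum(tab$V1 * tab$V2), h$total_kmers)
})

test_that("heterozygous reads leave a secondary bump at half depth", {
  r <- sim_diploid_reads(genome_len = 5e4, coverage = 50, read_len = 100,
                         het_rate = 0.02, err_rate = 0, seed = 5)
  h <- count_kmers(r$reads, k = 17)
  pk <- find_major_peak(h)
  expect_true(pk$half_depth_bump)
})
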
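test_that("pairs are ordered along chromosomes with NA marks", {
  pairs <- data.frame(target_gene = c("t3", "t1", "t2", "t4"),
                      reference_gene = c(NA, "r1", "r2", "r3"))
  coords <- data.frame(gene_id = paste0("t", 1:4), chrom = "tchr1",
                       start = c(100, 500, 900, 1300),
                       end = c(400, 800, 1200, 1600))
  ord <- order_pairs_and_mark_na(pairs, coords)
  expect_equal(ord$target_gene, paste0("t", 1:4))
  expect_equal(ord$is_na, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(order_pairs_and_mark_na(rbind(pairs, pairs[1, ]), coords),
               "duplicate")
})

test_that("empty and fully-unpaired tables degrade gracefully", {
  coords <- data.frame(gene_id = character(), chrom = character(),
                       start = numeric(), end = numeric())
  empty <- order_pairs_and_mark_na(
    data.frame(target_gene = character(), reference_gene = character()), coords)
  expect_equal(nrow(empty), 0L)
  coords2 <- data.frame(gene_id = c("t1", "t2"), chrom = "tchr1",
                        start = c(1, 100), end = c(50, 150))
  allna <- order_pairs_and_mark_na(
    data.frame(target_gene = c("t1", "t2"),
               reference_gene = c(NA, NA)), coords2)
  reg <- define_absent_regions(allna,
                               data.frame(gene_id = character(),
                                          chrom = character(),
                                          start = numeric(), end = numeric()),
                               c(rchr1 = 1000))
  expect_equal(reg$flank_status, c("none", "none"))
})

test_that("absent regions span the interval between flanking partners", {
  ord <- data.frame(target_gene = c("t1", "t2", "t3"),
                    chrom = "tchr1", start = c(100, 500, 900),
                    end = c(200, 600, 1000),
                    reference_gene = c("r2", NA, "r3"),
                    is_na = c(FALSE, TRUE, FALSE))
  ref <- data.frame(gene_id = c("r2", "r3"), chrom = "refChr1",
                    start = c(10000, 30000), end = c(12000, 33000))
  reg <- define_absent_regions(ord, ref, c(refChr1 = 50000))
  expect_equal(reg$ref_chrom, "refChr1")
  expect_equal(reg$start, 12000)
  expect_equal(reg$end, 30000)
  expect_equal(reg$flank_status, "both")
})

test_that("split flanks leave the region undefined", {
  ord <- data.frame(target_gene = c("t1", "t2", "t3"),
                    chrom = "tchr1", start = c(100, 500, 900),
                    end = c(200, 600, 1000),
                    reference_gene = c("r1", NA, "r9"),
                    is_na = c(FALSE, TRUE, FALSE))
  ref <- data.frame(gene_id = c("r1", "r9"), chrom = c("refChr1", "refChr4"),
                    start = c(100, 100), end = c(500, 500))
  reg <- define_absent_regions(ord, ref, c(refChr1 = 1e4, refChr4 = 1e4))
  expect_true(is.na(reg$start))
  expect_equal(reg$reason, "split flanks")
  expect_equal(reg$flank_status, "both")
})

test_that("chromosome-end NA genes use the single partner to the end", {
  ord <- data.frame(target_gene = c("t0", "t1"),
                    chrom = "tchr1", start = c(50, 500), end = c(80, 600),
                    reference_gene = c(NA, "r1"),
                    is_na = c(TRUE, FALSE))
  ref <- data.frame(gene_id = "r1", chrom = "refChrX",
                    start = 50000, end = 52000)
  reg <- define_absent_regions(ord, ref, c(refChrX = 100000))
  expect_equal(reg$flank_status, "right_only")
  expect_equal(c(reg$start, reg$end), c(1, 50000))

  ord2 <- ord[2:1, ]; ord2$start <- c(500, 900); ord2$end <- c(600, 1000)
  reg2 <- define_absent_regions(ord2, ref, c(refChrX = 100000))
  expect_equal(reg2$flank_status, "left_only")
  expect_equal(c(reg2$start, reg2$end), c(52000, 100000))
})

test_that("regions never overlap the interiors of partner spans", {
  set.seed(40)
  s <- sim_gene_order_pair(n_genes = 30, n_chroms = 2,
                           deletions = c("t0005", "t0017"),
                           unannotated_but_present = "t0022", seed = 40)
  ord <- order_pairs_and_mark_na(s$pairs, s$target_genes)
  reg <- define_absent_regions(ord, s$ref_genes, s$ref_chrom_lengths)
  for (i in seq_len(nrow(reg))) {
    if (is.na(reg$start[i])) next
    same <- s$ref_genes[s$ref_genes$chrom == reg$ref_chrom[i], ]
    inner <- same$start < reg$end[i] & same$end > reg$start[i]
    overl <- pmin(same$end[inner], reg$end[i]) -
      pmax(same$start[inner], reg$start[i])
    expect_true(all(overl <= 1))  # at most boundary-touching
  }
})

test_that("translated search finds an exactly encoded query", {
  set.seed(77)
  cds <- paste(sample(setdiff(apply(expand.grid(c("A","C","G","T"),
                                                c("A","C","G","T"),
                                                c("A","C","G","T")),
                                    1, paste, collapse = ""),
                              c("TAA", "TAG", "TGA")),
                      60, replace = TRUE), collapse = "")
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  region <- paste0(random_dna_str(150), cds, random_dna_str(150))
  hit <- translated_local_alignment(prot, region)
  expect_equal(hit$identity, 100)
  expect_equal(hit$coverage, 100)
  expect_equal(hit$frame, abs(hit$frame))  # found on the forward strand
  # and on the reverse strand after reverse-complementing the region
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(region)))
  hit_rc <- translated_local_alignment(prot, rc)
  expect_equal(hit_rc$identity, 100)
  expect_lt(hit_rc$frame, 0)
})

test_that("random regions do not reach the presence thresholds", {
  set.seed(13)
  cds <- paste(sample(setdiff(apply(expand.grid(c("A","C","G","T"),
                                                c("A","C","G","T"),
                                                c("A","C","G","T")),
                                    1, paste, collapse = ""),
                              c("TAA", "TAG", "TGA")),
                      100, replace = TRUE), collapse = "")
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  fails <- vapply(1:20, function(i) {
    hit <- translated_local_alignment(prot, random_dna_str(600))
    hit$identity < 50 || hit$coverage < 50
  }, logical(1))
  expect_true(all(fails))
})

test_that("N-only regions are unresolved", {
  hit <- translated_local_alignment(strrep("M", 20), strrep("N", 300))
  expect_true(hit$all_n)
  reg <- data.frame(target_gene = "t1", ref_chrom = "c1", start = 1, end = 300,
                    flank_status = "both", reason = NA)
  calls <- classify_retention_loss(reg, c(t1 = strrep("M", 20)),
                                   c(c1 = strrep("N", 400)))
  expect_equal(calls$status, "unresolved")
})

test_that("planted deletions and hidden genes classify exactly", {
  s <- sim_gene_order_pair(n_genes = 30, n_chroms = 2,
                           deletions = c("t0004", "t0011", "t0019"),
                           unannotated_but_present = c("t0008", "t0024"),
                           seed = 21)
  calls <- retention_loss_scan(s$pairs, s$target_genes, s$ref_genes,
                               s$ref_chrom_lengths, s$target_proteins,
                               s$ref_genome)
  expect_setequal(calls$target_gene[calls$status == "lost_in_reference"],
                  c("t0004", "t0011", "t0019"))
  expect_setequal(calls$target_gene[calls$status == "present_unannotated"],
                  c("t0008", "t0024"))
  expect_equal(sum(calls$status == "unresolved"), 0L)
})

test_that("zero thresholds turn every searched gene into present_unannotated", {
  s <- sim_gene_order_pair(n_genes = 12, n_chroms = 1,
                           deletions = "t0005", seed = 33)
  calls <- retention_loss_scan(s$pairs, s$target_genes, s$ref_genes,
                               s$ref_chrom_lengths, s$target_proteins,
                               s$ref_genome, min_identity = 0, min_coverage = 0)
  expect_true(all(calls$status == "present_unannotated"))
})
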
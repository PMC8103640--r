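#' Simulate diploid shotgun reads from a genome of known size
#'
#' Builds a random genome, derives a second haplotype by substituting bases
#' at `het_rate` sites, and draws uniform-start reads alternating between the
#' two haplotypes and strands, with per-base substitution errors at
#' `err_rate`. Intended as input to [count_kmers()]/[estimate_genome_size()]
#' with the genome length as ground truth.
#'
#' @param genome_len Genome length in bp.
#' @param coverage Total fold coverage (both haplotypes combined).
#' @param read_len Read length in bp; must not exceed `genome_len`.
#' @param het_rate Per-bp heterozygosity between the two haplotypes.
#' @param err_rate Per-bp sequencing substitution error rate.
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, write `reads.fastq` and `truth_genome.fasta`.
#' @return List with `reads` (character vector), `genome` (haplotype 1),
#'   `truth` (genome_len, n_het_sites), and file paths when written.
#' @export
sim_diploid_reads <- function(genome_len = 1e5, coverage = 40, read_len = 100L,
                              het_rate = 0, err_rate = 0, seed = 1L,
                              out_dir = NULL) {
  if (genome_len < read_len) stop("genome_len must be >= read_len")
  stopifnot(coverage > 0, read_len >= 1L, het_rate >= 0, het_rate < 1,
            err_rate >= 0, err_rate < 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  hap1 <- sample(bases, genome_len, replace = TRUE)
  hap2 <- hap1
  n_het <- rbinom(1L, genome_len, het_rate)
  if (n_het > 0L) {
    het_pos <- sample.int(genome_len, n_het)
    hap2[het_pos] <- vapply(hap1[het_pos],
                            function(b) sample(setdiff(bases, b), 1L), character(1))
  }
  n_reads <- ceiling(genome_len * coverage / read_len)
  starts <- sample.int(genome_len - read_len + 1L, n_reads, replace = TRUE)
  from_h2 <- sample(c(FALSE, TRUE), n_reads, replace = TRUE)
  rev_strand <- sample(c(FALSE, TRUE), n_reads, replace = TRUE)

  idx <- outer(starts, 0:(read_len - 1L), "+")
  mat <- matrix(hap1[idx], nrow = n_reads)
  if (any(from_h2)) mat[from_h2, ] <- matrix(hap2[idx[from_h2, , drop = FALSE]],
                                             nrow = sum(from_h2))
  if (err_rate > 0) {
    err <- matrix(runif(length(mat)) < err_rate, nrow = n_reads)
    if (any(err))
      mat[err] <- vapply(mat[err], function(b) sample(setdiff(bases, b), 1L),
                         character(1))
  }
  reads <- apply(mat, 1L, paste, collapse = "")
  if (any(rev_strand)) reads[rev_strand] <- revcomp(reads[rev_strand])
  names(reads) <- sprintf("read%06d", seq_len(n_reads))

  genome <- paste(hap1, collapse = "")
  out <- list(reads = reads, genome = genome,
              truth = list(genome_len = genome_len, n_het_sites = n_het),
              params = list(genome_len = genome_len, coverage = coverage,
                            read_len = read_len, het_rate = het_rate,
                            err_rate = err_rate, seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$fastq <- write_fastq(reads, file.path(out_dir, "reads.fastq"))
    out$genome_fasta <- write_fasta(c(truth_genome = genome),
                                    file.path(out_dir, "truth_genome.fasta"))
  }
  out
}
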
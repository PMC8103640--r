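# Small plain-text writers shared by the simulators and the pipeline.
# Every table goes out with a header and tab separation so the package's own
# readers can round-trip it.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "", quote = "", ...)
}

# BED3: 0-based half-open, no header per the format.
write_bed3 <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# 60-column wrapped FASTA from a named character vector.
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Phred+33 FASTQ with a constant quality string per read.
write_fastq <- function(seqs, path, qual_char = "I") {
  con <- file(path, "wt")
  on.exit(close(con))
  ids <- names(seqs)
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", ids[i]), seqs[[i]], "+",
                 strrep(qual_char, nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

# Minimal VCFv4.2 writer for the simulator: biallelic SNPs, GT-only FORMAT.
write_vcf_snps <- function(path, chrom, pos, ref, alt, dosages, sample_ids,
                           contig_lengths) {
  gt <- matrix("./.", nrow = nrow(dosages), ncol = ncol(dosages))
  gt[!is.na(dosages) & dosages == 0L] <- "0/0"
  gt[!is.na(dosages) & dosages == 1L] <- "0/1"
  gt[!is.na(dosages) & dosages == 2L] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=medsweep_sim_two_pop",
           sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                   as.integer(contig_lengths)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_ids), collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
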
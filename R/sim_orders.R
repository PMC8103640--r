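#' Simulate paired gene orders with planted gene losses
#'
#' Builds a "target" genome annotation (ordered genes with coding sequences)
#' and a "reference" genome that carries the same genes in the same order,
#' except that genes in `deletions` are physically absent from the reference
#' sequence and genes in `unannotated_but_present` are present in the
#' reference sequence but missing from its annotation and from the best-hit
#' table. Both classes are therefore "NA" in the best-hit table; only a
#' translated search of the intervening reference interval can tell them
#' apart — exactly the situation the retention/loss procedure resolves.
#'
#' @param n_genes Total target genes.
#' @param n_chroms Number of chromosomes (genes split evenly).
#' @param deletions Character vector of target gene IDs physically deleted
#'   from the reference.
#' @param unannotated_but_present Target gene IDs embedded in the reference
#'   sequence but not annotated; disjoint from `deletions`.
#' @param n_codons Codons per gene (default 100).
#' @param spacer Intergenic spacer length in the reference (default 200 bp).
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, write the gene-order TSVs, best-hit TSV,
#'   reference genome FASTA and target protein FASTA here.
#' @return List with `pairs` (best-hit table), `target_genes`, `ref_genes`
#'   (annotated reference coordinates), `ref_genome` (named character),
#'   `ref_chrom_lengths`, `target_proteins`, and `truth`.
#' @export
sim_gene_order_pair <- function(n_genes = 60L, n_chroms = 2L,
                                deletions = character(),
                                unannotated_but_present = character(),
                                n_codons = 100L, spacer = 200L, seed = 1L,
                                out_dir = NULL) {
  stopifnot(n_genes >= 1L, n_chroms >= 1L, n_codons >= 10L, spacer >= 50L)
  ids <- sprintf("t%04d", seq_len(n_genes))
  deletions <- as.character(deletions)
  unannotated_but_present <- as.character(unannotated_but_present)
  if (length(intersect(deletions, unannotated_but_present)))
    stop("deletions and unannotated_but_present must be disjoint")
  if (!all(c(deletions, unannotated_but_present) %in% ids))
    stop("deletion/unannotated IDs must be target gene IDs (t0001...)")
  set.seed(seed)

  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  gene_len <- 3L * n_codons
  cds <- vapply(seq_len(n_genes), function(i)
    paste(sample(codons, n_codons, replace = TRUE), collapse = ""), character(1))
  names(cds) <- ids
  proteins <- vapply(cds, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s))), character(1))

  chrom_of <- rep(seq_len(n_chroms), length.out = n_genes)
  chrom_of <- sort(chrom_of)
  target <- do.call(rbind, lapply(seq_len(n_chroms), function(ch) {
    g <- ids[chrom_of == ch]
    start <- spacer + (seq_along(g) - 1L) * (gene_len + spacer) + 1L
    data.frame(gene_id = g, chrom = paste0("tchr", ch), start = start,
               end = start + gene_len - 1L, strand = "+",
               stringsAsFactors = FALSE)
  }))

  absent <- ids %in% deletions
  hidden <- ids %in% unannotated_but_present
  ref_id <- ifelse(absent | hidden, NA_character_, sub("^t", "r", ids))

  ref_genes <- NULL
  ref_genome <- character(0)
  ref_chrom_lengths <- integer(0)
  for (ch in seq_len(n_chroms)) {
    sel <- which(chrom_of == ch)
    seq_parts <- character(0)
    ptr <- 0L
    rows <- list()
    for (i in sel) {
      seq_parts <- c(seq_parts, random_dna(spacer)); ptr <- ptr + spacer
      if (absent[i]) next  # deleted: no sequence in the reference
      seq_parts <- c(seq_parts, cds[[i]])
      if (!hidden[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = ref_id[i], chrom = paste0("rchr", ch), start = ptr + 1L,
          end = ptr + gene_len, strand = "+", stringsAsFactors = FALSE)
      }
      ptr <- ptr + gene_len
    }
    seq_parts <- c(seq_parts, random_dna(spacer)); ptr <- ptr + spacer
    ref_genome[paste0("rchr", ch)] <- paste(seq_parts, collapse = "")
    ref_chrom_lengths[paste0("rchr", ch)] <- ptr
    if (length(rows)) ref_genes <- rbind(ref_genes, do.call(rbind, rows))
  }

  pairs <- data.frame(target_gene = ids, reference_gene = ref_id,
                      stringsAsFactors = FALSE)

  out <- list(pairs = pairs, target_genes = target, ref_genes = ref_genes,
              ref_genome = ref_genome, ref_chrom_lengths = ref_chrom_lengths,
              target_proteins = proteins, cds = cds,
              truth = list(deleted = deletions,
                           unannotated_but_present = unannotated_but_present),
              params = list(n_genes = n_genes, n_chroms = n_chroms,
                            n_codons = n_codons, spacer = spacer, seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$target_order_tsv <- write_tsv(target, file.path(out_dir, "target_genes.tsv"))
    out$ref_order_tsv <- write_tsv(ref_genes, file.path(out_dir, "ref_genes.tsv"))
    out$pairs_tsv <- write_tsv(pairs, file.path(out_dir, "best_hits.tsv"))
    out$ref_fasta <- write_fasta(ref_genome, file.path(out_dir, "ref_genome.fasta"))
    out$protein_fasta <- write_fasta(proteins, file.path(out_dir, "target_proteins.fasta"))
  }
  out
}
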
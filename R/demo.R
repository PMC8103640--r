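#' Generate the bundled 7-vs-7 demonstration dataset
#'
#' Writes a complete synthetic input set for [run_sweep_pipeline()]: a VCF of
#' 7 tolerance + 7 control diploids on a 2 Mb chromosome with two planted
#' sweeps, the two population files, a GFF3 of evenly spaced genes, a
#' gene-to-GO annotation, the truth BED, and a ready-to-run `config.yaml`.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed.
#' @return The path of the written `config.yaml`, invisibly; the full file
#'   set as attribute `files`.
#' @export
demo_dataset <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sweeps <- list(list(start = 400001, end = 520000, pi_reduction = 10),
                 list(start = 1400001, end = 1520000, pi_reduction = 10))
  s <- sim_two_pop_genotypes(n_per_pop = 7L, chrom_len = 2e6, n_sites = 2e4,
                             F = 0.15, sweeps = sweeps, seed = seed,
                             out_dir = dir)
  set.seed(seed + 1L)
  n_genes <- 400L
  starts <- round(seq(1, 2e6 - 4000, length.out = n_genes))
  ids <- sprintf("gene%04d", seq_len(n_genes))
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               sprintf("chr1\tmedsweep_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       starts, starts + 2999L,
                       sample(c("+", "-"), n_genes, replace = TRUE), ids)),
             gff)
  g2g <- file.path(dir, "gene2go.tsv")
  terms <- sprintf("GO:%07d", seq_len(15L))
  writeLines(paste(sample(ids, 1200L, replace = TRUE),
                   sample(terms, 1200L, replace = TRUE), sep = "\t"), g2g)
  config <- list(vcf = s$vcf, gff = gff, pop_tolerance = s$pop_tolerance,
                 pop_control = s$pop_control,
                 out_dir = file.path(dir, "results"), gene2go = g2g,
                 seed = seed)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  attr(cfg_path, "files") <- c(vcf = s$vcf, gff = gff, gene2go = g2g,
                               truth_bed = s$truth_bed)
  invisible(cfg_path)
}
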
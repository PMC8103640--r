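#' Genotype matrix container
#'
#' Per-site diploid alternate-allele dosages (0/1/2, `NA` = missing) for a
#' panel of samples, with 1-based site coordinates. Sites are biallelic SNPs
#' with positions strictly increasing within each chromosome.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param dosages Integer matrix, sites x samples.
#' @param sample_ids Character vector matching `ncol(dosages)`.
#' @return An object of class `genotype_matrix`.
#' @export
new_genotype_matrix <- function(sites, dosages, sample_ids) {
  stopifnot(nrow(sites) == nrow(dosages), length(sample_ids) == ncol(dosages),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  colnames(dosages) <- sample_ids
  structure(list(sites = sites, dosages = dosages, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic sites x %d samples (%s)\n",
              nrow(x$sites), length(x$sample_ids),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Keeps biallelic SNP records only (single-base REF and ALT), drops sites
#' whose genotype call rate falls below `min_call_rate`, and converts GT
#' fields to alternate-allele dosages (`0/1` and `1|0` give 1, `1/1` gives 2,
#' `./.` is missing).
#'
#' @param path VCF v4.x file (plain or gzipped) with GT fields.
#' @param min_call_rate Minimum fraction of called genotypes per site.
#' @return A [new_genotype_matrix()] object with an attribute
#'   `contig_lengths` when the VCF header declares contigs.
#' @export
read_vcf_biallelic <- function(path, min_call_rate = 0) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns: ", path)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  alleles1 <- substr(gt, 1L, 1L)
  alleles2 <- substr(gt, 3L, 3L)
  dos <- suppressWarnings(as.integer(alleles1) + as.integer(alleles2))
  dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  if (min_call_rate > 0) {
    cr <- rowMeans(!is.na(dos))
    pass <- cr >= min_call_rate
    dos <- dos[pass, , drop = FALSE]
    keep[keep] <- pass
  }
  if (nrow(dos) == 0L) stop("no sites pass min_call_rate = ", min_call_rate)
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                      stringsAsFactors = FALSE)
  gm <- new_genotype_matrix(sites, dos, colnames(gt))
  meta <- v@meta
  ctg <- regmatches(meta, regexec("^##contig=<ID=([^,>]+),length=([0-9]+)", meta))
  ctg <- Filter(function(m) length(m) == 3L, ctg)
  if (length(ctg))
    attr(gm, "contig_lengths") <- setNames(
      as.numeric(vapply(ctg, `[`, character(1), 3L)),
      vapply(ctg, `[`, character(1), 2L))
  gm
}

#' Define a two-population split of the samples
#'
#' @param tolerance,control Disjoint, non-empty character vectors of sample
#'   IDs; every ID must be present in `gm` when supplied.
#' @param gm Optional [new_genotype_matrix()] to validate IDs against.
#' @return List of class `population_split` with `tolerance` and `control`.
#' @export
population_split <- function(tolerance, control, gm = NULL) {
  tolerance <- as.character(tolerance); control <- as.character(control)
  if (!length(tolerance) || !length(control))
    stop("both populations must be non-empty")
  if (length(intersect(tolerance, control)))
    stop("populations must be disjoint: ",
         paste(intersect(tolerance, control), collapse = ", "))
  if (!is.null(gm)) {
    missing <- setdiff(c(tolerance, control), gm$sample_ids)
    if (length(missing))
      stop("sample IDs absent from genotype matrix: ",
           paste(missing, collapse = ", "))
  }
  structure(list(tolerance = tolerance, control = control),
            class = "population_split")
}
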
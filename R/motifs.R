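IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Count IUPAC motif occurrences in a promoter
#'
#' Scans the forward strand (and, with `both_strands`, the reverse
#' complement) for matches of an IUPAC-ambiguity pattern. `overlapping`
#' counts every match start; `non_overlapping` advances past each match
#' before continuing.
#'
#' @param promoter DNA string over A/C/G/T/N.
#' @param motif IUPAC pattern, e.g. `"CNGTTR"`.
#' @param both_strands Also scan the reverse complement (default `TRUE`).
#' @param count_mode `"overlapping"` (default) or `"non_overlapping"`.
#' @return Integer occurrence count.
#' @export
count_motif_occurrences <- function(promoter, motif, both_strands = TRUE,
                                    count_mode = c("overlapping", "non_overlapping")) {
  count_mode <- match.arg(count_mode)
  motif <- toupper(motif)
  if (!nzchar(motif)) stop("motif must be non-empty")
  bad <- setdiff(strsplit(motif, "")[[1]], IUPAC_CODES)
  if (length(bad))
    stop("invalid IUPAC code(s) in motif: ", paste(unique(bad), collapse = ", "))
  promoter <- toupper(promoter)
  if (!nzchar(promoter) || nchar(promoter) < nchar(motif)) return(0L)
  pat <- Biostrings::DNAString(motif)
  count_one <- function(seq_str) {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq_str),
                                  fixed = "subject")
    starts <- sort(Biostrings::start(m))
    if (count_mode == "overlapping" || length(starts) <= 1L)
      return(length(starts))
    n <- 0L; nextok <- -Inf; w <- nchar(motif)
    for (s in starts) {
      if (s >= nextok) { n <- n + 1L; nextok <- s + w }
    }
    n
  }
  n <- count_one(promoter)
  if (both_strands) n <- n + count_one(revcomp(promoter))
  n
}

#' Filter genes by motif count
#'
#' Keeps genes whose promoter motif count exceeds `min_count` (strict `>`,
#' matching a "more than `min_count` elements" rule) or reaches it when
#' `strict_greater = FALSE`.
#'
#' @param counts Named integer vector (gene -> motif count).
#' @param min_count Threshold (default 2).
#' @param strict_greater Use `>` (default) rather than `>=`.
#' @return Character vector of gene IDs.
#' @export
filter_motif_targets <- function(counts, min_count = 2L, strict_greater = TRUE) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (!length(counts)) return(character(0))
  keep <- if (strict_greater) counts > min_count else counts >= min_count
  names(counts)[keep]
}

#' Extract strand-aware promoter sequences
#'
#' The `upstream` bp immediately 5' of each gene start (strand-aware,
#' truncated at chromosome ends), for motif scanning.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param genome Named character vector of chromosome sequences.
#' @param upstream Promoter length in bp (default 2000).
#' @return Named character vector of promoter sequences (5'->3' of the gene).
#' @export
extract_promoters <- function(genes, genome, upstream = 2000L) {
  out <- vapply(seq_len(nrow(genes)), function(i) {
    seq <- genome[[genes$chrom[i]]]
    if (is.null(seq)) stop("chromosome missing from genome: ", genes$chrom[i])
    if (identical(genes$strand[i], "-")) {
      lo <- genes$end[i] + 1L
      hi <- min(nchar(seq), genes$end[i] + upstream)
      if (lo > hi) return("")
      revcomp(substr(seq, lo, hi))
    } else {
      lo <- max(1L, genes$start[i] - upstream)
      hi <- genes$start[i] - 1L
      if (lo > hi) return("")
      substr(seq, lo, hi)
    }
  }, character(1))
  setNames(out, genes$gene_id)
}
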
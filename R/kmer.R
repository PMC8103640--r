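#' Canonical k-mer multiplicity histogram
#'
#' Counts every length-`k` window of every read in canonical form (the
#' lexicographically smaller of the k-mer and its reverse complement, so the
#' sequencing strand is irrelevant) and tabulates how many distinct canonical
#' k-mers occur at each multiplicity. Windows containing a non-ACGT character
#' are skipped.
#'
#' @param reads Character vector of read sequences, or the path of a
#'   FASTA/FASTQ file (gzip allowed; format detected from content).
#' @param k Odd integer word size, 3--31. Default 17, the conventional choice
#'   for plant genome-size estimation.
#' @return An object of class `kmer_histogram`: a list with `k`, `counts`
#'   (named integer vector, names are multiplicities in ascending order) and
#'   `total_kmers` (sum of multiplicity x count).
#' @examples
#' h <- count_kmers("ACGTACGT", k = 5)
#' h$counts       # the 4 windows collapse to 2 canonical k-mers seen twice
#' @export
count_kmers <- function(reads, k = 17L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 3L || k > 31L)
    stop("k must be a single integer in [3, 31]")
  if (k %% 2L == 0L)
    stop("k must be odd: even k admits palindromic k-mers with ambiguous canonical form")
  if (length(reads) == 1L && file.exists(reads))
    reads <- read_sequences(reads)
  reads <- as.character(reads)
  if (length(reads) == 0L) stop("no reads supplied")
  m <- kmer_histogram_cpp(reads, k)
  if (nrow(m) == 0L) stop("no k-mers counted (reads shorter than k, or all non-ACGT?)")
  counts <- setNames(m[, "count"], m[, "multiplicity"])
  structure(
    list(k = k, counts = counts,
         total_kmers = sum(as.numeric(names(counts)) * as.numeric(counts))),
    class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("kmer_histogram: k=%d, %d multiplicity classes, %.0f total k-mers\n",
              x$k, length(x$counts), x$total_kmers))
  invisible(x)
}

# Read a FASTA or FASTQ file (possibly gzipped) as a character vector.
read_sequences <- function(path) {
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) stop("empty sequence file: ", path)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

#' Locate the major peak of a k-mer histogram
#'
#' Finds the multiplicity with the largest distinct-k-mer count after an
#' error-k-mer cutoff. Sequencing errors create a large spike at multiplicity
#' 1 that would otherwise dominate; `first_local_min` excludes everything at
#' or below the first multiplicity whose count is smaller than the next one.
#'
#' @param hist A `kmer_histogram`.
#' @param error_cutoff_mode `"none"`, `"first_local_min"` (default) or
#'   `"fixed"` (with `fixed_cutoff`): multiplicities `<= cutoff` are excluded
#'   from the peak search.
#' @param fixed_cutoff Cutoff multiplicity when mode is `"fixed"`.
#' @return A list with `peak` (multiplicity), `error_cutoff` used, and
#'   `reliable` (`FALSE` when the peak sits directly at the cutoff boundary
#'   or a secondary peak near half the major depth suggests heterozygosity).
#' @export
find_major_peak <- function(hist,
                            error_cutoff_mode = c("first_local_min", "none", "fixed"),
                            fixed_cutoff = NULL) {
  stopifnot(inherits(hist, "kmer_histogram"))
  error_cutoff_mode <- match.arg(error_cutoff_mode)
  mult <- as.integer(names(hist$counts))
  cnt <- as.numeric(hist$counts)
  cutoff <- switch(error_cutoff_mode,
    none = 0L,
    fixed = {
      if (is.null(fixed_cutoff)) stop("fixed_cutoff required for mode 'fixed'")
      as.integer(fixed_cutoff)
    },
    first_local_min = {
      # smallest multiplicity m (present in the histogram) with counts[m] < counts[m+1]
      co <- NA_integer_
      for (i in seq_len(length(mult) - 1L)) {
        if (mult[i + 1L] == mult[i] + 1L && cnt[i] < cnt[i + 1L]) { co <- mult[i]; break }
      }
      if (is.na(co)) length(mult) + max(mult) else co  # no rise anywhere -> no peak
    })
  keep <- mult > cutoff
  if (!any(keep)) stop("peak not found: no multiplicity above the error cutoff")
  mk <- mult[keep]; ck <- cnt[keep]
  peak <- mk[which.max(ck)]
  reliable <- peak > cutoff + 1L || error_cutoff_mode == "none"
  # heterozygous genomes split k-mers between a half-depth (one-haplotype)
  # and a full-depth (shared) peak; whichever wins, flag the companion bump
  # so two-peak histograms are reported as ambiguous
  het_bump <- FALSE
  if (peak > 4L) {
    is_max <- vapply(seq_along(mk), function(i) {
      left <- if (i > 1L) ck[i - 1L] else -Inf
      right <- if (i < length(mk)) ck[i + 1L] else -Inf
      ck[i] >= left && ck[i] >= right
    }, logical(1))
    big <- is_max & mk != peak & ck >= 0.25 * ck[mk == peak]
    locs <- mk[big]
    het_bump <- any(abs(locs - peak / 2) <= max(2, 0.1 * peak) |
                      abs(locs - 2 * peak) <= max(2, 0.2 * peak))
  }
  list(peak = peak, error_cutoff = as.integer(cutoff),
       reliable = reliable, half_depth_bump = het_bump)
}

#' Estimate genome size from a k-mer histogram
#'
#' Genome size is the total number of k-mers divided by the depth of the
#' major peak. With `include_error_kmers = TRUE` the numerator is the total
#' over all multiplicities (the literal formula); with `FALSE`, multiplicities
#' at or below `error_cutoff` are excluded, removing the bias that sequencing
#' errors inflate the numerator.
#'
#' @param hist A `kmer_histogram`.
#' @param peak Peak multiplicity (e.g. from [find_major_peak()]), or a list
#'   returned by [find_major_peak()].
#' @param include_error_kmers Include k-mers below the error cutoff in the
#'   numerator (default `TRUE`, the literal total-over-peak formula).
#' @param error_cutoff Multiplicity cutoff used when excluding error k-mers;
#'   taken from `peak` when that is a [find_major_peak()] result.
#' @return A list of class `size_estimate` with `genome_size_bp`,
#'   `peak_depth`, `error_cutoff`, `total_kmers` (as used in the numerator)
#'   and `k`.
#' @export
estimate_genome_size <- function(hist, peak, include_error_kmers = TRUE,
                                 error_cutoff = 0L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (is.list(peak)) {
    error_cutoff <- peak$error_cutoff
    peak <- peak$peak
  }
  peak <- as.integer(peak)
  if (is.na(peak) || peak < 1L) stop("peak depth must be >= 1")
  mult <- as.numeric(names(hist$counts))
  cnt <- as.numeric(hist$counts)
  if (!include_error_kmers) {
    keep <- mult > error_cutoff
    mult <- mult[keep]; cnt <- cnt[keep]
  }
  total <- sum(mult * cnt)
  structure(
    list(genome_size_bp = total / peak, peak_depth = peak,
         error_cutoff = as.integer(error_cutoff), total_kmers = total, k = hist$k),
    class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf("k=%d genome-size estimate: %.0f bp (peak depth %d, %.0f k-mers)\n",
              x$k, x$genome_size_bp, x$peak_depth, x$total_kmers))
  invisible(x)
}

#' Write a k-mer histogram in two-column .histo format
#'
#' Whitespace-separated `multiplicity count` lines, ascending multiplicity —
#' the layout heterozygosity-model tools (e.g. GenomeScope) consume.
#'
#' @param hist A `kmer_histogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_histo <- function(hist, path) {
  stopifnot(inherits(hist, "kmer_histogram"))
  writeLines(paste(names(hist$counts), hist$counts), path)
  invisible(path)
}
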
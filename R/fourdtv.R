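PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_transversion <- function(b1, b2) {
  (b1 %in% PURINES & b2 %in% PYRIMIDINES) |
    (b1 %in% PYRIMIDINES & b2 %in% PURINES)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("alignment length not divisible by 3")
  starts <- seq(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Comparable fourfold-degenerate third-codon positions
#'
#' A codon column of a gap-free codon alignment qualifies iff neither codon
#' contains a gap or N, the first two bases are identical between the two
#' sequences, and that dinucleotide prefix belongs to a fourfold-degenerate
#' family of the standard genetic code (TC, CT, CC, CG, AC, GT, GC, GG).
#'
#' @param seq_a,seq_b Equal-length nucleotide strings, length divisible by 3.
#' @return Integer vector of qualifying codon indices (1-based).
#' @export
fourfold_comparable_sites <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must be aligned (equal length)")
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  pa <- substr(ca, 1L, 2L); pb <- substr(cb, 1L, 2L)
  which(clean & pa == pb & pa %in% FOURFOLD_PREFIXES)
}

#' 4DTv distance of one aligned CDS pair
#'
#' The fraction of comparable fourfold-degenerate third positions whose
#' bases differ by a transversion (purine to pyrimidine or vice versa),
#' uncorrected for multiple hits.
#'
#' @inheritParams fourfold_comparable_sites
#' @param min_sites Minimum comparable sites for a defined value (default 10).
#' @return List with `n_4d_sites`, `n_transversions`, `fourdtv` (`NA` with a
#'   `reason` when fewer than `min_sites` sites are comparable).
#' @export
fourdtv_distance <- function(seq_a, seq_b, min_sites = 10L) {
  idx <- fourfold_comparable_sites(seq_a, seq_b)
  if (length(idx) < min_sites) {
    return(list(n_4d_sites = length(idx), n_transversions = NA_integer_,
                fourdtv = NA_real_,
                reason = sprintf("only %d comparable 4D sites (< %d)",
                                 length(idx), min_sites)))
  }
  b3a <- substr(split_codons(toupper(seq_a))[idx], 3L, 3L)
  b3b <- substr(split_codons(toupper(seq_b))[idx], 3L, 3L)
  n_tv <- sum(is_transversion(b3a, b3b))
  list(n_4d_sites = length(idx), n_transversions = n_tv,
       fourdtv = n_tv / length(idx), reason = NA_character_)
}

#' 4DTv distances for a set of gene pairs
#'
#' @param seq_a,seq_b Named character vectors of aligned CDS (paired by
#'   position).
#' @param ids Optional pair identifiers.
#' @inheritParams fourdtv_distance
#' @return data.frame `pair`, `n_4d_sites`, `n_transversions`, `fourdtv`.
#' @export
fourdtv_table <- function(seq_a, seq_b, ids = NULL, min_sites = 10L) {
  stopifnot(length(seq_a) == length(seq_b))
  if (is.null(ids)) ids <- if (!is.null(names(seq_a))) names(seq_a)
                           else sprintf("pair%04d", seq_along(seq_a))
  rows <- lapply(seq_along(seq_a), function(i) {
    r <- fourdtv_distance(seq_a[[i]], seq_b[[i]], min_sites)
    data.frame(pair = ids[i], n_4d_sites = r$n_4d_sites,
               n_transversions = r$n_transversions, fourdtv = r$fourdtv)
  })
  do.call(rbind, rows)
}

#' Peaks of a 4DTv distribution
#'
#' Histograms the defined 4DTv values on `[0, 1]`, smooths with a centred
#' moving average, and reports local maxima ranked by height; the top one is
#' the candidate whole-genome-duplication peak. A flatness diagnostic flags
#' distributions whose maximum bin is less than 1.5x the median bin.
#'
#' @param values Numeric 4DTv values (NAs dropped).
#' @param bin_width Histogram bin width (default 0.01).
#' @param smooth_bins Moving-average width in bins (odd; default 3).
#' @param min_values Minimum number of defined values (default 50).
#' @return List with `peak` (midpoint of the maximum smoothed bin), `peaks`
#'   (data.frame of local maxima ranked by height) and `well_separated`.
#' @export
fourdtv_peak <- function(values, bin_width = 0.01, smooth_bins = 3L,
                         min_values = 50L) {
  values <- values[!is.na(values)]
  if (length(values) < min_values)
    stop("need at least ", min_values, " defined 4DTv values for a peak")
  if (any(values < 0 | values > 1)) stop("4DTv values must lie in [0, 1]")
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- hist(values, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  counts <- h$counts
  half <- (smooth_bins - 1L) %/% 2L
  sm <- vapply(seq_along(counts), function(i) {
    lo <- max(1L, i - half); hi <- min(length(counts), i + half)
    mean(counts[lo:hi])
  }, numeric(1))
  mids <- h$mids
  is_max <- vapply(seq_along(sm), function(i) {
    left <- if (i > 1L) sm[i - 1L] else -Inf
    right <- if (i < length(sm)) sm[i + 1L] else -Inf
    sm[i] > 0 && sm[i] >= left && sm[i] >= right
  }, logical(1))
  # plateaus: keep the first bin of each run of equal smoothed maxima
  peaks <- data.frame(location = mids[is_max], height = sm[is_max])
  peaks <- peaks[order(-peaks$height, peaks$location), , drop = FALSE]
  keep <- !duplicated(round(peaks$height, 12)) |
    c(TRUE, abs(diff(peaks$location)) > smooth_bins * bin_width)
  peaks <- peaks[keep, , drop = FALSE]
  rownames(peaks) <- NULL
  med <- stats::median(sm)
  well <- med == 0 || max(sm) >= 1.5 * med
  list(peak = peaks$location[1], peaks = peaks, well_separated = well)
}
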
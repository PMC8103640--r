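#' Select the top fraction of windows by a statistic
#'
#' Sorts the usable values descending and keeps the top `floor(q * N)`
#' windows plus any windows tied with the boundary value. With small `N`,
#' `floor(q * N)` can be 0, in which case nothing is selected and a warning
#' is emitted.
#'
#' @param stats data.frame of windows with the statistic in column `value_col`.
#' @param value_col Column name holding the statistic.
#' @param q Fraction in (0, 1); default 0.05 (top 5 percent).
#' @return List with `selected` (data.frame subset), `threshold` (boundary
#'   value) and `n_usable`.
#' @export
select_top_fraction <- function(stats, value_col, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  usable <- stats[!is.na(stats[[value_col]]), , drop = FALSE]
  if (nrow(usable) == 0L) stop("no usable windows for '", value_col, "'")
  v <- usable[[value_col]]
  n_sel <- floor(q * nrow(usable))
  if (n_sel == 0L) {
    warning("floor(q * N) = 0: no windows selected")
    return(list(selected = usable[0, , drop = FALSE], threshold = NA_real_,
                n_usable = nrow(usable)))
  }
  vs <- sort(v, decreasing = TRUE)
  threshold <- vs[n_sel]
  if (all(v == v[1]))
    warning("all values tied: selecting every window")
  sel <- usable[v >= threshold, , drop = FALSE]
  list(selected = sel, threshold = threshold, n_usable = nrow(usable))
}

window_key <- function(w) paste(w$chrom, w$start, w$end, sep = ":")

#' Combine the two top-fraction screens into sweep regions
#'
#' Intersects (default) or unions the windows selected by the Fst screen and
#' by the diversity-ratio screen, then merges overlapping or abutting
#' windows into maximal intervals.
#'
#' @param top_fst,top_ratio data.frames of selected windows (e.g.
#'   `select_top_fraction(...)$selected`); both must come from the same
#'   window grid (identical `size`/`step` attributes when present).
#' @param mode `"intersection"` (conservative default) or `"union"`.
#' @return List of class `sweep_regions`: `regions` (data.frame `chrom`,
#'   `start`, `end`, 0-based half-open) and `windows` (the combined window
#'   set).
#' @export
call_sweep_regions <- function(top_fst, top_ratio,
                               mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  for (at in c("size", "step")) {
    a1 <- attr(top_fst, at); a2 <- attr(top_ratio, at)
    if (!is.null(a1) && !is.null(a2) && a1 != a2)
      stop("window grids differ (", at, " ", a1, " vs ", a2, ")")
  }
  k1 <- window_key(top_fst); k2 <- window_key(top_ratio)
  keys <- if (mode == "intersection") intersect(k1, k2) else union(k1, k2)
  all_w <- unique(rbind(top_fst[, c("chrom", "start", "end")],
                        top_ratio[, c("chrom", "start", "end")]))
  win <- all_w[window_key(all_w) %in% keys, , drop = FALSE]
  if (nrow(win) == 0L) {
    return(structure(list(regions = win, windows = win), class = "sweep_regions"))
  }
  gr <- GenomicRanges::GRanges(win$chrom,
                               IRanges::IRanges(win$start + 1, win$end))
  merged <- GenomicRanges::reduce(gr)  # merges overlapping and abutting
  regions <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                        start = GenomicRanges::start(merged) - 1,
                        end = GenomicRanges::end(merged),
                        stringsAsFactors = FALSE)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(regions = regions, windows = win), class = "sweep_regions")
}

#' Read gene spans from a GFF3 file
#'
#' Extracts `gene` features (falling back to `mRNA` spans with a warning when
#' no `gene` features exist) as a data.frame of 1-based inclusive spans.
#'
#' @param gff Path to a GFF3 file.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff_genes <- function(gff) {
  g <- rtracklayer::import(gff, format = "gff3")
  types <- as.character(g$type)
  sel <- g[types == "gene"]
  if (length(sel) == 0L) {
    if (any(types == "mRNA")) {
      warning("no 'gene' features in ", gff, "; using mRNA spans")
      sel <- g[types == "mRNA"]
    } else {
      stop("no gene features in ", gff, "; available types: ",
           paste(unique(types), collapse = ", "))
    }
  }
  ids <- sel$ID
  if (is.null(ids) || all(is.na(ids))) ids <- sel$Name
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(sel)),
             start = GenomicRanges::start(sel), end = GenomicRanges::end(sel),
             strand = as.character(GenomicRanges::strand(sel)),
             stringsAsFactors = FALSE)
}

#' Candidate genes overlapping sweep regions
#'
#' A gene is a candidate iff its 1-based inclusive span overlaps any region
#' by at least 1 bp. IDs are deduplicated and returned sorted by position.
#'
#' @param genes data.frame from [read_gff_genes()] (or any table with
#'   `gene_id`, `chrom`, `start`, `end`), or a GFF3 path.
#' @param regions A `sweep_regions` object or a data.frame of 0-based
#'   half-open intervals.
#' @return data.frame of candidate genes sorted by (`chrom`, `start`).
#' @export
genes_in_regions <- function(genes, regions) {
  if (is.character(genes)) genes <- read_gff_genes(genes)
  if (inherits(regions, "sweep_regions")) regions <- regions$regions
  if (nrow(regions) == 0L || nrow(genes) == 0L)
    return(genes[0, , drop = FALSE])
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end))
  r <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1, regions$end))
  hit <- GenomicRanges::countOverlaps(g, r, minoverlap = 1L) > 0
  out <- genes[hit, , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full selective-sweep scan
#'
#' Convenience composition: windowed statistics via [scan_windows()], the two
#' top-fraction screens (Fst, and the positive log2 diversity ratio), window
#' combination and merging via [call_sweep_regions()].
#'
#' Windows enter the Fst ranking only with at least `min_snps` usable sites;
#' the ratio ranking additionally requires a defined, strictly positive
#' ratio.
#'
#' @inheritParams scan_windows
#' @param q Top fraction (default 0.05).
#' @param min_snps Minimum usable SNPs per ranked window (default 10).
#' @param combine `"intersection"` or `"union"`.
#' @return List with `windows` (all window stats), `top_fst`, `top_ratio`
#'   (screen results), and `regions` (a `sweep_regions`).
#' @export
sweep_scan <- function(gm, split, chrom_lengths = NULL, size = 40000,
                       step = 20000, q = 0.05, min_snps = 10,
                       combine = c("intersection", "union"),
                       clamp_negative = FALSE) {
  combine <- match.arg(combine)
  ws <- scan_windows(gm, split, chrom_lengths, size, step, clamp_negative)
  rankable <- ws[ws$n_snps >= min_snps, , drop = FALSE]
  attr(rankable, "size") <- size; attr(rankable, "step") <- step
  top_fst <- select_top_fraction(rankable, "fst", q)
  ratio_pool <- rankable[!is.na(rankable$log2_ratio) & rankable$log2_ratio > 0, ,
                         drop = FALSE]
  attr(ratio_pool, "size") <- size; attr(ratio_pool, "step") <- step
  top_ratio <- select_top_fraction(ratio_pool, "log2_ratio", q)
  sf <- top_fst$selected; attr(sf, "size") <- size; attr(sf, "step") <- step
  sr <- top_ratio$selected; attr(sr, "size") <- size; attr(sr, "step") <- step
  regions <- call_sweep_regions(sf, sr, combine)
  list(windows = ws, top_fst = top_fst, top_ratio = top_ratio,
       regions = regions)
}
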
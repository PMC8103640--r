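#' Order best-hit gene pairs along target chromosomes and mark NA
#'
#' Sorts the best-hit table by target gene position and marks target genes
#' without a reference partner as `NA` — the genes whose presence in the
#' reference genome the absent-region procedure will test.
#'
#' @param pairs data.frame with `target_gene` and `reference_gene` (`NA` or
#'   empty for unpaired genes).
#' @param target_genes data.frame of target coordinates (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @return The joined table ordered by (`chrom`, `start`), with `is_na`.
#' @export
order_pairs_and_mark_na <- function(pairs, target_genes) {
  stopifnot(all(c("target_gene", "reference_gene") %in% names(pairs)),
            all(c("gene_id", "chrom", "start", "end") %in% names(target_genes)))
  if (anyDuplicated(pairs$target_gene))
    stop("duplicate target gene IDs in the pair table")
  m <- match(pairs$target_gene, target_genes$gene_id)
  if (anyNA(m))
    stop("target genes without coordinates: ",
         paste(head(pairs$target_gene[is.na(m)], 5L), collapse = ", "))
  out <- data.frame(target_gene = pairs$target_gene,
                    chrom = target_genes$chrom[m],
                    start = target_genes$start[m],
                    end = target_genes$end[m],
                    reference_gene = pairs$reference_gene,
                    stringsAsFactors = FALSE)
  out$reference_gene[out$reference_gene %in% c("", "NA")] <- NA_character_
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$is_na <- is.na(out$reference_gene)
  rownames(out) <- NULL
  out
}

#' Define absent regions on the reference for NA-marked genes
#'
#' For each target gene without a reference partner, takes the nearest
#' upstream and downstream target genes (on the same target chromosome) that
#' do have reference partners. When both partners lie on one reference
#' chromosome, the absent region is the reference interval between the two
#' partner spans (from the end of the earlier partner to the start of the
#' later one, 1-based inclusive). A gene at a chromosome end uses the single
#' partner and extends to the reference chromosome end (or base 1); partners
#' on different reference chromosomes leave the region undefined.
#'
#' @param ordered Table from [order_pairs_and_mark_na()].
#' @param ref_genes Reference coordinates (`gene_id`, `chrom`, `start`, `end`).
#' @param ref_chrom_lengths Named vector of reference chromosome lengths.
#' @return data.frame with one row per NA gene: `target_gene`, `ref_chrom`,
#'   `start`, `end`, `flank_status` (both/left_only/right_only/none),
#'   `reason` for undefined regions.
#' @export
define_absent_regions <- function(ordered, ref_genes, ref_chrom_lengths) {
  ridx <- function(g) {
    i <- match(g, ref_genes$gene_id)
    if (is.na(i)) stop("reference gene without coordinates: ", g)
    i
  }
  na_rows <- which(ordered$is_na)
  rows <- lapply(na_rows, function(i) {
    ch <- ordered$chrom[i]
    same <- which(ordered$chrom == ch)
    left <- same[same < i & !ordered$is_na[same]]
    right <- same[same > i & !ordered$is_na[same]]
    left <- if (length(left)) max(left) else NA_integer_
    right <- if (length(right)) min(right) else NA_integer_
    res <- data.frame(target_gene = ordered$target_gene[i],
                      ref_chrom = NA_character_, start = NA_real_,
                      end = NA_real_, flank_status = "none",
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (is.na(left) && is.na(right)) {
      res$reason <- "no paired flanking genes"
      return(res)
    }
    if (!is.na(left) && !is.na(right)) {
      rl <- ridx(ordered$reference_gene[left])
      rr <- ridx(ordered$reference_gene[right])
      res$flank_status <- "both"
      if (ref_genes$chrom[rl] != ref_genes$chrom[rr]) {
        res$reason <- "split flanks"
        return(res)
      }
      # orientation-normalized: the interval between the two partner spans
      lo <- if (ref_genes$start[rl] <= ref_genes$start[rr]) rl else rr
      hi <- if (lo == rl) rr else rl
      res$ref_chrom <- ref_genes$chrom[lo]
      res$start <- ref_genes$end[lo]
      res$end <- ref_genes$start[hi]
      if (res$start >= res$end) {
        res$start <- NA_real_; res$end <- NA_real_
        res$reason <- "partners overlap or abut"
      }
      return(res)
    }
    one <- if (is.na(left)) right else left
    r1 <- ridx(ordered$reference_gene[one])
    res$flank_status <- if (is.na(left)) "right_only" else "left_only"
    res$ref_chrom <- ref_genes$chrom[r1]
    len <- ref_chrom_lengths[[res$ref_chrom]]
    if (is.null(len)) stop("no length for reference chromosome ", res$ref_chrom)
    if (is.na(left)) {  # first on its chromosome: region runs from base 1
      res$start <- 1
      res$end <- ref_genes$start[r1]
    } else {
      res$start <- ref_genes$end[r1]
      res$end <- len
    }
    res
  })
  if (!length(rows))
    return(data.frame(target_gene = character(), ref_chrom = character(),
                      start = numeric(), end = numeric(),
                      flank_status = character(), reason = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Translated local alignment of a protein against a DNA region
#'
#' Translates the region in all six frames, breaks each frame at stop
#' codons, and locally aligns the query protein against every resulting
#' segment under BLOSUM62 scoring with affine gaps (open 11, extend 1). The
#' best-scoring hit's percent identity over aligned columns and coverage of
#' the query are returned.
#'
#' @param query_protein Amino-acid string (>= 10 aa).
#' @param region_dna Nucleotide string (>= 3 bp).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return List with `identity` (percent), `coverage` (percent of query
#'   aligned), `frame` (+1..+3/-1..-3), `score`, `n_segments`; identity and
#'   coverage are 0 when nothing aligns; `all_n = TRUE` flags regions of
#'   only Ns (unresolvable).
#' @export
translated_local_alignment <- function(query_protein, region_dna,
                                       gap_opening = 11, gap_extension = 1) {
  query_protein <- toupper(gsub("\\*+$", "", query_protein))
  region_dna <- toupper(region_dna)
  if (nchar(query_protein) < 10L) stop("query must be at least 10 aa")
  if (nchar(region_dna) < 3L) stop("region must be at least 3 bp")
  if (grepl("^[N]+$", region_dna))
    return(list(identity = 0, coverage = 0, frame = NA_integer_, score = NA_real_,
                n_segments = 0L, all_n = TRUE))

  dna <- Biostrings::DNAString(region_dna)
  rc <- Biostrings::reverseComplement(dna)
  qlen <- nchar(query_protein)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62 <- get("BLOSUM62", envir = environment())

  segs <- character(0); seg_frame <- integer(0)
  for (strand in c(1L, -1L)) {
    s <- if (strand > 0) dna else rc
    for (off in 0:2) {
      len <- length(s) - off
      if (len < 3L) next
      sub <- Biostrings::subseq(s, off + 1L, off + (len %/% 3L) * 3L)
      aa <- suppressWarnings(as.character(
        Biostrings::translate(sub, if.fuzzy.codon = "X")))
      fr_segs <- strsplit(aa, "\\*")[[1]]
      fr_segs <- fr_segs[nchar(fr_segs) >= 3L]
      segs <- c(segs, fr_segs)
      seg_frame <- c(seg_frame, rep(strand * (off + 1L), length(fr_segs)))
    }
  }
  if (!length(segs))
    return(list(identity = 0, coverage = 0, frame = NA_integer_,
                score = NA_real_, n_segments = 0L, all_n = FALSE))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep(query_protein, length(segs))),
    Biostrings::AAStringSet(segs), type = "local",
    substitutionMatrix = BLOSUM62,
    gapOpening = gap_opening, gapExtension = gap_extension)
  sc <- Biostrings::score(aln)
  i <- which.max(sc)
  pc <- strsplit(as.character(Biostrings::alignedPattern(aln[i])), "")[[1]]
  sj <- strsplit(as.character(Biostrings::alignedSubject(aln[i])), "")[[1]]
  list(identity = 100 * sum(pc == sj & pc != "-") / length(pc),
       coverage = 100 * sum(pc != "-") / qlen,
       frame = seg_frame[i], score = sc[i], n_segments = length(segs),
       all_n = FALSE)
}

#' Classify NA-marked genes as lost or present-unannotated
#'
#' Runs the translated search over each gene's absent region and calls:
#' `present_unannotated` when the best hit reaches both thresholds,
#' `lost_in_reference` when a completed search stays below them, and
#' `unresolved` when the region is undefined or all Ns. Hits that reach the
#' identity but not the coverage threshold are flagged `partial` (as happens
#' when an intron or internal stop splits the frame).
#'
#' @param regions data.frame from [define_absent_regions()].
#' @param target_proteins Named character vector of query proteins (names =
#'   target gene IDs).
#' @param ref_genome Named character vector of reference chromosome
#'   sequences.
#' @param min_identity,min_coverage Presence thresholds in percent
#'   (default 50/50).
#' @return data.frame of calls (`target_gene`, `status`, `identity`,
#'   `coverage`, `frame`, `partial`, `region`), plus a `summary` attribute
#'   with counts per status.
#' @export
classify_retention_loss <- function(regions, target_proteins, ref_genome,
                                    min_identity = 50, min_coverage = 50) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    out <- data.frame(target_gene = r$target_gene, status = "unresolved",
                      identity = NA_real_, coverage = NA_real_,
                      frame = NA_integer_, partial = FALSE,
                      region = NA_character_, stringsAsFactors = FALSE)
    if (is.na(r$start) || is.na(r$end)) return(out)
    chrom_seq <- ref_genome[[r$ref_chrom]]
    if (is.null(chrom_seq)) stop("reference chromosome missing: ", r$ref_chrom)
    seg <- substr(chrom_seq, max(1, r$start), min(nchar(chrom_seq), r$end))
    q <- target_proteins[[r$target_gene]]
    if (is.null(q)) stop("no protein for target gene ", r$target_gene)
    hit <- translated_local_alignment(q, seg)
    out$region <- sprintf("%s:%d-%d", r$ref_chrom, as.integer(r$start),
                          as.integer(r$end))
    if (hit$all_n) return(out)
    out$identity <- hit$identity; out$coverage <- hit$coverage
    out$frame <- hit$frame
    if (hit$identity >= min_identity && hit$coverage >= min_coverage) {
      out$status <- "present_unannotated"
    } else {
      out$status <- "lost_in_reference"
      out$partial <- hit$identity >= min_identity && hit$coverage < min_coverage
    }
    out
  })
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_gene = character(), status = character(),
               identity = numeric(), coverage = numeric(), frame = integer(),
               partial = logical(), region = character())
  rownames(calls) <- NULL
  attr(calls, "summary") <- table(factor(
    calls$status, levels = c("lost_in_reference", "present_unannotated",
                             "unresolved")))
  calls
}

#' Run the full retention/loss procedure
#'
#' Composes [order_pairs_and_mark_na()], [define_absent_regions()] and
#' [classify_retention_loss()].
#'
#' @inheritParams order_pairs_and_mark_na
#' @inheritParams define_absent_regions
#' @inheritParams classify_retention_loss
#' @return The calls data.frame (see [classify_retention_loss()]).
#' @export
retention_loss_scan <- function(pairs, target_genes, ref_genes,
                                ref_chrom_lengths, target_proteins, ref_genome,
                                min_identity = 50, min_coverage = 50) {
  ordered <- order_pairs_and_mark_na(pairs, target_genes)
  regions <- define_absent_regions(ordered, ref_genes, ref_chrom_lengths)
  classify_retention_loss(regions, target_proteins, ref_genome,
                          min_identity, min_coverage)
}
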
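# Longest chain DP over anchors sorted by rank_a.
# dir = +1 requires rank_b strictly increasing, -1 strictly decreasing;
# consecutive anchors may skip at most max_gap intervening gene ranks on
# either genome. Returns indices (into the supplied rows) of the best chain.
best_chain <- function(ra, rb, dir, max_gap) {
  n <- length(ra)
  ord <- order(ra, if (dir > 0) rb else -rb)
  ra <- ra[ord]; rb <- rb[ord]
  len <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[j] >= ra[i]) next
      if (ra[i] - ra[j] - 1L > max_gap) next
      db <- dir * (rb[i] - rb[j])
      if (db <= 0 || db - 1L > max_gap) next
      if (len[j] + 1L > len[i]) { len[i] <- len[j] + 1L; prev[i] <- j }
    }
  }
  i <- which.max(len)
  chain <- integer(0)
  while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
  ord[chain]
}

#' Chain anchor gene pairs into syntenic blocks
#'
#' Within each chromosome pair, finds collinear chains of anchors by dynamic
#' programming over gene-order ranks: the longest strictly increasing
#' (orientation `+`) or strictly decreasing (orientation `-`) chain in
#' `rank_b` along increasing `rank_a`, breaking whenever more than `max_gap`
#' gene ranks intervene on either genome. Chains are extracted greedily by
#' descending length, each anchor assigned to at most one block, and chains
#' shorter than `min_block` genes are discarded.
#'
#' @param anchors data.frame with `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b` and optionally `evalue` (anchors above
#'   `evalue_max` are dropped).
#' @param min_block Minimum anchors per block (default 5).
#' @param max_gap Maximum intervening gene ranks between consecutive anchors
#'   (default 25).
#' @param evalue_max Similarity significance threshold (default 1e-5).
#' @return data.frame of anchors kept in blocks, with `block_id` and
#'   `orientation` columns; zero rows when no chain reaches `min_block`.
#' @export
chain_anchors <- function(anchors, min_block = 5L, max_gap = 25L,
                          evalue_max = 1e-5) {
  req <- c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")
  stopifnot(all(req %in% names(anchors)))
  if ("evalue" %in% names(anchors))
    anchors <- anchors[anchors$evalue <= evalue_max, , drop = FALSE]
  anchors <- anchors[!duplicated(anchors[, c("gene_a", "gene_b")]), , drop = FALSE]
  out <- list(); block_id <- 0L
  for (key in unique(paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))) {
    sub <- anchors[paste(anchors$chrom_a, anchors$chrom_b, sep = "\r") == key, ,
                   drop = FALSE]
    repeat {
      if (nrow(sub) < min_block) break
      ch_f <- best_chain(sub$rank_a, sub$rank_b, +1L, max_gap)
      ch_r <- best_chain(sub$rank_a, sub$rank_b, -1L, max_gap)
      if (length(ch_f) >= length(ch_r)) {
        chain <- ch_f; orient <- "+"
      } else {
        chain <- ch_r; orient <- "-"
      }
      if (length(chain) < min_block) break
      block_id <- block_id + 1L
      blk <- sub[chain, , drop = FALSE]
      blk$block_id <- block_id
      blk$orientation <- orient
      out[[block_id]] <- blk
      sub <- sub[-chain, , drop = FALSE]
    }
  }
  if (!length(out)) {
    empty <- anchors[0, , drop = FALSE]
    empty$block_id <- integer(0); empty$orientation <- character(0)
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract duplicated gene pairs from syntenic blocks
#'
#' Concatenates the anchor pairs of all blocks, deduplicated per
#' (`gene_a`, `gene_b`) with block provenance kept; a pair occurring in more
#' than one block (which the assignment rule precludes) is emitted once with
#' a warning.
#'
#' @param blocks data.frame from [chain_anchors()].
#' @return data.frame `gene_a`, `gene_b`, `block_id`.
#' @export
block_gene_pairs <- function(blocks) {
  if (nrow(blocks) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      block_id = integer()))
  key <- paste(blocks$gene_a, blocks$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    warning("anchor pair assigned to multiple blocks; emitting once")
    prov <- tapply(blocks$block_id, key, paste, collapse = ",")
    blocks <- blocks[!duplicated(key), , drop = FALSE]
    blocks$block_id <- as.character(prov[paste(blocks$gene_a, blocks$gene_b,
                                               sep = "\r")])
  }
  out <- blocks[, c("gene_a", "gene_b", "block_id")]
  rownames(out) <- NULL
  out
}

#' Validate the gap constraint of chained blocks
#'
#' Independent post-hoc check that every block's consecutive anchors respect
#' strict monotonicity and the `max_gap` bound on both genomes.
#'
#' @param blocks data.frame from [chain_anchors()].
#' @param max_gap The gap bound the blocks were built with.
#' @return `TRUE` (invisibly) or an error describing the violating block.
#' @export
check_block_gaps <- function(blocks, max_gap = 25L) {
  for (b in unique(blocks$block_id)) {
    blk <- blocks[blocks$block_id == b, , drop = FALSE]
    blk <- blk[order(blk$rank_a), , drop = FALSE]
    da <- diff(blk$rank_a)
    db <- diff(blk$rank_b) * (if (blk$orientation[1] == "+") 1 else -1)
    if (any(da <= 0) || any(db <= 0))
      stop("block ", b, ": ranks not strictly monotone")
    if (any(da - 1 > max_gap) || any(db - 1 > max_gap))
      stop("block ", b, ": gap constraint violated")
  }
  invisible(TRUE)
}
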
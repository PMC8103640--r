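#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability of observing at least `k` selected genes in a term of size
#' `K`, when `n` genes are selected from a universe of `N` — the one-sided
#' over-representation test. The tail sum is evaluated in log space
#' (via the hypergeometric CDF).
#'
#' @param k Selected genes in the term.
#' @param K Universe genes in the term.
#' @param n Selected-set size.
#' @param N Universe size.
#' @return The upper-tail probability P(X >= k).
#' @export
hypergeometric_test <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (K > N || n > N || k < 0 || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: on the sorted p-values,
#' `p_adj_(i) = min_(j >= i) p_(j) * m / j`, clipped at 1 and mapped back to
#' the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Rich factor
#'
#' The proportion of selected genes in a term to all genes in that term,
#' `k / K`.
#'
#' @param k Selected genes in the term.
#' @param K All genes in the term (must be >= 1; terms with `K = 0` are
#'   skipped upstream).
#' @return `k / K` (vectorized).
#' @export
rich_factor <- function(k, K) {
  if (any(K < 1)) stop("K must be >= 1")
  if (any(k < 0 | k > K)) stop("need 0 <= k <= K")
  k / K
}

#' GO term over-representation of a gene set
#'
#' One-sided hypergeometric test per term with BH correction across tested
#' terms and the rich factor `k/K`. Term gene sets are intersected with the
#' universe before testing; terms with no universe genes are skipped.
#'
#' @param selected Character vector of selected gene IDs (intersected with
#'   the universe).
#' @param term2genes Named list mapping term ID to a character vector of
#'   gene IDs.
#' @param universe Character vector of universe gene IDs (default: union of
#'   all annotated genes).
#' @return data.frame `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `rich_factor`, ordered by `p`.
#' @export
go_enrichment <- function(selected, term2genes, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(term2genes))
  universe <- unique(as.character(universe))
  selected <- intersect(unique(as.character(selected)), universe)
  N <- length(universe); n <- length(selected)
  rows <- lapply(names(term2genes), function(term) {
    tg <- intersect(term2genes[[term]], universe)
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(tg, selected))
    data.frame(term = term, k = k, K = K, n = n, N = N,
               p = hypergeometric_test(k, K, n, N),
               rich_factor = rich_factor(k, K), stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), rich_factor = numeric()))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$term),
             c("term", "k", "K", "n", "N", "p", "p_adj", "rich_factor")]
  rownames(out) <- NULL
  out
}

#' Read a gene-to-GO annotation TSV
#'
#' Two columns, `gene_id` and `term` (one pair per line, header optional),
#' returned as a term-to-genes list for [go_enrichment()].
#'
#' @param path TSV path.
#' @return Named list term -> character vector of gene IDs.
#' @export
read_gene2go <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("gene_id", "term"))
  if (df$gene_id[1] %in% c("gene_id", "gene")) df <- df[-1, , drop = FALSE]
  split(df$gene_id, df$term)
}
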
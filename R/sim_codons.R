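# Fourfold-degenerate codon prefixes under the standard genetic code:
# any third base after these dinucleotides encodes the same amino acid.
FOURFOLD_PREFIXES <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")

# K80 transition probabilities for a third-codon site after a branch with
# total transversion parameter beta_t (rate beta to each of the two
# transversion targets) and transition parameter alpha_t = kappa * beta_t:
#   P(specific transversion) = 1/4 - 1/4 e^{-4 beta t}
#   P(transition)            = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2(alpha+beta)t}
# so the total transversion probability is 0.5 (1 - e^{-4 beta t}).
k80_site_probs <- function(beta_t, kappa) {
  e4 <- exp(-4 * beta_t)
  e2 <- exp(-2 * (kappa * beta_t + beta_t))
  p_tv_each <- 0.25 - 0.25 * e4
  p_ts <- 0.25 + 0.25 * e4 - 0.5 * e2
  p_same <- 1 - 2 * p_tv_each - p_ts
  c(same = p_same, transition = p_ts, transversion = 2 * p_tv_each)
}

#' Simulate codon-aligned CDS pairs with known transversion load
#'
#' Each pair consists of two coding sequences identical at codon positions 1
#' and 2 (prefixes drawn from the fourfold-degenerate families), whose third
#' positions diverge under a K80 substitution process with total transversion
#' branch parameter `beta_T`. The expected 4DTv of a pair is the K80
#' closed form `0.5 * (1 - exp(-4 * beta_T))`.
#'
#' @param n_pairs Number of gene pairs.
#' @param sites_per_pair Fourfold-degenerate (= codon) sites per pair.
#' @param beta_T Total transversion branch parameter, `>= 0`.
#' @param kappa_ratio Transition/transversion rate ratio (default 2).
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, write `pairs_a.fasta`, `pairs_b.fasta` and
#'   `truth_codon_pairs.tsv` here.
#' @return List with `seq_a`, `seq_b` (named character vectors), `truth`
#'   data.frame (`pair`, `beta_T`, `n_sites`, `n_transversions`,
#'   `expected_4dtv`), and file paths when written.
#' @export
sim_codon_pair_set <- function(n_pairs = 100L, sites_per_pair = 300L,
                               beta_T = 0.25, kappa_ratio = 2, seed = 1L,
                               out_dir = NULL) {
  if (beta_T < 0) stop("beta_T must be >= 0")
  stopifnot(n_pairs >= 1L, sites_per_pair >= 1L, kappa_ratio >= 0)
  set.seed(seed)
  pr <- k80_site_probs(beta_T, kappa_ratio)
  bases <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                           C = c("A", "G"), T = c("A", "G"))

  seq_a <- character(n_pairs); seq_b <- character(n_pairs)
  n_tv <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    pre <- sample(FOURFOLD_PREFIXES, sites_per_pair, replace = TRUE)
    b3a <- sample(bases, sites_per_pair, replace = TRUE)
    fate <- sample(c("same", "transition", "transversion"), sites_per_pair,
                   replace = TRUE, prob = pr)
    b3b <- b3a
    ts <- fate == "transition"
    b3b[ts] <- transition_of[b3a[ts]]
    tv <- fate == "transversion"
    if (any(tv))
      b3b[tv] <- vapply(b3a[tv], function(b)
        sample(transversions_of[[b]], 1L), character(1))
    n_tv[i] <- sum(tv)
    seq_a[i] <- paste0(pre, b3a, collapse = "")
    seq_b[i] <- paste0(pre, b3b, collapse = "")
  }
  ids <- sprintf("pair%04d", seq_len(n_pairs))
  names(seq_a) <- paste0(ids, "_a"); names(seq_b) <- paste0(ids, "_b")
  truth <- data.frame(pair = ids, beta_T = beta_T, n_sites = sites_per_pair,
                      n_transversions = n_tv,
                      expected_4dtv = 0.5 * (1 - exp(-4 * beta_T)))
  out <- list(seq_a = seq_a, seq_b = seq_b, truth = truth,
              params = list(n_pairs = n_pairs, sites_per_pair = sites_per_pair,
                            beta_T = beta_T, kappa_ratio = kappa_ratio,
                            seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$fasta_a <- write_fasta(seq_a, file.path(out_dir, "pairs_a.fasta"))
    out$fasta_b <- write_fasta(seq_b, file.path(out_dir, "pairs_b.fasta"))
    out$truth_tsv <- write_tsv(truth, file.path(out_dir, "truth_codon_pairs.tsv"))
  }
  out
}
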
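---
title: "Methods: sweep scans, synteny dating and gene-loss screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scans, synteny dating and gene-loss screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsweep)
```

medsweep implements the computational core of a two-population
selective-sweep study on a resequenced plant panel, together with the
comparative-genomic utilities such a study leans on. This vignette explains
the models and procedures, the parameters that matter, what the simulators
do and do not emulate, and the design decisions taken where the procedure
left genuine freedom.

## The sweep scan

The scan assumes a panel of diploid accessions split into a *tolerance* and
a *control* population (the motivating design groups the 7 most tolerant
and the 7 least tolerant accessions of a 20-accession panel), genotyped at
biallelic SNPs.

**Fst.** Per site, the Weir–Cockerham variance components for two diploid
populations are computed from observed calls: with $r=2$ populations,
$n_i$ called individuals, alternate frequency $p_i$ and observed
heterozygote frequency $h_i$ in population $i$, the between-population
($a$), between-individual ($b$) and within-individual ($c$) components
follow the standard 1984 formulas. A window's estimate is the ratio of sums
$\hat\theta_w = \sum a / \sum(a+b+c)$ over its usable sites — the
"weighted" form computed by the classical tooling, preferred over averaging
per-site ratios because it is consistent and robust to low-information
sites. Sites with fewer than 2 called individuals in either population are
skipped; windows whose denominator is zero (e.g. all monomorphic) are
undefined and excluded from ranking. Negative estimates are retained by
default (clamping is available) so that ranking is not biased at the low
end. Two anchors pin the estimator: a fixed difference gives
$\hat\theta = 1$ exactly, and identical heterozygotes in both populations
give $\hat\theta = 0$ exactly.

**Nucleotide diversity.** Per site, the unbiased average pairwise
difference $\pi = 2 c_{\mathrm{ref}} c_{\mathrm{alt}} / (n(n-1))$ over the
$n$ observed alleles of the population; per window, the sum over SNPs
divided by the window span (per-bp $\theta_\pi$). The screening statistic
is $\log_2(\theta_{\pi,\mathrm{control}} / \theta_{\pi,\mathrm{tolerance}})$,
defined only when both diversities are positive; following the figure
convention of the motivating analysis, only windows with a *positive* ratio
(diversity lost in the tolerance population) enter the ratio ranking.

**Windows and screening.** Windows are 40 kb sliding by 20 kb, 0-based
half-open, with truncated terminal windows kept and flagged. Each screen
sorts its usable windows descending and keeps the top
$\lfloor qN \rfloor$ (default $q = 0.05$) plus boundary ties; the two
screens are combined by intersection (default; union available — the
source procedure does not state which was used, and intersection is the
conservative choice), and selected windows merging when they overlap or
abut. Candidate genes are all genes whose 1-based spans overlap a merged
region by at least 1 bp. Windows need at least `min_snps` (default 10)
usable sites to be ranked; the threshold guards against noise-dominated
windows and is configurable because the source procedure states none.

## Synthetic two-population data

`sim_two_pop_genotypes()` uses the Balding–Nichols model: ancestral
frequencies $p \sim U(0.05, 0.95)$ (bounded away from 0/1 so sites are
polymorphic with high probability), population frequencies
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, genotypes
$\mathrm{Bin}(2, p_i)$. This is the standard $F$-parameterised model whose
expected Weir–Cockerham estimate equals $F$, which is exactly what makes it
the right oracle for the estimator under test; at $F=0$ both populations
share $p$. Sweeps are planted deterministically rather than by coalescent
simulation — the tolerance-population frequency inside the interval is
pushed toward the nearer of $\{0,1\}$, dividing the distance by
`pi_reduction` (heterozygosity is approximately linear in the minor
frequency, so diversity falls by about that factor) and then moving a
further fraction `divergence_boost` of the remaining distance, which raises
between-population divergence. The default `divergence_boost = 0.9`
together with `pi_reduction = 10` makes sweep-window Fst about three times
the $F = 0.15$ background, the signal strength the recovery analyses are
specified at. Truth intervals are emitted as BED3.

The generator emulates differentiation and diversity *levels*, not
linkage: sites are independent, there is no recombination map, no allele
surfing, no background selection, and missingness is absent unless
injected. Passing recovery tests therefore demonstrates that the scan
detects the designed signal shape, not that it is robust to every
population-genetic nuisance in real panels.

## k-mer genome sizing

Reads are decomposed into canonical k-mers (lexicographic minimum of the
word and its reverse complement; k odd so no word is its own reverse
complement; windows containing non-ACGT characters are skipped), counted in
a C++ hash, and histogrammed by multiplicity. Counting is in-memory, which
is ample at the scales this package targets; streams beyond RAM would need
on-disk partitioning that is deliberately not implemented. The genome-size
estimate is (total k-mers)/(major-peak depth). The default peak search
excludes the sequencing-error spike via a first-local-minimum cutoff
(smallest multiplicity whose count is below its successor); the literal
all-k-mer numerator is the default (`include_error_kmers = TRUE`) with the
cutoff-filtered numerator available, since error k-mers bias the literal
formula upward and both behaviours are worth having. For a diploid of
heterozygosity $h$, k-mers private to one haplotype form a second peak near
half the homozygous depth; with $1-(1-h)^k$ of positions affected the
half-depth peak can hold *more* distinct k-mers than the full-depth peak,
so two-peak histograms are flagged (`half_depth_bump`) rather than silently
resolved. The histogram exports in the two-column format heterozygosity
modellers consume; heterozygosity estimation itself is out of scope.

At 40× error-free coverage of a 100 kb genome with 100 bp reads the
expected peak depth is $40 \times 84/100 = 33.6$; the discrete mode lands
at 33–34, giving an estimate within ~2% of truth — the 3% recovery bound
used in the tests reflects this discretisation.

## Synteny chaining and 4DTv

Anchors (similarity gene pairs at e-value ≤ 1e−5) are chained per
chromosome pair by $O(n^2)$ dynamic programming over gene-order ranks:
longest strictly-monotone chain (increasing for `+`, decreasing for `-`
orientation) with at most `max_gap = 25` intervening ranks between
consecutive anchors on either genome. Gene-order ranks, not bp, are the
coordinate, matching collinearity-tool practice. Chains are taken greedily
by descending length, each anchor used once, and chains under 5 anchors are
discarded — the minimum block size the procedure states. Full
weighted-interval optimisation is unnecessary at these scales.

4DTv is computed on gap-free codon-aligned CDS pairs: a codon column
qualifies iff both codons are clean (no gap/N), their first two bases are
identical, and the shared dinucleotide prefix is one of the eight
fourfold-degenerate families (TC, CT, CC, CG, AC, GT, GC, GG); the
statistic is the fraction of qualifying third positions differing by a
transversion, uncorrected for multiple hits (no correction is part of the
procedure; saturation therefore caps the value at 0.5). Requiring the
prefixes to be identical in *both* sequences is the stricter of the two
readings of "fourfold degenerate site" and the one implemented. The codon
simulator evolves third positions under K80 with total transversion branch
parameter $\beta T$, giving the closed form
$E[\text{4DTv}] = \tfrac12(1 - e^{-4\beta T})$ used as the analytic oracle.
Distribution peaks are read from a 0.01-wide histogram smoothed by a 3-bin
moving average; peak location is the midpoint of the maximal smoothed bin,
secondary maxima are reported ranked, and a flatness diagnostic (maximum
below 1.5× the median smoothed bin) flags distributions without a
well-separated peak. Binning and smoothing are configurable since the
source procedure does not state them.

## Retention/loss ("absent region") procedure

Best-hit gene pairs are sorted along the target genome's chromosomes;
target genes without a reference partner are marked NA. For each NA gene
the nearest flanking *paired* genes are found (consecutive NA runs skip to
the nearest paired neighbours); if their reference partners share a
chromosome, the absent region is the interval between the two partner
spans — from the earlier partner's end to the later partner's start,
orientation-normalized. An NA gene first or last on its chromosome uses
its single partner and runs to base 1 or the chromosome end; partners on
different reference chromosomes leave the region undefined
(`flank_status` records which flanks existed).

The region is then searched with the query protein by six-frame translated
local alignment: each frame is translated, split at stop codons, and every
segment is locally aligned under BLOSUM62 with affine gaps (open 11,
extend 1). A best hit reaching 50% identity and 50% query coverage
(defaults; the source states no thresholds) calls the gene
`present_unannotated`; a completed search below thresholds calls it
`lost_in_reference`; undefined or all-N regions are `unresolved`. Hits
passing identity but failing coverage are flagged `partial` — the expected
signature of an intron or internal stop splitting the reading frame, which
this deliberately unspliced aligner does not model. The
`sim_gene_order_pair()` generator plants physical deletions (sequence
absent) and unannotated-but-present genes (sequence embedded, annotation
and best hit removed), which the classifier must separate exactly; with
100-codon genes and ~50% identity thresholds, random intergenic DNA
essentially never reaches the presence thresholds.

## Enrichment and motifs

Term over-representation is the one-sided hypergeometric upper tail
$P(X \ge k)$ for $k$ selected genes in a term of $K$ among $n$ selected
from a universe of $N$ (evaluated via the log-space CDF), with
Benjamini–Hochberg correction across tested terms and the rich factor
$k/K$ reported per term. The universe defaults to all annotated genes in
the supplied map. GO-graph propagation is out of scope: annotations are
taken as given.

Promoter motifs are IUPAC patterns counted on the forward strand and, by
default, the reverse complement; overlapping and non-overlapping counting
are both offered. The MYB-core screen keeps genes with *more than*
`min_count = 2` elements (strict inequality, per the "more than two"
phrasing; `>=` is available behind a flag). The motif itself is a required
configurable (default `CNGTT`, a common MYB-core consensus) because the
exact database entry used by the motivating analysis is not stated;
promoters default to the 2000 bp upstream of the gene start, strand-aware.

## Determinism, sizes and limits

Every simulator is byte-deterministic given (parameters, seed), and the
pipeline writes no timestamps, so `run_sweep_pipeline()` outputs are
byte-identical across re-runs of one configuration. The problem sizes used
throughout the tests and the acceptance script — 50k sites × 40 diploids
for estimator recovery, 10 replicate 4 Mb chromosomes for sweep recovery,
$10^5$ codon sites per divergence level, a 100 kb genome at 40×, 60 genes
with 25 planted absences — were chosen as the smallest scales at which the
analytic expectations are sharp (Monte-Carlo error well inside the asserted
tolerances). Known limitations: no linkage or demographic realism in the
SNP simulator; no multiple-hit correction in 4DTv (by design); no spliced
alignment in the loss classifier; in-memory k-mer counting only.
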
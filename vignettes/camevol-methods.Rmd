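---
title: "Methods: models, parameters and design choices in camevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in camevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camevol)
```

camevol packages the computational analyses used to characterise the genome
and diel transcriptome of succulent CAM plants: group-specific orthogroup
expansion testing, tandem and segmental duplication detection, NG86 Ka/Ks
dating, LTR insertion-age estimation, diel rhythmicity and CAM-gene
classification, and circadian cis-element enrichment. This vignette explains
the statistical models, the tunable parameters and why their defaults are
what they are, and the design decisions taken where the methodology left
genuine freedom.

## Orthogroup expansion and contraction

Given an orthogroup-by-species gene count matrix split into a focal group A
(typically 5 succulent species) and a background group B (typically 13
non-succulents), the genes of each orthogroup are modelled as `n = S5n +
O13n` independent draws landing in group A with probability `p = |A|/(|A| +
|B|)` (5/18 for the default design). `binomial_group_test()` computes exact
one-sided tails — `P(X >= S5n)` for expansion and `P(X <= S5n)` for
contraction — by the binomial CDF, never a normal approximation, because
per-orthogroup counts are small (often under 30).

Three criteria then define a call in `classify_orthogroups()`:

1. a BH-adjusted tail probability below `q_alpha` (default 0.05);
2. a minimal number of *contributing* species — species with at least one
   gene — in the relevant group (defaults 3 of 5 in A for expansion, 7 of 13
   in B for contraction). "Contribution" is read as presence (count > 0),
   which parallels the species-count phrasing of the criterion; the cutoffs
   are exposed because "about three" admits neighbouring choices;
3. a per-species contribution ratio `(S5n/|A|)/(O13n/|B|)` above 1 for
   expansion (a family entirely absent from group B passes as ratio
   infinity) or below 1 for contraction.

Two open points were settled as package design choices. First, BH adjustment
is applied separately within the expansion family and the contraction
family: the two one-sided tests are not independent, and separate families
are conservative and symmetric in the two directions. Second, orthogroups
with zero genes in both groups are dropped before adjustment — they are
untestable and would only inflate the family size.

The companion rule for two-species comparisons, `two_species_expansion()`,
calls an orthogroup expanded in a species when a supplied p-value is below
0.05 and the species' count strictly exceeds the mean across all species.

## Tandem arrays, collinear blocks and duplication classes

`find_tandem_arrays()` grows arrays by single linkage on one chromosome: a
gene joins an array when it is homologous to at least one current member and
within `max_intervening` non-member genes of the nearest member. The default
`max_intervening = 0` (strictly consecutive) matches the classical
MCScanX-style tandem definition; the parameter is exposed because published
analyses rarely print the gap they allowed. Single linkage ("a hit to any
member suffices") is the semantics under which an array is a connected run
of a family, and it is also what the brute-force oracle in the test suite
implements, so the two can be compared set-for-set.

`chain_collinear_blocks()` chains homology anchors by sparse dynamic
programming per chromosome pair. A chain must be strictly monotone in rank
on both sides (descending on one side for inversions), with every internal
gap strictly smaller than `max_gap` genes; its score is the sum of anchor
scores (bit scores) minus `gap_penalty` per intervening gene. Published
block criteria fix only the thresholds — blocks of more than 10 genes with
gaps under 5 for cross-species comparisons, at least 5 genes for genome
self-comparisons — not the scoring, so the penalty is linear with unit cost
by default and exposed in the configuration. Blocks are extracted greedily
(best chain first, anchors retired), ties broken toward smaller total gap
and then lexicographic gene id so output is deterministic. On instances
small enough to enumerate exhaustively (up to 12 anchors) the chain score is
verified against full subset search in the test suite.

`classify_duplications()` labels anchor pairs of a self-comparison as
tandem (both genes in the tandem set), segmental (intra-chromosomal,
non-tandem) or interchromosomal, and `count_fusions()` computes the minimal
fusion count of an ancestral-karyotype painting as the sum over modern
chromosomes of (distinct ancestral labels − 1): each extra label on a
chromosome requires at least one fusion. Painted blocks below
`min_block_genes` are ignored first, because small stray blocks otherwise
inflate the bound.

## NG86 Ka/Ks and Ks-peak dating

`ng86_ka_ks()` implements Nei–Gojobori counting on gap-free codon
alignments. Per codon, the synonymous site fraction at each position is the
number of the three possible single-base changes that preserve the amino
acid, divided by 3 (changes to stop codons are never synonymous); `S` and
`N` are averaged over the two sequences, so `S + N` is exactly the
nucleotide length. Codons differing at more than one position are resolved
by enumerating all minimal substitution pathways with equal weights — the
original NG86 choice — excluding pathways that cross a stop codon and
renormalising; if every pathway crosses a stop, all are used rather than
dropping the codon. Proportions are corrected with Jukes–Cantor,
`K = -(3/4) ln(1 - (4/3) p)`, and a proportion at or above 3/4 is flagged
saturated with the rate left undefined rather than clamped.

`ks_distribution()` summarises a paranome: a fixed-width histogram over
`(0, ks_max]` plus the modes of a Gaussian kernel density (Silverman's
rule-of-thumb bandwidth by default), because whole-genome-duplication peaks
are read off a smoothed density, not raw bins. The mass attributed to each
mode is the fraction of values nearest it.

## LTR insertion ages

A retroelement's two LTRs are identical at insertion, so the age is
`T = K / (2 mu)` with `K` the JC69-corrected divergence between the 5' and
3' copies. Gapped columns and ambiguous bases are excluded from both the
numerator and denominator of the mismatch proportion. The substitution rate
`mu` (substitutions/site/year) deliberately has **no default**: published
burst ages depend entirely on the clock assumed, and the functions refuse to
run without an explicit rate rather than silently assuming one.
`age_summary()` reports the histogram, the kernel-density mode (the "burst"
age) and 5/50/95% quantiles.

## Diel rhythmicity, clustering and CAM classification

Expression is log2(FPKM + 1)-transformed before regression and clustering
(the transform can be disabled). `fit_rhythmicity()` regresses each gene's
transformed values on `{t, t^2, t^3}` across all replicate points of the
nine-timepoint, 3-hour design (the duplicated start/end clock time is kept
as two design points, mirroring the sampling scheme) and tests the cubic
model against the intercept by an F-test; a plain F-test was chosen because
the published degree-3/BH setting does not pin down any additional
goodness-of-fit cutoff. BH adjustment across genes gives the rhythmic set.
Genes whose expression does not vary at all are degenerate with p = 1.
Before any of this, `prefilter_expressed()` keeps genes whose replicate-mean
FPKM strictly exceeds 1 at one or more timepoints.

`cluster_profiles()` z-scores mean profiles, uses 1 − Pearson correlation as
the distance and average-linkage hierarchical clustering cut at `k = 9`
clusters. Only 'hclust' and k are fixed by the published setting; the
correlation distance and average linkage are the package's choices (both
configurable) because diel profiles are compared by shape, not level.

`classify_cam()` applies the published two-threshold rule to a gene's
correlations with a C3 reference (e.g. *Arabidopsis*) and a CAM reference
(e.g. pineapple): *divergent* when the correlation with the C3 ortholog
profile is below 0.5, *strong CAM* when additionally the correlation with
the CAM reference exceeds 0.8, otherwise *conserved*. The conjunction "both
Pearson and Spearman" implements the requirement that the rule be satisfied
by both coefficients; a Pearson-only switch is provided. Correlations are
computed on replicate-mean profiles — whether the original analysis used
replicate-level or mean profiles is not stated, and means are the stabler
choice for nine timepoints.

## Motif scanning and enrichment

The five circadian cis-elements (morning element CCACAC, evening element
AAAATATCT, CCA1-binding site AAAAATCT, TCP15 element NGGNCCCAC, G-box
CACGTG) are short consensus strings, for which probabilistic motif scanning
at a stringent p-value reduces to (near-)exact matching; `scan_motif()`
therefore performs exact IUPAC consensus matching (Biostrings under the
hood), with an exposed per-position mismatch allowance defaulting to 0. The
default strand policy scans both strands and counts palindromes (CACGTG is
its own reverse complement) once per position. `motif_enrichment()` tests
presence/absence (at least one occurrence) in 2×2 tables by Fisher's exact
test with BH across motifs; presence rather than counts is robust to
promoter-length effects, and a count-based Poisson rate-ratio test is
available as an option.

## The synthetic-data generators

Every generator is a pure function of its parameters and a seed, and every
dataset ships with a planted-truth table sufficient to score sensitivity and
FDR downstream.

- `sim_count_matrix()` draws background counts Poisson(λ = 2) per species —
  the simplest null with a tunable effect; the published analyses give no
  count distribution — and multiplies the mean by `fold_effect` (default 4)
  in group A for a planted 5% of orthogroups. `fold_effect = 1` is the
  global null used for calibration.
- `sim_genome_layout()` builds two toy genomes (2 chromosomes × 100 genes)
  with planted tandem arrays of 2–4 genes and planted collinear blocks of
  12–15 anchors (inverted with probability 0.3), and emits exactly the
  homology hits implied by the planted structures plus an optional noise
  rate.
- `sim_codon_pairs()` applies exactly the requested numbers of synonymous
  and nonsynonymous single-base changes, each in a distinct codon so the
  planted difference counts are pathway-unambiguous, and never creates a
  stop codon.
- `sim_diel_profiles()` generates `FPKM = exp(b + a cos(2π(t − φ)/24) + ε)`
  with lognormal noise (additive on the log scale), respecting FPKM
  positivity; the default design is nine timepoints at 3-hour spacing with
  three replicates and peak phases on the sampling grid.
- `sim_promoters()` plants concrete motif instances into uniform-ACGT
  backgrounds at recorded, non-overlapping positions.
- `sim_ltr_pairs()` draws element ages from a normal burst (80 ± 10 kya by
  default) and mutates each LTR copy at the per-site probability implied by
  half the target divergence.

What these generators deliberately do **not** emulate: phylogenetic
correlation among species (counts are independent given the group means),
GC content and repeat structure of real promoters, transcription-level
autocorrelation between adjacent timepoints, and alignment error in codon
or LTR pairs. Passing the closed-loop tests therefore demonstrates that the
algorithms recover what they are defined to recover, not that real data are
this clean.

## Numerical choices and problem sizes

Exact binomial tails are verified against direct pmf summation to 1e-12 up
to n = 10^4. The DP chainer's tie-breaks (smaller total gap, then gene id)
make block output independent of input row order. Calibration checks run at
the sizes a single CPU handles in minutes: 20 null matrices of 5,000
orthogroups for the expansion type-I check, 2,000 null profiles and 500
planted-cosine profiles for the rhythmicity F-test, ten replicates of
200 + 200 promoters for enrichment power, 1,000 Ks values for mode
recovery, and 1,000 LTR elements of 2 kb for age recovery. These sizes give
standard errors comfortably inside the asserted bounds while keeping the
whole suite quick to run.

## Known limitations

- The expansion test treats species as exchangeable; a phylogenetically
  clustered background (e.g. several close relatives in group B) violates
  the binomial null and the calibration statement does not transfer.
- NG86 with equal pathway weights is the historical baseline; maximum
  likelihood codon models would weight pathways by rate and can differ
  noticeably at high divergence.
- The minimal fusion count is a lower bound, not an estimate; fissions and
  reciprocal translocations can hide fusions from it.
- Insertion ages inherit all the uncertainty of the clock `mu`; the package
  reports ages conditional on the supplied rate and refuses to choose one.
- Exact consensus matching has no notion of binding affinity; a motif one
  mismatch away from consensus is invisible at the default settings.
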
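#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list, so a
#' whole run can be reproduced from the config plus a seed. Values not supplied
#' fall back to the defaults used throughout the package. The returned object
#' prints as a plain list and is accepted by the command-line driver.
#'
#' @param q_alpha FDR threshold for expansion/contraction calls (in (0,1)).
#' @param min_contrib_A,min_contrib_B minimal number of contributing species
#'   (count > 0) required in the succulent and non-succulent group.
#' @param max_intervening maximum number of non-member genes allowed between
#'   consecutive members of a tandem array (>= 0).
#' @param min_block_genes minimal number of anchor genes per collinear block.
#' @param max_gap maximal rank gap allowed between consecutive anchors of a
#'   block; gaps must be strictly smaller than this value.
#' @param gap_penalty linear per-rank gap cost used by the block chainer.
#' @param mu LTR substitution rate (substitutions/site/year). No default:
#'   insertion ages are meaningless without an explicit clock, so `NA` here
#'   makes the LTR stage refuse to run until one is supplied.
#' @param min_align_len,max_evalue homology-hit filter thresholds (strict
#'   inequalities: length > `min_align_len`, e-value < `max_evalue`).
#' @param t_low,t_high correlation cutoffs of the CAM classification rule.
#' @param min_mean_fpkm expressed-gene prefilter: a gene is kept when its
#'   replicate-mean FPKM exceeds this value at one or more timepoints.
#' @param rhythm_alpha BH-adjusted significance level for rhythmicity.
#' @param degree polynomial degree of the rhythmicity regression.
#' @param k number of diel expression clusters.
#' @param motifs named character vector of IUPAC motif consensus patterns.
#' @param species_delim delimiter between species prefix and gene id in
#'   OrthoMCL-style groups files.
#' @param seed integer seed recorded in all outputs.
#'
#' @return A named list of class `cam_config`.
#' @export
#' @examples
#' cfg <- cam_config(seed = 1, mu = 1.3e-8)
#' cfg$q_alpha
cam_config <- function(q_alpha = 0.05,
                       min_contrib_A = 3,
                       min_contrib_B = 7,
                       max_intervening = 0,
                       min_block_genes = 5,
                       max_gap = 5,
                       gap_penalty = 1,
                       mu = NA_real_,
                       min_align_len = 100,
                       max_evalue = 1e-5,
                       t_low = 0.5,
                       t_high = 0.8,
                       min_mean_fpkm = 1,
                       rhythm_alpha = 0.05,
                       degree = 3,
                       k = 9,
                       motifs = circadian_motifs(),
                       species_delim = "|",
                       seed = 1L) {
  stopifnot(
    q_alpha > 0, q_alpha < 1,
    min_contrib_A >= 0, min_contrib_B >= 0,
    max_intervening >= 0,
    min_block_genes >= 2,
    max_gap >= 1,
    gap_penalty >= 0,
    is.na(mu) || mu > 0,
    min_align_len > 0, max_evalue > 0,
    t_low > -1, t_low < 1, t_high > -1, t_high < 1,
    min_mean_fpkm >= 0,
    rhythm_alpha > 0, rhythm_alpha < 1,
    degree >= 1,
    k >= 2,
    length(motifs) >= 1, !is.null(names(motifs)),
    nchar(species_delim) == 1
  )
  structure(
    list(
      q_alpha = q_alpha, min_contrib_A = min_contrib_A,
      min_contrib_B = min_contrib_B, max_intervening = max_intervening,
      min_block_genes = min_block_genes, max_gap = max_gap,
      gap_penalty = gap_penalty, mu = mu,
      min_align_len = min_align_len, max_evalue = max_evalue,
      t_low = t_low, t_high = t_high, min_mean_fpkm = min_mean_fpkm,
      rhythm_alpha = rhythm_alpha, degree = degree, k = k,
      motifs = motifs, species_delim = species_delim,
      seed = as.integer(seed)
    ),
    class = "cam_config"
  )
}

#' The five circadian clock cis-element consensus motifs
#'
#' Morning element (ME), evening element (EE), CCA1-binding site (CBS),
#' TCP15 element and the G-box, as IUPAC consensus strings.
#'
#' @return Named character vector of IUPAC patterns.
#' @export
#' @examples
#' circadian_motifs()[["G-box"]]
circadian_motifs <- function() {
  c(
    "ME"    = "CCACAC",
    "EE"    = "AAAATATCT",
    "CBS"   = "AAAAATCT",
    "TCP15" = "NGGNCCCAC",
    "G-box" = "CACGTG"
  )
}
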
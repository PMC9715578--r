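.IUPAC_OK <- "^[ACGTRYSWKMBDHVN]+$"

.check_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  if (!nzchar(pattern) || !grepl(.IUPAC_OK, pattern)) {
    abort(sprintf("illegal IUPAC pattern: '%s'", pattern))
  }
  pattern
}

.revcomp_iupac <- function(pattern) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Exact (or near-exact, with an optional per-position mismatch allowance)
#' matching of a degenerate IUPAC consensus against a promoter sequence. All
#' possibly overlapping match start positions are reported, 0-based. With
#' `strand = "both"` the reverse complement of the pattern is also scanned
#' (positions still reported on the forward strand); palindromic patterns
#' such as CACGTG are counted once per position.
#'
#' @param sequence A/C/G/T/N string (N in the sequence matches only a fully
#'   degenerate pattern position).
#' @param pattern IUPAC consensus (A,C,G,T plus degenerate codes).
#' @param strand `"both"` (default) or `"forward"`.
#' @param max_mismatch Per-match mismatch allowance, default 0.
#' @return Sorted integer vector of 0-based match start positions; its length
#'   is the occurrence count.
#' @export
#' @examples
#' scan_motif("CACGTGCACGTG", "CACGTG") # 0, 6
#' scan_motif("AGGACCCAC", "NGGNCCCAC") # 0
scan_motif <- function(sequence, pattern, strand = c("both", "forward"),
                       max_mismatch = 0) {
  strand <- match.arg(strand)
  pattern <- .check_iupac(pattern)
  sequence <- toupper(sequence)
  if (nchar(sequence) < nchar(pattern)) return(integer(0))
  subj <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::start(Biostrings::matchPattern(
    pattern, subj, max.mismatch = max_mismatch, fixed = "subject"
  )) - 1L
  if (strand == "forward") return(sort(fwd))
  rc <- .revcomp_iupac(pattern)
  if (rc == pattern) return(sort(fwd)) # palindrome: one count per position
  rev <- Biostrings::start(Biostrings::matchPattern(
    rc, subj, max.mismatch = max_mismatch, fixed = "subject"
  )) - 1L
  sort(c(fwd, rev))
}

#' Count motif occurrences across a promoter set
#'
#' @param promoters Named character vector of promoter sequences (gene id ->
#'   sequence, conventionally 2 kb upstream), e.g. from [parse_fasta()].
#' @param motifs Named character vector of IUPAC patterns, default the five
#'   circadian cis-elements of [circadian_motifs()].
#' @inheritParams scan_motif
#' @return Long tibble: `gene_id`, `motif`, `count`, `positions`
#'   (list-column of 0-based starts). Genes with zero occurrences are
#'   included.
#' @export
promoter_motif_table <- function(promoters, motifs = circadian_motifs(),
                                 strand = c("both", "forward"),
                                 max_mismatch = 0) {
  strand <- match.arg(strand)
  stopifnot(!is.null(names(motifs)))
  if (length(promoters) == 0) {
    return(tibble(gene_id = character(0), motif = character(0),
                  count = integer(0), positions = list()))
  }
  grid <- tidyr::expand_grid(gene_id = names(promoters), motif = names(motifs))
  grid$positions <- purrr::map2(grid$gene_id, grid$motif, function(g, m) {
    scan_motif(promoters[[g]], motifs[[m]], strand = strand,
               max_mismatch = max_mismatch)
  })
  grid$count <- lengths(grid$positions)
  grid[, c("gene_id", "motif", "count", "positions")]
}

#' Motif enrichment between two gene groups
#'
#' For each motif, genes are split into carriers (at least one occurrence)
#' and non-carriers within each group, and the resulting 2x2 table is tested
#' with Fisher's exact test; p-values are BH-adjusted across motifs. The
#' reported odds ratio is the sample odds ratio, oriented so values above 1
#' mean enrichment in group A. A count-based Poisson rate-ratio test on total
#' occurrences is available as an alternative.
#'
#' @param table Motif count tibble from [promoter_motif_table()].
#' @param groups Data frame with `gene_id` and `group` columns covering the
#'   table's genes; exactly two groups, each non-empty.
#' @param method `"fisher"` (presence/absence, default) or `"poisson"`
#'   (total counts).
#' @return Tibble per motif: carrier counts per group, `odds_ratio` (or rate
#'   ratio), `p`, `q`.
#' @export
motif_enrichment <- function(table, groups, method = c("fisher", "poisson")) {
  method <- match.arg(method)
  stopifnot(all(c("gene_id", "group") %in% names(groups)))
  lv <- sort(unique(groups$group))
  if (length(lv) != 2) abort("exactly two groups are required")
  df <- left_join(table, groups[, c("gene_id", "group")], by = "gene_id")
  if (any(is.na(df$group))) abort("group labels must cover all table genes")
  for (g in lv) {
    if (!any(df$group == g)) abort(sprintf("group '%s' has zero genes", g))
  }
  res <- df |>
    group_by(.data$motif) |>
    group_modify(function(d, key) {
      a <- sum(d$group == lv[1] & d$count > 0)
      b <- sum(d$group == lv[1] & d$count == 0)
      c_ <- sum(d$group == lv[2] & d$count > 0)
      d_ <- sum(d$group == lv[2] & d$count == 0)
      if (method == "fisher") {
        p <- fisher.test(matrix(c(a, b, c_, d_), nrow = 2, byrow = TRUE))$p.value
        est <- (a * d_) / (b * c_)
      } else {
        n1 <- sum(d$count[d$group == lv[1]])
        n2 <- sum(d$count[d$group == lv[2]])
        t1 <- sum(d$group == lv[1])
        t2 <- sum(d$group == lv[2])
        pt <- poisson.test(c(n1, n2), c(t1, t2))
        p <- pt$p.value
        est <- unname(pt$estimate)
      }
      tibble(
        group_a = lv[1], group_b = lv[2],
        with_a = a, without_a = b, with_c = c_, without_c = d_,
        odds_ratio = est, p = p
      )
    }) |>
    ungroup()
  res$q <- bh_adjust(res$p)
  res
}
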
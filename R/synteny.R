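#' Chain homology anchors into collinear blocks
#'
#' Sparse dynamic programming over gene-rank pairs, per chromosome pair.
#' A chain is a set of anchors whose ranks are strictly increasing on side A
#' and strictly monotone on side B (increasing for same-orientation blocks,
#' decreasing for inversions), with every internal gap — intervening genes on
#' either side between consecutive anchors — strictly smaller than `max_gap`.
#' Chain score is the sum of anchor scores minus `gap_penalty` per intervening
#' gene. Blocks are extracted greedily: the best-scoring chain is reported,
#' its anchors retired, and the search repeated, so each anchor belongs to at
#' most one block. Chains with fewer than `min_block_genes` anchors are
#' discarded. Ties are broken toward the chain with smaller total gap, then
#' by gene id, so results are deterministic.
#'
#' @param anchors Tibble with columns `gene_a`, `chrom_a`, `rank_a`,
#'   `gene_b`, `chrom_b`, `rank_b`, `score` (e.g. homology bit scores).
#' @param min_block_genes Minimal anchors per reported block (cross-species
#'   comparisons conventionally use blocks of more than 10 genes; genome
#'   self-comparisons at least 5).
#' @param max_gap Internal gaps must be strictly below this many genes,
#'   default 5.
#' @param gap_penalty Score cost per intervening gene, default 1.
#' @return Long tibble, one row per anchor in a block: `block_id`, `chrom_a`,
#'   `chrom_b`, `orientation` (`"same"`/`"inverted"`), `gene_a`, `rank_a`,
#'   `gene_b`, `rank_b`, `score`, `n_genes`, `block_score`.
#' @export
chain_collinear_blocks <- function(anchors, min_block_genes = 5, max_gap = 5,
                                   gap_penalty = 1) {
  stopifnot(all(c("gene_a", "chrom_a", "rank_a", "gene_b", "chrom_b",
                  "rank_b", "score") %in% names(anchors)))
  empty <- tibble(
    block_id = character(0), chrom_a = character(0), chrom_b = character(0),
    orientation = character(0), gene_a = character(0), rank_a = integer(0),
    gene_b = character(0), rank_b = integer(0), score = numeric(0),
    n_genes = integer(0), block_score = numeric(0)
  )
  if (nrow(anchors) == 0) return(empty)
  out <- list()
  block_n <- 0L
  for (key in unique(paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))) {
    sub <- anchors[paste(anchors$chrom_a, anchors$chrom_b, sep = "\r") == key, ,
                   drop = FALSE]
    repeat {
      best <- .best_chain(sub, max_gap, gap_penalty)
      if (is.null(best) || length(best$idx) < min_block_genes) break
      block_n <- block_n + 1L
      chain <- sub[best$idx, , drop = FALSE]
      out[[block_n]] <- tibble(
        block_id = sprintf("block%d", block_n),
        chrom_a = chain$chrom_a, chrom_b = chain$chrom_b,
        orientation = best$orientation,
        gene_a = chain$gene_a, rank_a = chain$rank_a,
        gene_b = chain$gene_b, rank_b = chain$rank_b,
        score = chain$score,
        n_genes = length(best$idx),
        block_score = best$score
      )
      sub <- sub[-best$idx, , drop = FALSE]
      if (nrow(sub) == 0) break
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

# Best-scoring chain over one chromosome pair, both orientations.
# Returns list(idx = row indices into `sub`, score, orientation) or NULL.
.best_chain <- function(sub, max_gap, gap_penalty) {
  if (nrow(sub) == 0) return(NULL)
  cand <- list(
    same = .dp_chain(sub, sub$rank_b, max_gap, gap_penalty),
    inverted = .dp_chain(sub, -sub$rank_b, max_gap, gap_penalty)
  )
  pick <- NULL
  for (orient in c("same", "inverted")) {
    ch <- cand[[orient]]
    if (is.null(ch)) next
    better <- is.null(pick) ||
      ch$score > pick$score + 1e-9 ||
      (abs(ch$score - pick$score) <= 1e-9 && ch$gap < pick$gap)
    if (better) {
      pick <- ch
      pick$orientation <- orient
    }
  }
  pick
}

# O(n^2) DP: strictly increasing rank_a and rb, per-step intervening genes on
# both sides < max_gap, linear penalty. Ties toward smaller cumulative gap,
# then lexicographically smaller gene_a id.
.dp_chain <- function(sub, rb, max_gap, gap_penalty) {
  ord <- order(sub$rank_a, rb, sub$gene_a)
  ra <- sub$rank_a[ord]
  rb <- rb[ord]
  sc <- sub$score[ord]
  ids <- sub$gene_a[ord]
  n <- length(ra)
  dp <- sc
  gap_tot <- numeric(n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (ra[j] >= ra[i] || rb[j] >= rb[i]) next
      ga <- ra[i] - ra[j] - 1
      gb <- abs(rb[i] - rb[j]) - 1
      if (ga >= max_gap || gb >= max_gap) next
      cand <- dp[j] + sc[i] - gap_penalty * (ga + gb)
      cand_gap <- gap_tot[j] + ga + gb
      better <- cand > dp[i] + 1e-9 ||
        (abs(cand - dp[i]) <= 1e-9 &&
           (cand_gap < gap_tot[i] ||
              (cand_gap == gap_tot[i] && !is.na(prev[i]) && ids[j] < ids[prev[i]])))
      if (better) {
        dp[i] <- cand
        gap_tot[i] <- cand_gap
        prev[i] <- j
      }
    }
  }
  end <- which.max(dp)
  # backtrack
  idx <- integer(0)
  i <- end
  while (!is.na(i)) {
    idx <- c(i, idx)
    i <- prev[i]
  }
  list(idx = ord[idx], score = dp[end], gap = gap_tot[end])
}

#' Classify duplicate gene pairs from a genome self-comparison
#'
#' Labels each anchor pair of a self-comparison block set as `tandem` (both
#' genes in the supplied tandem-duplicate gene set, same chromosome),
#' `segmental` (intra-chromosomal, not tandem) or `interchromosomal`.
#' Trivial self-diagonal anchors (a gene matched to itself) are dropped.
#'
#' @param blocks Block tibble from [chain_collinear_blocks()] run on a
#'   self-comparison.
#' @param tandem_genes Character vector of tandem-duplicate gene ids (e.g.
#'   members of [find_tandem_arrays()] output).
#' @return The anchor rows with a `class` column.
#' @export
classify_duplications <- function(blocks, tandem_genes = character(0)) {
  df <- blocks[blocks$gene_a != blocks$gene_b, , drop = FALSE]
  df |>
    mutate(class = dplyr::case_when(
      .data$chrom_a == .data$chrom_b &
        .data$gene_a %in% tandem_genes &
        .data$gene_b %in% tandem_genes ~ "tandem",
      .data$chrom_a == .data$chrom_b ~ "segmental",
      .default = "interchromosomal"
    ))
}

#' Minimal chromosome-fusion count from an ancestral-karyotype painting
#'
#' Given modern chromosomes painted by ancestral linkage-group origin, the
#' minimal number of fusions is the sum over modern chromosomes of (number of
#' distinct ancestral labels present minus one). Painted blocks with fewer
#' than `min_block_genes` genes are ignored; a chromosome left with no
#' surviving blocks contributes zero with a warning.
#'
#' @param painting Tibble with columns `chrom` (modern chromosome),
#'   `ancestral` (linkage-group label) and `n_genes` (block size).
#' @param min_block_genes Minimal block size to count, default 5.
#' @return Integer lower bound on the number of fusions.
#' @export
#' @examples
#' p <- tibble::tibble(chrom = c("c1", "c1"), ancestral = c("A", "B"), n_genes = 10)
#' count_fusions(p) # one fusion joined A and B
count_fusions <- function(painting, min_block_genes = 5) {
  stopifnot(all(c("chrom", "ancestral", "n_genes") %in% names(painting)))
  keep <- painting[painting$n_genes >= min_block_genes, , drop = FALSE]
  empty <- setdiff(unique(painting$chrom), unique(keep$chrom))
  if (length(empty) > 0) {
    warn(sprintf("%d chromosome(s) have no surviving painted blocks", length(empty)))
  }
  if (nrow(keep) == 0) return(0L)
  per_chrom <- keep |>
    distinct(.data$chrom, .data$ancestral) |>
    count(.data$chrom)
  sum(pmax(per_chrom$n - 1L, 0L))
}

#' Build anchor pairs for block chaining from hits and annotations
#'
#' Joins a homology hit table to two gene annotations, attaching chromosome
#' and rank to each side. Hits naming genes absent from either annotation are
#' dropped. Bit scores become anchor scores.
#'
#' @param hits Hit tibble (see [parse_hit_table()]).
#' @param ann_a,ann_b Annotation tibbles for the query and subject genome
#'   (see [parse_gff3()]). For a self-comparison pass the same annotation
#'   twice; self-pairs (a gene hit against itself) are dropped.
#' @return Anchor tibble for [chain_collinear_blocks()].
#' @export
anchors_from_hits <- function(hits, ann_a, ann_b) {
  self <- identical(ann_a, ann_b)
  df <- tibble(
    gene_a = hits$query_id, gene_b = hits$subject_id,
    score = if ("bitscore" %in% names(hits)) hits$bitscore else 1
  )
  if (self) df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  df |>
    inner_join(
      ann_a |> select(gene_a = "gene_id", chrom_a = "chrom", rank_a = "rank"),
      by = "gene_a"
    ) |>
    inner_join(
      ann_b |> select(gene_b = "gene_id", chrom_b = "chrom", rank_b = "rank"),
      by = "gene_b"
    )
}
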
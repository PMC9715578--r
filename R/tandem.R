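#' Detect tandem-duplicate arrays from gene order and homology
#'
#' An array is a maximal set of mutually linked genes on one chromosome,
#' grown by single linkage: a gene joins an array when it is homologous to at
#' least one current member and lies within `max_intervening` non-member
#' genes of the nearest member (so `max_intervening = 0` means strictly
#' consecutive ranks, the classic MCScanX-style tandem definition). Homology
#' is symmetrised and self-hits are ignored; a homology pair naming a gene
#' absent from the annotation is skipped with a warning.
#'
#' @param annotation Gene annotation tibble with `gene_id`, `chrom`, `rank`
#'   (see [parse_gff3()]).
#' @param hits Either a hit tibble (see [parse_hit_table()]) or a two-column
#'   data frame of gene id pairs.
#' @param max_intervening Maximum number of intervening non-member genes
#'   between a joining gene and its nearest array member, default 0.
#' @return Long tibble with one row per array member: `array_id`, `chrom`,
#'   `gene_id`, `rank`, `n_members`; arrays numbered in chromosomal order.
#' @export
#' @examples
#' ann <- tibble::tibble(
#'   gene_id = c("g1", "g2", "g3"), chrom = "chr1",
#'   start = c(0, 100, 200), end = c(50, 150, 250),
#'   strand = "+", rank = 0:2
#' )
#' pairs <- tibble::tibble(query_id = c("g1", "g2"), subject_id = c("g2", "g3"))
#' find_tandem_arrays(ann, pairs)
find_tandem_arrays <- function(annotation, hits, max_intervening = 0) {
  stopifnot(max_intervening >= 0)
  pairs <- tibble(a = hits[[1]], b = hits[[2]])
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  known <- pairs$a %in% annotation$gene_id & pairs$b %in% annotation$gene_id
  if (any(!known)) {
    warn(sprintf("%d homology pair(s) name genes absent from the annotation; skipped",
                 sum(!known)))
    pairs <- pairs[known, , drop = FALSE]
  }
  rank_of <- setNames(annotation$rank, annotation$gene_id)
  chrom_of <- setNames(annotation$chrom, annotation$gene_id)
  # keep intra-chromosomal pairs only
  pairs <- pairs[chrom_of[pairs$a] == chrom_of[pairs$b], , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(tibble(array_id = character(0), chrom = character(0),
                  gene_id = character(0), rank = integer(0),
                  n_members = integer(0)))
  }
  # symmetric homology lookup
  homolog <- split(c(pairs$b, pairs$a), c(pairs$a, pairs$b))
  homolog <- purrr::map(homolog, unique)
  max_span <- max_intervening + 1

  out <- list()
  for (chr in unique(chrom_of[pairs$a])) {
    genes <- names(homolog)[chrom_of[names(homolog)] == chr]
    arrays <- .grow_arrays(genes, homolog, rank_of, max_span)
    for (arr in arrays) {
      out[[length(out) + 1]] <- tibble(
        chrom = chr,
        gene_id = arr[order(rank_of[arr])],
        rank = sort(unname(rank_of[arr]))
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(array_id = character(0), chrom = character(0),
                  gene_id = character(0), rank = integer(0),
                  n_members = integer(0)))
  }
  arr_tbl <- bind_rows(out, .id = "arr")
  ord <- arr_tbl |>
    group_by(.data$arr) |>
    summarise(chrom = first(.data$chrom), rank_min = min(.data$rank)) |>
    arrange(.data$chrom, .data$rank_min) |>
    mutate(array_id = sprintf("%s_arr%d", .data$chrom,
                              ave(rep(1, n()), .data$chrom, FUN = cumsum)))
  arr_tbl |>
    left_join(ord[, c("arr", "array_id")], by = "arr") |>
    group_by(.data$array_id) |>
    mutate(n_members = n()) |>
    ungroup() |>
    arrange(.data$chrom, .data$rank) |>
    select("array_id", "chrom", "gene_id", "rank", "n_members")
}

# Fixpoint single-linkage growth on one chromosome. Starts from homologous
# seed pairs within the rank window; a gene is absorbed when homologous to
# any member and within max_span ranks of the nearest member; arrays sharing
# a gene are merged. Returns a list of character vectors (>= 2 members).
.grow_arrays <- function(genes, homolog, rank_of, max_span) {
  arrays <- list()
  for (g in genes) {
    for (h in homolog[[g]]) {
      if (h > g && abs(rank_of[g] - rank_of[h]) <= max_span) {
        arrays[[length(arrays) + 1]] <- c(g, h)
      }
    }
  }
  if (length(arrays) == 0) return(list())
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    # merge arrays sharing members
    i <- 1
    while (i < length(arrays)) {
      j <- i + 1
      while (j <= length(arrays)) {
        if (length(intersect(arrays[[i]], arrays[[j]])) > 0) {
          arrays[[i]] <- union(arrays[[i]], arrays[[j]])
          arrays[[j]] <- NULL
          changed <- TRUE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
    # absorb outside genes
    for (g in genes) {
      for (k in seq_along(arrays)) {
        if (g %in% arrays[[k]]) next
        near <- min(abs(rank_of[g] - rank_of[arrays[[k]]]))
        if (near <= max_span && length(intersect(homolog[[g]], arrays[[k]])) > 0) {
          arrays[[k]] <- c(arrays[[k]], g)
          changed <- TRUE
        }
      }
    }
  }
  arrays[lengths(arrays) >= 2]
}

#' Classify tandem-duplicate genes as shared or species-specific
#'
#' A TD gene is "shared" when its orthogroup contains TD genes in both
#' species under comparison, otherwise it is specific to its species. TD
#' genes with no orthogroup assignment are classed species-specific with a
#' warning.
#'
#' @param td_genes Tibble with `species` and `gene_id` columns listing the
#'   tandem-duplicate genes of each species.
#' @param orthogroup_map Tibble with `gene_id` and `orthogroup` columns.
#' @return The input with `orthogroup` and a `status` column in
#'   `{"shared", "species_specific"}`.
#' @export
classify_td_lineage <- function(td_genes, orthogroup_map) {
  stopifnot(all(c("species", "gene_id") %in% names(td_genes)),
            all(c("gene_id", "orthogroup") %in% names(orthogroup_map)))
  df <- td_genes |>
    left_join(orthogroup_map[, c("gene_id", "orthogroup")], by = "gene_id")
  if (any(is.na(df$orthogroup))) {
    warn(sprintf("%d TD gene(s) without an orthogroup; classed species-specific",
                 sum(is.na(df$orthogroup))))
  }
  shared_og <- df |>
    filter(!is.na(.data$orthogroup)) |>
    distinct(.data$orthogroup, .data$species) |>
    count(.data$orthogroup) |>
    filter(.data$n >= 2) |>
    pull(.data$orthogroup)
  df |>
    mutate(status = ifelse(!is.na(.data$orthogroup) & .data$orthogroup %in% shared_og,
                           "shared", "species_specific"))
}

#' Welch two-sample t-test on per-species category percentages
#'
#' Compares the percentage of lineage-specific tandem-duplicate genes falling
#' in a functional category between two species groups (e.g. succulent vs
#' non-succulent), with Welch's unequal-variance t-test.
#'
#' @param bias_table Tibble with `species`, `category` and `percentage`
#'   columns (percentages in `[0, 100]`).
#' @param category Category to test.
#' @param group_a,group_b Species id vectors (>= 2 each).
#' @return One-row tibble: `category`, `t`, `df`, `p`, group means, and a
#'   `degenerate` flag (TRUE when both groups have zero variance, in which
#'   case `t` and `p` are `NA`).
#' @export
td_bias_test <- function(bias_table, category, group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  sub <- bias_table[bias_table$category == category, , drop = FALSE]
  xa <- sub$percentage[sub$species %in% group_a]
  xb <- sub$percentage[sub$species %in% group_b]
  if (length(xa) < 2 || length(xb) < 2) {
    abort("each group needs at least 2 species with values for this category")
  }
  degenerate <- sd(xa) == 0 && sd(xb) == 0
  if (degenerate) {
    return(tibble(category = category, t = NA_real_, df = NA_real_,
                  p = NA_real_, mean_a = mean(xa), mean_b = mean(xb),
                  degenerate = TRUE))
  }
  tt <- t.test(xa, xb, var.equal = FALSE)
  tibble(
    category = category,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_a = mean(xa), mean_b = mean(xb),
    degenerate = FALSE
  )
}
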
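#' Exact binomial test for group-specific orthogroup size shifts
#'
#' For each orthogroup, the genes observed across the two species groups are
#' treated as `n` Bernoulli draws landing in group A with probability
#' `p_success = |A| / (|A| + |B|)` under the null of proportional family
#' sizes (for 5 succulents among 18 species, `P(W) = 5/18`). One-sided exact
#' tail probabilities are computed — no normal approximation:
#' `p_expand = P(X >= S5n)` and `p_contract = P(X <= S5n)` with
#' `X ~ Binomial(n, p_success)`, where `S5n` is the group-A gene total.
#' Orthogroups with no genes in either group are untestable and dropped.
#'
#' @param counts Count tibble (see [read_count_matrix()]).
#' @param group_a,group_b Character vectors of species ids forming the focal
#'   (e.g. succulent, "S5") and background (e.g. "O13") groups. Must be
#'   disjoint, non-empty and present in the matrix.
#' @return Tibble with one row per testable orthogroup: gene totals (`S5n`,
#'   `O13n`, `n`), contributing species counts (`k_contrib_A`, `k_contrib_B`),
#'   the per-species contribution `ratio` `(S5n/|A|)/(O13n/|B|)` (`Inf` when
#'   `O13n` is 0), and one-sided p-values `p_expand`, `p_contract`.
#' @export
#' @examples
#' m <- tibble::tibble(orthogroup = "OG1", a = 4L, b = 0L, c = 0L)
#' binomial_group_test(m, "a", c("b", "c"))
binomial_group_test <- function(counts, group_a, group_b) {
  .validate_count_matrix(counts)
  species <- setdiff(names(counts), "orthogroup")
  missing <- setdiff(c(group_a, group_b), species)
  if (length(missing) > 0) {
    abort(sprintf("species not in matrix: %s", paste(missing, collapse = ", ")))
  }
  if (length(intersect(group_a, group_b)) > 0) abort("groups must be disjoint")
  if (length(group_a) == 0 || length(group_b) == 0) abort("groups must be non-empty")

  A <- as.matrix(counts[, group_a, drop = FALSE])
  B <- as.matrix(counts[, group_b, drop = FALSE])
  S5n <- rowSums(A)
  O13n <- rowSums(B)
  n <- S5n + O13n
  p_success <- length(group_a) / (length(group_a) + length(group_b))

  stats <- tibble(
    orthogroup = counts$orthogroup,
    S5n = S5n, O13n = O13n, n = n,
    k_contrib_A = rowSums(A > 0),
    k_contrib_B = rowSums(B > 0),
    ratio = ifelse(O13n == 0,
      ifelse(S5n > 0, Inf, NaN),
      (S5n / length(group_a)) / (O13n / length(group_b))
    ),
    p_expand = pbinom(S5n - 1, n, p_success, lower.tail = FALSE),
    p_contract = pbinom(S5n, n, p_success)
  )
  stats[stats$n > 0, , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`. `NaN`/`NA` is a
#'   hard error: an undefined p-value must be resolved upstream, not
#'   silently absorbed into the family.
#' @return Adjusted values, in the input order, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues))) abort("NA/NaN p-values are not allowed")
  if (any(pvalues < 0 | pvalues > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call expanded and contracted orthogroups from group-test statistics
#'
#' Applies the three published criteria. Expanded: (i) BH-adjusted expansion
#' p-value below `q_alpha`; (ii) at least `min_contrib_A` group-A species
#' contributing (count > 0); (iii) per-species contribution ratio
#' `(S5n/|A|)/(O13n/|B|)` above 1 (a family absent from group B counts as
#' ratio infinity). Contracted symmetrically: adjusted contraction p-value
#' below `q_alpha`, at least `min_contrib_B` group-B contributors, ratio
#' below 1. BH adjustment is applied separately within the expansion and the
#' contraction p-value family.
#'
#' @param stats Tibble from [binomial_group_test()]. If `q_expand`/
#'   `q_contract` columns are absent they are computed here with
#'   [bh_adjust()].
#' @param q_alpha FDR threshold, default 0.05.
#' @param min_contrib_A,min_contrib_B Minimal contributing-species counts,
#'   defaults 3 and 7.
#' @return An object of class `cam_expansion`: the stats tibble with
#'   `q_expand`, `q_contract` and a `call` column in
#'   `{"expanded", "contracted", "none"}`, plus the thresholds as attributes.
#' @export
classify_orthogroups <- function(stats, q_alpha = 0.05,
                                 min_contrib_A = 3, min_contrib_B = 7) {
  stopifnot(is.data.frame(stats))
  if (!all(c("q_expand", "q_contract") %in% names(stats))) {
    stats$q_expand <- bh_adjust(stats$p_expand)
    stats$q_contract <- bh_adjust(stats$p_contract)
  }
  ratio_gt1 <- is.infinite(stats$ratio) | (!is.nan(stats$ratio) & stats$ratio > 1)
  ratio_lt1 <- !is.nan(stats$ratio) & is.finite(stats$ratio) & stats$ratio < 1
  expanded <- stats$q_expand < q_alpha &
    stats$k_contrib_A >= min_contrib_A & ratio_gt1
  contracted <- stats$q_contract < q_alpha &
    stats$k_contrib_B >= min_contrib_B & ratio_lt1
  out <- stats
  out$call <- dplyr::case_when(
    expanded ~ "expanded",
    contracted ~ "contracted",
    .default = "none"
  )
  structure(
    out,
    class = c("cam_expansion", class(out)),
    q_alpha = q_alpha,
    min_contrib_A = min_contrib_A,
    min_contrib_B = min_contrib_B
  )
}

#' One-stop expansion/contraction analysis of a count matrix
#'
#' Runs [binomial_group_test()], BH-adjusts each direction's p-value family
#' with [bh_adjust()], and calls orthogroups with [classify_orthogroups()].
#'
#' @inheritParams binomial_group_test
#' @inheritParams classify_orthogroups
#' @return A `cam_expansion` object (see [classify_orthogroups()]).
#' @export
#' @examples
#' sim <- sim_count_matrix(n_orthogroups = 200, seed = 1)
#' res <- test_expansion(sim$counts, sim$group_a, sim$group_b)
#' glance(res)
test_expansion <- function(counts, group_a, group_b, q_alpha = 0.05,
                           min_contrib_A = 3, min_contrib_B = 7) {
  stats <- binomial_group_test(counts, group_a, group_b)
  classify_orthogroups(stats,
    q_alpha = q_alpha,
    min_contrib_A = min_contrib_A, min_contrib_B = min_contrib_B
  )
}

#' @exportS3Method generics::tidy
tidy.cam_expansion <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.cam_expansion <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_expanded = sum(x$call == "expanded"),
    n_contracted = sum(x$call == "contracted"),
    genes_expanded = sum(x$n[x$call == "expanded"]),
    genes_contracted = sum(x$n[x$call == "contracted"]),
    q_alpha = attr(x, "q_alpha")
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.cam_expansion <- function(object, ...) {
  df <- as_tibble(unclass(object))
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = log2(pmax(.data$ratio, 2^-8)),
      y = -log10(pmax(.data$q_expand, 1e-300)),
      colour = .data$call
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = "log2 contribution ratio (group A / group B)",
      y = "-log10 q (expansion)",
      colour = "call"
    ) +
    ggplot2::theme_minimal()
}

#' Two-species expansion calls from companion p-values
#'
#' The simpler per-species rule used for pairwise comparisons: an orthogroup
#' is expanded in a species when its companion p-value is below `alpha` and
#' the species' gene count strictly exceeds the mean count across all species
#' in the matrix.
#'
#' @param counts Count tibble (any number of species >= 2).
#' @param pvalues Either a numeric vector aligned with `counts` rows or a
#'   data frame with `orthogroup` and `p` columns. Missing p-values are a
#'   hard error.
#' @param alpha Significance threshold, default 0.05.
#' @return Long tibble: `orthogroup`, `species`, `count`, `mean_count`, `p`,
#'   `expanded`.
#' @export
two_species_expansion <- function(counts, pvalues, alpha = 0.05) {
  .validate_count_matrix(counts)
  if (is.data.frame(pvalues)) {
    idx <- match(counts$orthogroup, pvalues$orthogroup)
    p <- pvalues$p[idx]
  } else {
    p <- as.numeric(pvalues)
    if (length(p) != nrow(counts)) abort("pvalues length must match matrix rows")
  }
  if (any(is.na(p))) abort("missing p-value for one or more orthogroups")
  species <- setdiff(names(counts), "orthogroup")
  mean_count <- rowMeans(as.matrix(counts[, species]))
  counts |>
    mutate(mean_count = mean_count, p = p) |>
    tidyr::pivot_longer(
      all_of(species),
      names_to = "species", values_to = "count"
    ) |>
    mutate(expanded = .data$p < alpha & .data$count > .data$mean_count) |>
    select("orthogroup", "species", "count", "mean_count", "p", "expanded")
}
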
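#' Read / write a diel expression matrix
#'
#' On disk the matrix is a TSV with a `gene_id` column and one column per
#' sample named `t<hours>_r<replicate>` (e.g. `t0_r1` ... `t24_r3`, hours
#' since the first sampling time). In memory the package uses the long tidy
#' form.
#'
#' @param path Path to the TSV file.
#' @return Long tibble: `gene_id`, `timepoint` (hours), `replicate`, `fpkm`.
#' @export
read_expression <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  long <- tidyr::pivot_longer(wide, -"gene_id",
                              names_to = "sample", values_to = "fpkm")
  m <- stringr::str_match(long$sample, "^t([0-9.]+)_r([0-9]+)$")
  if (any(is.na(m[, 1]))) abort("sample columns must be named t<hours>_r<rep>")
  long$timepoint <- as.numeric(m[, 2])
  long$replicate <- as.integer(m[, 3])
  if (any(long$fpkm < 0)) abort("FPKM values must be non-negative")
  reps <- long |> distinct(.data$timepoint, .data$replicate) |> count(.data$timepoint)
  if (length(unique(reps$n)) != 1) {
    abort("every timepoint must have the same replicate count")
  }
  long |> select("gene_id", "timepoint", "replicate", "fpkm")
}

#' @rdname read_expression
#' @param expr Long expression tibble.
#' @return For the writer: `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  wide <- expr |>
    mutate(sample = sprintf("t%g_r%d", .data$timepoint, .data$replicate)) |>
    select("gene_id", "sample", "fpkm") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "fpkm")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Prefilter to expressed genes
#'
#' Keeps a gene when its replicate-mean FPKM strictly exceeds
#' `min_mean_fpkm` at one or more timepoints.
#'
#' @param expr Long expression tibble (see [read_expression()]).
#' @param min_mean_fpkm Threshold, default 1 (exclusive).
#' @return Character vector of surviving gene ids.
#' @export
prefilter_expressed <- function(expr, min_mean_fpkm = 1) {
  expr |>
    group_by(.data$gene_id, .data$timepoint) |>
    summarise(m = mean(.data$fpkm), .groups = "drop_last") |>
    summarise(keep = max(.data$m) > min_mean_fpkm) |>
    filter(.data$keep) |>
    pull(.data$gene_id)
}

#' Polynomial-regression rhythmicity test across a diel time course
#'
#' For each gene, ordinary least squares of `log2(FPKM + 1)` on
#' `{t, t^2, t^3}` (degree configurable) using every replicate point, and an
#' F-test of the polynomial model against the intercept-only model. Genes
#' whose expression does not vary at all are flagged degenerate with p = 1.
#' Multiple-testing adjustment across genes is the caller's job (see
#' [bh_adjust()] or the [detect_rhythmicity()] wrapper).
#'
#' @param expr Long expression tibble.
#' @param degree Polynomial degree, default 3.
#' @param log_transform Transform FPKM to `log2(FPKM + 1)` first, default TRUE.
#' @return Tibble: `gene_id`, coefficient columns `beta0` ... `beta<degree>`,
#'   `F`, `p`, `degenerate`.
#' @export
fit_rhythmicity <- function(expr, degree = 3, log_transform = TRUE) {
  wide <- expr |>
    arrange(.data$timepoint, .data$replicate) |>
    mutate(sample = sprintf("t%g_r%d", .data$timepoint, .data$replicate)) |>
    select("gene_id", "sample", "fpkm") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "fpkm")
  genes <- wide$gene_id
  Y <- t(as.matrix(wide[, -1]))
  samples <- expr |>
    distinct(.data$timepoint, .data$replicate) |>
    arrange(.data$timepoint, .data$replicate)
  t_obs <- samples$timepoint
  if (log_transform) Y <- log2(Y + 1)
  n <- nrow(Y)
  if (n < degree + 2) abort("too few samples for the requested degree")
  X <- cbind(1, stats::poly(t_obs, degree = degree, raw = TRUE))
  fit <- stats::lm.fit(X, Y)
  rss1 <- colSums(as.matrix(fit$residuals)^2)
  rss0 <- colSums(scale(Y, center = TRUE, scale = FALSE)^2)
  df1 <- degree
  df2 <- n - degree - 1
  degen <- rss0 <= .Machine$double.eps * n
  Fstat <- ifelse(degen, NA_real_,
                  ((rss0 - rss1) / df1) / pmax(rss1 / df2, .Machine$double.eps))
  p <- ifelse(degen, 1, pf(Fstat, df1, df2, lower.tail = FALSE))
  betas <- t(as.matrix(fit$coefficients))
  colnames(betas) <- paste0("beta", 0:degree)
  bind_cols(
    tibble(gene_id = genes),
    as_tibble(betas),
    tibble(F = Fstat, p = p, degenerate = degen)
  )
}

#' Rhythmicity detection with BH-FDR control
#'
#' Runs [fit_rhythmicity()] and adds BH-adjusted q-values and a `rhythmic`
#' flag (`q < alpha`).
#'
#' @inheritParams fit_rhythmicity
#' @param alpha FDR level, default 0.05.
#' @return The [fit_rhythmicity()] tibble plus `q` and `rhythmic`.
#' @export
detect_rhythmicity <- function(expr, degree = 3, alpha = 0.05,
                               log_transform = TRUE) {
  res <- fit_rhythmicity(expr, degree = degree, log_transform = log_transform)
  res$q <- bh_adjust(res$p)
  res$rhythmic <- res$q < alpha
  res
}

#' Replicate-mean diel profiles
#'
#' @param expr Long expression tibble.
#' @param log_transform Average `log2(FPKM + 1)` rather than raw FPKM,
#'   default TRUE (matching the transform used for regression/clustering).
#' @return Wide tibble: `gene_id` plus one `t<hours>` column per timepoint.
#' @export
mean_profiles <- function(expr, log_transform = TRUE) {
  expr |>
    mutate(v = if (log_transform) log2(.data$fpkm + 1) else .data$fpkm) |>
    group_by(.data$gene_id, .data$timepoint) |>
    summarise(m = mean(.data$v), .groups = "drop") |>
    mutate(timepoint = sprintf("t%g", .data$timepoint)) |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "m")
}

#' Hierarchical clustering of diel profiles
#'
#' Mean profiles are z-scored per gene, pairwise distance is 1 minus the
#' Pearson correlation, and the average-linkage tree is cut at `k` clusters.
#' Flat (zero-variance) profiles cannot be z-scored and are a hard error;
#' cluster the rhythmic subset.
#'
#' @param profiles Wide profile tibble from [mean_profiles()].
#' @param k Number of clusters, default 9.
#' @return Tibble: `gene_id`, `cluster` (integer).
#' @export
cluster_profiles <- function(profiles, k = 9) {
  if (k > nrow(profiles)) abort("k exceeds the number of genes")
  m <- as.matrix(profiles[, -1])
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) abort("zero-variance profile(s); cluster rhythmic genes only")
  z <- t(scale(t(m)))
  d <- as.dist(1 - cor(t(z)))
  hc <- hclust(d, method = "average")
  tibble(gene_id = profiles$gene_id, cluster = unname(cutree(hc, k = k)))
}

#' Pearson and Spearman correlation between two diel profiles
#'
#' @param x,y Numeric mean profiles on identical timepoint grids.
#' @return One-row tibble: `r_pearson`, `r_spearman`, `degenerate` (TRUE
#'   with `NA` coefficients when either profile has zero variance).
#' @export
diel_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r_pearson = NA_real_, r_spearman = NA_real_, degenerate = TRUE))
  }
  tibble(
    r_pearson = cor(x, y, method = "pearson"),
    r_spearman = cor(x, y, method = "spearman"),
    degenerate = FALSE
  )
}

#' Classify genes by cross-species diel correlation
#'
#' The published rule: a gene is *divergent* from the C3 reference when its
#' correlation with the C3 ortholog profile is below `t_low`, and a *strong
#' CAM* candidate when it is divergent and its correlation with the CAM
#' reference exceeds `t_high`; everything else is *conserved*. With
#' `rule = "both"` (default) a condition must hold for the Pearson and the
#' Spearman coefficient simultaneously; `rule = "pearson"` uses Pearson only.
#' Any undefined coefficient makes the gene *degenerate*.
#'
#' @param p_c3,s_c3 Pearson/Spearman correlation with the C3 reference.
#' @param p_cam,s_cam Pearson/Spearman correlation with the CAM reference.
#' @param t_low,t_high Thresholds, defaults 0.5 and 0.8 (strict < and >).
#' @param rule `"both"` or `"pearson"`.
#' @return Character vector of labels in
#'   `{"conserved", "divergent", "strong_CAM", "degenerate"}`.
#' @export
#' @examples
#' classify_cam(0.2, 0.3, 0.9, 0.85) # strong_CAM
#' classify_cam(0.2, 0.6, 0.9, 0.9)  # conserved: Spearman fails the < 0.5 rule
classify_cam <- function(p_c3, s_c3, p_cam, s_cam,
                         t_low = 0.5, t_high = 0.8,
                         rule = c("both", "pearson")) {
  rule <- match.arg(rule)
  if (rule == "both") {
    divergent <- p_c3 < t_low & s_c3 < t_low
    high <- p_cam > t_high & s_cam > t_high
    degen <- is.na(p_c3) | is.na(s_c3) | is.na(p_cam) | is.na(s_cam)
  } else {
    divergent <- p_c3 < t_low
    high <- p_cam > t_high
    degen <- is.na(p_c3) | is.na(p_cam)
  }
  dplyr::case_when(
    degen ~ "degenerate",
    divergent & high ~ "strong_CAM",
    divergent ~ "divergent",
    .default = "conserved"
  )
}
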
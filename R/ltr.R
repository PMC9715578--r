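#' Jukes-Cantor corrected divergence from a raw mismatch proportion
#'
#' `K = -(3/4) * log(1 - (4/3) * p)`. A proportion at or above 3/4 is
#' saturated: the correction is undefined and `NA` is returned.
#'
#' @param p Proportion(s) of differing ungapped sites, in `[0, 1]`.
#' @return Corrected distance(s); `NA` where saturated.
#' @export
#' @examples
#' jc69_distance(0.1) # -0.75 * log(13/15)
jc69_distance <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - (4 / 3) * p))
  if (any(p >= 0.75, na.rm = TRUE)) {
    warn(sprintf("%d proportion(s) >= 0.75 are saturated; K undefined",
                 sum(p >= 0.75, na.rm = TRUE)))
  }
  out
}

# p-distance between two aligned sequences: gap columns and ambiguous bases
# (anything outside A/C/G/T, including N) excluded from numerator and
# denominator. Returns NA when no alignable columns remain.
.p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) abort("aligned LTR sequences differ in length")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Estimate LTR retrotransposon insertion ages
#'
#' The 5' and 3' long terminal repeats of a retroelement are identical at
#' insertion and diverge afterwards at the neutral rate, so the age is
#' `T = K / (2 * mu)` with `K` the Jukes-Cantor corrected divergence between
#' the two LTRs and `mu` the substitution rate per site per year. `mu` has
#' no default: ages are meaningless without an explicit clock.
#'
#' @param pairs Tibble with `element_id` and either aligned sequences
#'   (`ltr5`, `ltr3`; equal length, gaps `-` allowed) or a precomputed
#'   `p_distance` column.
#' @param mu Substitution rate (substitutions/site/year), required, > 0.
#' @return Tibble: `element_id`, `p_distance`, `K`, `age_years`, and a
#'   `defined` flag (FALSE where saturated or no alignable columns).
#' @export
#' @examples
#' pairs <- tibble::tibble(element_id = "e1", p_distance = 0.0026)
#' ltr_insertion_age(pairs, mu = 1.3e-8)
ltr_insertion_age <- function(pairs, mu) {
  if (missing(mu) || is.na(mu)) {
    abort("a substitution rate `mu` must be supplied explicitly")
  }
  stopifnot(mu > 0, is.data.frame(pairs), "element_id" %in% names(pairs))
  if ("p_distance" %in% names(pairs)) {
    p <- pairs$p_distance
  } else {
    stopifnot(all(c("ltr5", "ltr3") %in% names(pairs)))
    p <- purrr::map2_dbl(pairs$ltr5, pairs$ltr3, .p_distance)
  }
  K <- suppressWarnings(ifelse(is.na(p) | p >= 0.75, NA_real_,
                               -0.75 * log(1 - (4 / 3) * p)))
  tibble(
    element_id = pairs$element_id,
    p_distance = p,
    K = K,
    age_years = K / (2 * mu),
    defined = !is.na(K)
  )
}

#' Summarise an LTR insertion-age distribution
#'
#' Histogram at a configurable bin width, the mode of a Gaussian
#' kernel-smoothed density (how an insertion burst is read off an age plot),
#' and 5/50/95% quantiles. Undefined (saturated) ages are excluded; if none
#' are defined, an empty summary is returned with a warning.
#'
#' @param ages Tibble from [ltr_insertion_age()] or a numeric vector of ages.
#' @param bin_width Histogram bin width in years, default 10,000.
#' @return An object of class `ltr_age_summary`: list with `histogram`,
#'   `mode_age`, `quantiles`, `n_used`.
#' @export
age_summary <- function(ages, bin_width = 1e4) {
  x <- if (is.data.frame(ages)) ages$age_years else as.numeric(ages)
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    warn("no defined ages; empty summary")
    return(structure(
      list(histogram = tibble(mid = numeric(0), count = integer(0)),
           mode_age = NA_real_,
           quantiles = c(`5%` = NA_real_, `50%` = NA_real_, `95%` = NA_real_),
           n_used = 0L, bin_width = bin_width),
      class = "ltr_age_summary"
    ))
  }
  breaks <- seq(0, max(x) + bin_width, by = bin_width)
  bins <- cut(x, breaks = breaks, right = TRUE, include.lowest = TRUE)
  hist_tbl <- tibble(
    mid = head(breaks, -1) + bin_width / 2,
    count = as.integer(table(bins))
  )
  mode_age <- if (length(unique(x)) == 1) {
    unique(x)
  } else {
    d <- density(x, n = 1024)
    d$x[which.max(d$y)]
  }
  structure(
    list(histogram = hist_tbl, mode_age = mode_age,
         quantiles = quantile(x, c(0.05, 0.5, 0.95)),
         n_used = length(x), bin_width = bin_width),
    class = "ltr_age_summary"
  )
}

#' @exportS3Method generics::glance
glance.ltr_age_summary <- function(x, ...) {
  tibble(
    n_used = x$n_used, mode_age = x$mode_age,
    q05 = unname(x$quantiles[1]), median = unname(x$quantiles[2]),
    q95 = unname(x$quantiles[3])
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.ltr_age_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$mid / 1e3, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width / 1e3, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$mode_age / 1e3, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "insertion age (kya)", y = "elements") +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::glance
glance.ks_distribution <- function(x, ...) {
  tibble(
    n_used = x$n_used,
    n_modes = nrow(x$modes),
    mode_1 = if (nrow(x$modes) >= 1) x$modes$ks[1] else NA_real_,
    mode_2 = if (nrow(x$modes) >= 2) x$modes$ks[2] else NA_real_
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.ks_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$modes$ks, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "Ks", y = "gene pairs") +
    ggplot2::theme_minimal()
}
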
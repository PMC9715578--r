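#' Nei-Gojobori (NG86) Ka/Ks estimation for codon-aligned sequence pairs
#'
#' Counts synonymous and nonsynonymous sites and differences by the NG86
#' method and applies the Jukes-Cantor multiple-hit correction. Synonymous
#' site fractions are computed per codon from the standard genetic code (at
#' each position, the number of the three possible single-base changes that
#' are synonymous, divided by 3); `S` and `N` are averaged over the two
#' sequences. Codons differing at more than one position are resolved by
#' enumerating all minimal substitution pathways with equal weights; pathways
#' passing through a stop codon are excluded and the remaining weights
#' renormalised (when every pathway crosses a stop, all pathways are used).
#' `Ks = -(3/4) * log(1 - (4/3) * pS)` and likewise for `Ka`; a proportion at
#' or above 3/4 is flagged saturated and the corrected rate is `NA`.
#'
#' @param pairs A data frame with columns `pair_id`, `seq_a`, `seq_b`: each
#'   row a gap-free codon alignment (equal length, multiple of 3, no stop
#'   codons, A/C/G/T only).
#' @return A tibble with one row per pair: site counts (`S`, `N`), difference
#'   counts (`Sd`, `Nd`), proportions (`pS`, `pN`), corrected rates (`Ks`,
#'   `Ka`), the `ka_ks` ratio and `saturated` flags.
#' @export
#' @examples
#' pairs <- tibble::tibble(
#'   pair_id = "p1",
#'   seq_a = strrep("GGT", 10),
#'   seq_b = paste0("GGC", strrep("GGT", 9))
#' )
#' ng86_ka_ks(pairs) # S = 10, Sd = 1, Ks = -0.75 * log(13/15)
ng86_ka_ks <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "seq_a", "seq_b") %in% names(pairs)))
  res <- pmap(
    list(pairs$pair_id, pairs$seq_a, pairs$seq_b),
    function(id, a, b) {
      est <- .ng86_one(a, b)
      tibble(pair_id = id, !!!est)
    }
  )
  bind_rows(res)
}

.check_cds <- function(seq, label) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    abort(sprintf("%s contains characters other than A/C/G/T", label))
  }
  codons <- .split_codons(seq)
  if (any(.is_stop_codon(codons))) {
    abort(sprintf("%s contains a stop codon", label))
  }
  codons
}

.ng86_one <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("aligned sequences differ in length")
  }
  ca <- .check_cds(seq_a, "seq_a")
  cb <- .check_cds(seq_b, "seq_b")
  sites <- .syn_sites_table()
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S

  diffs <- which(ca != cb)
  Sd <- 0
  Nd <- 0
  for (i in diffs) {
    d <- .codon_pair_diffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  ks_sat <- pS >= 0.75
  ka_sat <- pN >= 0.75
  Ks <- if (ks_sat) NA_real_ else -0.75 * log(1 - (4 / 3) * pS)
  Ka <- if (ka_sat) NA_real_ else -0.75 * log(1 - (4 / 3) * pN)
  list(
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    Ks = Ks, Ka = Ka,
    ka_ks = if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_,
    saturated_s = ks_sat, saturated_n = ka_sat
  )
}

# Average synonymous/nonsynonymous difference counts over all minimal
# substitution pathways between two codons. Pathways through stop codons are
# dropped and the rest reweighted; if none survive, all are used.
.codon_pair_diffs <- function(codon_a, codon_b) {
  pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(pos)
  if (k == 0) {
    return(c(sd = 0, nd = 0))
  }
  perms <- .permutations(pos)
  code <- .genetic_code()
  chars_b <- strsplit(codon_b, "")[[1]]
  path_sd <- numeric(0)
  path_nd <- numeric(0)
  path_ok <- logical(0)
  for (p in seq_len(nrow(perms))) {
    cur <- strsplit(codon_a, "")[[1]]
    sd <- 0
    nd <- 0
    ok <- TRUE
    for (step in perms[p, ]) {
      nxt <- cur
      nxt[step] <- chars_b[step]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (code[to] == "*") ok <- FALSE
      if (code[from] == code[to]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    path_sd <- c(path_sd, sd)
    path_nd <- c(path_nd, nd)
    path_ok <- c(path_ok, ok)
  }
  use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_ok))
  c(sd = mean(path_sd[use]), nd = mean(path_nd[use]))
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1) {
    return(matrix(x, nrow = 1))
  }
  out <- NULL
  for (i in seq_len(n)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Summarise a Ks distribution: histogram and density modes
#'
#' Builds a fixed-width histogram of Ks values over `(0, ks_max]` and locates
#' the modes (local maxima) of a Gaussian kernel density estimate, the way
#' whole-genome-duplication peaks are read off a smoothed paranome Ks plot.
#' Saturated estimates (`NA` Ks) are excluded.
#'
#' @param estimates A data frame with a `Ks` column (e.g. from
#'   [ng86_ka_ks()]), or a numeric vector of Ks values.
#' @param bin_width Histogram bin width.
#' @param ks_max Upper bound; values above it are dropped.
#' @param bw Kernel bandwidth, passed to [stats::density()]; the default
#'   `"nrd0"` is Silverman's rule of thumb.
#' @return An object of class `ks_distribution`: a list with `histogram`
#'   (tibble of bin midpoints and counts), `modes` (tibble of mode locations,
#'   density heights and the share of values nearest each mode), `n_used`, and
#'   the call parameters.
#' @export
#' @examples
#' ks <- c(rnorm(200, 0.1, 0.02), rnorm(200, 0.33, 0.02))
#' ks_distribution(ks)$modes
ks_distribution <- function(estimates, bin_width = 0.02, ks_max = 3, bw = "nrd0") {
  ks <- if (is.data.frame(estimates)) estimates$Ks else as.numeric(estimates)
  ks <- ks[!is.na(ks) & ks > 0 & ks <= ks_max]
  breaks <- seq(0, ks_max + bin_width, by = bin_width)
  if (length(ks) == 0) {
    return(structure(
      list(
        histogram = tibble(mid = numeric(0), count = integer(0)),
        modes = tibble(ks = numeric(0), height = numeric(0), mass = numeric(0)),
        n_used = 0L, bin_width = bin_width, ks_max = ks_max
      ),
      class = "ks_distribution"
    ))
  }
  bins <- cut(ks, breaks = breaks, right = TRUE, include.lowest = FALSE)
  counts <- as.integer(table(bins))
  hist_tbl <- tibble(
    mid = head(breaks, -1) + bin_width / 2,
    count = counts
  )
  modes <- .density_modes(ks, bw = bw)
  structure(
    list(histogram = hist_tbl, modes = modes, n_used = length(ks),
         bin_width = bin_width, ks_max = ks_max),
    class = "ks_distribution"
  )
}

# Local maxima of a Gaussian KDE, with the fraction of observations nearest
# each mode as its mass. A single unique value yields one mode at that value.
.density_modes <- function(x, bw = "nrd0") {
  if (length(unique(x)) == 1) {
    return(tibble(ks = unique(x), height = Inf, mass = 1))
  }
  d <- density(x, bw = bw, n = 1024)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  if (length(is_max) == 0) is_max <- which.max(y)
  locs <- d$x[is_max]
  nearest <- apply(abs(outer(x, locs, "-")), 1, which.min)
  mass <- as.numeric(table(factor(nearest, levels = seq_along(locs)))) / length(x)
  tibble(ks = locs, height = y[is_max], mass = mass) |>
    arrange(desc(.data$height))
}
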
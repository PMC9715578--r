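mk_expr <- function(values, timepoints = seq(0, 24, 3), reps = 3,
                    gene = "g1") {
  # values: matrix genes x (timepoints*reps) or vector for one gene
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  grid <- tidyr::expand_grid(timepoint = timepoints, replicate = seq_len(reps))
  purrr::map_dfr(seq_len(nrow(values)), function(i) {
    tibble::tibble(
      gene_id = if (nrow(values) == 1) gene else sprintf("g%03d", i),
      timepoint = grid$timepoint, replicate = grid$replicate,
      fpkm = values[i, ]
    )
  })
}

test_that("the expressed-gene prefilter is strict and matches a naive scan", {
  e1 <- mk_expr(rep(1, 27))
  expect_length(prefilter_expressed(e1), 0) # mean exactly 1 fails strict >

  e2 <- mk_expr(c(rep(0.1, 24), rep(5, 3)))
  expect_equal(prefilter_expressed(e2), "g1")

  set.seed(61)
  vals <- matrix(stats::rexp(300 * 27, rate = 1), nrow = 300)
  e3 <- mk_expr(vals)
  got <- prefilter_expressed(e3)
  want <- sprintf("g%03d", which(vapply(seq_len(300), function(i) {
    m <- tapply(vals[i, ], rep(seq(0, 24, 3), each = 3), mean)
    any(m > 1)
  }, TRUE)))
  expect_setequal(got, want)
})

test_that("the rhythmicity F-test is calibrated and powerful as specified", {
  set.seed(62)
  tp <- seq(0, 24, 3)
  # type I: constant profiles with additive normal noise, 2000 genes
  flat <- matrix(100 + rnorm(2000 * 27, sd = 1), nrow = 2000)
  r_null <- fit_rhythmicity(mk_expr(flat), log_transform = FALSE)
  rate <- mean(r_null$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rate - 0.05), 2.5 * se)

  # power: planted cosine at amplitude/noise = 5, q < 0.05 in >= 95% of genes
  grid_t <- rep(tp, each = 3)
  cosine <- t(vapply(seq_len(500), function(i) {
    5 * cos(2 * pi * (grid_t - sample(c(0, 6, 12, 18), 1)) / 24) +
      rnorm(27, sd = 1)
  }, numeric(27)))
  r_alt <- detect_rhythmicity(mk_expr(cosine), log_transform = FALSE)
  expect_gte(mean(r_alt$q < 0.05), 0.95)

  # zero-variance profile: degenerate with p = 1
  r_degen <- fit_rhythmicity(mk_expr(rep(3, 27)))
  expect_true(r_degen$degenerate)
  expect_equal(r_degen$p, 1)

  # time reversal leaves the F statistic unchanged (cubic basis is affine-closed)
  y <- 10 + 3 * cos(2 * pi * (grid_t - 6) / 24) + rnorm(27, sd = 0.3)
  f_fwd <- fit_rhythmicity(mk_expr(y), log_transform = FALSE)$F
  e_rev <- mk_expr(y)
  e_rev$timepoint <- 24 - e_rev$timepoint
  f_rev <- fit_rhythmicity(e_rev, log_transform = FALSE)$F
  expect_equal(f_fwd, f_rev, tolerance = 1e-9)
})

test_that("diel pipeline on simulated data meets sensitivity and FDR bounds", {
  sim <- sim_diel_profiles(n_genes = 500, rhythmic_fraction = 0.3,
                           amplitude = 2, noise_sd = 0.5, seed = 63)
  res <- detect_rhythmicity(sim$expr)
  called <- res$gene_id[res$rhythmic]
  planted <- sim$truth$gene_id[sim$truth$rhythmic]
  sens <- length(intersect(called, planted)) / length(planted)
  fdr <- if (length(called)) length(setdiff(called, planted)) / length(called) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("profile clustering recovers phase groups and ignores gene order", {
  set.seed(64)
  tp <- seq(0, 24, 3)
  two_phase <- rbind(
    t(replicate(15, cos(2 * pi * tp / 24))),
    t(replicate(15, cos(2 * pi * (tp - 12) / 24)))
  )
  prof <- tibble::as_tibble(cbind(
    tibble::tibble(gene_id = sprintf("g%02d", 1:30)),
    stats::setNames(as.data.frame(two_phase), sprintf("t%g", tp))
  ))
  cl <- cluster_profiles(prof, k = 2)
  truth <- rep(1:2, each = 15)
  expect_true(same_partition(cl$cluster, truth))

  # duplicate profiles always co-cluster; permutation leaves the partition
  noisy <- prof
  noisy[, -1] <- noisy[, -1] + matrix(rnorm(30 * 9, sd = 0.05), 30)
  noisy[5, -1] <- noisy[4, -1]
  cl2 <- cluster_profiles(noisy, k = 4)
  expect_equal(cl2$cluster[4], cl2$cluster[5])
  perm <- sample(30)
  cl3 <- cluster_profiles(noisy[perm, ], k = 4)
  expect_true(same_partition(
    cl3$cluster[match(noisy$gene_id, cl3$gene_id)], cl2$cluster
  ))

  expect_error(cluster_profiles(prof, k = 40), "exceeds")
})

test_that("diel correlations match textbook formulas and flag degeneracy", {
  x <- c(1, 3, 2, 5, 4, 6, 7, 9, 8)
  expect_equal(diel_correlation(x, x)$r_pearson, 1)
  expect_equal(diel_correlation(x, x)$r_spearman, 1)
  expect_equal(diel_correlation(x, -x)$r_pearson, -1)
  expect_true(diel_correlation(x, rep(2, 9))$degenerate)

  set.seed(65)
  for (i in 1:40) {
    a <- rnorm(9)
    b <- rnorm(9)
    got <- diel_correlation(a, b)
    pearson_hand <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    spearman_hand <- {
      ra <- rank(a)
      rb <- rank(b)
      sum((ra - mean(ra)) * (rb - mean(rb))) /
        sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    }
    expect_equal(got$r_pearson, pearson_hand, tolerance = 1e-12)
    expect_equal(got$r_spearman, spearman_hand, tolerance = 1e-12)
  }
})

test_that("CAM classification implements the two-threshold conjunction rule", {
  expect_equal(classify_cam(0.2, 0.3, 0.9, 0.85), "strong_CAM")
  expect_equal(classify_cam(0.2, 0.6, 0.9, 0.9), "conserved") # Spearman fails
  expect_equal(classify_cam(0.2, 0.3, 0.7, 0.9), "divergent")
  expect_equal(classify_cam(NA, 0.3, 0.9, 0.9), "degenerate")
  expect_equal(classify_cam(0.2, 0.6, 0.9, 0.9, rule = "pearson"), "strong_CAM")

  # exhaustive grid against the truth table
  vals <- c(-0.5, 0.2, 0.49, 0.5, 0.6, 0.8, 0.81, 0.95)
  grid <- expand.grid(p3 = vals, s3 = vals, pc = vals, sc = vals)
  got <- classify_cam(grid$p3, grid$s3, grid$pc, grid$sc)
  want <- with(grid, ifelse(
    p3 < 0.5 & s3 < 0.5,
    ifelse(pc > 0.8 & sc > 0.8, "strong_CAM", "divergent"),
    "conserved"
  ))
  expect_identical(got, want)
  # the labels partition the genes
  expect_true(all(got %in% c("conserved", "divergent", "strong_CAM")))
})

test_that("expression matrices round-trip through the TSV layout", {
  sim <- sim_diel_profiles(n_genes = 10, seed = 66)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(sim$expr, f)
  back <- read_expression(f)
  expect_equal(
    dplyr::arrange(back, gene_id, timepoint, replicate),
    dplyr::arrange(sim$expr, gene_id, timepoint, replicate),
    tolerance = 1e-12
  )
})
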
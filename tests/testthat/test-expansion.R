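test_that("exact binomial tails match closed forms and direct summation", {
  # 5 succulents vs 13 others: p_success = 5/18
  s5 <- sprintf("S%d", 1:5)
  o13 <- sprintf("O%d", 1:13)
  mk <- function(sa, sb) {
    row <- as.list(c(sa, rep(0, 4), sb, rep(0, 12)))
    names(row) <- c(s5, o13)
    tibble::as_tibble(c(list(orthogroup = "OG1"), lapply(row, as.integer)))
  }
  st <- binomial_group_test(mk(2, 0), s5, o13)
  expect_equal(st$p_expand, (5 / 18)^2, tolerance = 1e-15)

  st0 <- binomial_group_test(mk(0, 4), s5, o13)
  expect_equal(st0$p_expand, 1)
  expect_equal(st0$p_contract, (13 / 18)^4, tolerance = 1e-15)

  # n = 30, S5n = 20 vs direct pmf summation
  st30 <- binomial_group_test(mk(20, 10), s5, o13)
  expect_equal(st30$p_expand, oracle_binom_upper(20, 30, 5 / 18),
               tolerance = 1e-12)
  expect_equal(st30$p_contract, oracle_binom_lower(20, 30, 5 / 18),
               tolerance = 1e-12)

  # property: random cases up to n = 10^4 agree with summation to 1e-12
  set.seed(12)
  for (i in 1:25) {
    n <- sample(c(1:50, 200, 1000, 10000), 1)
    k <- sample(0:n, 1)
    st <- binomial_group_test(mk(k, n - k), s5, o13)
    expect_equal(st$p_expand, oracle_binom_upper(k, n, 5 / 18),
                 tolerance = 1e-12)
    expect_equal(st$p_contract, oracle_binom_lower(k, n, 5 / 18),
                 tolerance = 1e-12)
  }

  expect_error(binomial_group_test(mk(1, 1), c(s5, "S6"), o13), "S6")
})

test_that("BH adjustment matches the step-up definition and is permutation-safe", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, NA)), "NA")

  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm])[order(perm)], bh_adjust(p))
  }
})

test_that("orthogroup calls implement the three published criteria", {
  base <- tibble::tibble(
    orthogroup = c("a", "b", "c", "d"),
    S5n = c(20, 20, 2, 1), O13n = c(5, 5, 40, 0), n = S5n + O13n,
    k_contrib_A = c(5, 2, 1, 1), k_contrib_B = c(3, 3, 13, 0),
    ratio = c(10.4, 10.4, 0.13, Inf),
    p_expand = c(1e-6, 1e-6, 1, 0.27),
    p_contract = c(1, 1, 1e-8, 1),
    q_expand = c(1e-5, 1e-5, 1, 0.4),
    q_contract = c(1, 1, 1e-7, 1)
  )
  calls <- classify_orthogroups(base)
  expect_equal(calls$call, c("expanded", "none", "contracted", "none"))
  # "b" fails only criterion (ii): k_contrib_A = 2 < 3

  # random stat tables match a naive row-by-row filter
  set.seed(14)
  for (rep in 1:10) {
    nn <- 200
    s5n <- rpois(nn, 3)
    o13n <- rpois(nn, 6)
    st <- tibble::tibble(
      orthogroup = sprintf("og%03d", 1:nn),
      S5n = s5n, O13n = o13n, n = s5n + o13n,
      k_contrib_A = sample(0:5, nn, TRUE),
      k_contrib_B = sample(0:13, nn, TRUE),
      ratio = ifelse(o13n == 0, ifelse(s5n > 0, Inf, NaN),
                     (s5n / 5) / (o13n / 13)),
      q_expand = runif(nn), q_contract = runif(nn)
    )
    calls <- classify_orthogroups(st)
    naive <- vapply(seq_len(nn), function(i) {
      r <- st[i, ]
      ratio_gt1 <- !is.nan(r$ratio) && r$ratio > 1 # Inf > 1 counts as pass
      if (r$q_expand < 0.05 && r$k_contrib_A >= 3 && ratio_gt1) {
        "expanded"
      } else if (r$q_contract < 0.05 && r$k_contrib_B >= 7 &&
                   !is.nan(r$ratio) && is.finite(r$ratio) && r$ratio < 1) {
        "contracted"
      } else {
        "none"
      }
    }, "")
    expect_identical(calls$call, naive)
    expect_length(intersect(which(calls$call == "expanded"),
                            which(calls$call == "contracted")), 0)
  }
})

test_that("two-species expansion rule follows the p-value and mean-count criteria", {
  cm <- tibble::tibble(orthogroup = "og1", A = 10L, B = 1L, C = 1L, D = 0L)
  res <- two_species_expansion(cm, 0.01)
  expect_true(res$expanded[res$species == "A"])
  expect_false(any(res$expanded[res$species != "A"]))

  cm2 <- tibble::tibble(orthogroup = "og1", A = 3L, B = 3L, C = 3L)
  res2 <- two_species_expansion(cm2, 0.001)
  expect_false(any(res2$expanded)) # strict >: count equal to mean fails

  expect_error(two_species_expansion(cm, c(0.1, 0.2)), "length")

  set.seed(15)
  cm3 <- tibble::tibble(
    orthogroup = sprintf("og%03d", 1:500),
    spA = rpois(500, 3), spB = rpois(500, 3), spC = rpois(500, 3)
  )
  p <- runif(500)
  res3 <- two_species_expansion(cm3, p)
  mean_cnt <- rowMeans(cm3[, -1])
  for (sp in c("spA", "spB", "spC")) {
    naive <- p < 0.05 & cm3[[sp]] > mean_cnt
    expect_identical(res3$expanded[res3$species == sp][
      match(cm3$orthogroup, res3$orthogroup[res3$species == sp])
    ], naive)
  }
})

test_that("expansion pipeline recovers strong planted effects on simulated matrices", {
  sim <- sim_count_matrix(n_orthogroups = 2000, lambda = 2, fold_effect = 4,
                          planted_fraction = 0.05, seed = 17)
  res <- test_expansion(sim$counts, sim$group_a, sim$group_b)
  called <- res$orthogroup[res$call == "expanded"]
  planted <- sim$truth$orthogroup[sim$truth$planted]
  sens <- length(intersect(called, planted)) / length(planted)
  fdr <- if (length(called) > 0) {
    length(setdiff(called, planted)) / length(called)
  } else {
    0
  }
  expect_gte(sens, 0.85)
  expect_lte(fdr, 0.15)
  expect_s3_class(glance(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
})
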
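mk_ann <- function(n, chrom = "chr1") {
  tibble::tibble(
    gene_id = sprintf("%s_g%02d", chrom, seq_len(n)),
    chrom = chrom,
    start = (seq_len(n) - 1) * 1000,
    end = (seq_len(n) - 1) * 1000 + 500,
    strand = "+",
    rank = seq_len(n) - 1L
  )
}

test_that("tandem arrays grow by single linkage with the gap parameter", {
  ann <- mk_ann(5)
  g <- ann$gene_id

  # chained adjacency: g1-g2, g2-g3 homology makes one array of 3
  arr <- find_tandem_arrays(ann, tibble::tibble(a = g[1:2], b = g[2:3]))
  expect_equal(unique(arr$n_members), 3L)
  expect_setequal(arr$gene_id, g[1:3])

  # g1-g3 only: no array at max_intervening 0, one pair at 1
  arr0 <- find_tandem_arrays(ann, tibble::tibble(a = g[1], b = g[3]),
                             max_intervening = 0)
  expect_equal(nrow(arr0), 0)
  arr1 <- find_tandem_arrays(ann, tibble::tibble(a = g[1], b = g[3]),
                             max_intervening = 1)
  expect_setequal(arr1$gene_id, g[c(1, 3)])

  # hits naming unknown genes are skipped with a warning
  expect_warning(
    find_tandem_arrays(ann, tibble::tibble(a = c(g[1], "ghost"),
                                           b = c(g[2], g[3]))),
    "absent"
  )
})

test_that("tandem detection matches the growth-definition oracle on random layouts", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    mi <- sample(0:2, 1)
    ann <- mk_ann(n)
    # random homology among a subset of genes
    n_pairs <- sample(3:12, 1)
    pairs <- tibble::tibble(
      a = sample(ann$gene_id, n_pairs, replace = TRUE),
      b = sample(ann$gene_id, n_pairs, replace = TRUE)
    )
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    got <- find_tandem_arrays(ann, pairs, max_intervening = mi)
    got_sets <- unname(lapply(split(got$gene_id, got$array_id), sort))
    want_sets <- oracle_tandem_arrays(ann, pairs, max_intervening = mi)
    expect_setequal(
      vapply(got_sets, paste, "", collapse = ","),
      vapply(want_sets, paste, "", collapse = ",")
    )
  }
})

test_that("planted arrays are recovered exactly at zero noise", {
  for (seed in 1:5) {
    gl <- sim_genome_layout(n_tandem_arrays = 4, array_size_range = c(2, 5),
                            max_intervening = 1, n_collinear_blocks = 0,
                            n_noise_hits = 0, seed = seed)
    ann <- dplyr::bind_rows(gl$ann_a, gl$ann_b)
    got <- find_tandem_arrays(ann, gl$hits[, c("query_id", "subject_id")],
                              max_intervening = 1)
    got_sets <- unname(lapply(split(got$gene_id, got$array_id), sort))
    want_sets <- unname(lapply(
      split(gl$truth$arrays$gene_id, gl$truth$arrays$array_id), sort
    ))
    expect_setequal(
      vapply(got_sets, paste, "", collapse = ","),
      vapply(want_sets, paste, "", collapse = ",")
    )
  }
})

test_that("TD lineage classification separates shared from specific genes", {
  td <- tibble::tibble(
    species = c("cr", "cr", "vv", "cr"),
    gene_id = c("c1", "c2", "v1", "c3")
  )
  og <- tibble::tibble(
    gene_id = c("c1", "c2", "v1", "c3"),
    orthogroup = c("fam1", "fam2", "fam1", "fam2")
  )
  res <- classify_td_lineage(td, og)
  expect_equal(res$status[res$gene_id %in% c("c1", "v1")],
               rep("shared", 2))
  expect_equal(res$status[res$gene_id %in% c("c2", "c3")],
               rep("species_specific", 2))

  # missing orthogroup -> species-specific with warning
  expect_warning(
    res2 <- classify_td_lineage(td, og[og$gene_id != "c3", ]),
    "without an orthogroup"
  )
  expect_equal(res2$status[res2$gene_id == "c3"], "species_specific")

  # randomised assignments match a set-algebra oracle
  set.seed(22)
  for (rep in 1:10) {
    genes <- sprintf("g%02d", 1:40)
    td_r <- tibble::tibble(
      species = sample(c("cr", "vv"), 40, TRUE),
      gene_id = genes
    )
    og_r <- tibble::tibble(
      gene_id = genes,
      orthogroup = sample(sprintf("fam%d", 1:8), 40, TRUE)
    )
    res_r <- classify_td_lineage(td_r, og_r)
    both <- intersect(
      og_r$orthogroup[td_r$species == "cr"],
      og_r$orthogroup[td_r$species == "vv"]
    )
    want <- ifelse(og_r$orthogroup %in% both, "shared", "species_specific")
    expect_identical(res_r$status[match(genes, res_r$gene_id)], want)
  }
})

test_that("the TD bias Welch test behaves like the textbook computation", {
  tbl <- function(xa, xb) {
    tibble::tibble(
      species = c(sprintf("a%d", seq_along(xa)), sprintf("b%d", seq_along(xb))),
      category = "cellular_component",
      percentage = c(xa, xb)
    )
  }
  # mirror-image groups: t = 0, p = 1
  r0 <- td_bias_test(tbl(c(10, 20, 30), c(30, 20, 10)), "cellular_component",
                     c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_equal(r0$t, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)

  # clearly separated groups: p < 0.01, matching the hand Welch formula
  xa <- c(10, 11, 9)
  xb <- c(30, 29, 31)
  r1 <- td_bias_test(tbl(xa, xb), "cellular_component",
                     c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  se <- sqrt(var(xa) / 3 + var(xb) / 3)
  t_hand <- (mean(xa) - mean(xb)) / se
  df_hand <- se^4 / ((var(xa) / 3)^2 / 2 + (var(xb) / 3)^2 / 2)
  expect_equal(r1$t, t_hand, tolerance = 1e-12)
  expect_equal(r1$df, df_hand, tolerance = 1e-12)
  expect_equal(r1$p, 2 * stats::pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  expect_lt(r1$p, 0.01)

  # permuting species within a group changes nothing
  r2 <- td_bias_test(tbl(c(9, 10, 11), c(31, 30, 29)), "cellular_component",
                     c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_equal(r2$t, r1$t)
  expect_equal(r2$p, r1$p)

  # both groups constant: degenerate, p undefined
  r3 <- td_bias_test(tbl(c(5, 5, 5), c(7, 7, 7)), "cellular_component",
                     c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_true(r3$degenerate)
  expect_true(is.na(r3$p))
})
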
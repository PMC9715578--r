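test_that("count-matrix generator plants controlled expansions deterministically", {
  s1 <- sim_count_matrix(n_orthogroups = 200, seed = 42)
  s2 <- sim_count_matrix(n_orthogroups = 200, seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)

  s0 <- sim_count_matrix(n_orthogroups = 200, planted_fraction = 0, seed = 1)
  expect_false(any(s0$truth$planted))

  # fold_effect = 1: planted and background counts come from the same law
  sn <- sim_count_matrix(n_orthogroups = 5000, planted_fraction = 0.5,
                         fold_effect = 1, seed = 3)
  a_cols <- sn$group_a
  pooled_p <- unlist(sn$counts[sn$truth$planted, a_cols])
  pooled_b <- unlist(sn$counts[!sn$truth$planted, a_cols])
  ks <- suppressWarnings(stats::ks.test(pooled_p, pooled_b))
  expect_gt(ks$p.value, 0.01)
})

test_that("genome-layout generator plants arrays and blocks as specified", {
  gl <- sim_genome_layout(seed = 9)
  expect_identical(gl$hits, sim_genome_layout(seed = 9)$hits)

  # no arrays, no noise: every hit is a planted block anchor
  gl0 <- sim_genome_layout(n_tandem_arrays = 0, n_noise_hits = 0, seed = 2)
  anchor_pairs <- with(gl0$truth$blocks, paste(gene_a, gene_b))
  expect_setequal(paste(gl0$hits$query_id, gl0$hits$subject_id), anchor_pairs)

  # one size-3 array: exactly one maximal run of 3 consecutive homologues
  gl1 <- sim_genome_layout(n_tandem_arrays = 1, array_size_range = c(3, 3),
                           n_collinear_blocks = 0, seed = 5)
  ann <- dplyr::bind_rows(gl1$ann_a, gl1$ann_b)
  arrays <- find_tandem_arrays(ann, gl1$hits[, c("query_id", "subject_id")])
  expect_equal(length(unique(arrays$array_id)), 1)
  expect_equal(nrow(arrays), 3)
  expect_setequal(arrays$gene_id, gl1$truth$arrays$gene_id)

  expect_error(
    sim_genome_layout(genes_per_chromosome = 12, n_collinear_blocks = 10,
                      block_length_range = c(12, 12), seed = 1),
    "capacity"
  )
})

test_that("codon-pair generator plants exact substitution counts, never stops", {
  cp0 <- sim_codon_pairs(n_pairs = 5, syn_subs = 0, nonsyn_subs = 0, seed = 1)
  expect_identical(cp0$pairs$seq_a, cp0$pairs$seq_b)

  # closed loop: one synonymous change on 10 codons gives NG86 Sd=1, Nd=0
  cp1 <- sim_codon_pairs(n_pairs = 20, n_codons = 10, syn_subs = 1,
                         nonsyn_subs = 0, seed = 2)
  est <- ng86_ka_ks(cp1$pairs)
  expect_equal(est$Sd, rep(1, 20))
  expect_equal(est$Nd, rep(0, 20))

  # stop codons never appear (1000 simulated pairs)
  cp <- sim_codon_pairs(n_pairs = 1000, n_codons = 12, syn_subs = 2,
                        nonsyn_subs = 3, seed = 3)
  has_stop <- function(s) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    any(codons %in% c("TAA", "TAG", "TGA"))
  }
  expect_false(any(vapply(cp$pairs$seq_a, has_stop, TRUE)))
  expect_false(any(vapply(cp$pairs$seq_b, has_stop, TRUE)))

  expect_error(sim_codon_pairs(n_codons = 4, syn_subs = 3, nonsyn_subs = 3),
               "exceed")
})

test_that("diel generator respects amplitude, noise and planted phases", {
  d0 <- sim_diel_profiles(n_genes = 50, amplitude = 0, seed = 1)
  expect_false(any(d0$truth$amplitude > 0))

  # zero noise: replicates identical within timepoint
  dn <- sim_diel_profiles(n_genes = 20, noise_sd = 0, seed = 2)
  spread <- dn$expr |>
    dplyr::group_by(gene_id, timepoint) |>
    dplyr::summarise(d = diff(range(fpkm)), .groups = "drop")
  expect_true(all(spread$d == 0))

  # amplitude/noise = 4: planted phase recovered within +/- 3 h
  dr <- sim_diel_profiles(n_genes = 100, rhythmic_fraction = 1, amplitude = 2,
                          noise_sd = 0.5, seed = 3)
  prof <- mean_profiles(dr$expr)
  tp <- as.numeric(sub("^t", "", names(prof)[-1]))
  peak <- tp[apply(as.matrix(prof[, -1]), 1, which.max)]
  phase <- dr$truth$phase[match(prof$gene_id, dr$truth$gene_id)]
  dist <- pmin(abs(peak - phase) %% 24, 24 - abs(peak - phase) %% 24)
  expect_true(all(dist <= 3))
})

test_that("promoter generator plants motifs at recorded positions", {
  p1 <- sim_promoters(n_genes = 30, planted_rate = 1, seed = 1)
  expect_identical(p1$promoters, sim_promoters(n_genes = 30, planted_rate = 1,
                                               seed = 1)$promoters)
  # every planted instance is recoverable by the scanner
  for (i in seq_len(30)) {
    found <- scan_motif(p1$promoters[[i]], "AAAATATCT")
    expect_true(all(p1$truth$positions[[i]] %in% found))
    expect_gte(length(found), 1)
  }

  # background G-box count matches the analytic expectation within 3 SE
  n <- 10000
  len <- 500
  p0 <- sim_promoters(n_genes = n, length = len, motif = "CACGTG",
                      planted_rate = 0, seed = 9)
  counts <- vapply(p0$promoters, function(s) {
    length(scan_motif(s, "CACGTG", strand = "forward"))
  }, 0L)
  expected <- (len - 5) * (1 / 4)^6
  se <- sqrt(expected / n) # per-promoter counts are ~Poisson(expected)
  expect_lt(abs(mean(counts) - expected), 3 * se)

  expect_error(sim_promoters(n_genes = 1, length = 10, motif = "CACGTG",
                             planted_rate = 2), "capacity")
})

test_that("LTR pair generator reproduces the planted age scale", {
  lp <- sim_ltr_pairs(n_elements = 300, ltr_length = 2000, mean_age = 8e4,
                      sd_age = 1e4, mu = 1.3e-8, seed = 4)
  expect_identical(lp$pairs, sim_ltr_pairs(n_elements = 300, ltr_length = 2000,
                                           mean_age = 8e4, sd_age = 1e4,
                                           mu = 1.3e-8, seed = 4)$pairs)
  ages <- ltr_insertion_age(lp$pairs, mu = 1.3e-8)
  expect_true(all(ages$defined))
  expect_lt(abs(mean(ages$age_years) - 8e4) / 8e4, 0.1)
})
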
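#' Simulate a full synthetic project and run every analysis stage on it
#'
#' Generates one dataset of each input class (count matrix, two annotated
#' genomes with homology, codon alignment pairs, LTR pairs, diel expression,
#' promoters) with planted truth, writes them to `out_dir/data` in the same
#' on-disk formats the readers consume, then runs all analysis stages by
#' reading those files back and writes results to `out_dir/results`. Every
#' result file carries the seed; `truth.json` records the planted ground
#' truth. This is the programmatic equivalent of the command-line driver's
#' `simulate` + analysis subcommands.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for all generators.
#' @param mu LTR substitution rate (subs/site/year); required for the LTR
#'   stage.
#' @return Invisibly, a named list of the in-memory results.
#' @export
run_pipeline <- function(out_dir, seed = 1, mu = 1.3e-8) {
  data_dir <- file.path(out_dir, "data")
  res_dir <- file.path(out_dir, "results")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  tsv_out <- function(df, name) {
    path <- file.path(res_dir, name)
    writeLines(sprintf("# camevol seed=%d", seed), path)
    suppressWarnings(readr::write_tsv(df, path, append = TRUE,
                                      col_names = TRUE, progress = FALSE))
    path
  }

  ## --- simulate + serialize ------------------------------------------------
  cm <- sim_count_matrix(n_orthogroups = 1000, seed = seed)
  write_count_matrix(cm$counts, file.path(data_dir, "counts.tsv"))

  gl <- sim_genome_layout(seed = seed)
  write_gff3(gl$ann_a, file.path(data_dir, "genome_cr.gff3"))
  write_gff3(gl$ann_b, file.path(data_dir, "genome_vv.gff3"))
  write_hit_table(gl$hits, file.path(data_dir, "hits.tsv"))

  cp <- sim_codon_pairs(n_pairs = 60, n_codons = 150, syn_subs = 3,
                        nonsyn_subs = 3, seed = seed)
  codon_fa <- setNames(
    c(rbind(cp$pairs$seq_a, cp$pairs$seq_b)),
    c(rbind(paste0(cp$pairs$pair_id, "_a"), paste0(cp$pairs$pair_id, "_b")))
  )
  write_fasta(codon_fa, file.path(data_dir, "codon_pairs.fasta"))

  lp <- sim_ltr_pairs(n_elements = 400, ltr_length = 2000, mu = mu, seed = seed)
  ltr_fa <- setNames(
    c(rbind(lp$pairs$ltr5, lp$pairs$ltr3)),
    c(rbind(paste0(lp$pairs$element_id, "_5LTR"),
            paste0(lp$pairs$element_id, "_3LTR")))
  )
  write_fasta(ltr_fa, file.path(data_dir, "ltr_pairs.fasta"))

  dp <- sim_diel_profiles(n_genes = 300, seed = seed)
  write_expression(dp$expr, file.path(data_dir, "expression.tsv"))

  pr_night <- sim_promoters(n_genes = 100, motif = "AAAATATCT",
                            planted_rate = 0.8, seed = seed)
  pr_day <- sim_promoters(n_genes = 100, motif = "AAAATATCT",
                          planted_rate = 0.2, seed = seed + 1)
  names(pr_day$promoters) <- sub("^prom", "dayprom", names(pr_day$promoters))
  pr_day$truth$gene_id <- sub("^prom", "dayprom", pr_day$truth$gene_id)
  promoters <- c(pr_night$promoters, pr_day$promoters)
  write_fasta(promoters, file.path(data_dir, "promoters.fasta"))
  groups <- tibble(
    gene_id = names(promoters),
    group = rep(c("night", "day"), each = 100)
  )
  readr::write_tsv(groups, file.path(data_dir, "promoter_groups.tsv"),
                   progress = FALSE)

  jsonlite::write_json(
    list(
      seed = seed, mu = mu,
      expansion = cm$truth, arrays = gl$truth$arrays,
      blocks = gl$truth$blocks, codon = cp$truth[, c("pair_id", "syn_subs", "nonsyn_subs")],
      ltr = lp$truth, diel = dp$truth,
      promoters = bind_rows(pr_night$truth, pr_day$truth)[, c("gene_id", "n_planted")]
    ),
    file.path(data_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )

  ## --- analyses (reading back from disk) -----------------------------------
  counts <- read_count_matrix(file.path(data_dir, "counts.tsv"))
  expansion <- test_expansion(counts, cm$group_a, cm$group_b)
  tsv_out(tidy(expansion), "expansion.tsv")

  ann_a <- parse_gff3(file.path(data_dir, "genome_cr.gff3"))
  ann_b <- parse_gff3(file.path(data_dir, "genome_vv.gff3"))
  hits <- parse_hit_table(file.path(data_dir, "hits.tsv"))
  ann_all <- bind_rows(ann_a, ann_b)
  arrays <- find_tandem_arrays(ann_all, hits[, c("query_id", "subject_id")])
  tsv_out(arrays, "tandem_arrays.tsv")
  td <- arrays |>
    mutate(species = ifelse(grepl("^cr", .data$gene_id), "cr", "vv")) |>
    select("species", "gene_id")
  og_map <- arrays |> select("gene_id", orthogroup = "array_id")
  lineage <- classify_td_lineage(td, og_map)
  tsv_out(lineage, "tandem_lineage.tsv")

  anchors <- anchors_from_hits(hits, ann_a, ann_b)
  blocks <- chain_collinear_blocks(anchors, min_block_genes = 11, max_gap = 5)
  tsv_out(blocks, "synteny_blocks.tsv")
  painting <- blocks |>
    distinct(.data$block_id, .data$chrom_a, .data$chrom_b, .data$n_genes) |>
    select(chrom = "chrom_a", ancestral = "chrom_b", n_genes = "n_genes")
  fusions <- if (nrow(painting) > 0) count_fusions(painting, 5) else 0L

  estimates <- {
    fa <- parse_fasta(file.path(data_dir, "codon_pairs.fasta"))
    ids <- unique(sub("_[ab]$", "", names(fa)))
    ng86_ka_ks(tibble(
      pair_id = ids,
      seq_a = unname(fa[paste0(ids, "_a")]),
      seq_b = unname(fa[paste0(ids, "_b")])
    ))
  }
  tsv_out(estimates, "kaks.tsv")
  ksd <- ks_distribution(estimates, ks_max = 1)
  tsv_out(ksd$histogram, "ks_histogram.tsv")

  ltr_fa2 <- parse_fasta(file.path(data_dir, "ltr_pairs.fasta"))
  el <- unique(sub("_[53]LTR$", "", names(ltr_fa2)))
  ages <- ltr_insertion_age(
    tibble(element_id = el,
           ltr5 = unname(ltr_fa2[paste0(el, "_5LTR")]),
           ltr3 = unname(ltr_fa2[paste0(el, "_3LTR")])),
    mu = mu
  )
  tsv_out(ages, "ltr_ages.tsv")
  asum <- age_summary(ages)
  jsonlite::write_json(
    list(seed = seed, mu = mu, mode_age = asum$mode_age,
         quantiles = as.list(asum$quantiles), n_used = asum$n_used),
    file.path(res_dir, "ltr_summary.json"), auto_unbox = TRUE, digits = NA
  )

  expr <- read_expression(file.path(data_dir, "expression.tsv"))
  expressed <- prefilter_expressed(expr)
  rhythm <- detect_rhythmicity(expr[expr$gene_id %in% expressed, ])
  tsv_out(rhythm[, setdiff(names(rhythm), "degenerate")], "rhythmicity.tsv")
  prof <- mean_profiles(expr[expr$gene_id %in% rhythm$gene_id[rhythm$rhythmic], ])
  clusters <- if (nrow(prof) >= 9) cluster_profiles(prof, k = 9) else tibble()
  tsv_out(clusters, "clusters.tsv")
  # CAM classification against model references: the gene's planted-phase
  # cosine (CAM reference) and its 12 h antiphase (C3 stand-in)
  tp <- sort(unique(expr$timepoint))
  cam_calls <- prof |>
    rowwise() |>
    mutate(call = {
      y <- c_across(-"gene_id")
      ph <- dp$truth$phase[dp$truth$gene_id == .data$gene_id]
      if (is.na(ph)) ph <- tp[which.max(y)] # non-planted gene: use observed peak
      ref_cam <- cos(2 * pi * (tp - ph) / 24)
      ref_c3 <- cos(2 * pi * (tp - ph - 12) / 24)
      c1 <- diel_correlation(y, ref_c3)
      c2 <- diel_correlation(y, ref_cam)
      classify_cam(c1$r_pearson, c1$r_spearman, c2$r_pearson, c2$r_spearman)
    }) |>
    ungroup() |>
    select("gene_id", "call")
  tsv_out(cam_calls, "cam_classification.tsv")

  promoters2 <- parse_fasta(file.path(data_dir, "promoters.fasta"))
  motif_tab <- promoter_motif_table(promoters2)
  tsv_out(motif_tab[, c("gene_id", "motif", "count")], "motif_counts.tsv")
  enr <- motif_enrichment(motif_tab, groups)
  tsv_out(enr, "motif_enrichment.tsv")

  invisible(list(
    expansion = expansion, arrays = arrays, lineage = lineage,
    blocks = blocks, fusions = fusions, kaks = estimates, ks = ksd,
    ltr_ages = ages, ltr_summary = asum, rhythmicity = rhythm,
    clusters = clusters, cam_calls = cam_calls,
    motif_counts = motif_tab, enrichment = enr,
    truth = list(expansion = cm$truth, arrays = gl$truth$arrays,
                 blocks = gl$truth$blocks, diel = dp$truth)
  ))
}
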
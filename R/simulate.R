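# Synthetic-data generators with planted, recorded ground truth. Every
# generator is a pure function of its parameters plus seed (reruns are
# byte-identical) and the returned `truth` is sufficient to score downstream
# sensitivity/FDR without re-reading the parameters.

.sample1 <- function(x) x[sample.int(length(x), 1)]

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate an orthogroup-by-species gene count matrix with planted expansions
#'
#' Emulates an 18-genome orthogroup count matrix split into a focal
#' "succulent" block of `n_species_a` species and a background block of
#' `n_species_b` species. Background counts are Poisson with mean `lambda`
#' everywhere; a planted fraction of orthogroups draws its group-A counts at
#' `lambda * fold_effect` instead, so `fold_effect = 1` is the global null.
#'
#' @param n_orthogroups Number of orthogroups, default 2000.
#' @param n_species_a,n_species_b Group sizes, defaults 5 and 13.
#' @param lambda Background Poisson mean per species, default 2.
#' @param planted_fraction Fraction of orthogroups planted as expanded in
#'   group A, default 0.05.
#' @param fold_effect Multiplier on `lambda` in group A for planted
#'   orthogroups (>= 1), default 4.
#' @param seed Integer seed.
#' @return List: `counts` (tibble), `truth` (tibble with `orthogroup`,
#'   `planted`), `group_a`, `group_b`, `params`.
#' @export
#' @examples
#' sim <- sim_count_matrix(n_orthogroups = 100, seed = 7)
#' sum(sim$truth$planted)
sim_count_matrix <- function(n_orthogroups = 2000, n_species_a = 5,
                             n_species_b = 13, lambda = 2,
                             planted_fraction = 0.05, fold_effect = 4,
                             seed = 1) {
  stopifnot(lambda > 0, fold_effect >= 1,
            planted_fraction >= 0, planted_fraction <= 1,
            n_orthogroups >= 1, n_species_a >= 1, n_species_b >= 1)
  .with_seed(seed, {
    group_a <- sprintf("S%d", seq_len(n_species_a))
    group_b <- sprintf("O%d", seq_len(n_species_b))
    og <- sprintf("OG%05d", seq_len(n_orthogroups))
    n_planted <- round(planted_fraction * n_orthogroups)
    planted <- rep(FALSE, n_orthogroups)
    if (n_planted > 0) planted[sample.int(n_orthogroups, n_planted)] <- TRUE
    lam_a <- ifelse(planted, lambda * fold_effect, lambda)
    A <- matrix(rpois(n_orthogroups * n_species_a, rep(lam_a, n_species_a)),
                nrow = n_orthogroups)
    B <- matrix(rpois(n_orthogroups * n_species_b, lambda),
                nrow = n_orthogroups)
    colnames(A) <- group_a
    colnames(B) <- group_b
    counts <- bind_cols(tibble(orthogroup = og), as_tibble(A), as_tibble(B))
    list(
      counts = counts,
      truth = tibble(orthogroup = og, planted = planted),
      group_a = group_a, group_b = group_b,
      params = list(
        n_orthogroups = n_orthogroups, n_species_a = n_species_a,
        n_species_b = n_species_b, lambda = lambda,
        planted_fraction = planted_fraction, fold_effect = fold_effect,
        seed = seed
      )
    )
  })
}

#' Simulate two toy genomes with planted tandem arrays and collinear blocks
#'
#' Builds two annotated genomes ("cr" and "vv") whose genes sit at regular
#' coordinates, plants non-overlapping tandem arrays (runs of mutually
#' homologous genes separated by at most `max_intervening` non-members) in
#' each genome, plants collinear blocks (rank-monotone anchor chains between
#' the genomes, inverted with probability `inversion_probability`), and emits
#' the homology hit table covering exactly the planted relationships plus
#' `n_noise_hits` random spurious pairs.
#'
#' @param n_chromosomes Chromosomes per genome, default 2.
#' @param genes_per_chromosome Genes per chromosome, default 100.
#' @param n_tandem_arrays Arrays planted per genome, default 3.
#' @param array_size_range Min/max genes per array, default c(2, 4).
#' @param max_intervening Gap genes allowed inside planted arrays, default 0.
#' @param n_collinear_blocks Cross-genome blocks, default 2.
#' @param block_length_range Min/max anchors per block, default c(12, 15).
#' @param inversion_probability Probability a block is inverted, default 0.3.
#' @param n_noise_hits Random spurious homology hits, default 0.
#' @param seed Integer seed.
#' @return List: `ann_a`, `ann_b` (annotations), `hits` (12-column tibble),
#'   `truth` (list with `arrays` and `blocks` tibbles), `params`.
#' @export
sim_genome_layout <- function(n_chromosomes = 2, genes_per_chromosome = 100,
                              n_tandem_arrays = 3, array_size_range = c(2, 4),
                              max_intervening = 0, n_collinear_blocks = 2,
                              block_length_range = c(12, 15),
                              inversion_probability = 0.3,
                              n_noise_hits = 0, seed = 1) {
  stopifnot(n_chromosomes >= 1, genes_per_chromosome >= 10,
            array_size_range[1] >= 2,
            array_size_range[2] >= array_size_range[1],
            block_length_range[2] >= block_length_range[1],
            inversion_probability >= 0, inversion_probability <= 1)
  .with_seed(seed, {
    make_genome <- function(tag) {
      purrr::map_dfr(seq_len(n_chromosomes), function(ch) {
        tibble(
          gene_id = sprintf("%s_c%d_g%03d", tag, ch, seq_len(genes_per_chromosome)),
          chrom = sprintf("%s_chr%d", tag, ch),
          start = (seq_len(genes_per_chromosome) - 1) * 1000,
          end = (seq_len(genes_per_chromosome) - 1) * 1000 + 500,
          strand = "+",
          rank = seq_len(genes_per_chromosome) - 1L
        )
      })
    }
    ann_a <- make_genome("cr")
    ann_b <- make_genome("vv")
    anns <- list(cr = ann_a, vv = ann_b)

    # reserve non-overlapping rank windows per chromosome
    chrom_names <- unique(c(ann_a$chrom, ann_b$chrom))
    used <- setNames(vector("list", length(chrom_names)), chrom_names)
    used[] <- list(integer(0))
    reserve <- function(chrom, width) {
      taken <- used[[chrom]]
      cand <- setdiff(0:(genes_per_chromosome - width), unlist(
        lapply(taken, function(r) (r - width - max_intervening):(r + width + max_intervening))
      ))
      cand <- cand[cand >= 0]
      if (length(cand) == 0) {
        abort("requested arrays/blocks exceed chromosome capacity")
      }
      s <- .sample1(cand)
      used[[chrom]] <<- c(taken, s:(s + width - 1))
      s
    }

    hit_rows <- list()
    add_hits <- function(g1, g2, score = 200) {
      hit_rows[[length(hit_rows) + 1]] <<- tibble(
        query_id = g1, subject_id = g2, percent_identity = 95,
        alignment_length = 300, mismatches = 10, gap_opens = 0,
        q_start = 1, q_end = 300, s_start = 1, s_end = 300,
        evalue = 1e-50, bitscore = score
      )
    }

    # tandem arrays: planted in both genomes alternately
    arrays <- list()
    for (i in seq_len(n_tandem_arrays)) {
      genome <- if (i %% 2 == 1) "cr" else "vv"
      ann <- anns[[genome]]
      size <- .sample1(array_size_range[1]:array_size_range[2])
      gaps <- if (max_intervening > 0) {
        sample(0:max_intervening, size - 1, replace = TRUE)
      } else {
        rep(0L, size - 1)
      }
      width <- size + sum(gaps)
      chrom <- .sample1(unique(ann$chrom))
      s <- reserve(chrom, width)
      ranks <- s + cumsum(c(0, gaps + 1))
      members <- ann$gene_id[ann$chrom == chrom][ranks + 1]
      for (p in seq_len(size - 1)) {
        for (q in (p + 1):size) add_hits(members[p], members[q])
      }
      arrays[[i]] <- tibble(
        array_id = sprintf("planted_arr%d", i), genome = genome,
        chrom = chrom, gene_id = members, rank = ranks
      )
    }

    # collinear blocks between genomes
    blocks <- list()
    for (i in seq_len(n_collinear_blocks)) {
      L <- .sample1(block_length_range[1]:block_length_range[2])
      chrom_a <- .sample1(unique(ann_a$chrom))
      chrom_b <- .sample1(unique(ann_b$chrom))
      sa <- reserve(chrom_a, L)
      sb <- reserve(chrom_b, L)
      inverted <- runif(1) < inversion_probability
      ga <- ann_a$gene_id[ann_a$chrom == chrom_a][sa + seq_len(L)]
      gb <- ann_b$gene_id[ann_b$chrom == chrom_b][sb + seq_len(L)]
      if (inverted) gb <- rev(gb)
      purrr::walk2(ga, gb, add_hits)
      blocks[[i]] <- tibble(
        block_id = sprintf("planted_block%d", i),
        chrom_a = chrom_a, chrom_b = chrom_b,
        orientation = if (inverted) "inverted" else "same",
        gene_a = ga, gene_b = gb
      )
    }

    # noise hits: random pairs not already planted
    all_genes <- c(ann_a$gene_id, ann_b$gene_id)
    for (i in seq_len(n_noise_hits)) {
      pair <- sample(all_genes, 2)
      add_hits(pair[1], pair[2], score = 60)
    }

    list(
      ann_a = ann_a, ann_b = ann_b,
      hits = bind_rows(hit_rows),
      truth = list(
        arrays = if (length(arrays)) bind_rows(arrays) else tibble(),
        blocks = if (length(blocks)) bind_rows(blocks) else tibble()
      ),
      params = list(
        n_chromosomes = n_chromosomes,
        genes_per_chromosome = genes_per_chromosome,
        n_tandem_arrays = n_tandem_arrays,
        array_size_range = array_size_range,
        max_intervening = max_intervening,
        n_collinear_blocks = n_collinear_blocks,
        block_length_range = block_length_range,
        inversion_probability = inversion_probability,
        n_noise_hits = n_noise_hits, seed = seed
      )
    )
  })
}

.iupac_bases <- function(code) {
  switch(code,
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
    abort(sprintf("illegal IUPAC code '%s'", code))
  )
}

#' Simulate codon alignment pairs with exact planted substitution counts
#'
#' Each pair starts from a random gap-free CDS of sense codons; exactly
#' `syn_subs` synonymous and `nonsyn_subs` nonsynonymous single-nucleotide
#' changes are applied, each in a distinct codon (so the planted
#' synonymous/nonsynonymous difference counts are pathway-unambiguous), and
#' every change is verified against the standard genetic code. Stop codons
#' never occur in either sequence.
#'
#' @param n_pairs Number of pairs, default 50.
#' @param n_codons Codons per sequence, default 100.
#' @param syn_subs,nonsyn_subs Planted substitution counts per pair.
#' @param seed Integer seed.
#' @return List: `pairs` (tibble `pair_id`, `seq_a`, `seq_b`), `truth`
#'   (tibble with planted `syn_subs`, `nonsyn_subs` per pair), `params`.
#' @export
sim_codon_pairs <- function(n_pairs = 50, n_codons = 100, syn_subs = 2,
                            nonsyn_subs = 3, seed = 1) {
  if (syn_subs + nonsyn_subs > n_codons) {
    abort("requested substitutions exceed the number of codons")
  }
  code <- .genetic_code()
  sense <- .sense_codons()
  # precompute synonymous / nonsynonymous sense neighbours per codon
  nbrs <- purrr::map(setNames(nm = sense), .codon_neighbours)
  syn_nb <- purrr::map(setNames(nm = sense), function(cd) {
    nb <- nbrs[[cd]]
    nb[code[nb] == code[cd] & code[nb] != "*"]
  })
  non_nb <- purrr::map(setNames(nm = sense), function(cd) {
    nb <- nbrs[[cd]]
    nb[code[nb] != code[cd] & code[nb] != "*"]
  })
  .with_seed(seed, {
    out <- purrr::map(seq_len(n_pairs), function(i) {
      codons_a <- sample(sense, n_codons, replace = TRUE)
      ok_syn <- which(lengths(syn_nb[codons_a]) > 0)
      ok_non <- which(lengths(non_nb[codons_a]) > 0)
      if (length(ok_syn) < syn_subs) {
        abort("not enough codons with synonymous neighbours; request infeasible")
      }
      pos_syn <- if (syn_subs > 0) sample(ok_syn, syn_subs) else integer(0)
      ok_non <- setdiff(ok_non, pos_syn)
      if (length(ok_non) < nonsyn_subs) {
        abort("not enough codons with nonsynonymous neighbours; request infeasible")
      }
      pos_non <- if (nonsyn_subs > 0) sample(ok_non, nonsyn_subs) else integer(0)
      codons_b <- codons_a
      for (p in pos_syn) {
        ch <- syn_nb[[codons_a[p]]]
        codons_b[p] <- if (length(ch) == 1) ch else sample(ch, 1)
      }
      for (p in pos_non) {
        ch <- non_nb[[codons_a[p]]]
        codons_b[p] <- if (length(ch) == 1) ch else sample(ch, 1)
      }
      list(
        pair = tibble(
          pair_id = sprintf("pair%03d", i),
          seq_a = paste(codons_a, collapse = ""),
          seq_b = paste(codons_b, collapse = "")
        ),
        truth = tibble(
          pair_id = sprintf("pair%03d", i),
          syn_subs = syn_subs, nonsyn_subs = nonsyn_subs,
          syn_codons = list(pos_syn), nonsyn_codons = list(pos_non)
        )
      )
    })
    list(
      pairs = bind_rows(purrr::map(out, "pair")),
      truth = bind_rows(purrr::map(out, "truth")),
      params = list(n_pairs = n_pairs, n_codons = n_codons,
                    syn_subs = syn_subs, nonsyn_subs = nonsyn_subs,
                    seed = seed)
    )
  })
}

#' Simulate diel expression profiles with planted circadian phases
#'
#' Rhythmic genes follow `FPKM = exp(b + a cos(2 pi (t - phi) / 24) + e)`
#' with `e ~ N(0, noise_sd)` on the log scale (so noise is lognormal,
#' respecting FPKM positivity); flat genes have `a = 0`. The default design
#' mirrors a 24-hour sampling at 3-hour intervals with the start time
#' repeated at the end (9 timepoints, hours 0..24) and 3 replicates.
#'
#' @param n_genes Number of genes, default 300.
#' @param timepoints Sampling times in hours, default `seq(0, 24, by = 3)`.
#' @param replicates Replicates per timepoint, default 3.
#' @param rhythmic_fraction Fraction of genes planted rhythmic, default 0.3.
#' @param amplitude Cosine amplitude `a` on the natural-log scale, default 2.
#' @param phases Candidate peak phases (hours), default `c(0, 6, 12, 18)`.
#' @param noise_sd Log-scale noise SD, default 0.5.
#' @param baseline_range Range of the per-gene log baseline `b`, default
#'   c(1, 3).
#' @param seed Integer seed.
#' @return List: `expr` (long tibble), `truth` (tibble with `rhythmic`,
#'   `phase`, `amplitude`, `baseline`), `params`.
#' @export
sim_diel_profiles <- function(n_genes = 300, timepoints = seq(0, 24, by = 3),
                              replicates = 3, rhythmic_fraction = 0.3,
                              amplitude = 2, phases = c(0, 6, 12, 18),
                              noise_sd = 0.5, baseline_range = c(1, 3),
                              seed = 1) {
  stopifnot(replicates >= 2, amplitude >= 0, noise_sd >= 0,
            rhythmic_fraction >= 0, rhythmic_fraction <= 1)
  .with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    n_rhythmic <- round(rhythmic_fraction * n_genes)
    rhythmic <- rep(FALSE, n_genes)
    if (n_rhythmic > 0) rhythmic[sample.int(n_genes, n_rhythmic)] <- TRUE
    phase <- ifelse(rhythmic, sample(phases, n_genes, replace = TRUE), NA_real_)
    b <- runif(n_genes, baseline_range[1], baseline_range[2])
    a <- ifelse(rhythmic, amplitude, 0)
    grid <- tidyr::expand_grid(
      gene_idx = seq_len(n_genes),
      timepoint = timepoints,
      replicate = seq_len(replicates)
    )
    mu <- b[grid$gene_idx] +
      a[grid$gene_idx] *
        cos(2 * pi * (grid$timepoint - dplyr::coalesce(phase[grid$gene_idx], 0)) / 24)
    eps <- if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0
    expr <- tibble(
      gene_id = genes[grid$gene_idx],
      timepoint = grid$timepoint,
      replicate = grid$replicate,
      fpkm = exp(mu + eps)
    )
    list(
      expr = expr,
      truth = tibble(gene_id = genes, rhythmic = rhythmic, phase = phase,
                     amplitude = a, baseline = b),
      params = list(n_genes = n_genes, timepoints = timepoints,
                    replicates = replicates,
                    rhythmic_fraction = rhythmic_fraction,
                    amplitude = amplitude, phases = phases,
                    noise_sd = noise_sd, baseline_range = baseline_range,
                    seed = seed)
    )
  })
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' Background bases are i.i.d. uniform A/C/G/T; planted motif instances
#' (degenerate IUPAC positions instantiated at random) are inserted at
#' recorded positions without overlapping one another. `planted_rate` is the
#' expected number of planted instances per promoter: the integer part is
#' always inserted and the fractional part is a Bernoulli draw, so a rate of
#' 1 plants exactly one instance per promoter and 0.8 plants one instance in
#' 80% of promoters.
#'
#' @param n_genes Number of promoters, default 200.
#' @param length Promoter length in bp, default 2000.
#' @param motif IUPAC consensus to plant, default the evening element.
#' @param planted_rate Expected planted instances per promoter, default 1.
#' @param seed Integer seed.
#' @return List: `promoters` (named character vector), `truth` (tibble with
#'   `gene_id`, `n_planted`, `positions` list-column of 0-based starts),
#'   `params`.
#' @export
sim_promoters <- function(n_genes = 200, length = 2000,
                          motif = "AAAATATCT", planted_rate = 1, seed = 1) {
  motif <- .check_iupac(motif)
  m <- nchar(motif)
  stopifnot(length >= m, planted_rate >= 0)
  max_cap <- floor(length / m)
  if (ceiling(planted_rate) > max_cap) {
    abort("requested insertions exceed promoter capacity")
  }
  codes <- strsplit(motif, "")[[1]]
  .with_seed(seed, {
    genes <- sprintf("prom%04d", seq_len(n_genes))
    bases <- c("A", "C", "G", "T")
    out <- purrr::map(seq_len(n_genes), function(i) {
      seq <- sample(bases, length, replace = TRUE)
      n_ins <- floor(planted_rate) +
        rbinom(1, 1, planted_rate - floor(planted_rate))
      pos <- integer(0)
      tries <- 0
      while (length(pos) < n_ins) {
        cand <- sample.int(length - m + 1, 1) - 1L # 0-based
        if (!any(abs(cand - pos) < m)) {
          pos <- c(pos, cand)
        }
        tries <- tries + 1
        if (tries > 1000 * max(n_ins, 1)) {
          abort("requested insertions exceed promoter capacity")
        }
      }
      for (p in pos) {
        inst <- purrr::map_chr(codes, function(cd) {
          ch <- .iupac_bases(cd)
          if (length(ch) == 1) ch else sample(ch, 1)
        })
        seq[(p + 1):(p + m)] <- inst
      }
      list(seq = paste(seq, collapse = ""),
           truth = tibble(gene_id = genes[i], n_planted = length(pos),
                          positions = list(sort(pos))))
    })
    list(
      promoters = setNames(purrr::map_chr(out, "seq"), genes),
      truth = bind_rows(purrr::map(out, "truth")),
      params = list(n_genes = n_genes, length = length, motif = motif,
                    planted_rate = planted_rate, seed = seed)
    )
  })
}

#' Simulate aligned 5'/3' LTR pairs at a planted age distribution
#'
#' Ages are drawn from a normal distribution (truncated at 0); each element's
#' expected divergence is `2 * mu * age` and its LTR pair is generated by
#' mutating a random ancestral LTR at per-site probability
#' `p = 3/4 (1 - exp(-4/3 K))` split between the two copies.
#'
#' @param n_elements Number of LTR elements, default 500.
#' @param ltr_length LTR length in bp, default 1000.
#' @param mean_age,sd_age Age distribution in years, defaults 80e3 and 10e3.
#' @param mu Substitution rate (subs/site/year), default 1.3e-8.
#' @param seed Integer seed.
#' @return List: `pairs` (tibble `element_id`, `ltr5`, `ltr3`), `truth`
#'   (tibble with planted `age_years`), `params`.
#' @export
sim_ltr_pairs <- function(n_elements = 500, ltr_length = 1000,
                          mean_age = 80e3, sd_age = 10e3, mu = 1.3e-8,
                          seed = 1) {
  stopifnot(mu > 0, ltr_length >= 10)
  .with_seed(seed, {
    ids <- sprintf("ltr%04d", seq_len(n_elements))
    ages <- pmax(rnorm(n_elements, mean_age, sd_age), 0)
    bases <- c("A", "C", "G", "T")
    mutate_seq <- function(seq, p_site) {
      hit <- runif(length(seq)) < p_site
      if (any(hit)) {
        seq[hit] <- vapply(seq[hit], function(b) sample(setdiff(bases, b), 1), "")
      }
      seq
    }
    out <- purrr::map(seq_len(n_elements), function(i) {
      anc <- sample(bases, ltr_length, replace = TRUE)
      K <- 2 * mu * ages[i]
      # JC69 forward: expected observed mismatch fraction for divergence K
      p <- 0.75 * (1 - exp(-4 / 3 * K))
      # split the divergence across the two copies
      half <- 0.75 * (1 - exp(-4 / 3 * K / 2))
      tibble(
        element_id = ids[i],
        ltr5 = paste(mutate_seq(anc, half), collapse = ""),
        ltr3 = paste(mutate_seq(anc, half), collapse = "")
      )
    })
    list(
      pairs = bind_rows(out),
      truth = tibble(element_id = ids, age_years = ages),
      params = list(n_elements = n_elements, ltr_length = ltr_length,
                    mean_age = mean_age, sd_age = sd_age, mu = mu, seed = seed)
    )
  })
}
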
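#' Read a FASTA file into a named character vector
#'
#' Order-preserving; sequences are uppercased and RNA `U` is normalised to
#' `T`. Duplicate identifiers are an error; an empty file yields an empty
#' mapping with a warning. Identifiers are taken up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping sequence id to sequence.
#' @export
parse_fasta <- function(path) {
  stopifnot(file.exists(path))
  recs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) NULL
  )
  if (is.null(recs) || length(recs) == 0) {
    warn(sprintf("no FASTA records in '%s'", path))
    return(setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate sequence identifier(s) in '%s': %s",
      path, paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- chartr("U", "T", toupper(as.character(recs)))
  setNames(unname(seqs), ids)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector (id -> sequence).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)) || length(seqs) == 0)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene loci from a GFF3 file
#'
#' Parses records of one feature type into an ordered gene table. GFF3
#' coordinates (1-based, inclusive) are converted to the package's internal
#' 0-based half-open convention at this boundary, and a 0-based `rank` (the
#' index of the gene in start order along its chromosome) is computed.
#' Records with start > end are rejected with a warning.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type to keep (column 3), default `"gene"`.
#' @param id_attr Attribute key holding the identifier, default `"ID"`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `rank`.
#' @export
parse_gff3 <- function(path, feature_type = "gene", id_attr = "ID") {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(
    path,
    comment = "#", col_names = paste0("c", 1:9),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  raw <- raw[raw$c3 == feature_type, , drop = FALSE]
  start1 <- suppressWarnings(as.numeric(raw$c4))
  end1 <- suppressWarnings(as.numeric(raw$c5))
  bad <- is.na(start1) | is.na(end1) | start1 > end1
  if (any(bad)) {
    warn(sprintf("rejected %d GFF3 record(s) with start > end or unparsable coordinates", sum(bad)))
  }
  raw <- raw[!bad, , drop = FALSE]
  ids <- stringr::str_match(raw$c9, paste0("(?:^|;)\\s*", id_attr, "=([^;]+)"))[, 2]
  ids <- ifelse(is.na(ids), raw$c9, ids)
  ann <- tibble(
    gene_id = ids,
    chrom = raw$c1,
    start = start1[!bad] - 1,       # 0-based half-open
    end = end1[!bad],
    strand = ifelse(raw$c7 %in% c("+", "-"), raw$c7, "+")
  )
  rank_annotation(ann)
}

#' Recompute per-chromosome gene ranks from start positions
#'
#' @param ann Annotation tibble with `gene_id`, `chrom`, `start` columns.
#' @return The tibble sorted by chromosome and start, with a 0-based `rank`
#'   column (ties broken by gene id for determinism).
#' @export
rank_annotation <- function(ann) {
  ann |>
    arrange(.data$chrom, .data$start, .data$gene_id) |>
    group_by(.data$chrom) |>
    mutate(rank = seq_len(n()) - 1L) |>
    ungroup()
}

#' Write a gene annotation tibble as GFF3
#'
#' Internal 0-based half-open coordinates are converted back to GFF3's
#' 1-based inclusive convention.
#'
#' @param ann Annotation tibble (see [parse_gff3()]).
#' @param path Output path.
#' @param feature_type Feature type for column 3.
#' @param source Value for column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path, feature_type = "gene", source = "camevol") {
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
      ann$chrom, source, feature_type,
      as.integer(ann$start + 1), as.integer(ann$end),
      ann$strand, ann$gene_id
    )
  )
  writeLines(lines, path)
  invisible(path)
}

.hit_cols <- c(
  "query_id", "subject_id", "percent_identity", "alignment_length",
  "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
  "evalue", "bitscore"
)

#' Read a 12-column tabular homology hit file
#'
#' The conventional 12-column tab-separated hit layout (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query/subject
#' coordinates, e-value, bit score). Rows with malformed numeric fields are
#' rejected with a warning. Self-hits are retained; downstream consumers
#' decide what to do with them.
#'
#' @param path Path to the tab-separated file (>= 12 columns; extras dropped).
#' @return Tibble with canonical hit columns.
#' @export
parse_hit_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(
    path, col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(as_tibble(setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10)), .hit_cols
    )))
  }
  if (ncol(raw) < 12) abort("hit table has fewer than 12 columns")
  raw <- raw[, 1:12]
  names(raw) <- .hit_cols
  num <- suppressWarnings(
    purrr::map(raw[, 3:12], as.numeric)
  )
  bad <- Reduce(`|`, purrr::map(num, is.na))
  if (any(bad)) {
    warn(sprintf("rejected %d hit row(s) with malformed numeric fields", sum(bad)))
  }
  out <- bind_cols(raw[, 1:2], as_tibble(num))[!bad, , drop = FALSE]
  out
}

#' Write homology hits in the 12-column tabular layout
#'
#' @param hits Tibble as returned by [parse_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits[, .hit_cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Filter homology hits to candidate family members
#'
#' A query survives when it has at least one hit with alignment length
#' strictly greater than `min_align_len` and e-value strictly smaller than
#' `max_evalue` — the screen used to nominate candidate CAM-pathway and
#' stomatal-movement gene family members from BLAST hits.
#'
#' @param hits Hit tibble (see [parse_hit_table()]).
#' @param min_align_len Minimal alignment length in bp (exclusive), default 100.
#' @param max_evalue Maximal e-value (exclusive), default 1e-5.
#' @return Sorted character vector of surviving query ids.
#' @export
#' @examples
#' hits <- tibble::tibble(
#'   query_id = c("g1", "g2"), subject_id = "ref",
#'   percent_identity = 90, alignment_length = c(150, 100),
#'   mismatches = 0, gap_opens = 0, q_start = 1, q_end = 150,
#'   s_start = 1, s_end = 150, evalue = c(1e-10, 1e-10), bitscore = 200
#' )
#' filter_homology_hits(hits) # g2 dropped: length not > 100
filter_homology_hits <- function(hits, min_align_len = 100, max_evalue = 1e-5) {
  stopifnot(min_align_len > 0, max_evalue > 0)
  keep <- hits$alignment_length > min_align_len & hits$evalue < max_evalue
  sort(unique(hits$query_id[keep]))
}

.validate_count_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "orthogroup" %in% names(counts))
  species <- setdiff(names(counts), "orthogroup")
  if (length(species) < 2) abort("count matrix needs at least 2 species")
  if (anyDuplicated(counts$orthogroup)) abort("duplicate orthogroup identifiers")
  vals <- as.matrix(counts[, species])
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
    abort("counts must be non-negative integers")
  }
  invisible(counts)
}

#' Read an orthogroup-by-species gene count matrix from TSV
#'
#' First column `orthogroup`, one column per species, non-negative integer
#' counts.
#'
#' @param path Path to the TSV file.
#' @return Validated count tibble.
#' @export
read_count_matrix <- function(path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    orthogroup = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  .validate_count_matrix(counts)
  counts
}

#' Write a gene count matrix as TSV
#'
#' @param counts Count tibble (see [read_count_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read an OrthoMCL-style groups file into a count matrix
#'
#' Each line is `OG1: spA|g1 spA|g2 spB|g3`; the species prefix before the
#' delimiter is counted per group. A gene token without a parsable species
#' prefix is a hard error naming the token; an empty group becomes a row of
#' zeros with a warning.
#'
#' @param path Path to the groups file.
#' @param species_delim Single-character delimiter between species and gene,
#'   default `"|"`.
#' @return Count tibble with one column per species seen in the file.
#' @export
read_groups_file <- function(path, species_delim = "|") {
  stopifnot(file.exists(path), nchar(species_delim) == 1)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(lines, ":", 2)
  og_ids <- trimws(parts[, 1])
  members <- stringr::str_split(trimws(parts[, 2]), "\\s+")
  members <- purrr::map(members, function(x) x[nzchar(x)])
  if (any(lengths(members) == 0)) {
    warn(sprintf("%d empty group(s) read as all-zero rows", sum(lengths(members) == 0)))
  }
  all_tokens <- unlist(members)
  has_prefix <- stringr::str_detect(all_tokens, stringr::fixed(species_delim))
  if (any(!has_prefix)) {
    abort(sprintf("gene token without species prefix: '%s'", all_tokens[!has_prefix][1]))
  }
  species_of <- function(tok) {
    stringr::str_split_fixed(tok, stringr::fixed(species_delim), 2)[, 1]
  }
  species <- sort(unique(species_of(all_tokens)))
  counts <- purrr::map(members, function(m) {
    tab <- table(factor(species_of(m), levels = species))
    as.integer(tab)
  })
  mat <- do.call(rbind, counts)
  colnames(mat) <- species
  out <- bind_cols(tibble(orthogroup = og_ids), as_tibble(mat))
  .validate_count_matrix(out)
  out
}

#' Write a count matrix as an OrthoMCL-style groups file
#'
#' Member gene ids are synthesised as `<species><delim><orthogroup>_<i>`;
#' round-tripping through [read_groups_file()] recovers the counts.
#'
#' @param counts Count tibble.
#' @param path Output path.
#' @param species_delim Species/gene delimiter.
#' @return `path`, invisibly.
#' @export
write_groups_file <- function(counts, path, species_delim = "|") {
  species <- setdiff(names(counts), "orthogroup")
  lines <- purrr::map_chr(seq_len(nrow(counts)), function(i) {
    toks <- unlist(purrr::map(species, function(sp) {
      n <- counts[[sp]][i]
      if (n == 0) return(character(0))
      paste0(sp, species_delim, counts$orthogroup[i], "_", seq_len(n))
    }))
    paste0(counts$orthogroup[i], ": ", paste(toks, collapse = " "))
  })
  writeLines(lines, path)
  invisible(path)
}
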
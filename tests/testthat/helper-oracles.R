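# Independent oracle implementations used to cross-check the package.
# Deliberately written from the definitions (direct summation, recursive
# enumeration, position-by-position scanning), not by calling package code.

# upper/lower binomial tail by direct pmf summation with choose()
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}
oracle_binom_lower <- function(k, n, p) {
  sum(vapply(0:k, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

# BH step-up from the definition: q_(i) = min_{j >= i} ( m * p_(j) / j )
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# NG86 sites + differences by recursive pathway enumeration
oracle_ng86 <- function(seq_a, seq_b) {
  GC <- Biostrings::GENETIC_CODE
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(seq_a)
  cb <- split3(seq_b)
  site_count <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (substr(codon, pos, pos) == b) next
        mut <- codon
        substr(mut, pos, pos) <- b
        if (GC[[mut]] != "*" && GC[[mut]] == GC[[codon]]) s <- s + 1 / 3
      }
    }
    s
  }
  # depth-first enumeration of substitution orders; a path is "ok" when no
  # intermediate codon is a stop
  enum_paths <- function(from, to) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (length(pos) == 0) {
      return(list(list(sd = 0, nd = 0, ok = TRUE)))
    }
    out <- list()
    for (p in pos) {
      mid <- from
      substr(mid, p, p) <- substr(to, p, p)
      step_syn <- GC[[from]] == GC[[mid]]
      mid_stop <- GC[[mid]] == "*"
      for (tail_path in enum_paths(mid, to)) {
        out[[length(out) + 1]] <- list(
          sd = tail_path$sd + as.integer(step_syn),
          nd = tail_path$nd + as.integer(!step_syn),
          ok = tail_path$ok && !mid_stop
        )
      }
    }
    out
  }
  S <- (sum(vapply(ca, site_count, 0)) + sum(vapply(cb, site_count, 0))) / 2
  N <- 3 * length(ca) - S
  Sd <- 0
  Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    paths <- enum_paths(ca[i], cb[i])
    ok <- vapply(paths, function(x) x$ok, TRUE)
    use <- if (any(ok)) paths[ok] else paths
    Sd <- Sd + mean(vapply(use, function(x) x$sd, 0))
    Nd <- Nd + mean(vapply(use, function(x) x$nd, 0))
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

# best chain score by exhaustive enumeration over all anchor subsets (<= 12
# anchors, one chromosome pair); chains of any length >= 1 allowed
oracle_best_chain_score <- function(anchors, max_gap, gap_penalty) {
  n <- nrow(anchors)
  stopifnot(n <= 12)
  best <- -Inf
  bits <- 2^(0:(n - 1))
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, bits) > 0)
    ord <- idx[order(anchors$rank_a[idx])]
    ra <- anchors$rank_a[ord]
    rb <- anchors$rank_b[ord]
    if (anyDuplicated(ra)) next
    if (length(ord) == 1) {
      best <- max(best, anchors$score[ord])
      next
    }
    for (dir in c(1, -1)) {
      if (all(diff(dir * rb) > 0)) {
        ga <- diff(ra) - 1
        gb <- abs(diff(rb)) - 1
        if (all(ga < max_gap) && all(gb < max_gap)) {
          sc <- sum(anchors$score[ord]) - gap_penalty * sum(ga + gb)
          best <- max(best, sc)
        }
      }
    }
  }
  best
}

# tandem arrays from the growth definition: seed every homologous pair in
# the rank window, then alternately close each set (absorb any gene
# homologous to a member and within the window of its nearest member) and
# merge overlapping sets, until nothing changes
oracle_tandem_arrays <- function(ann, pairs, max_intervening) {
  rank_of <- setNames(ann$rank, ann$gene_id)
  chrom_of <- setNames(ann$chrom, ann$gene_id)
  hom <- function(x, y) {
    any((pairs$a == x & pairs$b == y) | (pairs$a == y & pairs$b == x))
  }
  window <- max_intervening + 1
  sets <- list()
  gene_ids <- ann$gene_id
  for (i in seq_along(gene_ids)) {
    for (j in seq_along(gene_ids)) {
      if (j <= i) next
      x <- gene_ids[i]
      y <- gene_ids[j]
      if (chrom_of[x] == chrom_of[y] && hom(x, y) &&
          abs(rank_of[x] - rank_of[y]) <= window) {
        sets[[length(sets) + 1]] <- c(x, y)
      }
    }
  }
  if (length(sets) == 0) return(list())
  repeat {
    before <- sets
    # close
    sets <- lapply(sets, function(s) {
      repeat {
        added <- FALSE
        for (g in setdiff(gene_ids[chrom_of == chrom_of[s[1]]], s)) {
          if (min(abs(rank_of[g] - rank_of[s])) <= window &&
              any(vapply(s, function(m) hom(g, m), TRUE))) {
            s <- c(s, g)
            added <- TRUE
          }
        }
        if (!added) break
      }
      s
    })
    # merge overlapping
    merged <- list()
    for (s in sets) {
      hit <- which(vapply(merged, function(m) length(intersect(m, s)) > 0, TRUE))
      if (length(hit) == 0) {
        merged[[length(merged) + 1]] <- s
      } else {
        merged[[hit[1]]] <- union(merged[[hit[1]]], s)
        if (length(hit) > 1) merged[hit[-1]] <- NULL
      }
    }
    sets <- merged
    if (identical(
      lapply(sets, function(s) sort(s)),
      lapply(before, function(s) sort(s))
    )) {
      break
    }
  }
  lapply(sets, sort)
}

# naive position-by-position IUPAC scan (0-based starts)
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
.iupac_comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")
oracle_revcomp <- function(pattern) {
  paste(rev(unname(.iupac_comp[strsplit(pattern, "")[[1]]])), collapse = "")
}
oracle_scan_forward <- function(sequence, pattern) {
  s <- strsplit(sequence, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  m <- length(p)
  hits <- integer(0)
  if (length(s) < m) return(hits)
  for (start in 0:(length(s) - m)) {
    ok <- TRUE
    for (k in seq_len(m)) {
      if (!(s[start + k] %in% .iupac_sets[[p[k]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, start)
  }
  hits
}
oracle_scan <- function(sequence, pattern, strand = "both") {
  fwd <- oracle_scan_forward(sequence, pattern)
  if (strand == "forward") return(sort(fwd))
  rc <- oracle_revcomp(pattern)
  if (rc == pattern) return(sort(fwd))
  sort(c(fwd, oracle_scan_forward(sequence, rc)))
}

# random IUPAC pattern / DNA sequence generators for fuzzing
random_pattern <- function(len) {
  paste(sample(names(.iupac_sets), len, replace = TRUE,
               prob = c(rep(5, 4), rep(1, 11))), collapse = "")
}
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# partitions agree up to label renaming
same_partition <- function(f1, f2) {
  all(apply(table(f1, f2) > 0, 1, sum) == 1) &&
    all(apply(table(f1, f2) > 0, 2, sum) == 1)
}
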
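# Standard genetic code helpers shared by the Ka/Ks estimator and the codon
# pair simulator. The code table comes from Biostrings; everything here is
# precomputed once at load time.

.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.codon_env$code)) {
    code <- Biostrings::GENETIC_CODE
    .codon_env$code <- setNames(as.character(code), names(code))
  }
  .codon_env$code
}

.is_stop_codon <- function(codon) {
  unname(.genetic_code()[codon] == "*")
}

.sense_codons <- function() {
  code <- .genetic_code()
  names(code)[code != "*"]
}

#' @noRd
#' All nine single-base neighbours of a codon, as a character vector.
.codon_neighbours <- function(codon) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  out <- character(9)
  i <- 1L
  for (pos in 1:3) {
    for (b in bases[bases != chars[pos]]) {
      nb <- chars
      nb[pos] <- b
      out[i] <- paste(nb, collapse = "")
      i <- i + 1L
    }
  }
  out
}

# Per-codon synonymous site count: at each of the three positions, the number
# of the three possible single-base changes that preserve the amino acid,
# divided by 3 (changes to stop codons are not synonymous). Summed over
# positions; nonsynonymous sites are 3 minus this.
.syn_sites_table <- function() {
  if (is.null(.codon_env$syn_sites)) {
    code <- .genetic_code()
    sense <- .sense_codons()
    s <- setNames(numeric(length(sense)), sense)
    for (codon in sense) {
      aa <- code[codon]
      nb <- .codon_neighbours(codon)
      s[codon] <- sum(code[nb] == aa & code[nb] != "*") / 3
    }
    .codon_env$syn_sites <- s
  }
  .codon_env$syn_sites
}

#' @noRd
#' Split a nucleotide string into codons; errors if not a multiple of 3.
.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) {
    abort(sprintf("sequence length %d is not divisible by 3", n))
  }
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}
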
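# Independent brute-force oracles used to cross-check the implementation.

# Enumerate ORFs by testing every position/frame for ATG and walking codons
# to the first stop. Deliberately naive and independent of scan_orfs().
oracle_scan_orfs <- function(seq, min_codons, max_codons = 80L,
                             mode = "longest_per_stop") {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  rows <- list()
  for (p in seq_len(max(L - 2L, 0L))) {        # 1-based start of codon
    if (substr(seq, p, p + 2L) != "ATG") next
    frame <- (p - 1L) %% 3L
    q <- p
    stop_at <- NA_integer_
    repeat {
      q <- q + 3L
      if (q + 2L > L) break
      codon <- substr(seq, q, q + 2L)
      if (grepl("N", codon, fixed = TRUE)) break
      if (codon %in% stops) { stop_at <- q; break }
    }
    if (is.na(stop_at)) next
    n <- (stop_at - p) %/% 3L
    if (n < min_codons || n > max_codons) next
    rows[[length(rows) + 1L]] <- data.frame(
      frame = frame, start = p - 1L, end = stop_at + 2L, n_codons = n)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      n_codons = integer()))
  }
  if (mode == "longest_per_stop") {
    out <- out[order(out$end, out$start), , drop = FALSE]
    out <- out[!duplicated(paste(out$frame, out$end)), , drop = FALSE]
  }
  out <- out[order(out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gotoh affine-gap local alignment (score only), independent of Biostrings.
# Opening a gap of length 1 costs gap_open + gap_extend.
oracle_local_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (vertical)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a (horizontal)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- mat[av[i - 1L], bv[j - 1L]]
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_extend,
                     X[i - 1L, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_extend,
                     Y[i, j - 1L] - gap_extend)
      M[i, j] <- max(0, max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                            Y[i - 1L, j - 1L]) + s)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

random_peptide_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# iid nucleotide sequences under an explicit composition; KL divergence of
# the induced hexamer distributions is 6x the per-nucleotide KL
sample_composition_seqs <- function(n_seqs, len, probs) {
  vapply(seq_len(n_seqs), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
}

nt_kl <- function(p, q) sum(p * log(p / q))

tiny_gen <- function(seed = 42) {
  generate_genomes(plant_spec(
    n_species = 2L, genome_length = 30000L, n_ordinary_genes = 6L,
    n_annotated_sorfs = 1L, n_sorf_families = 3L, seed = seed))
}
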
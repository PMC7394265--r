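#' Remove 100%-identical sequence duplicates
#'
#' Records with exactly identical sequences collapse to one survivor.
#' Comparison is on the nucleotide sequence when present, else on the
#' peptide. Among duplicates the annotation-derived record is preferred,
#' then the lexicographically smallest `record_id`. The number of removed
#' duplicates is reported with a message and stored in the
#' `n_removed` attribute.
#'
#' @param records sORF record tibble.
#' @return The unique records, original column set preserved.
#' @export
dedup_identical <- function(records) {
  if (nrow(records) == 0L) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  key <- ifelse(!is.na(records$nt_seq), paste0("nt:", records$nt_seq),
                paste0("aa:", records$aa_seq))
  src <- if ("source" %in% names(records)) records$source else
    rep(NA_character_, nrow(records))
  ord <- order(key, ifelse(!is.na(src) & src == "annotation", 0L, 1L),
               records$record_id)
  out <- records[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  n_removed <- sum(!keep)
  out <- out[keep, , drop = FALSE] |>
    arrange(.data$species_id, .data$seq_id, .data$start)
  if (n_removed > 0L) {
    message("dedup_identical: removed ", n_removed, " exact duplicate(s)")
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Pairwise peptide identity (shorter-sequence denominator)
#'
#' Identity is the number of identical columns of the optimal global
#' (Needleman-Wunsch, BLOSUM62, gap 11/1) alignment divided by the length
#' of the shorter sequence — the convention of greedy incremental
#' clusterers.
#'
#' @param a_aa Peptide string(s); may be a vector, compared element-wise
#'   against the single `b_aa`.
#' @param b_aa A single peptide string.
#' @return Numeric identity fraction(s) in `[0, 1]`.
#' @export
pairwise_identity <- function(a_aa, b_aa) {
  check_peptides(a_aa, "first")
  check_peptides(b_aa, "second")
  stopifnot(length(b_aa) == 1L)
  p <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a_aa), b_aa, type = "global",
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1
  )
  Biostrings::nmatch(p) / pmin(nchar(a_aa), nchar(b_aa))
}

AA_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

aa_dimer_counts <- function(seqs) {
  # 22x22 dimer count vectors, one column per sequence
  nmax <- length(AA_CHARS)
  m <- matrix(0L, nrow = nmax * nmax, ncol = length(seqs))
  for (i in seq_along(seqs)) {
    ch <- match(strsplit(seqs[i], "")[[1]], AA_CHARS)
    if (length(ch) < 2L) next
    code <- (ch[-length(ch)] - 1L) * nmax + ch[-1L]
    t <- tabulate(code, nbins = nmax * nmax)
    m[, i] <- t
  }
  m
}

#' Greedy identity clustering of sORF records
#'
#' Longest-first greedy clustering in the style of incremental clusterers:
#' records are sorted by decreasing peptide length (ties by ascending
#' `record_id`); each record joins the first existing cluster whose
#' representative it matches at `threshold` identity or better (boundary
#' inclusive, identity from [pairwise_identity()]), otherwise it founds a
#' new cluster. The output is deterministic and independent of input order.
#'
#' An exact dimer-count screen (`prefilter = TRUE`, default) skips
#' representative comparisons that provably cannot reach the threshold:
#' an alignment with at least `t * m` identical columns (m = shorter
#' length, n = longer) shares at least `2 t m - n - 1` dimers, so pairs
#' below that bound are pruned without changing the result.
#'
#' @param records De-duplicated sORF record tibble.
#' @param threshold Identity threshold, default 0.70.
#' @param prefilter Use the lossless dimer screen (default `TRUE`).
#' @return Member-level tibble: all input columns plus `cluster_id`,
#'   `representative_id`, `identity_to_rep`, `is_representative`.
#' @export
greedy_cluster <- function(records, threshold = 0.70, prefilter = TRUE) {
  if (nrow(records) == 0L) {
    return(records |> mutate(cluster_id = character(),
                             representative_id = character(),
                             identity_to_rep = numeric(),
                             is_representative = logical()))
  }
  ord <- order(-nchar(records$aa_seq), records$record_id)
  recs <- records[ord, , drop = FALSE]
  aa <- recs$aa_seq
  len <- nchar(aa)
  dim_counts <- if (prefilter) aa_dimer_counts(aa) else NULL
  n <- nrow(recs)
  cluster_of <- integer(n)
  ident <- numeric(n)
  reps <- integer(0)          # indices (into recs) of representatives
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (length(reps)) {
      cand <- reps
      if (prefilter) {
        shared <- colSums(pmin(dim_counts[, cand, drop = FALSE],
                               dim_counts[, i]))
        bound <- 2 * threshold * len[i] - len[cand] - 1
        cand <- cand[shared >= bound | bound <= 0]
      }
      if (length(cand)) {
        idv <- pairwise_identity(aa[cand], aa[i])
        hit <- which(idv >= threshold)
        if (length(hit)) {
          j <- cand[hit[1L]]   # first-fit in cluster founding order
          cluster_of[i] <- cluster_of[j]
          ident[i] <- idv[hit[1L]]
          assigned <- TRUE
        }
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster_of[i] <- length(reps)
      ident[i] <- 1
    }
  }
  recs |>
    mutate(cluster_id = sprintf("C%04d", cluster_of),
           representative_id = recs$record_id[reps[cluster_of]],
           identity_to_rep = ident,
           is_representative = .data$record_id == .data$representative_id) |>
    arrange(.data$cluster_id, dplyr::desc(.data$is_representative),
            .data$record_id)
}

#' Flag conserved clusters
#'
#' A cluster is conserved when its members span at least `min_species`
#' distinct species; singleton and single-species clusters are not
#' conserved.
#'
#' @param clusters Member-level cluster tibble from [greedy_cluster()].
#' @param min_species Minimum distinct species, default 2.
#' @return `clusters` with `n_species` and `conserved` columns.
#' @export
call_conserved <- function(clusters, min_species = 2L) {
  clusters |>
    group_by(.data$cluster_id) |>
    mutate(n_species = dplyr::n_distinct(.data$species_id),
           conserved = .data$n_species >= .env$min_species) |>
    ungroup()
}

#' Per-cluster summary
#'
#' @param clusters Member-level cluster tibble (after [call_conserved()]).
#' @return One row per cluster: `cluster_id`, `representative_id`,
#'   `n_members`, `n_species`, `conserved`.
#' @export
cluster_summary <- function(clusters) {
  if (!"conserved" %in% names(clusters)) clusters <- call_conserved(clusters)
  clusters |>
    group_by(.data$cluster_id) |>
    summarise(representative_id = first(.data$representative_id),
              n_members = n(),
              n_species = first(.data$n_species),
              conserved = first(.data$conserved), .groups = "drop")
}

#' Conservation breadth of conserved clusters
#'
#' For each conserved cluster, the fraction of surveyed genomes its
#' members cover, binned into genome-fraction quarters.
#'
#' @param clusters Member-level cluster tibble (after [call_conserved()]).
#' @param n_species_total Number of genomes surveyed.
#' @return One row per conserved cluster: `cluster_id`, `n_species`,
#'   `breadth`, `bin` (factor over `(0,1/4]`, `(1/4,1/2]`, `(1/2,3/4]`,
#'   `(3/4,1]`). Zero rows when nothing is conserved.
#' @export
conservation_breadth <- function(clusters, n_species_total) {
  stopifnot(n_species_total >= 1L)
  if (!"conserved" %in% names(clusters)) clusters <- call_conserved(clusters)
  levs <- c("(0,1/4]", "(1/4,1/2]", "(1/2,3/4]", "(3/4,1]")
  clusters |>
    filter(.data$conserved) |>
    distinct(.data$cluster_id, .data$n_species) |>
    mutate(breadth = .data$n_species / .env$n_species_total,
           bin = factor(levs[pmin(4L, ceiling(.data$breadth * 4))],
                        levels = levs)) |>
    arrange(.data$cluster_id)
}

#' Write the cluster table as TSV
#'
#' One row per member: `cluster_id`, `representative_id`, `record_id`,
#' `species_id`, `identity_to_rep`, `conserved`.
#'
#' @param clusters Member-level cluster tibble (after [call_conserved()]).
#' @param path Output path.
#' @export
write_cluster_tsv <- function(clusters, path) {
  clusters |>
    select("cluster_id", "representative_id", member = "record_id",
           species = "species_id", "identity_to_rep",
           dplyr::any_of("conserved")) |>
    readr::write_tsv(path)
  invisible(path)
}
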
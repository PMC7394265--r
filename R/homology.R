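empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(), score = numeric(),
         identity_fraction = numeric(), query_aln_start = integer(),
         query_aln_end = integer(), coverage = numeric(), no_hit = logical())
}

check_peptides <- function(x, what) {
  if (length(x) == 0L || any(!nzchar(x)) || anyNA(x)) {
    stop("empty ", what, " peptide")
  }
  invisible(x)
}

blosum62 <- function() {
  if (is.null(.sorfscan_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .sorfscan_cache$blosum62 <- e$BLOSUM62
  }
  .sorfscan_cache$blosum62
}

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman alignment under BLOSUM62 with affine gap costs (open 11,
#' extend 1; a gap of length L costs 11 + L). Identity is identical columns
#' over alignment columns (gap columns count in the denominator); coverage
#' is the aligned fraction of the query. A pair with no positive-scoring
#' window yields a zero-score row flagged `no_hit`.
#'
#' @param query_aa,subject_aa Peptide strings (20-letter alphabet plus `X`);
#'   `query_aa` may be a vector, aligning each element to the one subject.
#' @param query_id,subject_id Identifier(s) carried into the output.
#' @param gap_open,gap_extend Affine gap parameters.
#' @return Alignment-hit tibble: `query_id`, `subject_id`, `score`,
#'   `identity_fraction`, `query_aln_start`, `query_aln_end` (0-based
#'   half-open in query residues), `coverage`, `no_hit`.
#' @export
local_align <- function(query_aa, subject_aa, query_id = NULL,
                        subject_id = "subject", gap_open = 11,
                        gap_extend = 1) {
  check_peptides(query_aa, "query")
  check_peptides(subject_aa, "subject")
  stopifnot(length(subject_aa) == 1L)
  if (is.null(query_id)) query_id <- paste0("q", seq_along(query_aa))
  p <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(query_aa), subject_aa, type = "local",
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_extend
  )
  sc <- Biostrings::score(p)
  width <- Biostrings::nchar(p)             # alignment columns incl. gaps
  nid <- Biostrings::nmatch(p)
  qs <- IRanges::start(Biostrings::pattern(p)) - 1L
  qe <- IRanges::end(Biostrings::pattern(p))
  no_hit <- sc <= 0 | width == 0L
  tibble(
    query_id = query_id, subject_id = subject_id,
    score = ifelse(no_hit, 0, sc),
    identity_fraction = ifelse(no_hit, 0, nid / pmax(width, 1L)),
    query_aln_start = ifelse(no_hit, 0L, qs),
    query_aln_end = ifelse(no_hit, 0L, qe),
    coverage = ifelse(no_hit, 0, (qe - qs) / nchar(query_aa)),
    no_hit = no_hit
  )
}

#' Translated homology search of sORF candidates against annotated proteins
#'
#' Aligns every candidate peptide against every database protein with
#' [local_align()]. Candidates are already translated, so a protein-protein
#' local search takes the place of a six-frame translated search.
#'
#' @param records sORF record tibble (`record_id`, `aa_seq`).
#' @param db Protein database: tibble with `subject_id` and `aa_seq` columns
#'   (e.g. from [extract_cds_proteins()] with `transcript_id` renamed), or a
#'   named character vector.
#' @inheritParams local_align
#' @return Alignment-hit tibble over all query/subject pairs.
#' @export
search_homologs <- function(records, db, gap_open = 11, gap_extend = 1) {
  if (is.character(db)) db <- tibble(subject_id = names(db), aa_seq = unname(db))
  if (nrow(records) == 0L || nrow(db) == 0L) return(empty_hits())
  bind_rows(purrr::map2(db$subject_id, db$aa_seq, function(sid, saa) {
    local_align(records$aa_seq, saa, query_id = records$record_id,
                subject_id = sid, gap_open = gap_open,
                gap_extend = gap_extend)
  }))
}

#' Filter alignment hits by coverage and identity
#'
#' The default `AND_retain` mode keeps hits aligning to at least
#' `min_coverage` of the query and with at least `min_identity` identity
#' (both boundaries inclusive) — the strict reading of removing hits below
#' two thirds coverage and below 30% identity. `OR_retain` keeps hits that
#' fail at most one criterion (the literal reading of that removal rule).
#' `no_hit` rows are always removed.
#'
#' @param hits Alignment-hit tibble.
#' @param min_coverage Query-coverage cutoff, default 2/3.
#' @param min_identity Identity cutoff, default 0.30.
#' @param combine `"AND_retain"` or `"OR_retain"`.
#' @return The retained subset.
#' @export
filter_hits <- function(hits, min_coverage = 2 / 3, min_identity = 0.30,
                        combine = c("AND_retain", "OR_retain")) {
  combine <- match.arg(combine)
  hits <- hits |> filter(!.data$no_hit)
  if (combine == "AND_retain") {
    hits |> filter(.data$coverage >= .env$min_coverage,
                   .data$identity_fraction >= .env$min_identity)
  } else {
    hits |> filter(.data$coverage >= .env$min_coverage |
                     .data$identity_fraction >= .env$min_identity)
  }
}

#' Assign homology status to sORF records
#'
#' The best retained hit per query (highest score; ties resolved toward
#' `known_function`) decides the record's status; queries without a
#' retained hit get `"none"`.
#'
#' @param records sORF record tibble.
#' @param hits Retained alignment hits (after [filter_hits()]).
#' @param function_table Tibble mapping `subject_id` to `label` in
#'   `{known_function, hypothetical}`. Unlisted subjects are treated as
#'   `hypothetical`.
#' @return `records` with `homology_status` filled in.
#' @export
assign_homology_status <- function(records, hits, function_table = NULL) {
  if (is.null(function_table)) {
    function_table <- tibble(subject_id = character(), label = character())
  }
  if (nrow(hits) == 0L) {
    return(records |> mutate(homology_status = "none"))
  }
  best <- hits |>
    left_join(function_table, by = "subject_id") |>
    mutate(label = dplyr::coalesce(.data$label, "hypothetical"),
           .label_rank = if_else(.data$label == "known_function", 0L, 1L)) |>
    arrange(.data$query_id, dplyr::desc(.data$score), .data$.label_rank) |>
    distinct(.data$query_id, .keep_all = TRUE) |>
    select(record_id = "query_id", "label")
  records |>
    select(-dplyr::any_of("homology_status")) |>
    left_join(best, by = "record_id") |>
    mutate(homology_status = dplyr::coalesce(.data$label, "none")) |>
    select(-"label")
}
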
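SORF_RECORD_COLS <- c("record_id", "species_id", "seq_id", "region_label",
                      "strand", "frame", "start", "end", "nt_seq", "aa_seq",
                      "n_codons", "kozak", "source", "feature_id",
                      "coding_probability", "homology_status")

normalize_sorf_records <- function(x) {
  for (col in SORF_RECORD_COLS) {
    if (!col %in% names(x)) {
      x[[col]] <- switch(col,
        frame = NA_integer_, start = NA_integer_, end = NA_integer_,
        n_codons = NA_integer_, coding_probability = NA_real_,
        NA_character_)
    }
  }
  x$homology_status[is.na(x$homology_status)] <- "none"
  select(x, dplyr::all_of(SORF_RECORD_COLS))
}

#' Extract annotation-derived sORFs
#'
#' Transcripts whose summed CDS length translates to at most `max_codons`
#' amino acids (stop codon excluded) become sORF records with
#' `source = "annotation"`. Transcripts whose CDS length is not divisible by
#' 3 are skipped with a warning.
#'
#' @param bundle A `genome_bundle` with CDS features.
#' @param max_codons Peptide length cap, default 80.
#' @return sORF record tibble (see [pool_sorfs()] for the column contract).
#' @export
screen_annotated_sorfs <- function(bundle, max_codons = 80L) {
  prots <- extract_cds_proteins(bundle)
  empty <- normalize_sorf_records(tibble(species_id = character()))
  if (nrow(prots) == 0L) return(empty)
  # peptide excludes the trailing stop when the CDS carries one
  prots <- prots |> filter(.data$n_codons <= .env$max_codons)
  if (nrow(prots) == 0L) return(empty)
  spans <- bundle$features |>
    filter(.data$ftype == "CDS") |>
    group_by(transcript_id = .data$parent_id) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  recs <- prots |>
    inner_join(spans, by = "transcript_id") |>
    group_by(.data$seq_id) |>
    mutate(kozak = kozak_flag(bundle$sequences[[first(.data$seq_id)]],
                              .data$start, .data$end, .data$strand)) |>
    ungroup() |>
    mutate(record_id = paste0(.data$species_id, "-gi_", .data$transcript_id),
           region_label = "exonic", source = "annotation",
           feature_id = .data$transcript_id, nt_seq = .data$cds_nt,
           frame = NA_integer_)
  normalize_sorf_records(recs) |>
    arrange(.data$species_id, .data$seq_id, .data$start)
}

#' Consensus of two ab-initio ORF prediction sets
#'
#' Intersects the plain six-frame scanner output with the coding-potential
#' predictor output. `exact_interval` keeps candidates whose
#' (species, sequence, strand, start, end) key appears in both sets;
#' `shared_stop` keys on the stop-codon coordinate only and keeps the
#' scanner's coordinates, accommodating predictors that choose different
#' start codons for the same gene. Coding probabilities are copied onto the
#' retained records, which are labelled `source = "ab_initio"` and given
#' `sf`-prefixed identifiers.
#'
#' @param scanner_set,coding_set Candidate tibbles sharing the genomic
#'   coordinate convention; `coding_set` normally carries a
#'   `coding_probability` column.
#' @param match_mode `"exact_interval"` (default, strictest) or
#'   `"shared_stop"`.
#' @return sORF record tibble with `source = "ab_initio"`.
#' @export
consensus_orfs <- function(scanner_set, coding_set,
                           match_mode = c("exact_interval", "shared_stop")) {
  match_mode <- match.arg(match_mode)
  empty <- normalize_sorf_records(tibble(species_id = character()))
  if (nrow(scanner_set) == 0L || nrow(coding_set) == 0L) return(empty)
  if (!"coding_probability" %in% names(coding_set)) {
    coding_set$coding_probability <- NA_real_
  }
  if (match_mode == "exact_interval") {
    keys <- coding_set |>
      select("species_id", "seq_id", "strand", "start", "end",
             "coding_probability") |>
      distinct(.data$species_id, .data$seq_id, .data$strand, .data$start,
               .data$end, .keep_all = TRUE)
    hit <- scanner_set |>
      select(-dplyr::any_of("coding_probability")) |>
      inner_join(keys, by = c("species_id", "seq_id", "strand", "start", "end"))
  } else {
    stop_key <- function(x) if_else(x$strand == "+", x$end, x$start)
    keys <- coding_set |>
      mutate(.stop = stop_key(coding_set)) |>
      group_by(.data$species_id, .data$seq_id, .data$strand, .data$.stop) |>
      summarise(coding_probability = max(.data$coding_probability),
                .groups = "drop")
    hit <- scanner_set |>
      select(-dplyr::any_of("coding_probability")) |>
      mutate(.stop = stop_key(scanner_set)) |>
      inner_join(keys,
                 by = c("species_id", "seq_id", "strand", ".stop")) |>
      group_by(.data$species_id, .data$seq_id, .data$strand, .data$.stop) |>
      slice_max(.data$n_codons, n = 1, with_ties = FALSE) |>
      ungroup() |>
      select(-".stop")
  }
  if (nrow(hit) == 0L) return(empty)
  hit <- hit |>
    arrange(.data$species_id, .data$seq_id, .data$start, .data$strand) |>
    mutate(source = "ab_initio",
           record_id = paste0(.data$species_id, "-sf", row_number()))
  normalize_sorf_records(hit)
}

#' Pool annotation-derived and ab-initio sORF records
#'
#' Concatenates the two sources and collapses duplicates on
#' (species, sequence, strand, start, end), the annotation record winning.
#' Output order is stable: (species, sequence, start).
#'
#' @param annotation_records,ab_initio_records sORF record tibbles.
#' @return De-duplicated sORF record tibble.
#' @export
pool_sorfs <- function(annotation_records, ab_initio_records) {
  combined <- bind_rows(normalize_sorf_records(annotation_records),
                        normalize_sorf_records(ab_initio_records))
  if (nrow(combined) == 0L) return(combined)
  combined |>
    mutate(.src_rank = if_else(.data$source == "annotation", 0L, 1L)) |>
    arrange(.data$species_id, .data$seq_id, .data$start, .data$strand,
            .data$.src_rank) |>
    distinct(.data$species_id, .data$seq_id, .data$strand, .data$start,
             .data$end, .keep_all = TRUE) |>
    select(-".src_rank") |>
    arrange(.data$species_id, .data$seq_id, .data$start)
}

#' Write pooled sORF peptides as FASTA
#'
#' Headers are the record identifiers (`<species>-gi_*` for
#' annotation-derived records, `<species>-sf*` for ab-initio ones).
#'
#' @param records sORF record tibble.
#' @param path Output path.
#' @export
write_sorf_fasta <- function(records, path) {
  writeLines(rbind(paste0(">", records$record_id), records$aa_seq), path)
  invisible(path)
}
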
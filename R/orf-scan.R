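STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_lookup <- function() {
  if (is.null(.sorfscan_cache$codon_lookup)) {
    gc <- Biostrings::GENETIC_CODE
    .sorfscan_cache$codon_lookup <- list(codons = names(gc),
                                         aa = unname(gc))
  }
  .sorfscan_cache$codon_lookup
}

#' Scan one strand of a sequence for small ORFs
#'
#' Scans the three reading frames of the supplied string for open reading
#' frames that begin with `ATG` and end with an in-frame stop codon
#' (`TAA`/`TAG`/`TGA`). The caller supplies the reverse complement to scan
#' the opposite strand. Any codon containing `N` is neither a start nor a
#' stop and breaks an open frame, so no reported ORF spans an ambiguous
#' codon.
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @param min_codons Minimum peptide length in codons (stop excluded).
#' @param max_codons Maximum peptide length; the default 80 corresponds to
#'   the 240-nt small-ORF cap.
#' @param mode `"longest_per_stop"` reports the most-5' ATG per
#'   (frame, stop) pair, emulating one-gene-per-stop ORF callers;
#'   `"all_starts"` reports every qualifying ATG.
#' @return Tibble of ORFs in local coordinates: `frame` (0/1/2), `start`,
#'   `end` (0-based half-open, stop codon included), `nt_seq`, `aa_seq`
#'   (stop symbol excluded), `n_codons = nchar(aa_seq)`.
#' @export
scan_orfs <- function(seq, min_codons = 10L, max_codons = 80L,
                      mode = c("longest_per_stop", "all_starts")) {
  mode <- match.arg(mode)
  stopifnot(max_codons >= min_codons, min_codons >= 1L)
  empty <- tibble(frame = integer(), start = integer(), end = integer(),
                  nt_seq = character(), aa_seq = character(),
                  n_codons = integer())
  L <- nchar(seq)
  if (L < 3L * (min_codons + 1L)) return(empty)
  per_frame <- lapply(0:2, function(f) {
    k <- (L - f) %/% 3L
    if (k < min_codons + 1L) return(NULL)
    pos0 <- f + 3L * (seq_len(k) - 1L)       # 0-based codon starts
    codons <- substring(seq, pos0 + 1L, pos0 + 3L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    barrier <- is_stop | grepl("N", codons, fixed = TRUE)
    seg <- cumsum(barrier) - barrier         # segment index per codon
    stops <- which(is_stop)
    if (length(stops) == 0L) return(NULL)
    stop_of_seg <- setNames(stops, seg[stops])   # each segment ends in <=1 stop
    atgs <- which(is_atg)
    if (length(atgs) == 0L) return(NULL)
    j <- unname(stop_of_seg[as.character(seg[atgs])])
    ok <- !is.na(j)
    atgs <- atgs[ok]; j <- j[ok]
    n <- j - atgs
    ok <- n >= min_codons & n <= max_codons
    if (!any(ok)) return(NULL)
    atgs <- atgs[ok]; j <- j[ok]; n <- n[ok]
    if (mode == "longest_per_stop") {
      # most-5' ATG among the length-qualifying candidates of each stop
      keep <- !duplicated(j)
      atgs <- atgs[keep]; j <- j[keep]; n <- n[keep]
    }
    start <- f + 3L * (atgs - 1L)
    end <- f + 3L * j
    nt <- substring(seq, start + 1L, end)
    cl <- codon_lookup()
    aa_frame <- paste(ifelse(is.na(match(codons, cl$codons)), "X",
                             cl$aa[match(codons, cl$codons)]),
                      collapse = "")
    tibble(frame = f, start = start, end = end, nt_seq = nt,
           aa_seq = substring(aa_frame, atgs, j - 1L),
           n_codons = as.integer(n))
  })
  out <- bind_rows(per_frame)
  if (nrow(out) == 0L) return(empty)
  arrange(out, .data$start, .data$frame)
}

#' Map strand-local ORF coordinates onto the genome
#'
#' @param orfs Tibble from [scan_orfs()] (local coordinates on the region's
#'   scanned strand).
#' @param region One-row tibble or list with `seq_id`, `start`, `end`,
#'   `label` (0-based half-open genomic interval).
#' @param strand `"+"` or `"-"`; for `"-"` the scanned string is assumed to
#'   be the reverse complement of the region, and coordinates are mirrored
#'   (`start_g = region_end - end_local`).
#' @return The ORF tibble with genomic `start`/`end`, plus `seq_id`,
#'   `region_label`, `strand`.
#' @export
map_to_genome <- function(orfs, region, strand) {
  stopifnot(strand %in% c("+", "-"))
  rlen <- region$end - region$start
  if (nrow(orfs) && (min(orfs$start) < 0L || max(orfs$end) > rlen)) {
    stop("local ORF coordinates outside region bounds")
  }
  if (strand == "+") {
    gs <- region$start + orfs$start
    ge <- region$start + orfs$end
  } else {
    gs <- region$end - orfs$end
    ge <- region$end - orfs$start
  }
  orfs |>
    mutate(seq_id = region$seq_id, region_label = region$label,
           strand = .env$strand, start = as.integer(gs), end = as.integer(ge)) |>
    select("seq_id", "region_label", "strand", "frame", "start", "end",
           "nt_seq", "aa_seq", "n_codons")
}

#' Kozak-context flag for mapped ORF candidates
#'
#' Classifies the translation-initiation context of each candidate:
#' `positive` when the nucleotide at position -3 relative to the `A` of the
#' start codon is a purine (`A`/`G`) and position +4 is `G` (strand-aware);
#' `negative` otherwise; `undetermined` when the context extends past the
#' sequence bounds or touches an `N`. This motif check is a documented
#' stand-in for ORF-integrity-based Kozak calls of coding-potential tools.
#'
#' @param genome_seq Full chromosome/scaffold string the candidates map to.
#' @param start,end Integer vectors of 0-based half-open genomic coordinates.
#' @param strand Character vector of `"+"`/`"-"`.
#' @return Character vector in `{positive, negative, undetermined}`.
#' @export
kozak_flag <- function(genome_seq, start, end, strand) {
  L <- nchar(genome_seq)
  base_at <- function(pos0) {  # 0-based; NA outside bounds
    out <- rep(NA_character_, length(pos0))
    if (length(pos0) == 0L) return(out)
    ok <- pos0 >= 0L & pos0 < L
    if (!any(ok)) return(out)
    out[ok] <- substring(genome_seq, pos0[ok] + 1L, pos0[ok] + 1L)
    out[!is.na(out) & out == "N"] <- NA_character_
    out
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  plus <- strand == "+"
  up <- ifelse(plus, base_at(start - 3L), NA)
  p4 <- ifelse(plus, base_at(start + 3L), NA)
  up[!plus] <- unname(comp[base_at(end[!plus] + 2L)])
  p4[!plus] <- unname(comp[base_at(end[!plus] - 4L)])
  ifelse(is.na(up) | is.na(p4), "undetermined",
         ifelse(up %in% c("A", "G") & p4 == "G", "positive", "negative"))
}

#' Six-frame ORF scan of a genome bundle
#'
#' Partitions the genome (unless `regions` is supplied), extracts both
#' strands of every region, scans them with [scan_orfs()], maps candidates
#' back to genomic coordinates and attaches the Kozak flag.
#'
#' @param bundle A `genome_bundle`.
#' @param regions Optional interval tibble; defaults to
#'   [partition_regions()]. Pass a whole-sequence tibble with label
#'   `"genome"` to scan unpartitioned sequences.
#' @param region_labels Labels to scan (default: intergenic and intronic,
#'   the candidate space for unannotated sORFs).
#' @inheritParams scan_orfs
#' @return Candidate tibble: `species_id`, `seq_id`, `region_label`,
#'   `strand`, `frame`, `start`, `end`, `nt_seq`, `aa_seq`, `n_codons`,
#'   `kozak`, sorted by (`seq_id`, `start`, `strand`).
#' @export
scan_bundle <- function(bundle, regions = NULL,
                        region_labels = c("intergenic", "intronic"),
                        min_codons = 10L, max_codons = 80L,
                        mode = c("longest_per_stop", "all_starts")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bundle, "genome_bundle"))
  if (is.null(regions)) regions <- partition_regions(bundle)
  regions <- regions |> filter(.data$label %in% region_labels)
  rs <- extract_region_sequences(bundle, regions)
  hits <- purrr::pmap(rs, function(species_id, seq_id, label, start, end,
                                   strand, seq) {
    orfs <- scan_orfs(seq, min_codons = min_codons, max_codons = max_codons,
                      mode = mode)
    if (nrow(orfs) == 0L) return(NULL)
    map_to_genome(orfs, list(seq_id = seq_id, start = start, end = end,
                             label = label), strand)
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble(species_id = character(), seq_id = character(),
                  region_label = character(), strand = character(),
                  frame = integer(), start = integer(), end = integer(),
                  nt_seq = character(), aa_seq = character(),
                  n_codons = integer(), kozak = character()))
  }
  out |>
    mutate(species_id = bundle$species_id) |>
    group_by(.data$seq_id) |>
    mutate(kozak = kozak_flag(bundle$sequences[[first(.data$seq_id)]],
                              .data$start, .data$end, .data$strand)) |>
    ungroup() |>
    select("species_id", dplyr::everything()) |>
    arrange(.data$seq_id, .data$start, .data$strand, .data$frame)
}
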
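#' Read a genome FASTA file
#'
#' Reads plain or gzip-compressed FASTA. Sequence identifiers are taken as the
#' first whitespace-delimited token of the header. Sequences are folded to
#' uppercase (soft-masking removed), `U` is converted to `T`, and any residual
#' non-`ACGT` character (IUPAC ambiguity codes) is folded to `N`, so loaded
#' sequences are strings over `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return Named character vector of DNA sequences, one element per record.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("empty FASTA record in ", path)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- ids
  seqs
}

#' Read gene features from a GFF3 file
#'
#' Retains `gene`, `mRNA`, `exon` and `CDS` records and converts the 1-based
#' inclusive GFF coordinates to the package-internal 0-based half-open
#' convention (`start = col4 - 1`, `end = col5`). Records with `end < start`
#' and CDS records without a usable strand are dropped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `seq_id`, `start`, `end`, `strand`, `ftype`,
#'   `feature_id`, `parent_id` (0-based half-open coordinates).
#' @export
read_gff_features <- function(path) {
  stopifnot(file.exists(path))
  g <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")
  ))
  keep_types <- c("gene", "mRNA", "exon", "CDS")
  g <- g[as.character(g$type) %in% keep_types, , drop = FALSE]
  parent <- vapply(g$Parent, function(p) {
    if (length(p) == 0L || is.na(p[1])) NA_character_ else as.character(p[1])
  }, character(1))
  out <- tibble(
    seq_id = as.character(g$seqid),
    start = as.integer(g$start) - 1L,
    end = as.integer(g$end),
    strand = as.character(g$strand),
    ftype = as.character(g$type),
    feature_id = ifelse(is.na(g$ID), paste0(tolower(g$type), "_", seq_len(nrow(g))),
                        as.character(g$ID)),
    parent_id = parent
  )
  bad <- out$end <= out$start
  if (any(bad)) {
    warning(sum(bad), " feature(s) with end < start dropped")
    out <- out[!bad, , drop = FALSE]
  }
  bad_cds <- out$ftype == "CDS" & !(out$strand %in% c("+", "-"))
  if (any(bad_cds)) {
    warning(sum(bad_cds), " CDS feature(s) with unknown strand dropped")
    out <- out[!bad_cds, , drop = FALSE]
  }
  out
}

#' Bundle one species' sequences and features
#'
#' @param species_id Short unique species label.
#' @param sequences Named character vector of uppercase DNA sequences.
#' @param features Feature tibble as returned by [read_gff_features()]; may
#'   have zero rows for an unannotated genome.
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(species_id, sequences, features = NULL) {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            is.character(sequences), !is.null(names(sequences)))
  if (is.null(features)) {
    features <- tibble(seq_id = character(), start = integer(), end = integer(),
                       strand = character(), ftype = character(),
                       feature_id = character(), parent_id = character())
  }
  missing_seq <- setdiff(unique(features$seq_id), names(sequences))
  if (length(missing_seq)) {
    stop("features reference unknown sequence(s): ",
         paste(missing_seq, collapse = ", "))
  }
  if (nrow(features)) {
    lens <- nchar(sequences)[features$seq_id]
    if (any(features$start < 0L) || any(features$end > lens)) {
      stop("feature coordinates outside sequence bounds")
    }
    child <- features$ftype %in% c("exon", "CDS")
    if (any(child & is.na(features$parent_id))) {
      stop("exon/CDS features must carry a Parent attribute")
    }
  }
  structure(
    list(species_id = species_id, sequences = sequences, features = features),
    class = "genome_bundle"
  )
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("<genome_bundle> ", x$species_id, ": ", length(x$sequences),
      " sequence(s), ", sum(nchar(x$sequences)), " bp, ",
      nrow(x$features), " feature(s)\n", sep = "")
  invisible(x)
}

#' Read a FASTA + GFF3 pair into a genome bundle
#'
#' @param fasta,gff File paths.
#' @param species_id Species label; defaults to the FASTA file stem.
#' @return A `genome_bundle`.
#' @export
read_genome_bundle <- function(fasta, gff, species_id = NULL) {
  if (is.null(species_id)) {
    species_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(fasta))
  }
  genome_bundle(species_id, read_genome_fasta(fasta), read_gff_features(gff))
}

ranges_to_tibble <- function(ir, seq_id, label) {
  if (length(ir) == 0L) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  label = character()))
  }
  tibble(seq_id = seq_id, start = IRanges::start(ir) - 1L,
         end = IRanges::end(ir), label = label)
}

to_iranges <- function(start, end) {
  # 0-based half-open -> IRanges (1-based inclusive)
  IRanges::IRanges(start = start + 1L, end = end)
}

#' Partition a genome into exonic, intronic and intergenic intervals
#'
#' Exonic intervals are the union of exon features (falling back to CDS when
#' the annotation carries no exons). Gene spans are gene features, falling
#' back to the union of mRNA, then CDS. Intronic intervals are the intragenic
#' complement of the exonic union within gene spans (which equals the gaps
#' between consecutive exons of each transcript for ordinary gene models);
#' intergenic intervals are everything outside gene spans and exons. The
#' three label sets tile every sequence exactly once, with precedence
#' exonic > intronic > intergenic at annotation conflicts.
#'
#' @param bundle A `genome_bundle`.
#' @return Tibble of intervals: `seq_id`, `start`, `end` (0-based half-open),
#'   `label` in `{exonic, intronic, intergenic}`, sorted and non-overlapping
#'   within each label.
#' @export
partition_regions <- function(bundle) {
  stopifnot(inherits(bundle, "genome_bundle"))
  fts <- bundle$features
  exon_src <- if (any(fts$ftype == "exon")) "exon" else "CDS"
  span_src <- if (any(fts$ftype == "gene")) "gene" else
    if (any(fts$ftype == "mRNA")) "mRNA" else "CDS"
  out <- lapply(names(bundle$sequences), function(sid) {
    len <- nchar(bundle$sequences[[sid]])
    whole <- IRanges::IRanges(1L, len)
    f <- fts[fts$seq_id == sid, , drop = FALSE]
    ex <- IRanges::reduce(to_iranges(f$start[f$ftype == exon_src],
                                     f$end[f$ftype == exon_src]))
    sp <- IRanges::reduce(to_iranges(f$start[f$ftype == span_src],
                                     f$end[f$ftype == span_src]))
    covered <- IRanges::reduce(c(ex, sp))
    intergenic <- IRanges::setdiff(whole, covered)
    intronic <- IRanges::setdiff(covered, ex)
    bind_rows(
      ranges_to_tibble(ex, sid, "exonic"),
      ranges_to_tibble(intronic, sid, "intronic"),
      ranges_to_tibble(intergenic, sid, "intergenic")
    )
  })
  bind_rows(out) |> arrange(.data$seq_id, .data$start)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements (`N` preserved).
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract region sequences on both strands
#'
#' @param bundle A `genome_bundle`.
#' @param regions Interval tibble from [partition_regions()] (or any tibble
#'   with `seq_id`, `start`, `end`, `label`).
#' @return Tibble with one row per region per strand: `species_id`, `seq_id`,
#'   `label`, `start`, `end`, `strand`, `seq` (minus-strand rows carry the
#'   reverse complement).
#' @export
extract_region_sequences <- function(bundle, regions) {
  stopifnot(inherits(bundle, "genome_bundle"))
  if (nrow(regions) == 0L) {
    return(tibble(species_id = character(), seq_id = character(),
                  label = character(), start = integer(), end = integer(),
                  strand = character(), seq = character()))
  }
  fwd <- substring(bundle$sequences[regions$seq_id],
                   regions$start + 1L, regions$end)
  bind_rows(
    tibble(species_id = bundle$species_id, seq_id = regions$seq_id,
           label = regions$label, start = regions$start, end = regions$end,
           strand = "+", seq = unname(fwd)),
    tibble(species_id = bundle$species_id, seq_id = regions$seq_id,
           label = regions$label, start = regions$start, end = regions$end,
           strand = "-", seq = revcomp(unname(fwd)))
  ) |> arrange(.data$seq_id, .data$start, .data$strand)
}

#' Write region intervals as BED6
#'
#' 0-based half-open intervals, label in the name column, strand column `.`.
#'
#' @param regions Interval tibble.
#' @param path Output path.
#' @export
write_region_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.", regions$seq_id, regions$start,
                   regions$end, regions$label)
  writeLines(lines, path)
  invisible(path)
}

#' Write region sequences as multi-FASTA
#'
#' Headers follow `<species>|<seq_id>|<label>|<start>-<end>|<strand>`.
#'
#' @param region_seqs Tibble from [extract_region_sequences()].
#' @param path Output path.
#' @export
write_region_fasta <- function(region_seqs, path) {
  headers <- sprintf(">%s|%s|%s|%d-%d|%s", region_seqs$species_id,
                     region_seqs$seq_id, region_seqs$label, region_seqs$start,
                     region_seqs$end, region_seqs$strand)
  writeLines(rbind(headers, region_seqs$seq), path)
  invisible(path)
}

#' Write features back to GFF3
#'
#' Converts internal 0-based half-open coordinates back to 1-based inclusive.
#'
#' @param features Feature tibble (internal convention).
#' @param path Output path.
#' @export
write_gff3 <- function(features, path) {
  attrs <- paste0("ID=", features$feature_id,
                  ifelse(is.na(features$parent_id), "",
                         paste0(";Parent=", features$parent_id)))
  lines <- sprintf("%s\tsorfscan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   features$seq_id, features$ftype, features$start + 1L,
                   features$end, features$strand,
                   ifelse(features$ftype == "CDS", "0", "."), attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Translate DNA to protein
#'
#' Codons containing `N` translate to `X`; stop codons to `*`.
#'
#' @param x Character vector of DNA strings with lengths divisible by 3.
#' @return Character vector of amino-acid strings.
#' @export
translate_dna <- function(x) {
  if (length(x) == 0L) return(character())
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(x), if.fuzzy.codon = "X"
  )))
}

#' Spliced CDS proteins of all annotated transcripts
#'
#' Concatenates each transcript's CDS segments in transcript order
#' (reverse-complemented for minus-strand transcripts) and translates them.
#' Transcripts whose summed CDS length is not divisible by 3 are skipped with
#' a warning. A trailing stop codon, when present, is removed from the
#' peptide.
#'
#' @param bundle A `genome_bundle`.
#' @return Tibble with `species_id`, `transcript_id`, `seq_id`, `strand`,
#'   `cds_nt` (spliced, including any trailing stop), `aa_seq`, `n_codons`.
#' @export
extract_cds_proteins <- function(bundle) {
  stopifnot(inherits(bundle, "genome_bundle"))
  cds <- bundle$features |> filter(.data$ftype == "CDS")
  if (nrow(cds) == 0L) {
    return(tibble(species_id = character(), transcript_id = character(),
                  seq_id = character(), strand = character(),
                  cds_nt = character(), aa_seq = character(),
                  n_codons = integer()))
  }
  per_tx <- cds |>
    arrange(.data$parent_id, .data$start) |>
    group_by(.data$parent_id, .data$seq_id, .data$strand) |>
    summarise(nt = paste(substring(bundle$sequences[[first(.data$seq_id)]],
                                   .data$start + 1L, .data$end),
                         collapse = ""),
              .groups = "drop")
  bad <- nchar(per_tx$nt) %% 3L != 0L
  if (any(bad)) {
    warning(sum(bad), " transcript(s) with CDS length not divisible by 3 skipped")
    per_tx <- per_tx[!bad, , drop = FALSE]
  }
  if (nrow(per_tx) == 0L) {
    return(tibble(species_id = character(), transcript_id = character(),
                  seq_id = character(), strand = character(),
                  cds_nt = character(), aa_seq = character(),
                  n_codons = integer()))
  }
  nt <- ifelse(per_tx$strand == "-", revcomp(per_tx$nt), per_tx$nt)
  aa <- translate_dna(nt)
  has_stop <- endsWith(aa, "*")
  aa <- sub("\\*$", "", aa)
  tibble(species_id = bundle$species_id, transcript_id = per_tx$parent_id,
         seq_id = per_tx$seq_id, strand = per_tx$strand, cds_nt = nt,
         aa_seq = aa, n_codons = nchar(aa)) |>
    arrange(.data$transcript_id)
}
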
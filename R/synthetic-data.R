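sample_one <- function(x) {
  # avoid base sample()'s scalar expansion (sample(2, 1) draws from 1:2)
  if (length(x) == 1L) x else sample(x, 1L)
}

random_dna <- function(n, gc = 0.5) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

genetic_code_tables <- function() {
  if (is.null(.sorfscan_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    by_aa <- split(names(gc), unname(gc))
    # biased usage: strong preference for the first codon of each family so
    # coding sequence acquires a hexamer signature distinct from background
    weights <- lapply(by_aa, function(cs) {
      w <- rep(1, length(cs)); w[1] <- 6
      setNames(w / sum(w), cs)
    })
    .sorfscan_cache$codons <- list(code = gc, by_aa = by_aa, weights = weights)
  }
  .sorfscan_cache$codons
}

reverse_translate <- function(peptide) {
  tb <- genetic_code_tables()
  aa <- strsplit(peptide, "")[[1]]
  vapply(aa, function(a) {
    w <- tb$weights[[a]]
    sample(names(w), 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
}

random_peptide <- function(n_codons) {
  aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  paste0("M", paste(sample(aas, n_codons - 1L, replace = TRUE), collapse = ""))
}

mutate_codons <- function(codons, rate) {
  # single-nucleotide substitutions at the per-site rate, biased 2:1
  # toward synonymous outcomes among the three neighbour bases; the
  # initiator ATG is preserved and stops are never introduced
  if (rate <= 0) return(codons)
  tb <- genetic_code_tables()
  bases <- c("A", "C", "G", "T")
  out <- codons
  for (i in seq_along(codons)[-1L]) {
    n_events <- rbinom(1L, 3L, rate)
    if (n_events == 0L) next
    for (e in seq_len(n_events)) {
      cod <- strsplit(out[i], "")[[1]]
      aa <- tb$code[[out[i]]]
      # all nine single-nucleotide neighbours; stops excluded; the
      # synonymous category carries 2/3 of the substitution probability
      # whenever it is non-empty
      alts <- unlist(lapply(1:3, function(pos) {
        vapply(setdiff(bases, cod[pos]), function(b) {
          v <- cod; v[pos] <- b; paste(v, collapse = "")
        }, character(1))
      }), use.names = FALSE)
      alt_aa <- tb$code[alts]
      keep <- alt_aa != "*"
      alts <- alts[keep]; alt_aa <- alt_aa[keep]
      if (length(alts) == 0L) next
      syn <- alts[alt_aa == aa]
      nonsyn <- alts[alt_aa != aa]
      pick <- if (length(syn) && (length(nonsyn) == 0L || runif(1) < 2 / 3)) {
        syn
      } else {
        nonsyn
      }
      out[i] <- pick[sample.int(length(pick), 1L)]
    }
  }
  out
}

#' Specification for a synthetic multi-species genome fixture
#'
#' Defines the study conditions the generator emulates: background genomes
#' with ordinary multi-exon genes, a few annotated single-exon sORF genes,
#' and homologous sORF families planted into intergenic and intronic space
#' with known substitution divergence.
#'
#' @param n_species Number of species (default 3).
#' @param genome_length Genome length per species in bp (default 200000).
#' @param n_ordinary_genes Multi-exon background genes per species
#'   (default 40, >80 codons each).
#' @param n_annotated_sorfs Annotated single-exon sORF genes per species
#'   (default 2).
#' @param n_sorf_families Planted homologous sORF families (default 10).
#' @param family_size_range Copies per family = species covered; default
#'   `c(2, n_species)` so every family is conserved by construction.
#' @param sorf_length_range Planted peptide lengths in codons, default
#'   11-80.
#' @param substitution_rate Per-nucleotide substitution probability applied
#'   per copy (codon-aware, synonymous-biased 2:1); must lie in
#'   `[0, 0.3]`; default 0.05.
#' @param region_mix Placement probabilities `c(intergenic=, intronic=)`,
#'   summing to 1.
#' @param gc Background GC content (default 0.5).
#' @param seed Required integer seed; generation is deterministic given it.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(n_species = 3L, genome_length = 200000L,
                       n_ordinary_genes = 40L, n_annotated_sorfs = 2L,
                       n_sorf_families = 10L,
                       family_size_range = c(2L, n_species),
                       sorf_length_range = c(11L, 80L),
                       substitution_rate = 0.05,
                       region_mix = c(intergenic = 0.7, intronic = 0.3),
                       gc = 0.5, seed) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.3,
            sorf_length_range[1] >= 2L, sorf_length_range[2] <= 80L,
            abs(sum(region_mix) - 1) < 1e-9,
            family_size_range[1] >= 1L,
            family_size_range[1] <= family_size_range[2],
            family_size_range[2] <= n_species,
            !missing(seed))
  structure(list(n_species = n_species, genome_length = genome_length,
                 n_ordinary_genes = n_ordinary_genes,
                 n_annotated_sorfs = n_annotated_sorfs,
                 n_sorf_families = n_sorf_families,
                 family_size_range = family_size_range,
                 sorf_length_range = sorf_length_range,
                 substitution_rate = substitution_rate,
                 region_mix = region_mix, gc = gc, seed = as.integer(seed)),
            class = "plant_spec")
}

overlaps_any <- function(occ, start, end, margin) {
  if (nrow(occ) == 0L) return(FALSE)
  any(start < occ$end + margin & end + margin > occ$start)
}

place_interval <- function(occ, len, lo, hi, margin, max_tries = 2000L) {
  for (k in seq_len(max_tries)) {
    s <- sample.int(hi - lo - len + 1L, 1L) + lo - 1L
    if (!overlaps_any(occ, s, s + len, margin)) return(s)
  }
  stop("infeasible packing: could not place an interval of length ", len)
}

#' Generate a synthetic multi-species genome fixture with ground truth
#'
#' Builds one chromosome per species: i.i.d. background DNA, ordinary
#' multi-exon genes and annotated single-exon sORF genes (reverse
#' translated with a biased codon table so coding sequence carries a
#' learnable hexamer signature), and planted sORF family copies mutated
#' from a family ancestor. Every planted copy is preceded by an adjacent
#' in-frame stop codon so its ATG is the most-5' start for its stop and a
#' longest-per-stop scan recovers the exact planted interval. Planted
#' intervals never overlap each other or genes. Deterministic given the
#' spec seed.
#'
#' @param spec A [plant_spec()].
#' @return List with `bundles` (named list of `genome_bundle`), `truth`
#'   (tibble: `family_id`, `species_id`, `seq_id`, `start`, `end`,
#'   `strand`, `region_label`, `peptide`), `function_table` (tibble:
#'   `subject_id`, `label`) and the `spec`.
#' @export
generate_genomes <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  withr::with_seed(spec$seed, generate_genomes_impl(spec))
}

generate_genomes_impl <- function(spec) {
  species <- sprintf("sp%02d", seq_len(spec$n_species))
  genomes <- list()
  features <- list()
  introns <- list()      # per species tibble of intron intervals
  occupied <- list()
  function_rows <- list()
  for (s in species) {
    genome <- random_dna(spec$genome_length, spec$gc)
    occ <- tibble(start = integer(), end = integer())
    fts <- list()
    intr <- list()
    gene_defs <- c(rep("ordinary", spec$n_ordinary_genes),
                   rep("smallgene", spec$n_annotated_sorfs))
    for (gi in seq_along(gene_defs)) {
      kind <- gene_defs[gi]
      if (kind == "ordinary") {
        pep <- random_peptide(sample(100:220, 1L))
        n_ex <- sample(2:4, 1L)
      } else {
        pep <- random_peptide(sample(15:60, 1L))
        n_ex <- 1L
      }
      codons <- c(reverse_translate(pep), sample(STOP_CODONS, 1L))
      tx <- paste(codons, collapse = "")
      tx_len <- nchar(tx)
      if (n_ex > 1L) {
        cuts <- sort(sample(seq(30L, tx_len - 30L, by = 1L), n_ex - 1L))
        ex_len <- diff(c(0L, cuts, tx_len))
        in_len <- sample(80:300, n_ex - 1L, replace = TRUE)
      } else {
        ex_len <- tx_len
        in_len <- integer(0)
      }
      glen <- sum(ex_len) + sum(in_len)
      strand <- sample(c("+", "-"), 1L)
      gstart <- place_interval(occ, glen, 500L, spec$genome_length - 500L,
                               margin = 200L)
      occ <- bind_rows(occ, tibble(start = gstart, end = gstart + glen))
      # exon pieces in transcript order; genomic layout left-to-right
      pieces <- character(2L * n_ex - 1L)
      pieces[seq(1L, by = 2L, length.out = n_ex)] <-
        substring(tx, cumsum(c(1L, head(ex_len, -1L))),
                  cumsum(ex_len))
      if (n_ex > 1L) {
        pieces[seq(2L, by = 2L, length.out = n_ex - 1L)] <-
          vapply(in_len, function(l) paste(random_dna(l, spec$gc),
                                           collapse = ""), character(1))
      }
      block <- paste(pieces, collapse = "")
      if (strand == "-") block <- revcomp(block)
      genome[(gstart + 1L):(gstart + glen)] <- strsplit(block, "")[[1]]
      # genomic exon/intron intervals (order flips for minus strand)
      seg_len <- integer(0)
      for (k in seq_len(n_ex)) {
        seg_len <- c(seg_len, ex_len[k])
        if (k < n_ex) seg_len <- c(seg_len, in_len[k])
      }
      if (strand == "-") seg_len <- rev(seg_len)
      seg_end <- gstart + cumsum(seg_len)
      seg_start <- c(gstart, head(seg_end, -1L))
      is_exon <- rep(c(TRUE, FALSE), length.out = length(seg_len))
      gid <- paste0(s, "_g", gi); mid <- paste0(s, "_m", gi)
      ex_idx <- which(is_exon)
      fts[[length(fts) + 1L]] <- bind_rows(
        tibble(seq_id = "chr1", start = gstart, end = gstart + glen,
               strand = strand, ftype = "gene", feature_id = gid,
               parent_id = NA_character_),
        tibble(seq_id = "chr1", start = gstart, end = gstart + glen,
               strand = strand, ftype = "mRNA", feature_id = mid,
               parent_id = gid),
        tibble(seq_id = "chr1", start = seg_start[ex_idx],
               end = seg_end[ex_idx], strand = strand, ftype = "exon",
               feature_id = paste0(mid, "_e", seq_along(ex_idx)),
               parent_id = mid),
        tibble(seq_id = "chr1", start = seg_start[ex_idx],
               end = seg_end[ex_idx], strand = strand, ftype = "CDS",
               feature_id = paste0(mid, "_c", seq_along(ex_idx)),
               parent_id = mid)
      )
      if (any(!is_exon)) {
        intr[[length(intr) + 1L]] <-
          tibble(start = seg_start[!is_exon], end = seg_end[!is_exon])
      }
      if (kind == "ordinary") {
        function_rows[[length(function_rows) + 1L]] <-
          tibble(subject_id = mid,
                 label = sample(c("known_function", "hypothetical"), 1L))
      }
    }
    genomes[[s]] <- genome
    features[[s]] <- bind_rows(fts)
    introns[[s]] <- if (length(intr)) bind_rows(intr) else
      tibble(start = integer(), end = integer())
    occupied[[s]] <- occ
  }
  # plant sORF families
  truth <- list()
  if (spec$n_sorf_families > 0L) {
    for (f in seq_len(spec$n_sorf_families)) {
      fam_id <- sprintf("fam%02d", f)
      len <- sample_one(spec$sorf_length_range[1]:spec$sorf_length_range[2])
      anc_codons <- c(reverse_translate(random_peptide(len)),
                      sample(STOP_CODONS, 1L))
      k <- sample_one(spec$family_size_range[1]:spec$family_size_range[2])
      fam_species <- sample(species, k)
      for (s in fam_species) {
        codons <- mutate_codons(anc_codons, spec$substitution_rate)
        # keep the terminal codon a stop (mutate only among stops)
        codons[length(codons)] <- sample(STOP_CODONS, 1L)
        orf <- paste(codons, collapse = "")
        orf_len <- nchar(orf)
        chunk_len <- orf_len + 3L   # adjacent in-frame upstream stop guard
        strand <- sample(c("+", "-"), 1L)
        label <- sample(names(spec$region_mix), 1L, prob = spec$region_mix)
        occ <- occupied[[s]]
        pos <- NA_integer_
        if (label == "intronic") {
          cand <- introns[[s]] |>
            filter(.data$end - .data$start >= chunk_len + 12L)
          if (nrow(cand) > 0L) {
            # try introns in random order until one has a free slot
            for (ci in sample.int(nrow(cand))) {
              slot_lo <- cand$start[ci] + 6L
              slot_hi <- cand$end[ci] - 6L
              pos <- tryCatch(
                place_interval(occ, chunk_len, slot_lo, slot_hi,
                               margin = 3L, max_tries = 200L),
                error = function(e) NA_integer_)
              if (!is.na(pos)) break
            }
          }
          if (is.na(pos)) label <- "intergenic"
        }
        if (label == "intergenic") {
          pos <- place_interval(occ, chunk_len, 100L,
                                spec$genome_length - 100L, margin = 30L)
        }
        occupied[[s]] <- bind_rows(occ, tibble(start = pos,
                                               end = pos + chunk_len))
        if (strand == "+") {
          chunk <- paste0("TAA", orf)
          orf_start <- pos + 3L
        } else {
          chunk <- revcomp(paste0("TAA", orf))
          orf_start <- pos
        }
        genomes[[s]][(pos + 1L):(pos + chunk_len)] <- strsplit(chunk, "")[[1]]
        truth[[length(truth) + 1L]] <- tibble(
          family_id = fam_id, species_id = s, seq_id = "chr1",
          start = orf_start, end = orf_start + orf_len, strand = strand,
          region_label = label,
          peptide = translate_dna(substr(orf, 1L, orf_len - 3L))
        )
      }
    }
  }
  bundles <- lapply(species, function(s) {
    genome_bundle(s, c(chr1 = paste(genomes[[s]], collapse = "")),
                  features[[s]] |> arrange(.data$start, .data$feature_id))
  })
  names(bundles) <- species
  list(
    bundles = bundles,
    truth = if (length(truth)) {
      bind_rows(truth) |> arrange(.data$family_id, .data$species_id)
    } else {
      tibble(family_id = character(), species_id = character(),
             seq_id = character(), start = integer(), end = integer(),
             strand = character(), region_label = character(),
             peptide = character())
    },
    function_table = if (length(function_rows)) bind_rows(function_rows) else
      tibble(subject_id = character(), label = character()),
    spec = spec
  )
}

#' Write a generated fixture to disk
#'
#' Emits `<species>.fasta` and `<species>.gff` per species plus
#' `truth.tsv` and `function_table.tsv`.
#'
#' @param gen Output of [generate_genomes()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_bundles <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(gen$bundles)) {
    b <- gen$bundles[[s]]
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(b$sequences),
                                file.path(dir, paste0(s, ".fasta")))
    write_gff3(b$features, file.path(dir, paste0(s, ".gff")))
  }
  readr::write_tsv(gen$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(gen$function_table, file.path(dir, "function_table.tsv"))
  invisible(dir)
}

#' Score pipeline output against planted ground truth
#'
#' Truth copies are matched to cluster members by exact genomic interval.
#' A family counts as recovered when some conserved cluster contains its
#' copies from at least two species and no copies of any other family
#' (purity). `false_cluster_count` counts impure conserved clusters —
#' those mixing copies of two or more families. Conserved clusters that
#' match no truth copy at all (chance agglomerations of short background
#' ORFs) are reported separately as `spurious_conserved`, and
#' `truth_matching_conserved` counts conserved clusters containing at
#' least one truth copy.
#'
#' @param clusters Member-level cluster tibble (after [call_conserved()]).
#' @param truth Truth tibble from [generate_genomes()].
#' @param min_species Species threshold used for recovery (default 2).
#' @return One-row tibble: `family_recall`, `copy_recall`,
#'   `false_cluster_count`, `truth_matching_conserved`,
#'   `spurious_conserved`, `n_conserved_clusters`, `n_families`.
#' @export
score_recovery <- function(clusters, truth, min_species = 2L) {
  if (!"conserved" %in% names(clusters)) clusters <- call_conserved(clusters)
  cons <- clusters |> filter(.data$conserved)
  matched <- cons |>
    left_join(truth |>
                select("family_id", "species_id", "seq_id", "start", "end",
                       "strand"),
              by = c("species_id", "seq_id", "start", "end", "strand"))
  per_cluster <- matched |>
    group_by(.data$cluster_id) |>
    summarise(
      n_fam = dplyr::n_distinct(.data$family_id, na.rm = TRUE),
      fam = if (dplyr::n_distinct(.data$family_id, na.rm = TRUE) == 1L)
        .data$family_id[!is.na(.data$family_id)][1L] else NA_character_,
      n_truth_species = dplyr::n_distinct(
        .data$species_id[!is.na(.data$family_id)]),
      .groups = "drop")
  eligible_fams <- truth |>
    group_by(.data$family_id) |>
    summarise(n_sp = dplyr::n_distinct(.data$species_id), .groups = "drop") |>
    filter(.data$n_sp >= .env$min_species)
  recovered <- per_cluster |>
    filter(.data$n_fam == 1L, .data$n_truth_species >= .env$min_species,
           .data$fam %in% eligible_fams$family_id)
  n_fam <- nrow(eligible_fams)
  copies_in_recovered <- matched |>
    inner_join(recovered |> select("cluster_id", "fam"),
               by = "cluster_id") |>
    filter(!is.na(.data$family_id), .data$family_id == .data$fam)
  tibble(
    family_recall = if (n_fam == 0L) NA_real_ else
      length(unique(recovered$fam)) / n_fam,
    copy_recall = if (nrow(truth) == 0L) NA_real_ else
      nrow(copies_in_recovered) / nrow(truth),
    false_cluster_count = sum(per_cluster$n_fam > 1L),
    truth_matching_conserved = sum(per_cluster$n_fam >= 1L),
    spurious_conserved = sum(per_cluster$n_fam == 0L),
    n_conserved_clusters = dplyr::n_distinct(cons$cluster_id),
    n_families = n_fam
  )
}
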
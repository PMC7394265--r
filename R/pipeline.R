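#' Pipeline configuration
#'
#' Defaults reproduce the workflow's canonical parameters: the 80-codon
#' (240 nt) small-ORF cap, the 0.5 coding-probability threshold, the
#' exact-interval consensus, the two-thirds-coverage / 30%-identity
#' homology filter, 70% clustering identity, conservation across at least
#' two species, and 1000 bootstrap replicates.
#'
#' @param max_codons,min_codons Peptide length window for candidates.
#' @param coding_threshold Coding-probability cutoff (inclusive).
#' @param consensus_mode `"exact_interval"` or `"shared_stop"`.
#' @param min_coverage,min_identity,filter_mode Homology filter settings
#'   (see [filter_hits()]).
#' @param cluster_identity Greedy clustering threshold.
#' @param min_species Species count for a conserved call.
#' @param bootstrap_reps Bootstrap replicates per conserved-cluster tree.
#' @param seed Integer seed; required when `bootstrap_reps > 0`.
#' @param output_dir Optional directory for on-disk artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(max_codons = 80L, min_codons = 10L,
                            coding_threshold = 0.5,
                            consensus_mode = c("exact_interval", "shared_stop"),
                            min_coverage = 2 / 3, min_identity = 0.30,
                            filter_mode = c("AND_retain", "OR_retain"),
                            cluster_identity = 0.70, min_species = 2L,
                            bootstrap_reps = 1000L, seed = NULL,
                            output_dir = NULL) {
  consensus_mode <- match.arg(consensus_mode)
  filter_mode <- match.arg(filter_mode)
  stopifnot(max_codons >= min_codons, min_codons >= 1L,
            coding_threshold >= 0, coding_threshold <= 1,
            min_coverage >= 0, min_coverage <= 1,
            min_identity >= 0, min_identity <= 1,
            cluster_identity >= 0, cluster_identity <= 1,
            min_species >= 1L, bootstrap_reps >= 0L)
  if (bootstrap_reps > 0L && is.null(seed)) {
    stop("a seed is required when bootstrap_reps > 0")
  }
  structure(list(max_codons = as.integer(max_codons),
                 min_codons = as.integer(min_codons),
                 coding_threshold = coding_threshold,
                 consensus_mode = consensus_mode,
                 min_coverage = min_coverage, min_identity = min_identity,
                 filter_mode = filter_mode,
                 cluster_identity = cluster_identity,
                 min_species = as.integer(min_species),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

read_bundle_dir <- function(genome_dir) {
  fastas <- sort(list.files(genome_dir, pattern = "\\.(fa|fasta|fna)$",
                            full.names = TRUE))
  bundles <- list()
  for (f in fastas) {
    sp <- sub("\\.(fa|fasta|fna)$", "", basename(f))
    gff <- file.path(genome_dir, paste0(sp, ".gff"))
    if (!file.exists(gff)) gff <- file.path(genome_dir, paste0(sp, ".gff3"))
    if (!file.exists(gff)) {
      warning("no GFF for ", basename(f), "; species skipped")
      next
    }
    bundles[[sp]] <- read_genome_bundle(f, gff, species_id = sp)
  }
  if (length(bundles) == 0L) stop("no usable species bundles in ", genome_dir)
  bundles
}

#' Run the full conserved-sORF discovery workflow
#'
#' Executes, in order: region partition, annotation screen, six-frame
#' scan of intergenic and intronic space, per-species hexamer-model
#' training (CDS vs intergenic) and coding filter, consensus of the two
#' predictors, pooling, homology screen against all annotated proteins,
#' exact-duplicate removal, greedy clustering, conserved-cluster calling
#' and per-cluster bootstrap NJ trees. Per-stage in/out counts are
#' recorded per species and in total.
#'
#' @param input A directory containing `<species>.fasta` + `<species>.gff`
#'   pairs (plus optional `function_table.tsv`), a list of
#'   `genome_bundle`s, or the output of [generate_genomes()].
#' @param config A [pipeline_config()].
#' @param function_table Optional tibble (`subject_id`, `label`) for
#'   homology status; overrides any on-disk table.
#' @return A `sorf_run` object: `records` (pooled, annotated sORF
#'   records), `clusters` (member-level, with conservation flags),
#'   `trees` (Newick-ready `phylo` per conserved cluster), `breadth`,
#'   `stage_counts`, `species_counts`, `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(seed = 1L),
                         function_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(input)) {
    if (is.null(function_table)) {
      ft_path <- file.path(input, "function_table.tsv")
      if (file.exists(ft_path)) {
        function_table <- readr::read_tsv(ft_path, show_col_types = FALSE)
      }
    }
    bundles <- read_bundle_dir(input)
  } else if (is.list(input) && !is.null(input$bundles)) {
    if (is.null(function_table)) function_table <- input$function_table
    bundles <- input$bundles
  } else {
    bundles <- input
  }
  stopifnot(length(bundles) >= 1L)

  # first pass: regions, scans and training corpora per species; the
  # hexamer model is trained once on the pooled corpora of all species
  # (coding usage is shared at this scale, and pooling stabilises both the
  # log-odds table and the calibration)
  stage <- list()
  for (s in names(bundles)) {
    b <- bundles[[s]]
    regions <- partition_regions(b)
    scanner_set <- scan_bundle(b, regions,
                               region_labels = c("intergenic", "intronic"),
                               min_codons = config$min_codons,
                               max_codons = config$max_codons) |>
      mutate(species_id = s)
    prots <- extract_cds_proteins(b)
    intergenic_seqs <- extract_region_sequences(
      b, regions |> filter(.data$label == "intergenic")) |>
      filter(.data$strand == "+") |> pull("seq")
    stage[[s]] <- list(bundle = b, regions = regions,
                       scanner_set = scanner_set, prots = prots,
                       intergenic = intergenic_seqs)
  }
  all_cds <- unlist(lapply(stage, function(x) x$prots$cds_nt),
                    use.names = FALSE)
  all_intergenic <- unlist(lapply(stage, function(x) x$intergenic),
                           use.names = FALSE)
  model <- if (length(all_cds) > 0L && length(all_intergenic) > 0L) {
    train_hexamer_model(all_cds, all_intergenic)
  } else {
    NULL
  }

  per_species <- list()
  pooled <- list()
  db <- list()
  for (s in names(bundles)) {
    b <- stage[[s]]$bundle
    regions <- stage[[s]]$regions
    scanner_set <- stage[[s]]$scanner_set
    prots <- stage[[s]]$prots
    annotated <- screen_annotated_sorfs(b, max_codons = config$max_codons)
    coding_set <- scanner_set
    if (!is.null(model) && nrow(scanner_set) > 0L) {
      coding_set <- filter_by_probability(
        score_candidates(scanner_set, model),
        threshold = config$coding_threshold, max_codons = config$max_codons)
    }
    consensus <- consensus_orfs(scanner_set, coding_set,
                                match_mode = config$consensus_mode)
    pooled[[s]] <- pool_sorfs(annotated, consensus)
    db[[s]] <- prots |> select(subject_id = "transcript_id", "aa_seq")
    per_species[[s]] <- tibble(
      species_id = s,
      n_intergenic = sum(regions$label == "intergenic"),
      n_intronic = sum(regions$label == "intronic"),
      n_annotated = nrow(annotated),
      n_scanner = nrow(scanner_set),
      n_coding = nrow(coding_set),
      n_consensus = nrow(consensus),
      n_pooled = nrow(pooled[[s]])
    )
  }
  records <- bind_rows(pooled)
  db <- bind_rows(db)
  if (nrow(records) > 0L && nrow(db) > 0L) {
    hits <- search_homologs(records, db)
    retained <- filter_hits(hits, min_coverage = config$min_coverage,
                            min_identity = config$min_identity,
                            combine = config$filter_mode)
    records <- assign_homology_status(records, retained, function_table)
  }
  # duplicate removal is per species: identical sequences from different
  # genomes are independent observations and must survive to support a
  # conserved call
  unique_records <- records |>
    split(records$species_id) |>
    lapply(dedup_identical) |>
    bind_rows() |>
    arrange(.data$species_id, .data$seq_id, .data$start)
  clusters <- greedy_cluster(unique_records,
                             threshold = config$cluster_identity) |>
    call_conserved(min_species = config$min_species)
  trees <- build_cluster_trees(clusters, n_reps = config$bootstrap_reps,
                               seed = config$seed)
  breadth <- conservation_breadth(clusters, length(bundles))
  summ <- cluster_summary(clusters)
  species_counts <- bind_rows(per_species)
  stage_counts <- tibble(
    stage = c("pooled", "after_dedup", "clusters", "conserved_clusters",
              "conserved_records"),
    count = c(nrow(records), nrow(unique_records), nrow(summ),
              sum(summ$conserved), sum(clusters$conserved))
  )
  run <- structure(list(records = unique_records, clusters = clusters,
                        trees = trees, breadth = breadth,
                        species_counts = species_counts,
                        stage_counts = stage_counts, config = config),
                   class = "sorf_run")
  if (!is.null(config$output_dir)) write_run_outputs(run, config$output_dir)
  run
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$records |> select(-dplyr::any_of("coding_flag")),
                   file.path(dir, "sorf_records.tsv"))
  write_sorf_fasta(run$records, file.path(dir, "sorf_peptides.fasta"))
  write_cluster_tsv(run$clusters, file.path(dir, "clusters.tsv"))
  readr::write_tsv(run$species_counts, file.path(dir, "species_counts.tsv"))
  readr::write_tsv(run$stage_counts, file.path(dir, "stage_counts.tsv"))
  for (cid in names(run$trees)) {
    write_newick(run$trees[[cid]], file.path(dir, paste0(cid, ".nwk")))
  }
  report <- list(
    config = run$config[setdiff(names(run$config), "output_dir")],
    species_counts = run$species_counts,
    stage_counts = run$stage_counts
  )
  jsonlite::write_json(report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.sorf_run <- function(x, ...) {
  cat("<sorf_run> ", nrow(x$species_counts), " species, ",
      nrow(x$records), " pooled sORF records, ",
      sum(cluster_summary(x$clusters)$conserved), " conserved cluster(s)\n",
      sep = "")
  print(x$stage_counts)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.sorf_run <- function(x, ...) {
  summ <- cluster_summary(x$clusters)
  tibble(
    n_species = nrow(x$species_counts),
    n_annotated = sum(x$species_counts$n_annotated),
    n_scanner = sum(x$species_counts$n_scanner),
    n_consensus = sum(x$species_counts$n_consensus),
    n_pooled = sum(x$species_counts$n_pooled),
    n_unique = nrow(x$records),
    n_clusters = nrow(summ),
    n_conserved_clusters = sum(summ$conserved),
    n_conserved_records = sum(x$clusters$conserved)
  )
}

#' @exportS3Method generics::tidy
tidy.sorf_run <- function(x, ...) {
  cluster_summary(x$clusters)
}
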
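make_cds_bundle <- function(n_codons) {
  # single-exon gene whose CDS encodes n_codons residues plus a stop
  withr::with_seed(100 + n_codons, {
    pep <- paste0("M", random_peptide_str(n_codons - 1L))
    nt <- paste0(paste(sorfscan:::reverse_translate(pep), collapse = ""), "TAA")
  })
  left <- strrep("C", 50)
  genome <- paste0(left, nt, strrep("G", 50))
  len <- nchar(nt)
  fts <- tibble::tibble(
    seq_id = "chr1", start = c(50L, 50L, 50L, 50L),
    end = rep(50L + len, 4), strand = "+",
    ftype = c("gene", "mRNA", "exon", "CDS"),
    feature_id = c("g1", "m1", "e1", "c1"),
    parent_id = c(NA, "g1", "m1", "m1"))
  genome_bundle("sp", c(chr1 = genome), fts)
}

test_that("annotation screen keeps 80-codon CDS and drops 81", {
  r80 <- screen_annotated_sorfs(make_cds_bundle(80L))   # 243 nt with stop
  expect_equal(nrow(r80), 1L)
  expect_equal(r80$n_codons, 80L)
  expect_equal(r80$source, "annotation")
  expect_equal(r80$feature_id, "m1")
  r81 <- screen_annotated_sorfs(make_cds_bundle(81L))   # 246 nt
  expect_equal(nrow(r81), 0L)
})

test_that("broken-frame CDS is skipped with a warning", {
  b <- make_cds_bundle(30L)
  i <- which(b$features$ftype == "CDS")
  b$features$end[i] <- b$features$end[i] + 1L   # 100-nt-style frame break
  expect_warning(r <- screen_annotated_sorfs(b), "divisible")
  expect_equal(nrow(r), 0L)
})

base_cand <- function(start, end, strand = "+", species = "sp1",
                      prob = NA_real_) {
  tibble::tibble(species_id = species, seq_id = "chr1",
                 region_label = "intergenic", strand = strand,
                 frame = 0L, start = start, end = end,
                 nt_seq = "ATGAAATAA", aa_seq = "MK", n_codons = 2L,
                 kozak = "negative", coding_probability = prob)
}

test_that("exact-interval consensus keeps only shared intervals", {
  scanner <- dplyr::bind_rows(base_cand(0L, 9L), base_cand(30L, 39L))
  coding <- base_cand(0L, 9L, prob = 0.9)
  cons <- consensus_orfs(scanner, coding)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 0L)
  expect_equal(cons$coding_probability, 0.9)
  expect_equal(cons$source, "ab_initio")
  expect_true(startsWith(cons$record_id, "sp1-sf"))
})

test_that("shared-stop consensus collapses alternative starts", {
  # two ATGs sharing one stop: scanner reports the long one, the coding
  # predictor the short one
  scanner <- base_cand(0L, 12L)
  coding <- base_cand(3L, 12L, prob = 0.8)
  expect_equal(nrow(consensus_orfs(scanner, coding, "exact_interval")), 0L)
  ss <- consensus_orfs(scanner, coding, "shared_stop")
  expect_equal(nrow(ss), 1L)
  expect_equal(c(ss$start, ss$end), c(0L, 12L))   # scanner's coordinates
  expect_equal(ss$coding_probability, 0.8)
  # on the minus strand the stop is at the interval start
  scanner_m <- base_cand(0L, 12L, strand = "-")
  coding_m <- base_cand(0L, 9L, strand = "-", prob = 0.7)
  ssm <- consensus_orfs(scanner_m, coding_m, "shared_stop")
  expect_equal(nrow(ssm), 1L)
  expect_equal(ssm$end, 12L)
})

test_that("consensus size is bounded by both input sets", {
  withr::with_seed(21, {
    scanner <- dplyr::bind_rows(lapply(seq(0, 90, 10),
                                       function(s) base_cand(s, s + 9L)))
    coding <- scanner[sample(10, 6), ]
  })
  cons <- consensus_orfs(scanner, coding)
  expect_lte(nrow(cons), min(nrow(scanner), nrow(coding)))
  expect_equal(nrow(consensus_orfs(scanner, coding[0, ])), 0L)
})

test_that("pooling prefers annotation on duplicates and is idempotent", {
  ann <- base_cand(0L, 9L) |>
    dplyr::mutate(source = "annotation", record_id = "sp1-gi_m1",
                  feature_id = "m1")
  ab <- dplyr::bind_rows(base_cand(0L, 9L), base_cand(50L, 59L)) |>
    dplyr::mutate(source = "ab_initio",
                  record_id = c("sp1-sf1", "sp1-sf2"))
  pooled <- pool_sorfs(ann, ab)
  expect_equal(nrow(pooled), 2L)
  expect_equal(pooled$source[pooled$start == 0L], "annotation")
  again <- pool_sorfs(pooled, pooled[0, ])
  expect_equal(again, pooled)
  # disjoint sets concatenate
  expect_equal(nrow(pool_sorfs(ann, ab[2, ])), 2L)
  expect_equal(pool_sorfs(ann, ab[0, ])$record_id, ann$record_id)
})
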
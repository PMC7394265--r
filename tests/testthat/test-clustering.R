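`%||%` <- function(a, b) if (is.null(a)) b else a

rec_tbl <- function(aa, ids = NULL, species = NULL, nt = NA_character_,
                    source = "ab_initio") {
  n <- length(aa)
  if (is.null(ids)) ids <- paste0("r", seq_len(n))
  if (is.null(species)) species <- rep("sp1", n)
  tibble::tibble(
    record_id = ids,
    species_id = species,
    seq_id = "chr1", region_label = "intergenic", strand = "+",
    frame = 0L, start = seq_len(n) * 100L, end = seq_len(n) * 100L + 30L,
    nt_seq = nt, aa_seq = aa, n_codons = nchar(aa),
    kozak = "negative", source = source, feature_id = NA_character_,
    coding_probability = NA_real_, homology_status = "none")
}

test_that("exact duplicates collapse with annotation preference", {
  r <- rec_tbl(c("MKVLA", "MKVLA", "MKVLT"),
               ids = c("b", "a", "c"))
  r$source <- c("ab_initio", "annotation", "ab_initio")
  expect_message(out <- dedup_identical(r), "removed 1")
  expect_equal(nrow(out), 2L)
  expect_true("a" %in% out$record_id)     # annotation survivor
  expect_false("b" %in% out$record_id)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(nrow(dedup_identical(r[0, ])), 0L)
})

test_that("pairwise identity uses the shorter-sequence denominator", {
  withr::with_seed(41, a <- random_peptide_str(20))
  expect_equal(pairwise_identity(a, a), 1)
  # 5 substitutions in 20 residues, gap-free -> 15/20
  a <- "ACDEFGHIKLMNPQRSTVWY"
  b <- "WCDEWGHIWLMNWQRSTVWA"    # differs at positions 1, 5, 9, 13, 20
  expect_equal(pairwise_identity(a, b), 15 / 20)
  expect_equal(pairwise_identity("KKKK", "DDDD"), 0)
})

test_that("greedy clustering follows the documented procedure", {
  withr::with_seed(42, a <- random_peptide_str(40))
  a_prime <- a
  idx <- seq(1, 37, 4)   # 10 substitutions -> 75% identity
  for (i in idx) {
    substr(a_prime, i, i) <- setdiff(c("A", "G"), substr(a, i, i))[1]
  }
  withr::with_seed(43, b <- random_peptide_str(35))
  r <- rec_tbl(c(a, a_prime, b), ids = c("A", "Ap", "B"))
  cl <- greedy_cluster(r)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 2L)
  expect_equal(cl$cluster_id[cl$record_id == "A"],
               cl$cluster_id[cl$record_id == "Ap"])
  expect_gte(cl$identity_to_rep[cl$record_id == "Ap"], 0.70)
  # representative is the longest member
  expect_true(cl$is_representative[cl$record_id == "A"])
})

test_that("identity exactly at the threshold joins the cluster", {
  rep_seq <- "ACDEFGHIKL"          # 10 residues
  mem <- "ACDEFGHWYV"              # 7 identical -> exactly 0.70
  expect_equal(pairwise_identity(mem, rep_seq), 0.7)
  cl <- greedy_cluster(rec_tbl(c(rep_seq, mem), ids = c("R", "M")))
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1L)
})

test_that("clustering partitions records and respects the identity contract", {
  withr::with_seed(44, {
    seqs <- c(
      vapply(1:15, function(i) random_peptide_str(sample(10:50, 1)),
             character(1)))
    fam <- random_peptide_str(30)
    variants <- vapply(1:5, function(i) {
      v <- fam
      for (p in sample(30, 3)) substr(v, p, p) <- sample(c("A", "L"), 1)
      v
    }, character(1))
  })
  r <- rec_tbl(unique(c(seqs, variants)))
  cl <- greedy_cluster(r)
  expect_setequal(cl$record_id, r$record_id)
  expect_equal(anyDuplicated(cl$record_id), 0L)
  expect_true(all(cl$identity_to_rep >= 0.70))
  # post-hoc recheck against the representative
  for (cid in unique(cl$cluster_id)) {
    mem <- cl[cl$cluster_id == cid, ]
    rep_seq <- mem$aa_seq[mem$is_representative]
    expect_true(all(pairwise_identity(mem$aa_seq, rep_seq) >= 0.70))
  }
})

test_that("clustering is order-invariant and prefilter is lossless", {
  withr::with_seed(45, {
    r <- rec_tbl(vapply(1:25, function(i) random_peptide_str(sample(10:40, 1)),
                        character(1)))
  })
  ref <- greedy_cluster(r)
  key <- function(cl) {
    unname(split(sort(cl$record_id), cl$cluster_id[order(cl$record_id)]))
  }
  withr::with_seed(46, {
    for (i in 1:5) {
      perm <- greedy_cluster(r[sample(nrow(r)), ])
      expect_equal(key(perm), key(ref))
    }
  })
  expect_equal(key(greedy_cluster(r, prefilter = FALSE)), key(ref))
})

test_that("lowering the threshold never increases the cluster count", {
  withr::with_seed(47, {
    r <- rec_tbl(vapply(1:20, function(i) random_peptide_str(sample(10:30, 1)),
                        character(1)))
  })
  n_at <- vapply(c(0.9, 0.7, 0.5, 0.3), function(th) {
    dplyr::n_distinct(greedy_cluster(r, threshold = th)$cluster_id)
  }, numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("conservation calls require two species and flag breadth", {
  r <- rec_tbl(c("MKVLAMKVLA", "MKVLAMKVLA", "MKVVAMKVLA", "WWWWWWWWWW"),
               ids = c("x1", "x2", "x3", "y1"),
               species = c("spA", "spB", "spA", "spC"))
  r$nt_seq <- c("ATG1", "ATG2", "ATG3", "ATG4")  # distinct, no dedup
  cl <- call_conserved(greedy_cluster(dedup_identical(r)))
  summ <- cluster_summary(cl)
  big <- summ[summ$n_members == 3L, ]
  expect_true(big$conserved)
  expect_false(summ$conserved[summ$n_members == 1L])
  br <- conservation_breadth(cl, n_species_total = 4L)
  expect_equal(nrow(br), 1L)
  expect_equal(br$breadth, 0.5)
  expect_equal(as.character(br$bin), "(1/4,1/2]")
  # single-species cluster set: no conserved clusters, empty breadth
  r2 <- rec_tbl(c("MKVLAMKVLA", "WWWWWWWWWW"), species = c("spA", "spA"))
  br2 <- conservation_breadth(call_conserved(greedy_cluster(r2)), 4L)
  expect_equal(nrow(br2), 0L)
})
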
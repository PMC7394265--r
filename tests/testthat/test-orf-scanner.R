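test_that("basic ORF calls match direct translation", {
  r <- scan_orfs("ATGAAATAA", min_codons = 1L)
  expect_equal(nrow(r), 1L)
  expect_equal(r$aa_seq, "MK")
  expect_equal(r$n_codons, 2L)
  expect_equal(c(r$start, r$end), c(0L, 9L))
  expect_equal(r$nt_seq, "ATGAAATAA")
})

test_that("start-codon modes enumerate ATGs as specified", {
  lp <- scan_orfs("ATGATGAAATAA", min_codons = 1L)
  expect_equal(nrow(lp), 1L)
  expect_equal(lp$start, 0L)
  expect_equal(lp$aa_seq, "MMK")
  as <- scan_orfs("ATGATGAAATAA", min_codons = 1L, mode = "all_starts")
  expect_equal(nrow(as), 2L)
  expect_equal(sort(as$start), c(0L, 3L))
  expect_equal(unique(as$end), 12L)
})

test_that("the 80-codon cap is respected at the boundary", {
  withr::with_seed(5, {
    aa80 <- paste0("ATG", strrep("GCT", 79L), "TAA")   # 80 codons + stop
    aa81 <- paste0("ATG", strrep("GCT", 80L), "TAA")   # 81 codons + stop
  })
  expect_equal(scan_orfs(aa80, min_codons = 1L)$n_codons, 80L)
  expect_equal(nrow(scan_orfs(aa81, min_codons = 1L)), 0L)
})

test_that("codons containing N break open frames", {
  # ATG AAN AAA TAA: the N codon severs the ORF
  expect_equal(nrow(scan_orfs("ATGAANAAATAA", min_codons = 1L)), 0L)
  # N after the stop is harmless
  expect_equal(nrow(scan_orfs("ATGAAATAANNN", min_codons = 1L)), 1L)
})

test_that("short sequences yield an empty candidate list", {
  expect_equal(nrow(scan_orfs("ATGTAA", min_codons = 5L)), 0L)
})

test_that("genome mapping mirrors coordinates on the minus strand", {
  orfs <- tibble::tibble(frame = 0L, start = 5L, end = 20L, nt_seq = "x",
                         aa_seq = "y", n_codons = 4L)
  reg <- list(seq_id = "chr1", start = 100L, end = 200L, label = "intergenic")
  plus <- map_to_genome(orfs, reg, "+")
  expect_equal(c(plus$start, plus$end), c(105L, 120L))
  orfs2 <- dplyr::mutate(orfs, start = 0L, end = 15L)
  minus <- map_to_genome(orfs2, reg, "-")
  expect_equal(c(minus$start, minus$end), c(185L, 200L))
  full <- map_to_genome(dplyr::mutate(orfs, start = 0L, end = 100L), reg, "+")
  expect_equal(c(full$start, full$end), c(100L, 200L))
  expect_error(
    map_to_genome(dplyr::mutate(orfs, start = 90L, end = 120L), reg, "+"),
    "bounds")
})

test_that("Kozak context is classified strand-aware", {
  # GCCACC ATG G: purine at -3, G at +4
  expect_equal(kozak_flag("GCCACCATGG", 6L, 9L, "+"), "positive")
  expect_equal(kozak_flag("TTTTTTATGC", 6L, 9L, "+"), "negative")
  # ATG starting at position 1: -3 context missing
  expect_equal(kozak_flag("GATGGGGGGG", 1L, 4L, "+"), "undetermined")
  # minus strand: genome is revcomp of GCCACCATGG
  g <- revcomp("GCCACCATGG")
  expect_equal(kozak_flag(g, 1L, 4L, "-"), "positive")
})

test_that("scanner agrees with the brute-force enumerator", {
  withr::with_seed(101, {
    for (i in 1:25) {
      s <- random_dna_str(sample(100:600, 1))
      for (mode in c("longest_per_stop", "all_starts")) {
        got <- scan_orfs(s, min_codons = 3L, mode = mode)
        exp <- oracle_scan_orfs(s, min_codons = 3L, mode = mode)
        expect_equal(got[, c("frame", "start", "end", "n_codons")],
                     tibble::as_tibble(exp))
      }
    }
  })
})

test_that("no emitted ORF contains an in-frame internal stop", {
  withr::with_seed(77, s <- random_dna_str(2000))
  r <- scan_orfs(s, min_codons = 2L, mode = "all_starts")
  for (aa in r$aa_seq) expect_false(grepl("*", aa, fixed = TRUE))
  expect_true(all(startsWith(r$nt_seq, "ATG")))
  expect_true(all(substr(r$nt_seq, nchar(r$nt_seq) - 2L, nchar(r$nt_seq))
                  %in% c("TAA", "TAG", "TGA")))
})

test_that("minus-strand scanning is a coordinate-mirrored bijection", {
  withr::with_seed(13, s <- random_dna_str(900))
  L <- nchar(s)
  fwd_on_rc <- scan_orfs(revcomp(s), min_codons = 3L, mode = "all_starts")
  b <- genome_bundle("sp", c(chr1 = s))
  reg <- tibble::tibble(seq_id = "chr1", start = 0L, end = L,
                        label = "genome")
  both <- scan_bundle(b, reg, region_labels = "genome", min_codons = 3L,
                      mode = "all_starts")
  minus <- both[both$strand == "-", ]
  expect_equal(nrow(minus), nrow(fwd_on_rc))
  expect_setequal(paste(L - fwd_on_rc$end, L - fwd_on_rc$start),
                  paste(minus$start, minus$end))
})
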
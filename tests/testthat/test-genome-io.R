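test_that("FASTA reading folds case, trims headers and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 some description", "acgt", ">s2", "AAUU"), f)
  seqs <- read_genome_fasta(f)
  expect_identical(seqs, c(s1 = "ACGT", s2 = "AATT"))

  writeLines(c(">a", "ACG", ">a", "TT"), f)
  expect_error(read_genome_fasta(f), "duplicate")

  writeLines(c(">a", "", ">b", "ACGT"), f)
  expect_error(read_genome_fasta(f), "empty")
})

test_that("GFF3 features convert to 0-based half-open and are filtered", {
  f <- withr::local_tempfile(fileext = ".gff")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t21\t50\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t21\t50\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\tCDS\t21\t50\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\tsrc\tregion\t1\t100\t.\t+\t.\tID=r1",
    "chr1\tsrc\tCDS\t60\t80\t.\t.\t0\tID=c2;Parent=m1"
  ), f)
  expect_warning(fts <- read_gff_features(f), "strand")
  expect_setequal(fts$ftype, c("gene", "mRNA", "CDS"))
  g <- fts[fts$feature_id == "g1", ]
  expect_equal(c(g$start, g$end), c(20L, 50L))
  expect_equal(fts$parent_id[fts$feature_id == "c1"], "m1")
  expect_false("r1" %in% fts$feature_id)
  expect_false("c2" %in% fts$feature_id)
})

test_that("region partition matches hand-derived interval arithmetic", {
  seqs <- c(chr1 = strrep("A", 100))
  # one gene [20,50) with a single exon: no introns
  fts <- tibble::tibble(
    seq_id = "chr1", start = c(20L, 20L, 20L), end = c(50L, 50L, 50L),
    strand = "+", ftype = c("gene", "mRNA", "exon"),
    feature_id = c("g1", "m1", "e1"), parent_id = c(NA, "g1", "m1"))
  reg <- partition_regions(genome_bundle("sp", seqs, fts))
  expect_equal(reg$label[reg$start == 0], "intergenic")
  expect_equal(reg[reg$label == "intergenic", ]$start, c(0L, 50L))
  expect_equal(reg[reg$label == "intergenic", ]$end, c(20L, 100L))
  expect_false("intronic" %in% reg$label)

  # gene [10,90), exons [10,30) and [60,90): intron [30,60)
  fts2 <- tibble::tibble(
    seq_id = "chr1", start = c(10L, 10L, 10L, 60L),
    end = c(90L, 90L, 30L, 90L), strand = "+",
    ftype = c("gene", "mRNA", "exon", "exon"),
    feature_id = c("g1", "m1", "e1", "e2"),
    parent_id = c(NA, "g1", "m1", "m1"))
  reg2 <- partition_regions(genome_bundle("sp", seqs, fts2))
  intr <- reg2[reg2$label == "intronic", ]
  expect_equal(c(intr$start, intr$end), c(30L, 60L))

  # no features: a single intergenic interval
  reg3 <- partition_regions(genome_bundle("sp", seqs))
  expect_equal(nrow(reg3), 1L)
  expect_equal(c(reg3$start, reg3$end, reg3$label),
               c("0", "100", "intergenic"))
})

test_that("the three region labels tile every sequence exactly", {
  gen <- tiny_gen()
  for (b in gen$bundles) {
    reg <- partition_regions(b)
    expect_equal(sum(reg$end - reg$start), sum(nchar(b$sequences)))
    # no overlaps anywhere: sorted starts must begin at previous ends
    for (sid in names(b$sequences)) {
      r <- reg[reg$seq_id == sid, ]
      r <- r[order(r$start), ]
      expect_equal(r$start, c(0L, utils::head(r$end, -1L)))
      expect_equal(r$end[nrow(r)], nchar(b$sequences[[sid]]))
    }
  }
})

test_that("reverse complement preserves N and is an involution", {
  expect_equal(revcomp("ATGC"), "GCAT")
  expect_equal(revcomp("ANT"), "ANT")
  withr::with_seed(11, {
    seqs <- vapply(1:20, function(i) random_dna_str(50), character(1))
  })
  expect_equal(revcomp(revcomp(seqs)), seqs)
})

test_that("region sequences come out on both strands", {
  b <- genome_bundle("sp", c(chr1 = "ATGCNGGG"))
  reg <- tibble::tibble(seq_id = "chr1", start = 0L, end = 4L,
                        label = "intergenic")
  rs <- extract_region_sequences(b, reg)
  expect_equal(nrow(rs), 2L)
  expect_equal(rs$seq[rs$strand == "+"], "ATGC")
  expect_equal(rs$seq[rs$strand == "-"], "GCAT")
  expect_equal(nrow(extract_region_sequences(b, reg[0, ])), 0L)
})

test_that("GFF round-trip reproduces identical intervals", {
  gen <- tiny_gen()
  fts <- gen$bundles[[1]]$features
  f <- withr::local_tempfile(fileext = ".gff")
  write_gff3(fts, f)
  back <- read_gff_features(f)
  ord <- function(x) dplyr::arrange(x, ftype, seq_id, start, end, feature_id)
  expect_equal(ord(back), ord(fts))
})

test_that("spliced CDS proteins are translated strand-aware", {
  gen <- tiny_gen()
  b <- gen$bundles[[1]]
  prots <- extract_cds_proteins(b)
  expect_gt(nrow(prots), 0L)
  expect_true(all(startsWith(prots$aa_seq, "M")))
  expect_false(any(grepl("\\*", prots$aa_seq)))
  expect_true(all(nchar(prots$cds_nt) %% 3 == 0))
  # transcripts with broken frame are skipped with a warning
  b2 <- b
  b2$features$end[which(b2$features$ftype == "CDS")[1]] <-
    b2$features$end[which(b2$features$ftype == "CDS")[1]] + 1L
  expect_warning(extract_cds_proteins(b2), "divisible")
})
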
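test_that("JTT transition matrices behave like a reversible model", {
  P0 <- jtt_prob_matrix(0)
  expect_equal(unname(P0), diag(20), tolerance = 1e-10)
  P <- jtt_prob_matrix(0.3)
  expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-10)
  pi <- sorfscan:::jtt_eigen()$pi
  # detailed balance: diag(pi) %*% P is symmetric
  expect_equal(pi * P, t(pi * P), tolerance = 1e-10)
  # equilibrium at large t
  Pinf <- jtt_prob_matrix(500)
  expect_equal(unname(Pinf[1, ]), unname(pi), tolerance = 1e-6)
})

test_that("JTT distances hit the trivial and saturated boundaries", {
  withr::with_seed(51, a <- random_peptide_str(50))
  d0 <- jtt_distance(a, a)
  expect_equal(as.numeric(d0), 0)
  expect_false(attr(d0, "unreliable"))
  # all-different saturated pair: capped at d_max
  x <- strrep("A", 40); y <- strrep("W", 40)
  expect_equal(as.numeric(jtt_distance(x, y, aligned = TRUE)), 5)
  # few comparable columns flagged unreliable
  short <- jtt_distance("MKV", "MKV", aligned = TRUE)
  expect_true(attr(short, "unreliable"))
  # symmetry
  withr::with_seed(52, {
    p <- simulate_jtt_pair(120, 0.4)
  })
  expect_equal(as.numeric(jtt_distance(p$a, p$b, aligned = TRUE)),
               as.numeric(jtt_distance(p$b, p$a, aligned = TRUE)))
})

test_that("simulated JTT pairs recover the generating distance", {
  withr::with_seed(53, {
    est <- vapply(1:20, function(i) {
      p <- simulate_jtt_pair(500, 0.3)
      as.numeric(jtt_distance(p$a, p$b, aligned = TRUE))
    }, numeric(1))
  })
  expect_gte(mean(abs(est - 0.3) <= 0.05), 0.9)
})

test_that("distances agree with an independent JTT implementation", {
  skip_if_not_installed("phangorn")
  evolve <- function(s, t) {
    P <- jtt_prob_matrix(t)
    aa <- sorfscan:::JTT_AA
    ch <- match(strsplit(s, "")[[1]], aa)
    paste(aa[vapply(ch, function(i) sample.int(20L, 1L, prob = P[i, ]),
                    integer(1))], collapse = "")
  }
  withr::with_seed(54, {
    anc <- simulate_jtt_pair(400, 0)$a
    seqs <- c(t1 = evolve(anc, 0.1), t2 = evolve(anc, 0.2),
              t3 = evolve(anc, 0.3), t4 = evolve(anc, 0.15))
  })
  ours <- jtt_distance_matrix(seqs, aligned = TRUE)
  pd <- phangorn::phyDat(t(sapply(strsplit(seqs, ""), identity)),
                         type = "AA")
  theirs <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))
  expect_equal(unname(ours), unname(theirs[names(seqs), names(seqs)]),
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("neighbor joining solves the three-point configuration exactly", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  expect_s3_class(tr, "phylo")
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_equal(write_newick(tr), "(A:1.000000,B:1.000000,C:3.000000);")
})

make_additive_dm <- function(tree) {
  dm <- ape::cophenetic.phylo(tree)
  dm[tree$tip.label, tree$tip.label]
}

test_that("NJ reconstructs trees behind additive matrices exactly", {
  t4 <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:3):0.7);")
  t5 <- ape::read.tree(text = "(((A:1,B:0.4):0.6,C:2):0.3,(D:1.2,E:0.8):0.5);")
  for (tr in list(t4, t5)) {
    out <- neighbor_joining(make_additive_dm(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(out)), 0,
                 ignore_attr = TRUE)
    expect_equal(make_additive_dm(out)[tr$tip.label, tr$tip.label],
                 make_additive_dm(tr), tolerance = 1e-9)
  }
})

test_that("NJ agrees with an independent implementation on random matrices", {
  withr::with_seed(55, {
    for (i in 1:5) {
      n <- sample(4:7, 1)
      pts <- matrix(runif(n * 3), n)
      dm <- as.matrix(dist(pts))
      rownames(dm) <- colnames(dm) <- paste0("t", 1:n)
      ours <- neighbor_joining(dm)
      theirs <- ape::nj(dm)
      expect_equal(ape::dist.topo(ours, theirs), 0, ignore_attr = TRUE)
    }
  })
})

test_that("two taxa give the trivial split tree", {
  dm <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- neighbor_joining(dm)
  expect_equal(sum(tr$edge.length), 3)
  expect_setequal(tr$tip.label, c("A", "B"))
})

test_that("newick output round-trips and quotes awkward labels", {
  t4 <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:3):0.7);")
  s <- write_newick(t4)
  back <- ape::read.tree(text = s)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(t4)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(t4$edge.length))
  t4$tip.label[1] <- "taxon one"
  expect_match(write_newick(t4), "'taxon one'", fixed = TRUE)
  # ape keeps the quote characters on re-parse; the label itself survives
  expect_equal(gsub("'", "", ape::read.tree(text = write_newick(t4))$tip.label[1]),
               "taxon one")
})

test_that("bootstrap supports are reproducible and bounded", {
  withr::with_seed(56, {
    base <- random_peptide_str(60)
    mut <- function(s, k) {
      for (p in sample(nchar(s), k)) {
        substr(s, p, p) <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 1)
      }
      s
    }
    far <- mut(base, 30)
    aln <- c(A = base, B = mut(base, 2), C = far, D = mut(far, 2))
  })
  tr1 <- bootstrap_support(aln, n_reps = 100, seed = 9)
  tr2 <- bootstrap_support(aln, n_reps = 100, seed = 9)
  expect_equal(write_newick(tr1), write_newick(tr2))
  sup <- tr1$node.label[!is.na(tr1$node.label)]
  expect_true(all(sup >= 0 & sup <= 1))
  # strong signal: the AB|CD bipartition is near-certain
  expect_gte(sup[1], 0.95)
  # no supports requested
  expect_null(bootstrap_support(aln, n_reps = 0)$node.label)
})

test_that("identical sequences produce a degenerate but valid tree", {
  aln <- setNames(rep(strrep("MKVL", 10), 3), c("A", "B", "C"))
  tr <- bootstrap_support(aln, n_reps = 10, seed = 2)
  expect_s3_class(tr, "phylo")
  expect_equal(sum(tr$edge.length), 0)
})

test_that("cluster alignment stacks members on the representative", {
  aln <- cluster_alignment(c(r1 = "MKVLLA", r2 = "MKVLA", r3 = "MKVLLAG"))
  expect_equal(unique(nchar(aln)), 7L)       # representative r3 length
  expect_equal(aln[["r3"]], "MKVLLAG")
  expect_equal(aln[["r1"]], "MKVLLA-")
})
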
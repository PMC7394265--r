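pair_substitution_counts <- function(a_chars, b_chars) {
  # 20x20 site-pattern counts over comparable columns (gap/X/other excluded)
  ai <- match(a_chars, JTT_AA)
  bi <- match(b_chars, JTT_AA)
  ok <- !is.na(ai) & !is.na(bi)
  matrix(tabulate((ai[ok] - 1L) * 20L + bi[ok], nbins = 400L), 20L, 20L,
         byrow = TRUE)
}

jtt_ml_distance_from_counts <- function(N, d_max = 5) {
  n_sites <- sum(N)
  if (n_sites == 0L) {
    # no comparable columns (e.g. a bootstrap replicate drew only gapped
    # columns for this pair): saturation cap, flagged unreliable
    return(structure(d_max, n_sites = 0L, unreliable = TRUE))
  }
  unreliable <- n_sites < 10L
  if (sum(N) == sum(diag(N))) {
    return(structure(0, n_sites = n_sites, unreliable = unreliable))
  }
  pi <- jtt_eigen()$pi
  nz <- which(N > 0, arr.ind = TRUE)
  w <- N[nz]
  negll <- function(t) {
    P <- jtt_prob_matrix(t)
    -sum(w * log(pmax(pi[nz[, 1]] * P[nz], 1e-300)))
  }
  opt <- optimize(negll, c(1e-8, d_max))
  d <- opt$minimum
  if (d > d_max - 1e-4 || negll(d_max) <= opt$objective) d <- d_max
  structure(d, n_sites = n_sites, unreliable = unreliable)
}

#' Maximum-likelihood JTT distance between two peptides
#'
#' Estimates the evolutionary separation (expected substitutions per site)
#' of two peptides under the Jones-Taylor-Thornton model by maximising the
#' site-wise likelihood `sum log(pi(a_i) P_JTT(a_i -> b_i | t))` over
#' `t` in `[0, d_max]`. Unless `aligned = TRUE`, the pair is globally
#' aligned first (BLOSUM62, gap 11/1). Columns containing a gap, `X`, or
#' any non-standard residue are excluded. Identical sequences return
#' exactly 0; saturated pairs return the `d_max` cap. Fewer than 10
#' comparable columns set the `unreliable` attribute (the distance is
#' still returned).
#'
#' @param a_aa,b_aa Peptide strings.
#' @param aligned If `TRUE`, the inputs are already aligned rows of equal
#'   length (gaps as `-`).
#' @param d_max Saturation cap, default 5 substitutions/site.
#' @return Numeric distance with attributes `n_sites` and `unreliable`.
#' @export
jtt_distance <- function(a_aa, b_aa, aligned = FALSE, d_max = 5) {
  stopifnot(length(a_aa) == 1L, length(b_aa) == 1L)
  if (!aligned) {
    p <- Biostrings::pairwiseAlignment(
      a_aa, b_aa, type = "global", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1
    )
    a_aa <- as.character(Biostrings::alignedPattern(p))
    b_aa <- as.character(Biostrings::alignedSubject(p))
  } else {
    stopifnot(nchar(a_aa) == nchar(b_aa))
  }
  N <- pair_substitution_counts(strsplit(a_aa, "")[[1]],
                                strsplit(b_aa, "")[[1]])
  jtt_ml_distance_from_counts(N, d_max = d_max)
}

#' Pairwise JTT distance matrix
#'
#' @param seqs Named character vector of peptides. With `aligned = TRUE`
#'   all elements must have equal length (rows of one alignment); gap and
#'   `X` columns are excluded per pair.
#' @inheritParams jtt_distance
#' @return Symmetric distance matrix with zero diagonal, labelled by
#'   `names(seqs)`; attribute `unreliable` is a logical matrix marking
#'   pairs with fewer than 10 comparable columns.
#' @export
jtt_distance_matrix <- function(seqs, aligned = FALSE, d_max = 5) {
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  unrel <- matrix(FALSE, n, n, dimnames = dimnames(d))
  chars <- if (aligned) strsplit(seqs, "") else NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- if (aligned) {
        jtt_ml_distance_from_counts(
          pair_substitution_counts(chars[[i]], chars[[j]]), d_max = d_max)
      } else {
        jtt_distance(seqs[[i]], seqs[[j]], d_max = d_max)
      }
      d[i, j] <- d[j, i] <- as.numeric(dij)
      unrel[i, j] <- unrel[j, i] <- isTRUE(attr(dij, "unreliable"))
    }
  }
  structure(d, unreliable = unrel)
}

clamp_pair <- function(v1, v2) {
  # clamp negative branch lengths to 0, moving the deficit to the sibling
  if (v1 < 0) { v2 <- v2 + v1; v1 <- 0 }
  if (v2 < 0) { v1 <- max(v1 + v2, 0); v2 <- 0 }
  c(v1, v2)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: the pair minimising the Q criterion is
#' joined at each step, ties broken toward the smallest (row, column)
#' index pair. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling edge. The result is an unrooted
#' `phylo` tree (stored with a basal trifurcation; a two-taxon input
#' yields the trivial single-edge tree with the distance split evenly).
#'
#' @param dm Symmetric distance matrix with taxon dimnames (or a `dist`).
#' @return An [ape::ape-package] `phylo` object.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm),
            !is.null(rownames(dm)), all(is.finite(dm)))
  taxa <- rownames(dm)
  n <- length(taxa)
  stopifnot(n >= 2L)
  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = rep(dm[1, 2] / 2, 2), tip.label = taxa,
                 Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  # node ids: 1..n tips; internal nodes allocated upward
  active <- seq_len(n)
  children <- vector("list", 2L * n)   # per internal id: list of (child, length)
  next_id <- n + 1L
  D <- dm
  ids <- active
  while (length(ids) > 3L) {
    m <- length(ids)
    r <- rowSums(D)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1L)) {
      qrow <- (m - 2) * D[i, (i + 1L):m] - r[i] - r[(i + 1L):m]
      k <- which.min(qrow)            # first minimum: smallest j wins ties
      if (qrow[k] < best - 1e-12) {   # strict: smallest i wins ties
        best <- qrow[k]; bi <- i; bj <- i + k
      }
    }
    vi <- D[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (m - 2))
    vj <- D[bi, bj] - vi
    v <- clamp_pair(vi, vj)
    children[[next_id]] <- list(list(ids[bi], v[1]), list(ids[bj], v[2]))
    keep <- setdiff(seq_len(m), c(bi, bj))
    dnew <- (D[bi, keep] + D[bj, keep] - D[bi, bj]) / 2
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew),
                c(dnew, 0))
    ids <- c(ids[keep], next_id)
    rownames(D2) <- colnames(D2) <- as.character(ids)
    D <- D2
    next_id <- next_id + 1L
  }
  # final three nodes joined at the root trifurcation (three-point formulas)
  va <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  vb <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  vc <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  children[[next_id]] <- list(list(ids[1], va), list(ids[2], vb),
                              list(ids[3], vc))
  root <- next_id
  # flatten to ape phylo numbering (tips 1..n, internals n+1.. in preorder)
  n_internal <- root - n
  edge <- matrix(0L, nrow = n + n_internal - 1L, ncol = 2L)
  elen <- numeric(nrow(edge))
  new_id <- integer(root)
  internal_counter <- n
  row <- 0L
  assign_ids <- function(node) {
    internal_counter <<- internal_counter + 1L
    new_id[node] <<- internal_counter
    for (ch in children[[node]]) {
      child <- ch[[1L]]
      row <<- row + 1L
      this_row <- row
      if (child <= n) {
        new_id[child] <<- child
        edge[this_row, ] <<- c(new_id[node], child)
      } else {
        edge[this_row, 1L] <<- new_id[node]
        assign_ids(child)
        edge[this_row, 2L] <<- new_id[child]
      }
      elen[this_row] <<- ch[[2L]]
    }
  }
  assign_ids(root)
  tree <- list(edge = edge, edge.length = elen, tip.label = taxa,
               Nnode = n_internal)
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' Representative-anchored stacked alignment of a cluster
#'
#' Globally aligns every member to the cluster representative and projects
#' it onto the representative's columns (insertions relative to the
#' representative are dropped, deletions become gaps), yielding a
#' rectangular pseudo-alignment without an external multiple-alignment
#' step. An externally computed MSA (equal-length named sequences) can be
#' used anywhere this function's output is accepted.
#'
#' @param seqs Named character vector of member peptides.
#' @param representative_id Name of the anchor sequence (default: the
#'   longest member, ties by name).
#' @return Named character vector of equal-length aligned rows.
#' @export
cluster_alignment <- function(seqs, representative_id = NULL) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (is.null(representative_id)) {
    representative_id <- names(seqs)[order(-nchar(seqs), names(seqs))][1L]
  }
  rep_seq <- seqs[[representative_id]]
  out <- setNames(character(length(seqs)), names(seqs))
  out[representative_id] <- rep_seq
  for (id in setdiff(names(seqs), representative_id)) {
    p <- Biostrings::pairwiseAlignment(
      seqs[[id]], rep_seq, type = "global",
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1
    )
    mem <- strsplit(as.character(Biostrings::alignedPattern(p)), "")[[1]]
    anc <- strsplit(as.character(Biostrings::alignedSubject(p)), "")[[1]]
    out[id] <- paste(mem[anc != "-"], collapse = "")
  }
  out
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the JTT/NJ tree from a stacked alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds the tree
#' for each replicate, and reports the fraction of replicates containing
#' each internal bipartition as node support in `[0, 1]` (stored in
#' `node.label`; the basal node carries no support). Reproducible given
#' `seed`; `n_reps = 0` returns the tree without supports.
#'
#' @param alignment Named character vector of equal-length aligned
#'   peptides (e.g. from [cluster_alignment()]).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed; required when `n_reps > 0`.
#' @param d_max Distance saturation cap passed to the JTT estimator.
#' @return A `phylo` tree, with numeric `node.label` supports when
#'   `n_reps > 0`.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = NULL,
                              d_max = 5) {
  stopifnot(length(alignment) >= 3L,
            length(unique(nchar(alignment))) == 1L)
  n_cols <- nchar(alignment[[1L]])
  stopifnot(n_cols >= 1L)
  chars <- do.call(rbind, strsplit(alignment, ""))
  tree <- neighbor_joining(jtt_distance_matrix(alignment, aligned = TRUE,
                                               d_max = d_max))
  if (n_reps == 0L) return(tree)
  stopifnot(!is.null(seed))
  boot_trees <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(rep) {
      cols <- sample.int(n_cols, n_cols, replace = TRUE)
      rs <- setNames(apply(chars[, cols, drop = FALSE], 1L, paste,
                           collapse = ""), names(alignment))
      neighbor_joining(jtt_distance_matrix(rs, aligned = TRUE,
                                           d_max = d_max))
    })
  })
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  support <- counts / n_reps
  support[1L] <- NA_real_            # basal node: no internal edge
  tree$node.label <- support
  tree
}

format_newick_label <- function(x) {
  needs_quote <- grepl("[^A-Za-z0-9_.|-]", x)
  x[needs_quote] <- paste0("'", gsub("'", "''", x[needs_quote]), "'")
  x
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with six decimal places; bootstrap supports
#' (when present in `node.label`) become internal node labels; labels
#' containing spaces or Newick metacharacters are quoted. The output
#' round-trips through [ape::read.tree()].
#'
#' @param tree A `phylo` object.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  node_label <- function(node) {
    if (is.null(tree$node.label)) return("")
    lab <- tree$node.label[node - n]
    if (is.na(lab) || identical(lab, "")) "" else
      if (is.numeric(lab)) format(lab, trim = TRUE) else
        format_newick_label(as.character(lab))
  }
  recurse <- function(node) {
    if (node <= n) return(format_newick_label(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    inner <- vapply(rows, function(r) {
      paste0(recurse(tree$edge[r, 2L]),
             sprintf(":%.6f", tree$edge.length[r]))
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")", node_label(node))
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  s <- paste0(recurse(root), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Per-cluster JTT/NJ trees for conserved clusters
#'
#' For every conserved cluster with at least three members, builds the
#' representative-anchored alignment and the bootstrap-supported NJ tree.
#'
#' @param clusters Member-level cluster tibble (after [call_conserved()]).
#' @param n_reps Bootstrap replicates per cluster.
#' @param seed Base seed; each cluster uses `seed + cluster index` so runs
#'   are reproducible and clusters independent.
#' @param d_max Distance saturation cap.
#' @return Named list of `phylo` trees, one per eligible cluster.
#' @export
build_cluster_trees <- function(clusters, n_reps = 1000L, seed = NULL,
                                d_max = 5) {
  if (!"conserved" %in% names(clusters)) clusters <- call_conserved(clusters)
  eligible <- clusters |> filter(.data$conserved)
  ids <- unique(eligible$cluster_id)
  trees <- list()
  for (k in seq_along(ids)) {
    mem <- eligible |> filter(.data$cluster_id == ids[k])
    if (nrow(mem) < 3L) next
    aln <- cluster_alignment(setNames(mem$aa_seq, mem$record_id),
                             representative_id = mem$representative_id[1L])
    trees[[ids[k]]] <- bootstrap_support(
      aln, n_reps = n_reps,
      seed = if (is.null(seed)) NULL else seed + k, d_max = d_max)
  }
  trees
}
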
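# Jones-Taylor-Thornton (1992) empirical amino-acid substitution model:
# published exchangeability counts (lower triangle, PAML amino-acid order
# ARNDCQEGHILKMFPSTWYV) and equilibrium frequencies.

JTT_AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

JTT_EXCH_LOWER <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54,
  15, 194, 378, 475, 9, 11, 298, 45, 16, 113, 310, 29,
  137, 328, 22, 38, 646, 44, 5, 74, 101, 64, 126, 20,
  17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10,
  15, 503, 232, 8, 70, 16, 10, 49, 767, 130, 112, 11,
  7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5,
  59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209,
  62, 323, 26, 597, 9, 72, 292, 43, 4, 164, 53, 51,
  18, 24, 20, 119, 26, 12, 9, 181, 18, 5, 18, 30,
  32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201,
  33, 55, 8, 47, 16, 56, 45, 33, 40, 115, 73, 46,
  8, 573, 11, 229, 21, 479, 89, 10, 40, 245, 9, 32,
  961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4,
  21, 47, 103, 10, 8, 14, 43, 16, 29, 226, 24, 18,
  323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23,
  477, 35, 63, 38, 12, 21, 112, 71, 25, 16
)

JTT_FREQ <- c(
  0.0767479233, 0.0516909483, 0.0426449574, 0.0515439485, 0.0198029802, 0.0407519592,
  0.0618299382, 0.0731519268, 0.0229439771, 0.0537609462, 0.0919039081, 0.0586759413,
  0.0238259762, 0.0401259599, 0.0509009491, 0.0687649312, 0.0585649414, 0.0142609857,
  0.0321019679, 0.0660049340
)

jtt_eigen <- function() {
  cached <- .sorfscan_cache$jtt_eigen
  if (!is.null(cached)) return(cached)
  S <- matrix(0, 20, 20, dimnames = list(JTT_AA, JTT_AA))
  S[lower.tri(S)] <- JTT_EXCH_LOWER
  S <- S + t(S)
  pi <- JTT_FREQ / sum(JTT_FREQ)
  Q <- S * rep(pi, each = 20)          # Q[i,j] = S[i,j] * pi[j]
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)          # expected rate 1 substitution/site
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))           # symmetric similarity transform
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  out <- list(pi = pi,
              left = (1 / sp) * eig$vectors,       # diag(1/sp) %*% V
              right = t(eig$vectors * sp),         # t(V) %*% diag(sp)
              values = eig$values)
  .sorfscan_cache$jtt_eigen <- out
  out
}

#' JTT transition probability matrix
#'
#' `P(t) = exp(Q t)` for the rate-normalised Jones-Taylor-Thornton model
#' (one expected substitution per site per unit time), computed through the
#' cached eigen-decomposition.
#'
#' @param t Evolutionary distance in expected substitutions per site.
#' @return A 20x20 stochastic matrix over `ARNDCQEGHILKMFPSTWYV`.
#' @export
jtt_prob_matrix <- function(t) {
  stopifnot(t >= 0)
  e <- jtt_eigen()
  P <- e$left %*% (exp(e$values * t) * e$right)
  dimnames(P) <- list(JTT_AA, JTT_AA)
  # numerical floor: eigen round-off can give tiny negatives at t ~ 0
  P[P < 0] <- 0
  P
}

#' Simulate a peptide pair under the JTT model
#'
#' Draws one sequence from the JTT equilibrium frequencies and evolves it
#' over the given distance. Uses the current RNG state; seed with
#' [set.seed()] for reproducibility.
#'
#' @param n_sites Number of sites.
#' @param distance Separation in expected substitutions per site.
#' @return List with peptide strings `a` and `b`.
#' @export
simulate_jtt_pair <- function(n_sites, distance) {
  e <- jtt_eigen()
  P <- jtt_prob_matrix(distance)
  a <- sample.int(20L, n_sites, replace = TRUE, prob = e$pi)
  b <- vapply(a, function(i) sample.int(20L, 1L, prob = P[i, ]), integer(1))
  list(a = paste(JTT_AA[a], collapse = ""), b = paste(JTT_AA[b], collapse = ""))
}
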
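all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  do.call(paste0, g)
}

hexamer_counts <- function(seqs) {
  # overlapping 6-mer counts, windows containing N excluded
  seqs <- seqs[nchar(seqs) >= 6L]
  if (length(seqs) == 0L) return(setNames(numeric(4096L), all_hexamers()))
  m <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                            width = 6L, step = 1L)
  colSums(m)
}

#' Train a hexamer log-odds coding-potential model
#'
#' Counts overlapping 6-mers (step 1, windows containing `N` skipped) in a
#' coding and a noncoding corpus, forms per-hexamer log-odds
#' `log P(h|coding) - log P(h|noncoding)` with additive smoothing, and fits
#' a 1-D logistic calibration `p = logistic(a * mean_logodds + b)` on the
#' training sequences so that scores map to a coding probability. Training
#' identical corpora yields an all-zero table and every sequence scores 0.5.
#'
#' @param coding_seqs,noncoding_seqs Non-empty character vectors of DNA
#'   sequences (typically spliced CDS vs intergenic sequence).
#' @param pseudocount Positive smoothing constant added to every hexamer
#'   count (default 1), guaranteeing finite log-odds.
#' @return Object of class `hexamer_model`.
#' @export
train_hexamer_model <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  if (length(coding_seqs) == 0L || length(noncoding_seqs) == 0L) {
    stop("both training corpora must be non-empty")
  }
  stopifnot(pseudocount > 0)
  cc <- hexamer_counts(coding_seqs)
  cn <- hexamer_counts(noncoding_seqs)
  if (sum(cc) == 0 || sum(cn) == 0) {
    stop("each corpus must contain at least one N-free hexamer")
  }
  make_logodds <- function(counts_c, counts_n) {
    log((counts_c + pseudocount) / (sum(counts_c) + 4096 * pseudocount)) -
      log((counts_n + pseudocount) / (sum(counts_n) + 4096 * pseudocount))
  }
  model <- structure(list(logodds = make_logodds(cc, cn),
                          pseudocount = pseudocount, a = 1, b = 0),
                     class = "hexamer_model")
  # calibration on a held-out split: log-odds from one half of each corpus,
  # logistic fit on the other half, so the boundary is not inflated by
  # in-sample memorisation of rare hexamers. The held-out sequences are
  # chopped into fixed-length windows (the length scale of the ORFs the
  # filter judges) and the classes balanced: full-length corpora separate
  # perfectly, which leaves the logistic maximum-likelihood boundary
  # undetermined inside the gap, whereas window scores overlap enough to
  # pin it down.
  odd_c <- seq_along(coding_seqs) %% 2L == 1L
  odd_n <- seq_along(noncoding_seqs) %% 2L == 1L
  fit_model <- model
  held_c <- coding_seqs
  held_n <- noncoding_seqs
  if (any(odd_c) && any(!odd_c) && any(odd_n) && any(!odd_n)) {
    cc_h <- hexamer_counts(coding_seqs[odd_c])
    cn_h <- hexamer_counts(noncoding_seqs[odd_n])
    if (sum(cc_h) > 0 && sum(cn_h) > 0) {
      fit_model <- structure(list(logodds = make_logodds(cc_h, cn_h),
                                  pseudocount = pseudocount, a = 1, b = 0),
                             class = "hexamer_model")
      held_c <- chop_windows(coding_seqs[!odd_c])
      held_n <- chop_windows(noncoding_seqs[!odd_n])
      n_bal <- min(length(held_c), length(held_n))
      held_c <- held_c[seq_len(n_bal)]
      held_n <- held_n[seq_len(n_bal)]
    }
  }
  # closed-form discriminant solution of the 1-D logistic: slope from the
  # pooled within-class variance, boundary at the class-mean midpoint. A
  # maximum-likelihood logistic fit is undefined whenever the window scores
  # separate completely (the usual case for well-trained corpora), leaving
  # the boundary to float anywhere inside the gap; the moment solution is
  # the equal-variance-Gaussian logistic and is always determined.
  s_c <- mean_logodds(fit_model, held_c)
  s_n <- mean_logodds(fit_model, held_n)
  s_c <- s_c[!is.na(s_c)]; s_n <- s_n[!is.na(s_n)]
  if (length(s_c) >= 2L && length(s_n) >= 2L) {
    pooled_var <- (sum((s_c - mean(s_c))^2) + sum((s_n - mean(s_n))^2)) /
      (length(s_c) + length(s_n) - 2L)
    if (pooled_var > 1e-12 && mean(s_c) > mean(s_n)) {
      model$a <- (mean(s_c) - mean(s_n)) / pooled_var
      model$b <- -model$a * (mean(s_c) + mean(s_n)) / 2
    }
  }
  model
}

chop_windows <- function(seqs, width = 240L, min_width = 60L) {
  # non-overlapping fixed-length windows; a short trailing piece is kept
  # when it still carries enough hexamers to score
  out <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L <= width) return(s)
    starts <- seq(1L, L, by = width)
    w <- substring(s, starts, pmin(starts + width - 1L, L))
    w[nchar(w) >= min_width]
  }), use.names = FALSE)
  if (length(out) == 0L) seqs else out
}

mean_logodds <- function(model, seqs) {
  # NA for sequences with no valid hexamer (too short or all-N windows)
  out <- rep(NA_real_, length(seqs))
  ok <- nchar(seqs) >= 6L
  if (!any(ok)) return(out)
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs[ok]), width = 6L, step = 1L)
  tot <- rowSums(m)
  val <- as.numeric(m %*% model$logodds)
  out[ok] <- ifelse(tot > 0, val / tot, NA_real_)
  out
}

#' Coding probability of DNA sequences under a hexamer model
#'
#' Deterministic logistic map of the mean hexamer log-odds. Sequences
#' shorter than 6 nt (or with no `N`-free window) have an undefined score
#' and are reported as probability 0.5 with flag `"too_short"`.
#'
#' @param model A `hexamer_model`.
#' @param seqs Character vector of DNA sequences.
#' @param details If `TRUE`, return a tibble with the mean log-odds and a
#'   flag column instead of the bare probability vector.
#' @return Numeric vector of probabilities in `[0, 1]` (or a tibble when
#'   `details = TRUE`).
#' @export
score_coding <- function(model, seqs, details = FALSE) {
  stopifnot(inherits(model, "hexamer_model"))
  s <- mean_logodds(model, seqs)
  p <- stats::plogis(model$a * s + model$b)
  flag <- ifelse(is.na(s), "too_short", "ok")
  p[is.na(s)] <- 0.5
  if (details) {
    return(tibble(mean_logodds = s, probability = p, flag = flag))
  }
  p
}

#' Attach coding probabilities to ORF candidates
#'
#' @param candidates Candidate tibble with an `nt_seq` column.
#' @param model A `hexamer_model`.
#' @return `candidates` with `coding_probability` and `coding_flag` columns.
#' @export
score_candidates <- function(candidates, model) {
  d <- score_coding(model, candidates$nt_seq, details = TRUE)
  candidates |>
    mutate(coding_probability = d$probability, coding_flag = d$flag)
}

#' Filter candidates by coding probability and length
#'
#' Retains candidates whose coding probability is at least `threshold`
#' (boundary inclusive) and whose peptide is at most `max_codons` residues.
#'
#' @param candidates Candidate tibble; scored with [score_candidates()]
#'   first when `model` is supplied and no `coding_probability` column
#'   exists.
#' @param model Optional `hexamer_model` used to score unscored candidates.
#' @param threshold Probability cutoff (default 0.5).
#' @param max_codons Peptide length cap (default 80).
#' @return The retained subset, same columns as input plus scores.
#' @export
filter_by_probability <- function(candidates, model = NULL, threshold = 0.5,
                                  max_codons = 80L) {
  if (!"coding_probability" %in% names(candidates)) {
    stopifnot(!is.null(model))
    candidates <- score_candidates(candidates, model)
  }
  candidates |>
    filter(.data$coding_probability >= .env$threshold,
           .data$n_codons <= .env$max_codons)
}

#' @export
print.hexamer_model <- function(x, ...) {
  cat("<hexamer_model> 4096 hexamer log-odds, pseudocount ", x$pseudocount,
      ", calibration a=", signif(x$a, 4), " b=", signif(x$b, 4), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hexamer_model <- function(x, ...) {
  tibble(hexamer = names(x$logodds), log_odds = unname(x$logodds))
}

#' @exportS3Method generics::glance
glance.hexamer_model <- function(x, ...) {
  tibble(pseudocount = x$pseudocount, calibration_scale = x$a,
         calibration_offset = x$b,
         mean_abs_log_odds = mean(abs(x$logodds)))
}

#' Serialize / deserialize a hexamer model
#'
#' The log-odds table is written as TSV (`hexamer`, `log_odds`); the
#' pseudocount and logistic calibration go into a JSON sidecar.
#'
#' @param model A `hexamer_model`.
#' @param tsv_path Path for the table; the JSON header is written next to it
#'   (`.json` extension) unless `json_path` is given.
#' @param json_path Optional explicit path for the JSON header.
#' @return `tsv_path`, invisibly ([write_hexamer_model()]); the restored
#'   model ([read_hexamer_model()]).
#' @export
write_hexamer_model <- function(model, tsv_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- paste0(sub("\\.tsv$", "", tsv_path), ".json")
  readr::write_tsv(tidy(model), tsv_path)
  jsonlite::write_json(list(pseudocount = model$pseudocount, a = model$a,
                            b = model$b),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}

#' @rdname write_hexamer_model
#' @export
read_hexamer_model <- function(tsv_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- paste0(sub("\\.tsv$", "", tsv_path), ".json")
  tab <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  hdr <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(logodds = setNames(tab$log_odds, tab$hexamer),
                 pseudocount = hdr$pseudocount, a = hdr$a, b = hdr$b),
            class = "hexamer_model")
}
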
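# PWM scanning with exact score-distribution p-values (dynamic programming
# over discretized per-position score distributions, FIMO-style) and
# class-wise motif prevalence testing around peak summits.

# Smoothed log2-odds score matrix: rows A,C,G,T; columns positions.
motif_score_matrix <- function(motif) {
  q <- t(motif$probs)                      # alphabet x position
  bg <- motif$background
  q <- (q + motif$pseudocount * bg) / (1 + motif$pseudocount)
  log2(q / bg)
}

reverse_complement_motif <- function(motif) {
  probs <- motif$probs[rev(seq_len(nrow(motif$probs))), c("T", "G", "C", "A"),
                       drop = FALSE]
  colnames(probs) <- c("A", "C", "G", "T")
  motif_model(paste0(motif$name, "_rc"), probs,
              motif$background[c("T", "G", "C", "A")], motif$pseudocount)
}

encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
}

#' Log-odds score of a motif against a sequence window
#'
#' `sum_i log2(q[b_i, i] / bg[b_i])` with pseudocount-smoothed position
#' probabilities `q = (p + pseudocount * bg) / (1 + pseudocount)`. Windows
#' containing a non-ACGT letter score `-Inf` (excluded from hit lists).
#'
#' @param motif a [motif_model()].
#' @param window character sequence of exactly the motif length.
#' @return Score in bits.
#' @export
log_odds_score <- function(motif, window) {
  S <- motif_score_matrix(motif)
  code <- encode_dna(window)
  if (length(code) != ncol(S)) {
    stop("sequence window length must equal the motif length")
  }
  if (anyNA(code)) return(-Inf)
  sum(S[cbind(code, seq_along(code))])
}

#' Exact score distribution of a motif under the background model
#'
#' Discretizes each position's four possible scores to bins of width
#' `1/granularity` bits and convolves the per-position distributions under
#' the 0-order background by dynamic programming. Returns the survival
#' function `P(score >= s)`.
#'
#' @param motif a [motif_model()].
#' @param granularity bins per bit of score (>= 100; default 1000, i.e.
#'   1/1000-bit bins, which bounds the discretization error explicitly).
#' @return A `score_pvalue_table` list: `delta` (bin width), `bins` (integer
#'   score bins), `scores` (bin centers in bits), `survival`
#'   (`P(score >= bin)`).
#' @export
score_pvalue_table <- function(motif, granularity = 1000) {
  if (granularity < 100) stop("granularity must be >= 100 bins per bit")
  delta <- 1 / granularity
  S <- motif_score_matrix(motif)
  iS <- round(S / delta)
  L <- ncol(iS)
  bg <- motif$background
  lo <- sum(apply(iS, 2, min)); hi <- sum(apply(iS, 2, max))
  dist <- numeric(hi - lo + 1)                  # index k <-> score bin lo+k-1
  dist[0 - lo + 1] <- 1                          # start at score 0
  cur_lo <- 0; cur_hi <- 0
  for (j in seq_len(L)) {
    new <- numeric(length(dist))
    for (b in 1:4) {
      sh <- iS[b, j]
      src <- (cur_lo - lo + 1):(cur_hi - lo + 1)
      new[src + sh] <- new[src + sh] + bg[b] * dist[src]
    }
    dist <- new
    cur_lo <- cur_lo + min(iS[, j]); cur_hi <- cur_hi + max(iS[, j])
  }
  stopifnot(abs(sum(dist) - 1) < 1e-9)
  surv <- rev(cumsum(rev(dist)))
  bins <- lo:hi
  structure(list(delta = delta, bins = bins, scores = bins * delta,
                 survival = surv, motif = motif$name),
            class = "score_pvalue_table")
}

# P(score >= s | background) for scores in bits, via the DP table.
score_pvalue <- function(table, score) {
  b <- round(score / table$delta)
  idx <- pmin(pmax(b - table$bins[1] + 1, 1), length(table$survival))
  p <- table$survival[idx]
  p[b > table$bins[length(table$bins)]] <- 0
  p[b < table$bins[1]] <- 1
  p
}

# Vectorized per-position scores of one motif along an encoded sequence.
scan_scores <- function(code, S) {
  L <- ncol(S)
  n <- length(code) - L + 1
  if (n < 1) return(numeric(0))
  total <- numeric(n)
  nas <- is.na(code)
  code0 <- ifelse(nas, 1L, code)
  for (j in seq_len(L)) {
    idx <- j:(j + n - 1)
    total <- total + S[cbind(code0[idx], j)]
    total[nas[idx]] <- -Inf
  }
  total
}

#' Scan peak regions for motif occurrences on both strands
#'
#' Both strands are scanned (the reverse strand via the reverse-complemented
#' motif on the forward sequence); at each position the better-scoring
#' strand is kept, and hits with `p <= p_threshold` are reported in
#' genome-absolute, 0-based half-open coordinates.
#'
#' @param motif a [motif_model()].
#' @param sequences named character vector of chromosome sequences.
#' @param regions a [peak_set()] of regions to scan (must lie within the
#'   sequences).
#' @param p_threshold report hits at `P(score >= s) <= p_threshold`
#'   (default 1e-4).
#' @param pvalue_table optional precomputed [score_pvalue_table()].
#' @return Data frame of hits: `chrom`, `start`, `end`, `strand`, `score`,
#'   `pvalue`, `region`.
#' @export
scan_intervals <- function(motif, sequences, regions, p_threshold = 1e-4,
                           pvalue_table = NULL) {
  if (is.null(pvalue_table)) pvalue_table <- score_pvalue_table(motif)
  S_fwd <- motif_score_matrix(motif)
  S_rev <- motif_score_matrix(reverse_complement_motif(motif))
  L <- ncol(S_fwd)
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    if (!chrom %in% names(sequences)) {
      stop("region '", regions$name[i], "' on unknown sequence: ", chrom)
    }
    slen <- nchar(sequences[[chrom]])
    if (regions$end[i] > slen || regions$start[i] < 0) {
      stop("region '", regions$name[i], "' exceeds sequence bounds")
    }
    sub <- substr(sequences[[chrom]], regions$start[i] + 1, regions$end[i])
    code <- match(strsplit(toupper(sub), "")[[1]], c("A", "C", "G", "T"))
    fwd <- scan_scores(code, S_fwd)
    rev_ <- scan_scores(code, S_rev)
    if (!length(fwd)) next
    better <- ifelse(fwd >= rev_, fwd, rev_)
    strand <- ifelse(fwd >= rev_, "+", "-")
    p <- score_pvalue(pvalue_table, better)
    keep <- is.finite(better) & p <= p_threshold
    if (!any(keep)) next
    pos <- which(keep)
    hits[[length(hits) + 1]] <- data.frame(
      chrom = chrom, start = regions$start[i] + pos - 1,
      end = regions$start[i] + pos - 1 + L, strand = strand[keep],
      score = better[keep], pvalue = p[keep], region = regions$name[i],
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), region = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

# TRUE per peak iff >= 1 hit center lies within summit +/- window.
peaks_with_motif <- function(hits, peaks, window) {
  has <- logical(nrow(peaks))
  if (!nrow(hits)) return(has)
  centers <- floor((hits$start + hits$end) / 2)
  for (chrom in unique(peaks$chrom)) {
    pc <- which(peaks$chrom == chrom)
    cc <- sort(centers[hits$chrom == chrom])
    if (!length(cc)) next
    lo <- findInterval(peaks$summit[pc] - window - 1, cc)
    hi <- findInterval(peaks$summit[pc] + window, cc)
    has[pc] <- hi > lo
  }
  has
}

#' Class-wise motif prevalence test around peak summits
#'
#' A peak "has the motif" iff at least one hit center lies within
#' `summit +/- window`. Prevalence across directional classes is compared by
#' a Pearson chi-square test of the class x has-motif contingency table
#' (no continuity correction, `df = #classes - 1`).
#'
#' @param hits hit data frame from [scan_intervals()].
#' @param peaks a [peak_set()].
#' @param classes character vector of per-peak class labels (parallel to
#'   `peaks`), e.g. `increased` / `unchanged` / `decreased`.
#' @param window bp half-width around the summit (default 150).
#' @return A list: `table` (per-class `n_with_motif`, `n_total`,
#'   `prevalence`), `statistic`, `df`, `p.value`, `window`,
#'   `low_expected` (TRUE when some expected cell count < 1).
#' @export
prevalence_test <- function(hits, peaks, classes, window = 150) {
  stopifnot(length(classes) == nrow(peaks))
  has <- peaks_with_motif(hits, peaks, window)
  lev <- intersect(c("increased", "unchanged", "decreased"), unique(classes))
  if (length(lev) < 2) lev <- unique(classes)
  if (length(lev) < 2) stop("prevalence test needs >= 2 non-empty classes")
  tab <- table(factor(classes, levels = lev), factor(has, levels = c(FALSE, TRUE)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  chi <- if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    0  # degenerate margin: no evidence against independence
  } else {
    sum((tab - expected)^2 / expected)
  }
  res <- list(table = data.frame(class = lev,
                                 n_with_motif = as.integer(tab[, "TRUE"]),
                                 n_total = as.integer(rowSums(tab)),
                                 prevalence = as.numeric(tab[, "TRUE"] / rowSums(tab)),
                                 stringsAsFactors = FALSE),
              statistic = chi, df = df,
              p.value = pchisq(chi, df, lower.tail = FALSE),
              window = window, low_expected = any(expected < 1))
  if (res$low_expected) {
    warning("some expected cell counts are < 1; chi-square approximation weak")
  }
  res
}

#' Motif prevalence per timepoint and class
#'
#' Applies the [prevalence_test()] membership rule per timepoint using a
#' matrix of per-timepoint classifications against the same control, and
#' reports the fraction of peaks with the motif in each (timepoint, class)
#' cell; empty classes give NA.
#'
#' @param hits hit data frame from [scan_intervals()].
#' @param peaks a [peak_set()].
#' @param class_matrix character matrix, peaks x timepoints, of class labels.
#' @param window bp half-width around the summit.
#' @return Numeric matrix timepoint x class of prevalence fractions.
#' @export
prevalence_timecourse <- function(hits, peaks, class_matrix, window = 150) {
  stopifnot(nrow(class_matrix) == nrow(peaks))
  has <- peaks_with_motif(hits, peaks, window)
  lev <- c("increased", "unchanged", "decreased")
  out <- matrix(NA_real_, ncol(class_matrix), length(lev),
                dimnames = list(colnames(class_matrix), lev))
  for (j in seq_len(ncol(class_matrix))) {
    for (cl in lev) {
      in_cl <- class_matrix[, j] == cl
      if (any(in_cl)) out[j, cl] <- mean(has[in_cl])
    }
  }
  out
}
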
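# Anchor-dependent redistribution of a second transcription factor:
# fold-change grouping by gene-class windows and by summit-to-summit
# distance to the nearest anchor peak, with one-sample and rank-sum tests.

# one-sample two-sided t-test of x against 0, with degenerate-sd handling
one_sample_t <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(list(n = 0, mean = NA_real_, t = NA_real_, p = NA_real_))
  m <- mean(x)
  s <- sd(x)
  if (n < 2 || is.na(s)) return(list(n = n, mean = m, t = NA_real_, p = NA_real_))
  if (s == 0) {
    if (m == 0) return(list(n = n, mean = m, t = 0, p = 1))
    return(list(n = n, mean = m, t = sign(m) * Inf, p = 0))
  }
  t <- m / (s / sqrt(n))
  list(n = n, mean = m, t = t, p = 2 * pt(-abs(t), n - 1))
}

stars_of <- function(p) ifelse(!is.na(p) & p < 1e-3, "***",
                               ifelse(!is.na(p) & p > 0.1, "N.S.", ""))

group_summary <- function(label, values) {
  tt <- one_sample_t(values)
  data.frame(group = label, n = tt$n, mean_log2fc = tt$mean, t = tt$t,
             p = tt$p, stars = stars_of(tt$p), stringsAsFactors = FALSE)
}

#' Fold changes of second-factor peaks grouped by nearby gene class
#'
#' A peak joins a gene class group iff its summit lies within `TSS +/-
#' window` of at least one gene of that class; by default a peak may join
#' several classes (set `exclusive = TRUE` to assign each peak only to the
#' class of its nearest gene). Each group's log2 fold changes are tested
#' against 0 with a two-sided one-sample t-test; `"***"` marks `p < 1e-3`.
#'
#' @param er_results `DiffResult` data frame for the second factor's peaks
#'   (feature ids matching `er_peaks$name`).
#' @param er_peaks a [peak_set()] of the second factor's peaks.
#' @param genes gene annotation data frame with columns `gene_id`, `chrom`,
#'   `tss` and a `class` column (`activated`/`repressed`/`unchanged`).
#' @param window bp half-width around each TSS (default 100000).
#' @param exclusive assign each peak only to its nearest gene's class.
#' @return A list: `summary` (per-group n, mean, t, p, stars) and `groups`
#'   (member peak ids and values per group).
#' @export
fc_by_gene_class <- function(er_results, er_peaks, genes, window = 1e5,
                             exclusive = FALSE) {
  stopifnot(all(c("gene_id", "chrom", "tss", "class") %in% names(genes)))
  lfc <- setNames(er_results$log2fc, er_results$feature_id)
  classes <- intersect(c("activated", "repressed", "unchanged"),
                       unique(genes$class))
  members <- setNames(vector("list", length(classes)), classes)
  if (exclusive) {
    nd <- nearest_distance(
      data.frame(gene_id = er_peaks$name, chrom = er_peaks$chrom,
                 tss = er_peaks$summit, strand = "+"),
      peak_set(genes$chrom, pmax(0, genes$tss), genes$tss + 1,
               name = genes$gene_id),
      mode = "summit")
    cls <- genes$class[match(nd$peak, genes$gene_id)]
    ok <- !nd$no_peak & nd$distance <= window
    for (cl in classes) {
      members[[cl]] <- er_peaks$name[ok & cls == cl]
    }
  } else {
    for (cl in classes) {
      sub <- genes[genes$class == cl, , drop = FALSE]
      hit <- logical(nrow(er_peaks))
      for (chrom in unique(er_peaks$chrom)) {
        pi <- which(er_peaks$chrom == chrom)
        tss <- sort(sub$tss[sub$chrom == chrom])
        if (!length(tss)) next
        lo <- findInterval(er_peaks$summit[pi] - window - 1, tss)
        hi <- findInterval(er_peaks$summit[pi] + window, tss)
        hit[pi] <- hi > lo
      }
      members[[cl]] <- er_peaks$name[hit]
    }
  }
  summ <- do.call(rbind, lapply(classes, function(cl) {
    group_summary(cl, unname(lfc[members[[cl]]]))
  }))
  empty <- summ$group[summ$n == 0]
  if (length(empty)) {
    warning("empty gene-class group(s): ", paste(empty, collapse = ", "))
  }
  list(summary = summ,
       groups = lapply(members, function(ids) {
         list(peaks = ids, log2fc = unname(lfc[ids]))
       }))
}

#' Fold changes of second-factor peaks grouped by distance to anchors
#'
#' Distance is summit-to-summit to the nearest anchor peak on the same
#' chromosome; peaks on anchor-free chromosomes are excluded and counted.
#' Each distance bin's log2 fold changes are tested against 0 with a
#' two-sided one-sample t-test; `"***"` marks `p < 1e-3`.
#'
#' @param er_results `DiffResult` data frame for the second factor's peaks.
#' @param er_peaks a [peak_set()] of the second factor's peaks.
#' @param anchors a non-empty [peak_set()] of anchor peaks.
#' @param bins strictly increasing distance bin edges starting at 0 (a final
#'   `Inf` edge is appended when absent); bins are `[a, b)`.
#' @return A list: `summary` (per-bin n, mean, t, p, stars), `distance`
#'   (per included peak), `bin` assignments, `n_excluded`.
#' @export
fc_by_distance_to_anchor <- function(er_results, er_peaks, anchors,
                                     bins = c(0, 1e4, 1e5)) {
  if (nrow(anchors) == 0) stop("anchor set is empty")
  if (any(diff(bins) <= 0)) stop("distance bins must be strictly increasing")
  if (bins[1] != 0) stop("first bin edge must be 0")
  if (is.finite(bins[length(bins)])) bins <- c(bins, Inf)
  dist <- rep(NA_real_, nrow(er_peaks))
  for (chrom in unique(er_peaks$chrom)) {
    pi <- which(er_peaks$chrom == chrom)
    anc <- sort(anchors$summit[anchors$chrom == chrom])
    if (!length(anc)) next
    s <- er_peaks$summit[pi]
    j <- findInterval(s, anc)
    d_lo <- ifelse(j >= 1, s - anc[pmax(j, 1)], Inf)
    d_hi <- ifelse(j < length(anc), anc[pmin(j + 1, length(anc))] - s, Inf)
    dist[pi] <- pmin(d_lo, d_hi)
  }
  included <- !is.na(dist)
  lfc <- setNames(er_results$log2fc, er_results$feature_id)[er_peaks$name]
  labels <- paste0("[", head(bins, -1), ",", tail(bins, -1), ")")
  bin <- cut(dist, bins, right = FALSE, labels = labels)
  summ <- do.call(rbind, lapply(labels, function(lb) {
    group_summary(lb, unname(lfc[included & !is.na(bin) & bin == lb]))
  }))
  list(summary = summ,
       distance = setNames(dist[included], er_peaks$name[included]),
       bin = setNames(bin[included], er_peaks$name[included]),
       n_excluded = sum(!included))
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) comparison
#'
#' Uses exact enumeration over all rank assignments (midranks for ties)
#' when `n_a + n_b <= 20`, else the normal approximation with tie and
#' continuity corrections. The reported statistic is the Mann-Whitney U of
#' the first sample (the `W` of [stats::wilcox.test()]).
#'
#' @param values_a,values_b numeric vectors (each non-empty).
#' @return A list: `statistic` (U), `p.value`, `method`.
#' @export
rank_sum_compare <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both samples must be non-empty")
  n <- na + nb
  r <- rank(c(a, b))
  W_rank <- sum(r[seq_len(na)])              # rank-sum of sample a
  U <- W_rank - na * (na + 1) / 2
  if (n <= 20) {
    combs <- utils::combn(n, na)
    sums <- colSums(matrix(r[combs], nrow = na))
    mu <- na * (n + 1) / 2
    p <- mean(abs(sums - mu) >= abs(W_rank - mu) - 1e-12)
    return(list(statistic = U, p.value = p, method = "exact"))
  }
  ties <- table(r)
  mu_u <- na * nb / 2
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- U - mu_u
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(statistic = U, p.value = min(1, 2 * pnorm(-abs(z))),
       method = "normal")
}
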
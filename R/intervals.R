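# Interval geometry: nearest-feature distances, overlap filtering, read
# counting in features, ECDF + Kolmogorov-Smirnov comparison, and
# strand-separated composite signal profiles around summits.

#' Distance from each gene TSS to its nearest peak
#'
#' Distance is 0 when the TSS lies inside the (half-open) peak interval,
#' else `min(|TSS - start|, |TSS - (end - 1)|)` to the nearest occupied
#' base. Ties are broken by leftmost peak start, then lexicographic peak
#' name. In `"summit"` mode the distance is `|TSS - summit|` instead
#' (summit-to-point distance). Queries with no same-chromosome peak get an
#' infinite distance and are flagged.
#'
#' @param genes gene annotation data frame (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param peaks a [peak_set()].
#' @param mode `"interval"` (default) or `"summit"`.
#' @return Data frame: `gene_id`, `peak`, `distance`, `no_peak` (flag).
#' @export
nearest_distance <- function(genes, peaks, mode = c("interval", "summit")) {
  mode <- match.arg(mode)
  n <- nrow(genes)
  out <- data.frame(gene_id = genes$gene_id, peak = NA_character_,
                    distance = Inf, no_peak = TRUE, stringsAsFactors = FALSE)
  for (chrom in unique(genes$chrom)) {
    gi <- which(genes$chrom == chrom)
    pi <- which(peaks$chrom == chrom)
    if (!length(pi)) next
    ps <- peaks[pi, , drop = FALSE]
    for (g in gi) {
      tss <- genes$tss[g]
      d <- if (mode == "summit") {
        abs(tss - ps$summit)
      } else {
        ifelse(tss >= ps$start & tss < ps$end, 0,
               pmin(abs(tss - ps$start), abs(tss - (ps$end - 1))))
      }
      best <- which(d == min(d))
      if (length(best) > 1) {
        best <- best[order(ps$start[best], ps$name[best])][1]
      }
      out$peak[g] <- ps$name[best]
      out$distance[g] <- d[best]
      out$no_peak[g] <- FALSE
    }
  }
  out
}

#' Subset peaks of one set overlapping another
#'
#' Overlap means a half-open intersection of at least 1 bp.
#'
#' @param a,b [peak_set()]s.
#' @return The subset of `a` overlapping at least one interval of `b`.
#' @export
filter_peaks_overlapping <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a[integer(0), , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      minoverlap = 1)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Count read positions in features
#'
#' Counts, per sample, the read positions falling within each half-open
#' feature interval (strand-agnostic).
#'
#' @param read_positions named list (one element per sample) of data frames
#'   with columns `chrom`, `pos` (0-based bp), and optionally `strand`.
#' @param features a [peak_set()].
#' @param meta optional sample metadata (see [count_matrix()]); when given,
#'   a [count_matrix()] is returned instead of a plain matrix.
#' @return Integer matrix features x samples, or a [count_matrix()].
#' @export
count_in_intervals <- function(read_positions, features, meta = NULL) {
  fr <- as_granges(features)
  counts <- vapply(read_positions, function(df) {
    r <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(start = df$pos + 1, width = 1))
    GenomicRanges::countOverlaps(fr, r)
  }, integer(nrow(features)))
  counts <- matrix(counts, nrow = nrow(features),
                   dimnames = list(features$name, names(read_positions)))
  if (is.null(meta)) return(counts)
  count_matrix(counts, meta)
}

# survival function of the asymptotic Kolmogorov distribution
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample ECDF comparison with a Kolmogorov-Smirnov test
#'
#' `D = sup |F_a - F_b|`; the two-sided p-value uses the asymptotic
#' Kolmogorov distribution at effective size `n_a n_b / (n_a + n_b)`, or a
#' seeded permutation null when `exact = TRUE`. Non-finite values (e.g.
#' infinite-distance records) are excluded and counted.
#'
#' @param distances_a,distances_b numeric vectors (>= 3 finite values each).
#' @param exact use a permutation p-value instead of the asymptotic one.
#' @param n_perm,seed permutation settings for `exact = TRUE`.
#' @return A list: `ecdf_a`, `ecdf_b`, `statistic` (D), `p.value`,
#'   `n_excluded`.
#' @export
ecdf_ks <- function(distances_a, distances_b, exact = FALSE, n_perm = 2000,
                    seed = 1) {
  excl <- sum(!is.finite(distances_a)) + sum(!is.finite(distances_b))
  a <- distances_a[is.finite(distances_a)]
  b <- distances_b[is.finite(distances_b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("each sample needs >= 3 finite values")
  }
  ks_d <- function(x, y) {
    grid <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  }
  D <- ks_d(a, b)
  ne <- length(a) * length(b) / (length(a) + length(b))
  if (exact) {
    set.seed(derive_seed(seed, "perm"))
    pool <- c(a, b)
    na <- length(a)
    perm <- replicate(n_perm, {
      idx <- sample.int(length(pool), na)
      ks_d(pool[idx], pool[-idx])
    })
    p <- (1 + sum(perm >= D - 1e-12)) / (1 + n_perm)
  } else {
    p <- if (D == 0) 1 else kolmogorov_sf(sqrt(ne) * D)
  }
  list(ecdf_a = ecdf(a), ecdf_b = ecdf(b), statistic = D, p.value = p,
       n_excluded = excl)
}

#' Strand-separated composite signal profile around summits
#'
#' Means, over anchors, the per-base signal at `summit + offset` for
#' offsets in `[-half_width, half_width]`, separately for plus and minus
#' strand signal. Anchors whose window would leave the chromosome are
#' excluded.
#'
#' @param signal data frame with columns `chrom`, `pos` (0-based bp),
#'   `strand` (`"+"`/`"-"`), `value` (bedGraph-like per-base values;
#'   positions absent from the table count as 0).
#' @param anchors a [peak_set()] with summits.
#' @param half_width window half-width in bp (>= 1).
#' @param chrom_lengths optional named vector for edge exclusion.
#' @return A `composite_profile` list: `offsets`, `plus_signal`,
#'   `minus_signal`, `n_anchors`.
#' @export
composite_profile <- function(signal, anchors, half_width,
                              chrom_lengths = NULL) {
  stopifnot(half_width >= 1)
  offsets <- -half_width:half_width
  keep <- anchors$summit - half_width >= 0
  if (!is.null(chrom_lengths)) {
    keep <- keep & anchors$summit + half_width <
      chrom_lengths[anchors$chrom]
  }
  anc <- anchors[keep, , drop = FALSE]
  if (!nrow(anc)) stop("no anchor with a complete window")
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  want_chrom <- rep(anc$chrom, each = length(offsets))
  want_pos <- rep(anc$summit, each = length(offsets)) + offsets
  lookup <- function(strand) {
    sub <- signal[signal$strand == strand, , drop = FALSE]
    v <- sub$value[match(key(want_chrom, want_pos), key(sub$chrom, sub$pos))]
    v[is.na(v)] <- 0
    colMeans(matrix(v, nrow = nrow(anc), byrow = TRUE))
  }
  structure(list(offsets = offsets, plus_signal = lookup("+"),
                 minus_signal = lookup("-"), n_anchors = nrow(anc)),
            class = "composite_profile")
}
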
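# Gene-set machinery: Fisher over-representation, weighted running-sum
# enrichment (GSEA) with permutation p-values, per-patient cohort z-score
# ranking, the two-tailed regulon dES, and patient activity classification.

#' Construct a gene set
#' @param name set name.
#' @param genes member gene ids (deduplicated).
#' @return A `gene_set` list.
#' @export
gene_set <- function(name, genes) {
  structure(list(name = name, genes = unique(as.character(genes))),
            class = "gene_set")
}

#' Construct a regulon of paired depletion-response gene sets
#'
#' The `activated` half contains genes that go UP upon depletion of the
#' factor — i.e. the factor's REPRESSED targets; the `repressed` half goes
#' DOWN upon depletion — the factor's ACTIVATED targets. This sign mapping
#' is the single most error-prone point of the analysis and is pinned here
#' once: high factor activity in a sample means the `activated`
#' (depletion-up) half is negatively enriched and the `repressed`
#' (depletion-down) half positively enriched.
#'
#' @param activated gene ids up upon depletion (or a [gene_set()]).
#' @param repressed gene ids down upon depletion (or a [gene_set()]).
#' @return A `regulon` list of two disjoint [gene_set()]s.
#' @export
regulon <- function(activated, repressed) {
  if (!inherits(activated, "gene_set")) {
    activated <- gene_set("depletion_up", activated)
  }
  if (!inherits(repressed, "gene_set")) {
    repressed <- gene_set("depletion_down", repressed)
  }
  if (length(intersect(activated$genes, repressed$genes))) {
    stop("regulon halves must be disjoint")
  }
  structure(list(activated = activated, repressed = repressed),
            class = "regulon")
}

#' Fisher over-representation analysis
#'
#' One-sided hypergeometric test of each set's overlap with the hit list
#' within the universe, BH-adjusted across sets.
#'
#' @param hits a [gene_set()] or character vector of hit gene ids (must lie
#'   in the universe).
#' @param universe character vector of all testable gene ids.
#' @param sets list of [gene_set()]s (each intersected with the universe
#'   first).
#' @return Data frame: `set`, `overlap`, `set_size`, `odds_ratio`, `p`,
#'   `padj`.
#' @export
fisher_ora <- function(hits, universe, sets) {
  if (inherits(hits, "gene_set")) hits <- hits$genes
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe is empty")
  if (length(setdiff(hits, universe))) {
    stop("hits must be a subset of the universe")
  }
  hits <- unique(hits)
  N <- length(universe); H <- length(hits)
  rows <- lapply(sets, function(s) {
    sg <- intersect(s$genes, universe)
    a <- length(intersect(hits, sg))
    b <- H - a
    c_ <- length(sg) - a
    d <- N - H - c_
    p <- phyper(a - 1, length(sg), N - length(sg), H, lower.tail = FALSE)
    or <- (a * d) / (b * c_)
    data.frame(set = s$name, overlap = a, set_size = length(sg),
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Weighted running-sum enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov statistic: walking down the ranked
#' list, set members increment the running sum by `|w|^exponent /
#' sum_hits |w|^exponent` and non-members decrement it by `1 / (N - |S|)`.
#' The enrichment score is the signed maximum deviation from zero.
#'
#' @param ranked character vector of gene ids, best-to-worst.
#' @param weights ranking weights parallel to `ranked` (e.g. z-scores or
#'   shrunken fold changes).
#' @param set a [gene_set()] or character vector.
#' @param exponent weight power (0 gives the classic unweighted statistic).
#' @return A list: `es`, `running` (running-sum after each step),
#'   `hit_positions`.
#' @export
gsea_es <- function(ranked, weights, set, exponent = 1) {
  if (inherits(set, "gene_set")) set <- set$genes
  N <- length(ranked)
  hit <- ranked %in% set
  m <- sum(hit)
  if (m == 0) stop("set has no member in the ranked list")
  if (m == N) stop("set covers the whole ranked list")
  w <- abs(weights)^exponent
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - m)
  running <- cumsum(inc)
  maxP <- max(running, 0)
  minP <- min(running, 0)
  # magnitude ties (to numerical precision) give 0, keeping ES
  # antisymmetric under ranking reversal
  es <- if (maxP + minP > 1e-9) maxP else if (maxP + minP < -1e-9) minP else 0
  list(es = es, running = running, hit_positions = which(hit))
}

# ES values for many position sets at once: `pos` is an m x B matrix of
# column-sorted hit positions into a ranked list with |weight|^exponent
# vector `wpow`. Used for permutation nulls.
es_from_positions <- function(pos, wpow, N) {
  m <- nrow(pos); B <- ncol(pos)
  W <- matrix(wpow[pos], m, B)
  cumW <- apply(W, 2, cumsum)
  S <- rep(cumW[m, ], each = m)
  kidx <- matrix(seq_len(m), m, B)
  after <- cumW / S - (pos - kidx) / (N - m)
  before <- after - W / S
  maxP <- pmax(do.call(pmax, lapply(seq_len(m), function(i) after[i, ])), 0)
  minP <- pmin(do.call(pmin, lapply(seq_len(m), function(i) before[i, ])), 0)
  ifelse(maxP + minP > 1e-9, maxP, ifelse(maxP + minP < -1e-9, minP, 0))
}

#' Gene-label permutation p-value for an enrichment score
#'
#' The null is generated by drawing random sets of the same size from the
#' ranked list. The p-value is one-tailed on the observed sign with the
#' standard +1 correction: `(1 + #{same-sign permutations with |ES| >=
#' |ES_obs|}) / (1 + #same-sign permutations)`.
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed (deterministic given the seed).
#' @return A list: `p.value`, `es`, `n_perm`.
#' @export
gsea_permutation_p <- function(ranked, weights, set, exponent = 1,
                               n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("use at least 100 permutations")
  obs <- gsea_es(ranked, weights, set, exponent)
  N <- length(ranked)
  m <- length(obs$hit_positions)
  set.seed(derive_seed(seed, "perm"))
  pos <- vapply(seq_len(n_perm),
                function(i) sort.int(sample.int(N, m)), integer(m))
  pos <- matrix(pos, nrow = m)
  wpow <- abs(weights)^exponent
  es_null <- es_from_positions(pos, wpow, N)
  same <- sign(es_null) == sign(obs$es)
  p <- (1 + sum(same & abs(es_null) >= abs(obs$es) - 1e-12)) / (1 + sum(same))
  list(p.value = min(1, p), es = obs$es, n_perm = n_perm)
}

#' Rank a patient's genes by cohort-scaled expression
#'
#' Per gene, `z = (x_patient - mean_cohort) / sd_cohort` over all patients;
#' genes are ordered by decreasing z (ties broken by gene id) and the z
#' itself is the ranking weight. Zero-variance genes are dropped and
#' counted.
#'
#' @param expression numeric matrix genes x patients (>= 3 patients).
#' @param patient_id column to rank.
#' @return Data frame `gene`, `z`, ordered; dropped-gene count in
#'   `attr(, "n_dropped")`.
#' @export
cohort_zscore_rank <- function(expression, patient_id) {
  if (ncol(expression) < 3) stop("cohort ranking needs >= 3 patients")
  if (!patient_id %in% colnames(expression)) {
    stop("unknown patient: ", patient_id)
  }
  mu <- rowMeans(expression)
  sdv <- apply(expression, 1, sd)
  keep <- sdv > 0
  z <- (expression[keep, patient_id] - mu[keep]) / sdv[keep]
  ord <- order(-z, rownames(expression)[keep])
  out <- data.frame(gene = rownames(expression)[keep][ord], z = z[ord],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Two-tailed regulon activity (dES) per patient
#'
#' For each patient, genes are ranked by cohort-scaled expression and the
#' two regulon halves are scored separately:
#' `dES = ES(depletion-up half) - ES(depletion-down half)`. A patient has
#' HIGH factor activity iff the depletion-up (factor-repressed) half is
#' significantly negatively enriched AND the depletion-down
#' (factor-activated) half significantly positively enriched; LOW activity
#' is the mirror image; everything else is intermediate. Significance is a
#' permutation p `<= alpha`. Patients are returned ranked by dES
#' (ascending: most negative dES = highest factor activity).
#'
#' @param expression numeric matrix genes x patients.
#' @param regulon a [regulon()]; each half must overlap the expressed genes
#'   in >= 5 members.
#' @param exponent GSEA weight power (default 1).
#' @param n_perm permutations per patient and half.
#' @param alpha significance level for the classification rule.
#' @param seed integer seed.
#' @return Data frame (one row per patient, ordered by dES): `patient_id`,
#'   `es_up` (depletion-up half), `es_down`, `p_up`, `p_down`, `dES`,
#'   `class` (`high`/`intermediate`/`low`).
#' @export
patient_activity <- function(expression, regulon, exponent = 1,
                             n_perm = 1000, alpha = 0.05, seed = 1) {
  genes <- rownames(expression)
  up <- intersect(regulon$activated$genes, genes)
  down <- intersect(regulon$repressed$genes, genes)
  if (length(up) < 5 || length(down) < 5) {
    stop("each regulon half must overlap the expressed genes in >= 5 members")
  }
  patients <- colnames(expression)
  set.seed(derive_seed(seed, "perm"))
  mu <- rowMeans(expression)
  sdv <- apply(expression, 1, sd)
  keep <- sdv > 0
  res <- data.frame(patient_id = patients, es_up = NA_real_,
                    es_down = NA_real_, p_up = NA_real_, p_down = NA_real_,
                    dES = NA_real_, class = "intermediate",
                    stringsAsFactors = FALSE)
  for (j in seq_along(patients)) {
    z <- (expression[keep, j] - mu[keep]) / sdv[keep]
    ord <- order(-z, genes[keep])
    ranked <- genes[keep][ord]
    wts <- z[ord]
    wpow <- abs(wts)^exponent
    N <- length(ranked)
    score_half <- function(members) {
      obs <- gsea_es(ranked, wts, members, exponent)
      m <- length(obs$hit_positions)
      pos <- matrix(vapply(seq_len(n_perm),
                           function(i) sort.int(sample.int(N, m)),
                           integer(m)), nrow = m)
      es_null <- es_from_positions(pos, wpow, N)
      same <- sign(es_null) == sign(obs$es)
      p <- (1 + sum(same & abs(es_null) >= abs(obs$es) - 1e-12)) /
        (1 + sum(same))
      list(es = obs$es, p = min(1, p))
    }
    su <- score_half(up)
    sdn <- score_half(down)
    res$es_up[j] <- su$es; res$p_up[j] <- su$p
    res$es_down[j] <- sdn$es; res$p_down[j] <- sdn$p
    res$dES[j] <- su$es - sdn$es
    sig_up <- su$p <= alpha; sig_dn <- sdn$p <= alpha
    if (su$es < 0 && sig_up && sdn$es > 0 && sig_dn) {
      res$class[j] <- "high"
    } else if (su$es > 0 && sig_up && sdn$es < 0 && sig_dn) {
      res$class[j] <- "low"
    }
  }
  res <- res[order(res$dES), , drop = FALSE]
  rownames(res) <- NULL
  res
}
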
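# Independent brute-force oracles, kept deliberately naive: each implements
# the defining formula of its statistic directly, sharing no code with the
# package paths it checks.

# Benjamini-Hochberg step-up by definition: q_i = min_{j: p_(j) >= p_(i)}
# min(1, m * p_(j) / j)
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ranks_ge <- which(p[ord] >= p[i] - 1e-15)
    q[i] <- min(1, min(m * p[ord][ranks_ge] / ranks_ge))
  }
  q
}

# Pearson chi-square from a contingency table, cell by cell
brute_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# one-sided hypergeometric upper tail by explicit summation
brute_fisher_tail <- function(a, set_size, hits_size, N) {
  ks <- a:min(set_size, hits_size)
  sum(choose(set_size, ks) * choose(N - set_size, hits_size - ks)) /
    choose(N, hits_size)
}

# two-sample KS D by scanning every observed value
brute_ks_d <- function(x, y) {
  pts <- sort(c(x, y))
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Kaplan-Meier product-limit by walking distinct event times
brute_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# k-group logrank chi-square from first principles: O-E vector and its
# covariance accumulated over distinct event times
brute_logrank <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    n_t <- sum(time >= t)
    d_t <- sum(time == t & event == 1)
    for (g in seq_len(k)) {
      n_g <- sum(time >= t & group == levels(group)[g])
      d_g <- sum(time == t & event == 1 & group == levels(group)[g])
      O[g] <- O[g] + d_g
      E[g] <- E[g] + d_t * n_g / n_t
      for (h in seq_len(k)) {
        n_h <- sum(time >= t & group == levels(group)[h])
        V[g, h] <- V[g, h] + d_t * (n_t - d_t) / max(n_t - 1, 1) *
          (n_g / n_t) * ((g == h) - n_h / n_t)
      }
    }
  }
  x <- (O - E)[-k]
  drop(t(x) %*% solve(V[-k, -k, drop = FALSE]) %*% x)
}

# one-sample t by its closed form
brute_t_one <- function(x) mean(x) / (sd(x) / sqrt(length(x)))

# exact two-sided rank-sum p by enumerating every subset of ranks
brute_ranksum_exact <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  W_obs <- sum(r[seq_along(a)])
  mu <- length(a) * (n + 1) / 2
  combs <- combn(n, length(a))
  sums <- colSums(matrix(r[combs], nrow = length(a)))
  mean(abs(sums - mu) >= abs(W_obs - mu) - 1e-12)
}

# GSEA running sum by an explicit walk down the list
brute_es <- function(ranked, weights, set, exponent) {
  N <- length(ranked)
  hit <- ranked %in% set
  wsum <- sum(abs(weights[hit])^exponent)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) abs(weights[i])^exponent / wsum else
      -1 / (N - sum(hit))
    run[i] <- cur
  }
  hi <- max(run, 0); lo <- min(run, 0)
  if (hi + lo > 1e-9) hi else if (hi + lo < -1e-9) lo else 0
}

# nearest peak by all-pairs minimum under the package's distance convention
brute_nearest <- function(tss, starts, ends, names) {
  d <- ifelse(tss >= starts & tss < ends, 0,
              pmin(abs(tss - starts), abs(tss - (ends - 1))))
  best <- which(d == min(d))
  best <- best[order(starts[best], names[best])][1]
  list(distance = d[best], peak = names[best])
}

# plain (unadjusted) Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# survival-function table of a motif score by exhaustive 4^L enumeration on
# the same integer score discretization the DP uses
brute_score_sf <- function(iS, bg) {
  L <- ncol(iS)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- rowSums(matrix(iS[cbind(as.vector(grid),
                                    rep(seq_len(L), each = nrow(grid)))],
                           nrow(grid)))
  probs <- apply(matrix(bg[grid], nrow(grid)), 1, prod)
  list(scores = scores, probs = probs)
}
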
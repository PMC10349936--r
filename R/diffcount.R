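# Differential testing of count matrices: median-of-ratios normalization,
# moment-based NB dispersion estimation with trend shrinkage, pairwise Wald
# tests, time-course likelihood-ratio tests, normal-prior fold-change
# shrinkage, BH adjustment and directional classification.
#
# The module is deliberately DESeq2-inspired rather than DESeq2-identical:
# no outlier handling or independent filtering, moment (not Cox-Reid)
# dispersions, and a simple normal prior for shrinkage. Directional calls at
# a chosen FDR are the quantity of interest, not any package's internals.

#' Median-of-ratios size factors
#'
#' For each sample `j`, the factor is the median over features (positive in
#' every sample) of `k_ij / geometric-mean_i`, rescaled so the factors have
#' geometric mean 1.
#'
#' @param counts a [count_matrix()] or a plain count matrix.
#' @return Named numeric vector of positive per-sample scale factors.
#' @export
size_factors <- function(counts) {
  k <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  loggeo <- rowMeans(log(k))
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("no feature has positive counts in every sample; ",
         "filter all-zero-containing features first")
  }
  s <- apply(k[use, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - loggeo[use]))
  })
  s <- s / exp(mean(log(s)))
  s
}

#' Moment-based NB dispersion estimation with trend shrinkage
#'
#' Per feature, the raw dispersion is the moment estimate
#' `(var - mean) / mean^2` of size-factor-normalized counts pooled over
#' replicate groups (condition x timepoint), floored at `floor`. A
#' log-linear mean-dispersion trend is fit through arithmetic bin means of
#' the raw estimates (binning by mean count keeps the trend unbiased
#' despite the strong right skew of per-feature moment estimates), and the
#' final dispersion is the log-scale weighted average of raw and trend
#' values. By default the trend weight is chosen empirically, in the
#' moderated-statistics spirit: the sampling variance of a log moment
#' estimate at `d` residual degrees of freedom is approximated by
#' `trigamma(d/2)`, and the weight is the fraction of the observed
#' log-residual scatter it explains, so that data with no feature-specific
#' dispersion signal collapse onto the trend.
#'
#' @param counts a [count_matrix()].
#' @param factors per-sample size factors; computed when `NULL`.
#' @param prior_weight fixed weight on the trend in the log-scale average,
#'   or `NULL` (default) for the adaptive empirical weight.
#' @param floor lower bound for raw dispersions.
#' @param n_bins number of mean bins for the trend fit.
#' @return A `dispersion_model` list: `raw`, `trend_coef`, `fitted_trend`,
#'   `shrunk`, `prior_weight` (as used), `base_mean`.
#' @export
estimate_dispersions <- function(counts, factors = NULL, prior_weight = NULL,
                                 floor = 1e-8, n_bins = 20) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(factors)) factors <- size_factors(counts)
  k <- sweep(counts$counts, 2, factors, "/")
  group <- interaction(counts$meta$condition, counts$meta$timepoint, drop = TRUE)
  sizes <- table(group)
  if (!any(sizes >= 2)) {
    stop("dispersion estimation needs at least one group with >= 2 replicates")
  }
  groups <- names(sizes)[sizes >= 2]
  num <- 0; den <- 0
  for (gname in groups) {
    cols <- which(group == gname)
    m <- rowMeans(k[, cols, drop = FALSE])
    v <- apply(k[, cols, drop = FALSE], 1, var)
    w <- length(cols) - 1
    contrib <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    num <- num + ifelse(is.na(contrib), 0, w * contrib)
    den <- den + ifelse(is.na(contrib), 0, w)
  }
  raw <- ifelse(den > 0, num / den, NA_real_)
  raw <- pmax(raw, floor)
  base_mean <- rowMeans(k)
  usable <- !is.na(raw) & base_mean > 0
  ## trend through arithmetic bin means of the raw estimates
  if (sum(usable) >= 40) {
    nb <- max(3, min(n_bins, sum(usable) %/% 20))
    qs <- unique(quantile(log(base_mean[usable]), probs = seq(0, 1, length.out = nb + 1)))
    bin <- cut(log(base_mean[usable]), qs, include.lowest = TRUE)
    bin_alpha <- tapply(raw[usable], bin, mean)
    bin_mu <- tapply(base_mean[usable], bin, mean)
    bin_n <- tapply(raw[usable], bin, length)
    ok <- !is.na(bin_alpha) & bin_alpha > floor
    if (sum(ok) >= 3) {
      fit <- lm(log(bin_alpha[ok]) ~ log(bin_mu[ok]), weights = bin_n[ok])
      trend_coef <- unname(coef(fit))
    } else {
      trend_coef <- c(log(max(mean(raw[usable]), floor)), 0)
    }
  } else {
    mid <- if (any(usable)) max(mean(raw[usable]), floor) else 0.1
    trend_coef <- c(log(mid), 0)
  }
  fitted_trend <- pmax(exp(trend_coef[1] +
                             trend_coef[2] * log(pmax(base_mean, 1e-8))),
                       floor)
  ## empirical trend weight: fraction of the log-residual scatter explained
  ## by the sampling noise of a log moment estimate at d residual df
  if (is.null(prior_weight)) {
    d <- sum(sizes[sizes >= 2] - 1)
    ## delta-method variance of the log moment estimate; the Poisson part
    ## of the NB variance inflates it at small alpha * mu
    s2_samp <- trigamma(max(d, 2) / 2) *
      (1 + 1 / pmax(fitted_trend * base_mean, 1e-3))^2
    informative <- usable & raw > floor * 1.01
    if (sum(informative) >= 20) {
      resid <- log(raw[informative]) - log(fitted_trend[informative])
      s2_obs <- (stats::IQR(resid) / 1.349)^2
      s2_sig <- max(0, s2_obs - median(s2_samp[informative]))
    } else {
      s2_sig <- 0
    }
    prior_weight <- s2_samp / (s2_samp + s2_sig)
  }
  shrunk <- exp(prior_weight * log(fitted_trend) +
                  (1 - prior_weight) * log(raw))
  shrunk[is.na(shrunk)] <- fitted_trend[is.na(shrunk)]
  structure(list(raw = raw, trend_coef = trend_coef,
                 fitted_trend = fitted_trend, shrunk = pmax(shrunk, floor),
                 prior_weight = prior_weight, base_mean = base_mean),
            class = "dispersion_model")
}

# NB GLM with log link and fixed dispersion alpha, fit by IRLS.
# Model: log mu = X beta + offset; variance mu + alpha mu^2.
fit_nb_glm <- function(y, X, offset, alpha, max_iter = 100L, tol = 1e-8) {
  if (all(y == 0)) {
    return(list(converged = FALSE, all_zero = TRUE))
  }
  alpha <- max(alpha, 1e-8)
  mu <- pmax(y, 0.5)
  eta <- log(mu) - offset
  beta <- tryCatch(qr.solve(X, eta), error = function(e) rep(0, ncol(X)))
  eta <- drop(X %*% beta)
  mu <- exp(pmin(pmax(eta + offset, -30), 30))
  dev_old <- Inf
  XtWX <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- mu / (1 + alpha * mu)
    z <- eta + (y - mu) / mu
    XtW <- t(X * W)
    XtWX <- XtW %*% X
    beta_new <- tryCatch(drop(solve(XtWX, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) {
      return(list(converged = FALSE, all_zero = FALSE))
    }
    beta <- beta_new
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- pmax(exp(eta + offset), 1e-10)
    dev <- -2 * sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  W <- mu / (1 + alpha * mu)
  XtWX <- t(X * W) %*% X
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) return(list(converged = FALSE, all_zero = FALSE))
  list(converged = converged, all_zero = FALSE, beta = beta,
       se = sqrt(pmax(diag(cov), 0)), loglik = -dev_old / 2, mu = mu)
}

new_diff_result <- function(feature_id, n) {
  data.frame(feature_id = feature_id,
             base_mean = rep(NA_real_, n), log2fc = NA_real_,
             log2fc_se = NA_real_, stat = NA_real_, pvalue = NA_real_,
             padj = NA_real_, shrunken_log2fc = NA_real_,
             class = "unchanged", stringsAsFactors = FALSE)
}

#' Per-feature NB Wald test between two conditions
#'
#' Fits, per feature, an NB GLM with log link and design
#' `intercept + condition` (size factors as offsets, fixed dispersion from
#' the dispersion model). `log2fc` is the condition coefficient in log2
#' units for `contrast[1]` relative to `contrast[2]`; the Wald statistic is
#' `z = log2fc / SE` with `p = 2 * (1 - Phi(|z|))`. All-zero features get NA
#' statistics and are excluded from the BH denominator; non-converged fits
#' are flagged the same way.
#'
#' @param counts a [count_matrix()].
#' @param contrast length-2 character vector `(numerator, denominator)` of
#'   condition labels.
#' @param factors size factors (computed when `NULL`).
#' @param dispersions a `dispersion_model` (computed when `NULL`).
#' @param fdr FDR threshold used for the directional class labels.
#' @param shrink also fill `shrunken_log2fc` via [shrink_lfc()]?
#' @return A `DiffResult` data frame with columns `feature_id`, `base_mean`,
#'   `log2fc`, `log2fc_se`, `stat`, `pvalue`, `padj`, `shrunken_log2fc`,
#'   `class`.
#' @export
wald_test <- function(counts, contrast, factors = NULL, dispersions = NULL,
                      fdr = 0.1, shrink = TRUE) {
  stopifnot(inherits(counts, "count_matrix"), length(contrast) == 2)
  cond <- counts$meta$condition
  if (!all(contrast %in% cond)) {
    stop("contrast condition(s) absent from the data: ",
         paste(setdiff(contrast, cond), collapse = ", "))
  }
  keep <- cond %in% contrast
  if (sum(keep) < 2) stop("need >= 2 samples across the two conditions")
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, factors)
  k <- counts$counts[, keep, drop = FALSE]
  sf <- factors[keep]
  x <- as.numeric(cond[keep] == contrast[1])
  X <- cbind(1, x)
  offset <- log(sf)
  n <- nrow(k)
  res <- new_diff_result(rownames(k), n)
  res$base_mean <- rowMeans(sweep(k, 2, sf, "/"))
  ln2 <- log(2)
  for (i in seq_len(n)) {
    fit <- fit_nb_glm(k[i, ], X, offset, dispersions$shrunk[i])
    if (!isTRUE(fit$converged)) next
    res$log2fc[i] <- fit$beta[2] / ln2
    res$log2fc_se[i] <- fit$se[2] / ln2
  }
  res$stat <- res$log2fc / res$log2fc_se
  res$pvalue <- 2 * pnorm(-abs(res$stat))
  res$padj <- bh_adjust(res$pvalue)
  if (shrink) res <- shrink_lfc(res)
  classify_features(res, fdr = fdr)
}

#' Time-course likelihood-ratio test
#'
#' Per feature, compares the full NB GLM `intercept + timepoint factor`
#' against the intercept-only reduced model at fixed dispersion;
#' `stat = 2 * (ll_full - ll_reduced)` is referred to a chi-square with
#' `#timepoints - 1` degrees of freedom. `log2fc` reports the last-versus-
#' first timepoint coefficient for directional classification.
#'
#' @inheritParams wald_test
#' @return A `DiffResult` data frame (see [wald_test()]).
#' @export
lrt_timecourse <- function(counts, factors = NULL, dispersions = NULL,
                           fdr = 0.1, shrink = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  tps <- sort(unique(counts$meta$timepoint))
  if (length(tps) < 2) stop("time-course test needs >= 2 timepoints")
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, factors)
  k <- counts$counts
  tp_fac <- factor(counts$meta$timepoint, levels = tps)
  X_full <- model.matrix(~tp_fac)
  X_red <- X_full[, 1, drop = FALSE]
  offset <- log(factors)
  n <- nrow(k)
  df <- length(tps) - 1
  res <- new_diff_result(rownames(k), n)
  res$base_mean <- rowMeans(sweep(k, 2, factors, "/"))
  ln2 <- log(2)
  last_col <- ncol(X_full)
  for (i in seq_len(n)) {
    a <- dispersions$shrunk[i]
    full <- fit_nb_glm(k[i, ], X_full, offset, a)
    red <- fit_nb_glm(k[i, ], X_red, offset, a)
    if (!isTRUE(full$converged) || !isTRUE(red$converged)) next
    res$stat[i] <- max(0, 2 * (full$loglik - red$loglik))
    res$log2fc[i] <- full$beta[last_col] / ln2
    res$log2fc_se[i] <- full$se[last_col] / ln2
  }
  res$pvalue <- pchisq(res$stat, df = df, lower.tail = FALSE)
  res$padj <- bh_adjust(res$pvalue)
  if (shrink) res <- shrink_lfc(res)
  res <- classify_features(res, fdr = fdr)
  attr(res, "df") <- df
  res
}

#' Normal-prior shrinkage of log2 fold changes
#'
#' The prior variance `tau^2 = max(0, var(lfc) - mean(se^2))` is estimated by
#' moment matching on the MLE fold changes; the posterior mean is
#' `lfc * tau^2 / (tau^2 + se^2)`. With `tau^2 = 0` every shrunken value is 0.
#'
#' @param results a `DiffResult` data frame with `log2fc` and `log2fc_se`.
#' @return `results` with `shrunken_log2fc` filled.
#' @export
shrink_lfc <- function(results) {
  lfc <- results$log2fc
  se <- results$log2fc_se
  ok <- !is.na(lfc) & !is.na(se)
  tau2 <- if (sum(ok) >= 2) {
    max(0, var(lfc[ok]) - mean(se[ok]^2))
  } else 0
  shr <- rep(NA_real_, length(lfc))
  shr[ok] <- if (tau2 == 0) 0 else lfc[ok] * tau2 / (tau2 + se[ok]^2)
  results$shrunken_log2fc <- shr
  attr(results, "tau2") <- tau2
  results
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment in which the number of tests `m` counts only
#' non-NA p-values; NA entries stay NA.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted q-values, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Directional classification at an FDR threshold
#'
#' A feature is `increased` iff `padj < fdr` and `log2fc > 0`, `decreased`
#' iff `padj < fdr` and `log2fc < 0`, else `unchanged` (NA `padj` always
#' yields `unchanged`).
#'
#' @param results a `DiffResult` data frame with `padj` computed.
#' @param fdr FDR threshold (default 0.1).
#' @return `results` with the `class` column set.
#' @export
classify_features <- function(results, fdr = 0.1) {
  cls <- rep("unchanged", nrow(results))
  sig <- !is.na(results$padj) & results$padj < fdr & !is.na(results$log2fc)
  cls[sig & results$log2fc > 0] <- "increased"
  cls[sig & results$log2fc < 0] <- "decreased"
  results$class <- cls
  attr(results, "fdr") <- fdr
  results
}
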
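# Kaplan-Meier estimation, logrank comparison across activity strata, and
# the log-linear growth model with a treatment x time interaction test.

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times, with
#' events processed before censorings at tied times.
#'
#' @param records data frame with columns `time` (>= 0) and `event`
#'   (1 = event, 0 = censored).
#' @param group optional label stored with the estimate.
#' @return A `km_estimate` list: `time` (distinct event times), `surv`,
#'   `n_risk`, `n_event`, `n`, `group`.
#' @export
km_estimate <- function(records, group = NA_character_) {
  if (!nrow(records)) stop("need at least one record")
  if (any(records$time < 0)) stop("negative follow-up time")
  fit <- survival::survfit(survival::Surv(records$time, records$event) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], surv = fit$surv[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 n = nrow(records), group = group), class = "km_estimate")
}

#' Logrank test across groups
#'
#' Standard unweighted, unstratified logrank: at each event time, observed
#' versus expected events per group under a common hazard; the chi-square
#' statistic has `#groups - 1` degrees of freedom.
#'
#' @param records data frame with columns `time` and `event`.
#' @param group vector of group labels parallel to `records`.
#' @return A list: `statistic`, `df`, `p.value`, `n_per_group`.
#' @export
logrank_test <- function(records, group) {
  group <- as.factor(droplevels(factor(group)))
  if (nlevels(group) < 2) stop("logrank needs >= 2 non-empty groups")
  if (sum(records$event) == 0) stop("logrank needs >= 1 observed event")
  fit <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ group)
  df <- nlevels(group) - 1
  list(statistic = fit$chisq, df = df,
       p.value = pchisq(fit$chisq, df, lower.tail = FALSE),
       n_per_group = as.integer(table(group)))
}

#' Growth-rate interaction test on log-transformed cell counts
#'
#' Fits a reduced model `ln(N) ~ day` and a full model adding a treatment
#' main effect and a `day x treated` interaction, and compares them with an
#' F-test; the interaction coefficient is the treatment effect on the
#' exponential growth rate. Doubling time per condition is `ln 2 / rate`.
#'
#' @param table data frame with columns `day`, `condition`, `replicate`,
#'   `count` (> 0; the log transform requires positive counts).
#' @param reference control condition label (default the first level;
#'   `"DMSO"` when present).
#' @return A `growth_fit` list: `coefficients`, `rate_control`,
#'   `rate_treated`, `doubling_control`, `doubling_treated`, `rss_full`,
#'   `rss_reduced`, `F`, `df`, `p.value`.
#' @export
growth_interaction_test <- function(table, reference = NULL) {
  need <- c("day", "condition", "count")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("growth table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(table$count <= 0)) stop("counts must be > 0 (log undefined)")
  conds <- unique(table$condition)
  if (length(conds) != 2) stop("exactly 2 conditions are required")
  if (length(unique(table$day)) < 3) stop("need >= 3 distinct days")
  if (is.null(reference)) {
    reference <- if ("DMSO" %in% conds) "DMSO" else conds[1]
  }
  treated <- as.numeric(table$condition != reference)
  y <- log(table$count)
  day <- table$day
  full <- lm(y ~ day + treated + day:treated)
  reduced <- lm(y ~ day)
  rss_full <- sum(residuals(full)^2)
  rss_red <- sum(residuals(reduced)^2)
  df_num <- full$rank - reduced$rank
  df_den <- full$df.residual
  if (rss_red - rss_full < 1e-12) {
    Fstat <- 0; p <- 1
  } else if (rss_full < 1e-12) {
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- ((rss_red - rss_full) / df_num) / (rss_full / df_den)
    p <- pf(Fstat, df_num, df_den, lower.tail = FALSE)
  }
  cf <- coef(full)
  rate_c <- unname(cf["day"])
  rate_t <- unname(cf["day"] + cf["day:treated"])
  structure(list(coefficients = cf, rate_control = rate_c,
                 rate_treated = rate_t,
                 doubling_control = log(2) / rate_c,
                 doubling_treated = log(2) / rate_t,
                 rss_full = rss_full, rss_reduced = rss_red,
                 F = Fstat, df = c(df_num, df_den), p.value = p,
                 reference = reference), class = "growth_fit")
}
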
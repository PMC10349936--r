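test_that("size factors follow the median-of-ratios definition", {
  # identical columns are symmetric
  m <- matrix(c(5, 9, 5, 9), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # hand computation: counts [[2,4],[4,8]] -> (1/sqrt(2), sqrt(2))
  m2 <- matrix(c(2, 4, 4, 8), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # scaling one column by c scales its factor by c (up to the global
  # geometric-mean rescale, c^(1/n_samples))
  set.seed(1)
  m3 <- matrix(rpois(60, 50) + 1, 20, 3,
               dimnames = list(paste0("f", 1:20), paste0("s", 1:3)))
  s0 <- size_factors(m3)
  m4 <- m3; m4[, 2] <- m4[, 2] * 3
  s1 <- size_factors(m4)
  expect_equal(unname(s1[2] / s0[2]), 3 / 3^(1 / 3), tolerance = 1e-12)

  # invariant to feature order
  expect_equal(size_factors(m3[sample(20), ]), s0)

  # no feature positive everywhere -> advisory error
  m5 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(m5), "filter")
})

test_that("dispersion estimation recovers planted values and floors", {
  # planted alpha = 0.1 recovered at n = 4 replicates, 1000 features
  cfg <- sim_config(seed = 7, dispersion = 0.1)
  lfc <- matrix(0, 1000, 2, dimnames = list(sprintf("f%04d", 1:1000),
                                            c(0, 1440)))
  d <- estimate_dispersions(simulate_timecourse_counts(lfc, cfg))
  expect_gt(median(d$shrunk), 0.05)
  expect_lt(median(d$shrunk), 0.2)

  # near-Poisson data at means > 100: median shrunk dispersion below 0.01
  cfgp <- sim_config(seed = 7, dispersion = 1e-6,
                     baseline_meanlog = log(300), baseline_sdlog = 0.3)
  dp <- estimate_dispersions(simulate_timecourse_counts(lfc, cfgp))
  expect_lt(median(dp$shrunk), 0.01)

  # variance < mean: the raw moment estimate hits the floor
  m <- matrix(c(10, 10, 10, 10, 7, 13, 6, 14), 2, byrow = TRUE,
              dimnames = list(c("const", "noisy"), paste0("s", 1:4)))
  cm <- toy_counts(m, conditions = rep("DMSO", 4), timepoints = rep(0, 4),
                   reps = 1:4)
  dd <- estimate_dispersions(cm, factors = rep(1, 4))
  expect_equal(dd$raw[["const"]], 1e-8)
})

test_that("the Wald test matches the saturated two-group closed form", {
  # identical replicate columns relabeled as two conditions: no effect
  m <- matrix(rep(c(12, 30, 7), 4), 3,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  cm <- toy_counts(m, conditions = c("DMSO", "dTAG", "DMSO", "dTAG"))
  res <- wald_test(cm, c("dTAG", "DMSO"), factors = rep(1, 4),
                   dispersions = fixed_dispersions(3, 0.05))
  expect_equal(res$log2fc, rep(0, 3), tolerance = 1e-8)

  # A = (10, 10), B = (40, 40), equal size factors -> log2fc exactly 2
  m2 <- matrix(c(10, 10, 40, 40), 1,
               dimnames = list("f1", paste0("s", 1:4)))
  cm2 <- toy_counts(m2, conditions = c("A", "A", "B", "B"))
  res2 <- wald_test(cm2, c("B", "A"), factors = rep(1, 4),
                    dispersions = fixed_dispersions(1, 0.1))
  expect_equal(res2$log2fc, 2, tolerance = 1e-7)

  # all-zero features get NA and are excluded from the BH denominator
  m3 <- rbind(m2, f0 = c(0, 0, 0, 0))
  cm3 <- toy_counts(m3, conditions = c("A", "A", "B", "B"))
  res3 <- wald_test(cm3, c("B", "A"), factors = rep(1, 4),
                    dispersions = fixed_dispersions(2, 0.1))
  expect_true(is.na(res3$pvalue[2]))
  expect_equal(res3$padj[1], res3$pvalue[1])  # m = 1 testable feature
  expect_equal(res3$class[2], "unchanged")
})

test_that("planted log2FC = +2 is recovered by the Wald estimator", {
  cfg <- sim_config(seed = 13)
  lfc <- matrix(0, 1500, 2, dimnames = list(sprintf("f%04d", 1:1500),
                                            c(0, 1440)))
  lfc[1:500, 2] <- 2
  cm <- simulate_timecourse_counts(lfc, cfg)
  res <- wald_test(cm, c("dTAG", "DMSO"),
                   factors = attr(cm, "size_factors"))
  m_est <- mean(res$log2fc[1:500], na.rm = TRUE)
  expect_gt(m_est, 1.8)
  expect_lt(m_est, 2.2)
})

test_that("the time-course LRT reduces to a deviance difference at 2 levels", {
  cfg <- sim_config(seed = 4, n_replicates = 4)
  lfc <- matrix(c(0, 1), 30, 2, byrow = TRUE,
                dimnames = list(sprintf("f%02d", 1:30), c(0, 30)))
  cm <- simulate_timecourse_counts(lfc, cfg)
  disp <- fixed_dispersions(30, 0.05)
  res <- lrt_timecourse(cm, factors = rep(1, 8), dispersions = disp)
  expect_equal(attr(res, "df"), 1)

  # oracle: deviance difference from closed-form group-mean fits
  for (i in c(1, 15, 30)) {
    y <- cm$counts[i, ]
    g <- cm$meta$timepoint
    mu_full <- ave(y, g)
    mu_red <- rep(mean(y), length(y))
    ll <- function(mu) sum(dnbinom(y, size = 1 / 0.05, mu = mu, log = TRUE))
    stat_oracle <- 2 * (ll(mu_full) - ll(mu_red))
    expect_equal(res$stat[i], stat_oracle, tolerance = 1e-6)
  }
})

test_that("fold-change shrinkage follows the normal-prior formula", {
  df <- new_res <- data.frame(feature_id = paste0("f", 1:4),
                              log2fc = c(2, -2, 2, -2),
                              log2fc_se = sqrt(8 / 3))
  # var(lfc) = 16/3, mean(se^2) = 8/3 -> tau2 = 8/3 = se^2 -> halved
  out <- shrink_lfc(df)
  expect_equal(out$shrunken_log2fc, c(1, -1, 1, -1), tolerance = 1e-12)

  # se -> 0: no shrinkage for that feature
  df2 <- data.frame(feature_id = paste0("f", 1:4),
                    log2fc = c(2, -2, 2, -2),
                    log2fc_se = c(1e-12, 1, 1, 1))
  out2 <- shrink_lfc(df2)
  expect_equal(out2$shrunken_log2fc[1], 2, tolerance = 1e-6)

  # all fold changes zero -> tau2 = 0 -> all shrunken values zero
  df3 <- data.frame(feature_id = paste0("f", 1:4), log2fc = rep(0, 4),
                    log2fc_se = rep(0.5, 4))
  expect_equal(shrink_lfc(df3)$shrunken_log2fc, rep(0, 4))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)             # m = 1
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5)) # capped at 1
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # property: agrees with brute-force step-up on random vectors
  set.seed(99)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }

  # NA handling: m counts only testable entries
  p <- c(0.01, NA, 0.04)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], brute_bh(c(0.01, 0.04)))
})

test_that("directional classification partitions features at the FDR", {
  res <- data.frame(feature_id = paste0("f", 1:4),
                    log2fc = c(1, 0, -1, 2),
                    padj = c(0.05, 0.05, 0.05, NA))
  out <- classify_features(res, fdr = 0.1)
  expect_equal(out$class, c("increased", "unchanged", "decreased",
                            "unchanged"))
  # partition property on random results
  set.seed(3)
  res2 <- data.frame(feature_id = paste0("f", 1:200),
                     log2fc = rnorm(200),
                     padj = ifelse(runif(200) < 0.1, NA, runif(200)))
  out2 <- classify_features(res2, fdr = 0.1)
  expect_equal(sum(table(out2$class)), 200L)
})
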
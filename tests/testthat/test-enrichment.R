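test_that("over-representation p-values are exactly hypergeometric", {
  universe <- sprintf("g%02d", 1:20)
  # hits = set = universe is completely uninformative
  out <- fisher_ora(universe, universe, list(gene_set("all", universe)))
  expect_equal(out$p, 1)

  # hand-built 2x2 table (8,2; 2,8)
  hits <- universe[1:10]
  s <- gene_set("s", universe[c(1:8, 11, 12)])
  out2 <- fisher_ora(hits, universe, list(s))
  expect_equal(out2$p, brute_fisher_tail(8, 10, 10, 20), tolerance = 1e-12)

  # disjoint hit list and set with a large neither cell
  big_universe <- sprintf("g%03d", 1:200)
  out3 <- fisher_ora(big_universe[1:10], big_universe,
                     list(gene_set("far", big_universe[50:60])))
  expect_gte(out3$p, 0.95)

  # property: matches exhaustive tail summation for margins <= 30
  set.seed(77)
  for (i in 1:60) {
    N <- sample(10:30, 1)
    uni <- sprintf("u%02d", 1:N)
    hits <- sample(uni, sample(2:(N - 1), 1))
    st <- sample(uni, sample(2:(N - 1), 1))
    mine <- fisher_ora(hits, uni, list(gene_set("s", st)))
    a <- length(intersect(hits, st))
    expect_equal(mine$p, brute_fisher_tail(a, length(st), length(hits), N),
                 tolerance = 1e-12)
    # and agrees with stats::fisher.test one-sided
    tab <- matrix(c(a, length(hits) - a, length(st) - a,
                    N - length(hits) - length(st) + a), 2)
    expect_equal(mine$p, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }

  expect_error(fisher_ora("x", character(), list()), "universe")
  expect_error(fisher_ora("zzz", universe, list()), "subset")
})

test_that("enrichment scores follow the weighted running-sum definition", {
  ranked <- sprintf("g%02d", 1:10)
  w <- seq(2, -2, length.out = 10)

  # single member ranked first at exponent 0: ES = 1
  expect_equal(gsea_es(ranked, w, ranked[1], exponent = 0)$es, 1)

  # single member ranked last at exponent 0: the extreme pre-hit deviation
  # walks down to -(N-1)/(N-|S|) = -1 (brute-force running sum)
  es_last <- gsea_es(ranked, w, ranked[10], exponent = 0)$es
  expect_equal(es_last, brute_es(ranked, w, ranked[10], 0))
  expect_equal(es_last, -1, tolerance = 1e-12)

  # property: package ES equals the brute-force walk, stays in [-1, 1],
  # and the running sum returns to ~0
  set.seed(15)
  for (i in 1:40) {
    N <- sample(20:100, 1)
    ranked <- sprintf("r%03d", 1:N)
    w <- sort(rnorm(N), decreasing = TRUE)
    st <- sample(ranked, sample(3:10, 1))
    expo <- sample(c(0, 1), 1)
    out <- gsea_es(ranked, w, st, exponent = expo)
    expect_equal(out$es, brute_es(ranked, w, st, expo), tolerance = 1e-12)
    expect_lte(abs(out$es), 1)
    expect_lt(abs(out$running[N]), 1e-9)
  }

  # reversing the ranking negates ES at exponent 0
  for (i in 1:20) {
    N <- 50
    ranked <- sprintf("r%03d", 1:N)
    w <- sort(rnorm(N), decreasing = TRUE)
    st <- sample(ranked, 6)
    es_f <- gsea_es(ranked, w, st, exponent = 0)$es
    es_r <- gsea_es(rev(ranked), rev(w), st, exponent = 0)$es
    expect_equal(es_r, -es_f, tolerance = 1e-12)
  }

  expect_error(gsea_es(ranked, w, "absent"), "no member")
  expect_error(gsea_es(ranked, w, ranked), "whole")
})

test_that("enrichment scores agree with fgsea's statistic", {
  library(fgsea)
  set.seed(23)
  for (i in 1:20) {
    N <- 80
    stats_v <- sort(rnorm(N), decreasing = TRUE)
    names(stats_v) <- sprintf("r%03d", 1:N)
    sel <- sort(sample(N, 8))
    mine <- gsea_es(names(stats_v), stats_v, names(stats_v)[sel],
                    exponent = 1)$es
    ref <- fgsea::calcGseaStat(stats_v, selectedStats = sel, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("permutation p-values are deterministic with extreme-case floor", {
  N <- 60
  ranked <- sprintf("r%03d", 1:N)
  w <- sort(rnorm(N), decreasing = TRUE)
  top <- ranked[1:6]
  out <- gsea_permutation_p(ranked, w, top, exponent = 1, n_perm = 200,
                            seed = 3)
  out2 <- gsea_permutation_p(ranked, w, top, exponent = 1, n_perm = 200,
                             seed = 3)
  expect_equal(out$p.value, out2$p.value)
  # planted top-ranked set attains (nearly) the minimum attainable p; the
  # conditional denominator counts only same-sign permutations
  expect_gte(out$p.value, 1 / (1 + 200))
  expect_lte(out$p.value, 0.05)
  expect_error(gsea_permutation_p(ranked, w, top, n_perm = 10), "100")
})

test_that("the fast position-set ES path equals the full computation", {
  set.seed(31)
  N <- 100
  w <- sort(abs(rnorm(N)) + 0.01, decreasing = TRUE)
  ranked <- sprintf("r%03d", 1:N)
  for (i in 1:20) {
    pos <- sort(sample(N, 7))
    fast <- tfredist:::es_from_positions(matrix(pos, ncol = 1), w, N)
    slow <- gsea_es(ranked, w, ranked[pos], exponent = 1)$es
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("cohort z-score ranking scales against all patients", {
  expr <- matrix(c(1, 1, 1,
                   5, 2, 2,
                   3, 3, 3), 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), c("p1", "p2", "p3")))
  # gC has zero variance and is dropped; gB is high in p1
  out <- cohort_zscore_rank(expr, "p1")
  expect_equal(attr(out, "n_dropped"), 2)  # gA and gC are both constant
  expect_equal(out$gene[1], "gB")

  # a strongly outlying gene ranks first with the expected z weight
  set.seed(2)
  expr2 <- matrix(rnorm(50 * 10), 50, 10,
                  dimnames = list(sprintf("g%02d", 1:50), sprintf("p%02d", 1:10)))
  expr2["g07", ] <- c(0, 0, 10, rep(0, 7))
  out2 <- cohort_zscore_rank(expr2, "p03")
  expect_equal(out2$gene[1], "g07")
  expect_equal(out2$z[1], (10 - 1) / sd(expr2["g07", ]), tolerance = 1e-12)

  # adding a constant to a gene across all patients leaves its z unchanged
  expr3 <- expr2; expr3["g20", ] <- expr3["g20", ] + 100
  z_a <- cohort_zscore_rank(expr2, "p05")
  z_b <- cohort_zscore_rank(expr3, "p05")
  expect_equal(z_a$z[z_a$gene == "g20"], z_b$z[z_b$gene == "g20"],
               tolerance = 1e-12)

  # a patient at the cohort mean of every gene: all z = 0, order is the
  # stable gene-id tie-break
  expr5 <- matrix(rep(c(-1, 0, 1), each = 4), 4, 3,
                  dimnames = list(c("gd", "ga", "gc", "gb"),
                                  c("p1", "p2", "p3")))
  out5 <- cohort_zscore_rank(expr5, "p2")
  expect_equal(out5$gene, sort(rownames(expr5)))
  expect_equal(out5$z, rep(0, 4))

  expect_error(cohort_zscore_rank(expr[, 1:2], "p1"), ">= 3")
})

test_that("patient activity classification follows the pinned sign rule", {
  # craft one patient whose depletion-up genes sit at the bottom of the
  # ranking and depletion-down genes at the top -> high factor activity
  set.seed(41)
  G <- 300; P <- 30
  genes <- sprintf("g%03d", 1:G)
  up <- genes[1:20]; down <- genes[21:40]
  expr <- matrix(rnorm(G * P), G, P,
                 dimnames = list(genes, sprintf("p%02d", 1:P)))
  expr[up, 1] <- expr[up, 1] - 4
  expr[down, 1] <- expr[down, 1] + 4
  reg <- regulon(up, down)
  act <- patient_activity(expr, reg, n_perm = 199, seed = 5)
  expect_equal(act$class[act$patient_id == "p01"], "high")
  # ... and it carries the most negative dES of the cohort
  expect_equal(act$patient_id[1], "p01")

  # classification is exhaustive and exclusive
  expect_true(all(act$class %in% c("high", "intermediate", "low")))
  expect_equal(nrow(act), P)

  # dES is antisymmetric under swapping the regulon halves
  act_sw <- patient_activity(expr, regulon(down, up), n_perm = 199, seed = 5)
  m <- match(act$patient_id, act_sw$patient_id)
  expect_equal(act$dES, -act_sw$dES[m], tolerance = 1e-12)

  # regulon halves must overlap the expressed genes
  expect_error(patient_activity(expr[50:300, ], reg), ">= 5")
  expect_error(regulon(up, c(down, up[1])), "disjoint")
})
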
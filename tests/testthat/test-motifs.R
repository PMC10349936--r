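test_that("log-odds scoring matches the smoothed PWM definition", {
  m <- unit_motif("A")
  expect_equal(log_odds_score(m, "A"), 2, tolerance = 1e-4)

  # a motif equal to the background scores 0 everywhere
  flat <- motif_model("flat", matrix(0.25, 3, 4))
  for (s in c("ACG", "TTT", "GCA")) {
    expect_equal(log_odds_score(flat, s), 0, tolerance = 1e-9)
  }

  # N yields the -Inf sentinel; length mismatches error
  expect_identical(log_odds_score(flat, "ANG"), -Inf)
  expect_error(log_odds_score(flat, "ACGT"), "length")
})

test_that("the score-distribution DP is exact on its own discretization", {
  set.seed(21)
  for (rep in 1:5) {
    L <- sample(2:6, 1)
    probs <- t(vapply(seq_len(L), function(i) {
      x <- rexp(4) + 0.05
      x / sum(x)
    }, numeric(4)))
    bg <- c(0.3, 0.2, 0.2, 0.3)
    m <- motif_model(paste0("r", rep), probs, bg)
    tab <- score_pvalue_table(m)
    iS <- round(tfredist:::motif_score_matrix(m) / tab$delta)
    enum <- brute_score_sf(iS, bg)
    # survival at every achievable discretized score matches enumeration
    for (q in sort(unique(enum$scores))) {
      expect_equal(tab$survival[q - tab$bins[1] + 1],
                   sum(enum$probs[enum$scores >= q]), tolerance = 1e-9)
    }
    # and exact (undiscretized) scores are located within L rounding bins
    S <- tfredist:::motif_score_matrix(m)
    grid <- as.matrix(expand.grid(rep(list(1:4), L)))
    exact <- rowSums(matrix(S[cbind(as.vector(grid),
                                    rep(seq_len(L), each = nrow(grid)))],
                            nrow(grid)))
    expect_true(all(abs(exact - enum$scores * tab$delta) <=
                      L * tab$delta / 2 + 1e-12))
  }
})

test_that("score-distribution edge cases behave", {
  # single-position motif concentrated on A under a uniform background
  tab <- score_pvalue_table(unit_motif("A"))
  expect_equal(tfredist:::score_pvalue(tab, 2), 0.25, tolerance = 1e-12)
  # the minimum achievable score has survival 1
  expect_equal(tab$survival[1], 1, tolerance = 1e-12)
  # a fully uniform motif has a single score value with p = 1
  flat <- motif_model("flat", matrix(0.25, 2, 4))
  tabf <- score_pvalue_table(flat)
  expect_equal(tfredist:::score_pvalue(tabf, 0), 1, tolerance = 1e-12)
  expect_error(score_pvalue_table(flat, granularity = 10), ">= 100")
  # total probability mass is conserved
  m <- fixture_motifs()$gata
  tabg <- score_pvalue_table(m)
  expect_equal(max(tabg$survival), 1, tolerance = 1e-9)
})

test_that("interval scanning finds planted sites and respects thresholds", {
  set.seed(2)
  motifs <- fixture_motifs()
  bgseq <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  consensus <- paste(c("A", "C", "G", "T")[apply(motifs$gata$probs, 1,
                                                 which.max)], collapse = "")
  seqs <- c(chrT = bgseq)
  substr(seqs["chrT"], 2001, 2000 + nchar(consensus)) <- consensus
  regions <- peak_set("chrT", 1900, 2100, name = "r1")
  hits <- scan_intervals(motifs$gata, seqs, regions)
  expect_true(any(hits$start == 2000 & hits$strand == "+"))

  # p_threshold = 0 yields no hits at all
  expect_equal(nrow(scan_intervals(motifs$gata, seqs, regions,
                                   p_threshold = 0)), 0)

  # regions outside the sequence are rejected by name
  bad <- peak_set("chrT", 3950, 4100, name = "off_end")
  expect_error(scan_intervals(motifs$gata, seqs, bad), "off_end")
})

test_that("palindromic motifs score identically on both strands", {
  # rows chosen so the motif equals its own reverse complement
  p1 <- c(0.6, 0.1, 0.1, 0.2)
  p2 <- c(0.3, 0.2, 0.2, 0.3)
  probs <- rbind(p1, p2, rev(p2), rev(p1))
  pal <- motif_model("pal", probs)
  set.seed(8)
  seqs <- c(chrP = paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                         collapse = ""))
  S_fwd <- tfredist:::motif_score_matrix(pal)
  S_rev <- tfredist:::motif_score_matrix(
    tfredist:::reverse_complement_motif(pal))
  code <- tfredist:::encode_dna(seqs[["chrP"]])
  expect_equal(tfredist:::scan_scores(code, S_fwd),
               tfredist:::scan_scores(code, S_rev), tolerance = 1e-12)
})

test_that("scanning is translation-equivariant", {
  set.seed(5)
  motifs <- fixture_motifs()
  body <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  shift <- 137
  seqs1 <- c(chr = body)
  seqs2 <- c(chr = paste0(paste(rep("C", shift), collapse = ""), body))
  r1 <- peak_set("chr", 0, 1000, name = "w")
  r2 <- peak_set("chr", shift, 1000 + shift, name = "w")
  h1 <- scan_intervals(motifs$gata, seqs1, r1, p_threshold = 1e-3)
  h2 <- scan_intervals(motifs$gata, seqs2, r2, p_threshold = 1e-3)
  expect_equal(h2$start, h1$start + shift)
  expect_equal(h2$score, h1$score)
})

test_that("prevalence chi-square equals the textbook Pearson statistic", {
  # hand-checked 2x2 table (20,5; 5,20) -> chi-square 18
  case <- prevalence_case(counts_with = list(increased = 20, unchanged = 5),
                          counts_total = list(increased = 25, unchanged = 25))
  out <- prevalence_test(case$hits, case$peaks, case$classes)
  expect_equal(out$statistic, 18, tolerance = 1e-12)
  expect_equal(out$df, 1)

  # independence: identical prevalence in both classes
  case0 <- prevalence_case(counts_with = list(increased = 10, unchanged = 10),
                           counts_total = list(increased = 20, unchanged = 20))
  out0 <- prevalence_test(case0$hits, case0$peaks, case0$classes)
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p.value, 1)

  # property: random 3x2 tables against the brute-force formula
  set.seed(14)
  for (i in 1:50) {
    tot <- list(increased = sample(5:30, 1), unchanged = sample(5:30, 1),
                decreased = sample(5:30, 1))
    with_ <- lapply(tot, function(n) sample(0:n, 1))
    cs <- suppressWarnings(
      prevalence_test(prevalence_case(with_, tot)$hits,
                      prevalence_case(with_, tot)$peaks,
                      prevalence_case(with_, tot)$classes))
    tab <- cbind(unlist(with_), unlist(tot) - unlist(with_))
    if (any(colSums(tab) == 0)) {
      expect_equal(cs$statistic, 0)
    } else {
      expect_equal(cs$statistic, brute_chisq(tab[, 2:1]), tolerance = 1e-9)
    }
  }
})

test_that("time-course prevalence reports per-class fractions with NAs", {
  case <- prevalence_case(counts_with = list(increased = 15, unchanged = 5),
                          counts_total = list(increased = 20, unchanged = 30))
  cls <- matrix(rep(case$classes, 3), ncol = 3,
                dimnames = list(NULL, c("30", "60", "120")))
  out <- prevalence_timecourse(case$hits, case$peaks, cls)
  # identical classifications across timepoints give identical rows
  expect_equal(out["30", ], out["120", ])
  expect_equal(unname(out["30", "increased"]), 0.75)
  # a class empty at some timepoint gives NA there
  cls2 <- cls
  cls2[cls2[, 2] == "increased", 2] <- "unchanged"
  out2 <- prevalence_timecourse(case$hits, case$peaks, cls2)
  expect_true(is.na(out2["60", "increased"]))
})
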
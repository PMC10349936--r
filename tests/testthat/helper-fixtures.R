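# Small fixtures built in code at test time.

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

narrowpeak_line <- function(chrom, start, end, name, score = 50, strand = ".",
                            offset = 30) {
  paste(chrom, start, end, name, score, strand, 8, 4, 2, offset, sep = "\t")
}

# minimal count matrix with two conditions x `reps` replicates
toy_counts <- function(mat, conditions, timepoints = NULL, reps = NULL) {
  n <- ncol(mat)
  if (is.null(timepoints)) timepoints <- ifelse(conditions == "DMSO", 0, 30)
  if (is.null(reps)) reps <- ave(seq_len(n), conditions, FUN = seq_along)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("f", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(n))
  count_matrix(mat, data.frame(sample = colnames(mat),
                               condition = conditions,
                               timepoint = timepoints, replicate = reps))
}

# a fixed dispersion model, bypassing estimation
fixed_dispersions <- function(n, alpha) {
  structure(list(raw = rep(alpha, n), trend_coef = c(log(alpha), 0),
                 fitted_trend = rep(alpha, n), shrunk = rep(alpha, n),
                 prior_weight = 1, base_mean = rep(NA_real_, n)),
            class = "dispersion_model")
}

# a sharp single-position motif concentrated on one letter
unit_motif <- function(letter = "A", pseudocount = 1e-6) {
  p <- rep(0, 4)
  p[match(letter, c("A", "C", "G", "T"))] <- 1
  motif_model("unit", matrix(p, 1, 4), pseudocount = pseudocount)
}

fixture_motifs <- function() {
  read_meme_motif(system.file("extdata", "synthetic_motifs.meme",
                              package = "tfredist"))
}

# construct peaks + synthetic hits realizing a class x has-motif table
prevalence_case <- function(counts_with, counts_total, window = 150) {
  classes <- rep(names(counts_total), counts_total)
  n <- length(classes)
  summit <- seq_len(n) * 10000
  peaks <- peak_set("chrF", summit - 100, summit + 100,
                    name = sprintf("p%03d", seq_len(n)), summit = summit)
  classes <- classes[match(peaks$name, sprintf("p%03d", seq_len(n)))]
  with_motif <- unlist(lapply(names(counts_total), function(cl) {
    k <- counts_total[[cl]]
    c(rep(TRUE, counts_with[[cl]]), rep(FALSE, k - counts_with[[cl]]))
  }))
  with_motif <- with_motif[match(peaks$name, sprintf("p%03d", seq_len(n)))]
  hp <- peaks$summit[with_motif]
  hits <- data.frame(chrom = "chrF", start = hp - 4, end = hp + 4,
                     strand = "+", score = 10, pvalue = 1e-6,
                     region = peaks$name[with_motif])
  list(peaks = peaks, classes = classes, hits = hits, window = window)
}
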
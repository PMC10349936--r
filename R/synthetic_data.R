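# Seeded generators for synthetic inputs carrying the statistical structure
# every downstream stage assumes: a peak landscape with planted motif and
# geometry effects, NB time-course counts, a patient cohort with a latent
# regulon driver, and exponential growth curves.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate the
#' design of a degron depletion time course: six timepoints (DMSO vehicle
#' assigned 0 min; treatments at 30, 60, 120, 240, 1440 min), four
#' replicates, more increased than decreased accessibility peaks, a GATA-like
#' motif planted preferentially in increased peaks and an ER-half-site-like
#' motif in both directional classes, and a second factor whose binding gains
#' intensity proximal to the depleted factor and loses it distally.
#'
#' @param seed master integer seed; every generator derives its own fixed
#'   stream from it.
#' @param n_peaks number of accessibility peaks.
#' @param n_genes number of annotated genes.
#' @param n_er_peaks number of second-factor (ER) binding peaks.
#' @param timepoints depletion time course, minutes; 0 is the vehicle control.
#' @param n_replicates replicates per timepoint.
#' @param frac_increased,frac_decreased fractions of peaks planted as
#'   directionally responsive (must sum to <= 1).
#' @param frac_secondary fraction of increased peaks with delayed (secondary)
#'   kinetics and background motif probability.
#' @param lfc_mean,lfc_sd planted log2 fold-change magnitude distribution.
#' @param dispersion NB dispersion alpha (variance `mu + alpha * mu^2`).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean counts.
#' @param size_factor_sdlog log-normal sd of per-sample depth factors.
#' @param motif_enrichment list of per-class planting probabilities for the
#'   `gata` and `er_half` motifs.
#' @param gene_frac_activated,gene_frac_repressed planted gene class fractions.
#' @param gene_lfc planted log2 fold-change magnitude for responsive genes.
#' @param geometry list of distance-effect coupling parameters (bp):
#'   `peak_spacing`, `peak_width`, `prox_max` (max planted offset of proximal
#'   ER sites from an anchor summit), `mid_range`, `distal_min`,
#'   `tail_length` (anchor-free region carrying distal ER sites),
#'   `er_frac_proximal`, `er_frac_mid`, `lfc_er`, `lfc_er_sd`, `gene_offset`
#'   (TSS offset range from the driving peak).
#' @param motifs named list of [motif_model()]s to plant (`gata`, `er_half`);
#'   defaults to the synthetic pair shipped in `inst/extdata`.
#' @param cohort list: `n_patients`, `n_genes`, `regulon_size` (per half),
#'   `beta` (expression shift per unit latent activity), `gamma` (log-hazard
#'   per unit latent activity), `baseline_hazard` (events/month),
#'   `censoring_rate`, `followup_cap` (months), `noise_sd`.
#' @param growth list: `days`, `n_replicates`, `n0`, `rate_control`,
#'   `rate_treated` (per-day exponential rates), `noise_sdlog`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_peaks = 1500, n_genes = 400, n_er_peaks = 600,
                       timepoints = c(0, 30, 60, 120, 240, 1440),
                       n_replicates = 4,
                       frac_increased = 0.25, frac_decreased = 0.10,
                       frac_secondary = 0.30,
                       lfc_mean = 2, lfc_sd = 0.3, dispersion = 0.05,
                       baseline_meanlog = log(150), baseline_sdlog = 1,
                       size_factor_sdlog = 0.05,
                       motif_enrichment = list(
                         gata = c(increased = 0.8, unchanged = 0.2,
                                  decreased = 0.2),
                         er_half = c(increased = 0.6, unchanged = 0.15,
                                     decreased = 0.6)),
                       gene_frac_activated = 0.25,
                       gene_frac_repressed = 0.25,
                       gene_lfc = 1.5,
                       geometry = list(),
                       motifs = NULL,
                       cohort = list(),
                       growth = list()) {
  geom_default <- list(peak_spacing = 4000, peak_width = 300,
                       prox_max = 8000, mid_range = c(15000, 90000),
                       distal_min = 150000, tail_length = 1.5e6,
                       er_frac_proximal = 0.45, er_frac_mid = 0.15,
                       lfc_er = 0.8, lfc_er_sd = 0.3,
                       gene_offset = c(500, 5000))
  cohort_default <- list(n_patients = 200, n_genes = 1000, regulon_size = 50,
                         beta = 2, gamma = 1, baseline_hazard = 0.02,
                         censoring_rate = 0.01, followup_cap = 350,
                         noise_sd = 1)
  growth_default <- list(days = c(0, 3, 7, 10, 14), n_replicates = 4,
                         n0 = 1.25e4, rate_control = log(2) / 2,
                         rate_treated = log(2) / 2 - 0.1, noise_sdlog = 0.1)
  geometry <- utils::modifyList(geom_default, geometry)
  cohort <- utils::modifyList(cohort_default, cohort)
  growth <- utils::modifyList(growth_default, growth)
  cfg <- list(seed = as.integer(seed), n_peaks = n_peaks, n_genes = n_genes,
              n_er_peaks = n_er_peaks, timepoints = sort(unique(timepoints)),
              n_replicates = n_replicates,
              frac_increased = frac_increased, frac_decreased = frac_decreased,
              frac_secondary = frac_secondary,
              lfc_mean = lfc_mean, lfc_sd = lfc_sd, dispersion = dispersion,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              size_factor_sdlog = size_factor_sdlog,
              motif_enrichment = motif_enrichment,
              gene_frac_activated = gene_frac_activated,
              gene_frac_repressed = gene_frac_repressed,
              gene_lfc = gene_lfc,
              geometry = geometry, motifs = motifs,
              cohort = cohort, growth = growth)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_increased, cfg$frac_decreased)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("class fractions must lie in [0, 1] and sum to <= 1")
  }
  gfr <- c(cfg$gene_frac_activated, cfg$gene_frac_repressed)
  if (any(gfr < 0) || sum(gfr) > 1) stop("gene class fractions invalid")
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (cfg$n_peaks < 1 || cfg$n_genes < 1 || cfg$n_er_peaks < 1 ||
      cfg$n_replicates < 1) {
    stop("entity counts must be >= 1")
  }
  if (cfg$cohort$regulon_size * 2 > cfg$cohort$n_genes) {
    stop("regulon halves must fit in at most half the cohort genes each")
  }
  invisible(cfg)
}

default_motifs <- function() {
  path <- system.file("extdata", "synthetic_motifs.meme", package = "tfredist")
  read_meme_motif(path)
}

# time-response shapes: fraction of the full planted effect present at t min
ramp_fast <- function(t) 1 - exp(-t / 30)
ramp_slow <- function(t) pmax(0, t - 60) / (1440 - 60)

#' Simulate a peak landscape with planted motif and geometry effects
#'
#' Generates, on one synthetic chromosome: accessibility (ATAC) peaks with
#' planted increased/decreased/unchanged classes and per-timepoint log2
#' fold-change trajectories; anchor (TRPS1-like) peaks at the summits of the
#' primary increased peaks; second-factor (ER-like) peaks placed at
#' controlled summit-to-summit distances from the anchors, gaining planted
#' intensity proximally and losing it distally; gene TSSs whose response
#' class correlates with proximity to increased peaks (activated genes near
#' primary increased peaks, repressed genes in the anchor-free distal
#' region); and, optionally, the chromosome sequence with motif instances
#' planted at summit-centered positions per class probabilities.
#'
#' @param config a [sim_config()].
#' @param sequences generate the chromosome sequence and plant motif
#'   instances (`TRUE`, default)? Disable for analyses that only need the
#'   interval geometry and truth table.
#' @return A list with elements `atac`, `trps1`, `er` ([peak_set()]s),
#'   `genes` (gene annotation data frame), `genome` (named character vector
#'   of sequences, or `NULL`), `truth` (a `truth_table`), and `config`.
#' @export
simulate_peak_landscape <- function(config = sim_config(), sequences = TRUE) {
  g <- config$geometry
  set.seed(derive_seed(config$seed, "landscape"))
  width <- g$peak_width
  if (g$peak_spacing < 2 * width) {
    stop("requested peaks exceed genome capacity at the minimum spacing: ",
         "peak_spacing must be >= 2 * peak_width")
  }
  n <- config$n_peaks
  region1 <- n * g$peak_spacing
  tp <- config$timepoints

  ## --- ATAC peaks -----------------------------------------------------
  jitter <- round(runif(n, -g$peak_spacing / 8, g$peak_spacing / 8))
  summit <- round((seq_len(n) - 0.5) * g$peak_spacing) + jitter
  n_inc <- round(config$frac_increased * n)
  n_dec <- round(config$frac_decreased * n)
  class <- sample(c(rep("increased", n_inc), rep("decreased", n_dec),
                    rep("unchanged", n - n_inc - n_dec)))
  kinetic <- rep("none", n)
  inc_idx <- which(class == "increased")
  sec <- inc_idx[runif(length(inc_idx)) < config$frac_secondary]
  kinetic[inc_idx] <- "primary"
  kinetic[sec] <- "secondary"
  kinetic[class == "decreased"] <- "primary"
  magnitude <- pmax(0.2, rnorm(n, config$lfc_mean, config$lfc_sd))
  magnitude[class == "unchanged"] <- 0
  sign <- ifelse(class == "decreased", -1, ifelse(class == "increased", 1, 0))
  shape <- rbind(fast = ramp_fast(tp), slow = ramp_slow(tp))
  peak_lfc <- (sign * magnitude) *
    shape[ifelse(kinetic == "secondary", "slow", "fast"), , drop = FALSE]
  dimnames(peak_lfc) <- list(sprintf("atac_%04d", seq_len(n)), as.character(tp))

  ## motif plantings per class probability
  plant_prob <- function(map) unname(map[class])
  gata <- runif(n) < plant_prob(config$motif_enrichment$gata)
  gata[kinetic == "secondary"] <- runif(sum(kinetic == "secondary")) <
    config$motif_enrichment$gata[["unchanged"]]
  er_half <- runif(n) < plant_prob(config$motif_enrichment$er_half)

  atac <- peak_set(chrom = "chrS", start = summit - width %/% 2,
                   end = summit + width - width %/% 2,
                   name = rownames(peak_lfc), summit = summit)

  ## --- anchor (TRPS1-like) peaks --------------------------------------
  anchor_at <- which(class == "increased" & kinetic == "primary")
  extra <- sample(which(class == "unchanged"),
                  max(1, round(0.15 * length(anchor_at))))
  t_idx <- sort(c(anchor_at, extra))
  t_summit <- summit[t_idx] + round(runif(length(t_idx), -25, 25))
  trps1 <- peak_set(chrom = "chrS", start = t_summit - 100,
                    end = t_summit + 100,
                    name = sprintf("trps1_%04d", seq_along(t_idx)),
                    summit = t_summit)
  anchor_summits <- sort(t_summit)
  last_anchor <- max(anchor_summits)

  ## --- second-factor (ER-like) peaks ----------------------------------
  n_er <- config$n_er_peaks
  n_prox <- round(g$er_frac_proximal * n_er)
  n_mid <- round(g$er_frac_mid * n_er)
  n_dist <- n_er - n_prox - n_mid
  prox_pos <- anchor_summits[sample.int(length(anchor_summits), n_prox,
                                        replace = TRUE)] +
    sample(c(-1, 1), n_prox, replace = TRUE) *
      round(runif(n_prox, 100, 0.9 * g$prox_max))
  mid_pos <- last_anchor + round(runif(n_mid, g$mid_range[1], g$mid_range[2]))
  dist_pos <- last_anchor + g$distal_min +
    round(runif(n_dist, 0, g$tail_length - width))
  er_summit <- c(prox_pos, mid_pos, dist_pos)
  er_summit <- pmax(er_summit, width)
  ## true summit-to-summit distance to the nearest anchor (direct minimum)
  er_dist <- vapply(er_summit,
                    function(s) min(abs(s - anchor_summits)), numeric(1))
  er_lfc <- ifelse(er_dist < 1e4, g$lfc_er,
                   ifelse(er_dist < 1e5, 0, -g$lfc_er)) +
    rnorm(n_er, 0, g$lfc_er_sd)
  er_names <- sprintf("er_%04d", seq_len(n_er))
  er <- peak_set(chrom = "chrS", start = er_summit - width %/% 2,
                 end = er_summit + width - width %/% 2,
                 name = er_names, summit = er_summit)
  er_lfc_tp <- outer(er_lfc, as.numeric(tp > 0))
  dimnames(er_lfc_tp) <- list(er_names, as.character(tp))

  ## --- genes -----------------------------------------------------------
  genome_len <- region1 + g$distal_min + g$tail_length + g$peak_spacing
  ng <- config$n_genes
  n_act <- round(config$gene_frac_activated * ng)
  n_rep <- round(config$gene_frac_repressed * ng)
  n_unc <- ng - n_act - n_rep
  primary_summits <- summit[anchor_at]
  off <- function(k) sample(c(-1, 1), k, replace = TRUE) *
    round(runif(k, g$gene_offset[1], g$gene_offset[2]))
  # degenerate configs without driving peaks place the genes uniformly
  tss_act <- if (length(primary_summits)) {
    primary_summits[sample.int(length(primary_summits), n_act,
                               replace = TRUE)] + off(n_act)
  } else round(runif(n_act, 0, region1 - 1))
  tss_rep <- if (length(dist_pos)) {
    dist_pos[sample.int(length(dist_pos), n_rep, replace = TRUE)] +
      off(n_rep)
  } else round(runif(n_rep, 0, region1 - 1))
  tss_unc <- round(runif(n_unc, 0, genome_len - 1))
  gene_class <- c(rep("activated", n_act), rep("repressed", n_rep),
                  rep("unchanged", n_unc))
  gene_tss <- pmax(0, c(tss_act, tss_rep, tss_unc))
  gene_kin <- rep("none", ng)
  resp <- which(gene_class != "unchanged")
  gene_kin[resp] <- sample(c("fast", "slow"), length(resp), replace = TRUE)
  gene_sign <- ifelse(gene_class == "activated", 1,
                      ifelse(gene_class == "repressed", -1, 0))
  gene_lfc_tp <- (gene_sign * config$gene_lfc) *
    shape[ifelse(gene_kin == "slow", "slow", "fast"), , drop = FALSE]
  gene_ids <- sprintf("gene_%04d", seq_len(ng))
  dimnames(gene_lfc_tp) <- list(gene_ids, as.character(tp))
  genes <- data.frame(gene_id = gene_ids, chrom = "chrS", tss = gene_tss,
                      strand = sample(c("+", "-"), ng, replace = TRUE),
                      stringsAsFactors = FALSE)

  ## --- genome sequence with planted motif instances --------------------
  genome <- NULL
  if (sequences) {
    motifs <- config$motifs
    if (is.null(motifs)) motifs <- default_motifs()
    stopifnot(all(c("gata", "er_half") %in% names(motifs)))
    letters4 <- c("A", "C", "G", "T")
    seq_chars <- sample(letters4, genome_len, replace = TRUE)
    draw_instance <- function(motif) {
      inst <- apply(motif$probs, 1, function(p) sample(letters4, 1, prob = p))
      if (runif(1) < 0.5) inst <- rev(chartr("ACGT", "TGCA", inst))
      inst
    }
    plant_all <- function(chars, starts, motif) {
      w <- nrow(motif$probs)
      if (!length(starts)) return(chars)
      idx <- as.vector(vapply(starts, function(s) s:(s + w - 1),
                              numeric(w)))
      chars[idx] <- as.vector(vapply(seq_along(starts),
                                     function(i) draw_instance(motif),
                                     character(w)))
      chars
    }
    seq_chars <- plant_all(seq_chars,
                           summit[gata] - nrow(motifs$gata$probs) %/% 2,
                           motifs$gata)
    seq_chars <- plant_all(seq_chars, summit[er_half] + 30, motifs$er_half)
    genome <- c(chrS = paste(seq_chars, collapse = ""))
  }

  truth <- structure(list(
    peaks = data.frame(name = rownames(peak_lfc), chrom = "chrS",
                       summit = summit, class = class, kinetic = kinetic,
                       gata = gata, er_half = er_half,
                       lfc = sign * magnitude, stringsAsFactors = FALSE),
    peak_lfc = peak_lfc,
    er = data.frame(name = er_names, summit = er_summit,
                    dist_to_anchor = er_dist,
                    bin = cut(er_dist, c(0, 1e4, 1e5, Inf), right = FALSE,
                              labels = c("proximal", "mid", "distal")),
                    lfc = er_lfc, stringsAsFactors = FALSE),
    er_lfc = er_lfc_tp,
    genes = data.frame(gene_id = gene_ids, tss = gene_tss, class = gene_class,
                       kinetic = gene_kin, lfc = gene_sign * config$gene_lfc,
                       stringsAsFactors = FALSE),
    gene_lfc = gene_lfc_tp,
    timepoints = tp), class = "truth_table")

  list(atac = atac, trps1 = trps1, er = er, genes = genes, genome = genome,
       truth = truth, config = config)
}

#' Simulate NB time-course counts from planted fold-change trajectories
#'
#' Counts are drawn as `NB(mean = baseline * sizefactor * 2^lfc(t),
#' dispersion)` with log-normal baselines and per-sample size factors. The
#' DMSO vehicle is the 0-minute timepoint; every other timepoint carries the
#' `dTAG` condition label.
#'
#' @param truth a `truth_table` from [simulate_peak_landscape()], or a plain
#'   numeric matrix of planted log2 fold changes (features x timepoints,
#'   column names in minutes).
#' @param config a [sim_config()].
#' @param features which planted trajectory of the truth table to use:
#'   `"atac"` peaks, `"genes"`, or `"er"` peaks.
#' @return A [count_matrix()].
#' @export
simulate_timecourse_counts <- function(truth, config = sim_config(),
                                       features = c("atac", "genes", "er")) {
  features <- match.arg(features)
  lfc <- if (is.matrix(truth)) truth else switch(features,
    atac = truth$peak_lfc, genes = truth$gene_lfc, er = truth$er_lfc)
  set.seed(derive_seed(config$seed, paste0("counts_", features)))
  tp <- as.numeric(colnames(lfc))
  n <- nrow(lfc)
  reps <- config$n_replicates
  samples <- expand.grid(replicate = seq_len(reps), timepoint = tp,
                         KEEP.OUT.ATTRS = FALSE)
  s <- nrow(samples)
  baseline <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  sf <- rlnorm(s, 0, config$size_factor_sdlog)
  tp_col <- match(as.character(samples$timepoint), colnames(lfc))
  mu <- baseline * t(t(2^lfc[, tp_col, drop = FALSE]) * sf)
  counts <- matrix(rnbinom(n * s, mu = mu, size = 1 / config$dispersion),
                   nrow = n)
  rownames(counts) <- rownames(lfc)
  colnames(counts) <- sprintf("t%04d_r%d", samples$timepoint,
                              samples$replicate)
  meta <- data.frame(sample = colnames(counts),
                     condition = ifelse(samples$timepoint == 0, "DMSO", "dTAG"),
                     timepoint = samples$timepoint,
                     replicate = samples$replicate,
                     stringsAsFactors = FALSE)
  cm <- count_matrix(counts, meta)
  # the drawn depth factors and baselines, for parameter-recovery checks
  attr(cm, "size_factors") <- setNames(sf, colnames(counts))
  attr(cm, "baseline") <- setNames(baseline, rownames(counts))
  cm
}

#' Simulate a patient cohort driven by a latent regulon score
#'
#' Each patient carries a latent score `a ~ N(0, 1)` describing how strongly
#' its expression profile resembles the depletion response: genes of the
#' depletion-up regulon half are shifted by `+beta * a`, depletion-down genes
#' by `-beta * a`, all other genes are noise. Survival times are exponential
#' with hazard `h0 * exp(gamma * a)` under independent exponential censoring
#' capped at `followup_cap` months.
#'
#' @param config a [sim_config()]; see the `cohort` element.
#' @return A list: `expression` (genes x patients matrix), `survival`
#'   (data frame `patient_id`, `time`, `event`, `er_status`), `regulon`
#'   (a [regulon()]), `truth` (data frame `patient_id`, `activity`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  co <- config$cohort
  set.seed(derive_seed(config$seed, "cohort"))
  G <- co$n_genes; P <- co$n_patients; m <- co$regulon_size
  genes <- sprintf("g%04d", seq_len(G))
  patients <- sprintf("p%03d", seq_len(P))
  up <- genes[seq_len(m)]
  down <- genes[seq_len(m) + m]
  activity <- rnorm(P)
  delta <- numeric(G)
  delta[seq_len(m)] <- 1
  delta[seq_len(m) + m] <- -1
  mu_g <- rnorm(G, 8, 2)
  expr <- mu_g + co$beta * outer(delta, activity) +
    matrix(rnorm(G * P, 0, co$noise_sd), G, P)
  dimnames(expr) <- list(genes, patients)
  death <- rexp(P, co$baseline_hazard * exp(co$gamma * activity))
  cens <- pmin(rexp(P, co$censoring_rate), co$followup_cap)
  surv <- data.frame(patient_id = patients,
                     time = pmin(death, cens),
                     event = as.integer(death <= cens),
                     er_status = sample(c("positive", "negative"), P,
                                        replace = TRUE, prob = c(0.75, 0.25)),
                     stringsAsFactors = FALSE)
  list(expression = expr, survival = surv,
       regulon = regulon(activated = up, repressed = down),
       truth = data.frame(patient_id = patients, activity = activity,
                          stringsAsFactors = FALSE))
}

#' Simulate exponential growth curves with a treatment-modified rate
#'
#' Cell counts follow `N0 * exp(r_c * day)` with log-normal multiplicative
#' noise and a condition-specific per-day rate `r_c`.
#'
#' @param config a [sim_config()]; see the `growth` element.
#' @return Data frame with columns `day`, `condition`, `replicate`, `count`.
#' @export
simulate_growth <- function(config = sim_config()) {
  gw <- config$growth
  set.seed(derive_seed(config$seed, "growth"))
  des <- expand.grid(replicate = seq_len(gw$n_replicates), day = gw$days,
                     condition = c("DMSO", "dTAG"), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  rate <- ifelse(des$condition == "DMSO", gw$rate_control, gw$rate_treated)
  noise <- if (gw$noise_sdlog > 0) rlnorm(nrow(des), 0, gw$noise_sdlog) else 1
  data.frame(day = des$day, condition = des$condition,
             replicate = des$replicate,
             count = gw$n0 * exp(rate * des$day) * noise,
             stringsAsFactors = FALSE)
}
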
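# Shared genomic data model and readers/writers for the plain-text formats
# the pipeline touches. Coordinates are 0-based, half-open (BED convention)
# throughout; all distances are in bp between point positions.

#' Construct a peak set
#'
#' A peak set is an ordered collection of genomic intervals with point-source
#' summits, the unit of all classification, proximity, and prevalence
#' analyses. Intervals are 0-based half-open; the summit is an absolute bp
#' position inside the interval.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param name unique identifiers; generated (`peak_1`, ...) when `NULL`.
#' @param score numeric score (default 0).
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @param summit absolute summit position in `[start, end)`; defaults to the
#'   interval midpoint `floor((start + end)/2)` so that summitless inputs
#'   still flow through summit-based operations.
#' @param genome optional named vector of chromosome lengths.
#' @return A `peak_set`: a data frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`, `summit`, sorted by `(chrom, start)`.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = 0,
                     strand = ".", summit = NULL, genome = NULL) {
  n <- length(chrom)
  if (n == 0) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     name = character(), score = numeric(),
                     strand = character(), summit = integer())
    class(df) <- c("peak_set", "data.frame")
    attr(df, "genome") <- genome
    return(df)
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.null(name)) name <- paste0("peak_", seq_len(n))
  if (is.null(summit)) summit <- floor((start + end) / 2)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   summit = as.numeric(summit), stringsAsFactors = FALSE)
  validate_peak_set(df)
  df <- df[order(df$chrom, df$start, df$end, df$name), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  attr(df, "genome") <- genome
  df
}

validate_peak_set <- function(df) {
  if (any(df$start < 0)) stop("peak start positions must be >= 0")
  if (any(df$start >= df$end)) stop("peak intervals require start < end")
  if (anyDuplicated(df$name)) {
    stop("peak names must be unique within a set; duplicated: ",
         paste(unique(df$name[duplicated(df$name)])[1:3], collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  bad <- df$summit < df$start | df$summit >= df$end
  if (any(bad)) {
    stop("summit outside [start, end) for peak(s): ",
         paste(head(df$name[bad], 3), collapse = ", "))
  }
  invisible(df)
}

as_granges <- function(ps) {
  GenomicRanges::GRanges(ps$chrom,
                         IRanges::IRanges(start = ps$start + 1, end = ps$end))
}

#' Read peaks from narrowPeak or BED6 files
#'
#' narrowPeak records carry a summit offset in column 10 (`summit = start +
#' offset`); an offset of -1 (no point source called) and all BED6 records
#' fall back to the interval midpoint. Malformed lines raise an error naming
#' the line number.
#'
#' @param path file path.
#' @param format `"narrowPeak"` (10 columns) or `"bed6"` (>= 6 columns).
#' @return A [peak_set()], sorted by `(chrom, start)`.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track")
  idx <- which(keep)
  if (length(idx) == 0) return(peak_set(character(), integer(), integer()))
  need <- if (format == "narrowPeak") 10L else 6L
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < need)) {
    bad <- idx[which(nf < need)[1]]
    stop(sprintf("parse error at line %d: expected >= %d tab-delimited fields",
                 bad, need))
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
    if (anyNA(v)) {
      bad <- idx[which(is.na(v))[1]]
      stop(sprintf("parse error at line %d: non-numeric %s", bad, what))
    }
    v
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- num(2L, "start")
  end <- num(3L, "end")
  nm <- vapply(fields, `[[`, "", 4L)
  score <- num(5L, "score")
  strand <- vapply(fields, `[[`, "", 6L)
  if (format == "narrowPeak") {
    off <- num(10L, "summit offset")
    if (any(off >= end - start)) {
      bad <- idx[which(off >= end - start)[1]]
      stop(sprintf("validation error at line %d: summit offset >= peak length",
                   bad))
    }
    summit <- ifelse(off < 0, floor((start + end) / 2), start + off)
  } else {
    summit <- floor((start + end) / 2)
  }
  peak_set(chrom, start, end, nm, score, strand, summit)
}

#' Write a peak set to narrowPeak or BED6
#'
#' narrowPeak output stores the summit as an offset in column 10, so
#' `read_peaks(write_peaks(x))` is the identity on coordinates, names, and
#' summits. BED6 has no summit column; the summit is recoverable only when it
#' equals the interval midpoint.
#'
#' @param x a [peak_set()].
#' @param path output file path.
#' @param format `"narrowPeak"` or `"bed6"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  if (format == "narrowPeak") {
    out <- data.frame(x$chrom, x$start, x$end, x$name, x$score, x$strand,
                      0, -1, -1, x$summit - x$start)
  } else {
    out <- data.frame(x$chrom, x$start, x$end, x$name, x$score, x$strand)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Construct a count matrix with sample metadata
#'
#' @param counts integer matrix (features x samples) of non-negative read
#'   counts, with unique rownames (feature ids) and colnames (sample ids).
#' @param meta data frame with one row per sample and columns `sample`,
#'   `condition`, `timepoint` (minutes), `replicate`.
#' @return A `count_matrix`: `list(counts, meta)` with samples aligned.
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("feature ids must be unique")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  need <- c("sample", "condition", "timepoint", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(meta$condition) || anyNA(meta$timepoint)) {
    stop("every sample needs a condition and a timepoint")
  }
  extra <- setdiff(colnames(counts), meta$sample)
  absent <- setdiff(meta$sample, colnames(counts))
  if (length(extra) || length(absent)) {
    stop("sample mismatch between counts and metadata; missing from metadata: ",
         paste(extra, collapse = ", "), "; missing from counts: ",
         paste(absent, collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:", paste(unique(x$meta$condition), collapse = ", "), "\n")
  cat("timepoints (min):",
      paste(sort(unique(x$meta$timepoint)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a count table with companion sample metadata
#'
#' The count TSV has a leading feature-id column and one column per sample;
#' the metadata TSV maps `sample` to `condition`, `timepoint`, `replicate`.
#' Non-integer cells and sample mismatches raise validation errors naming
#' the offenders.
#'
#' @param path count TSV path.
#' @param meta_path metadata TSV path.
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, meta_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count table needs a feature column plus samples")
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)[1, ]
    stop(sprintf("validation error: non-numeric count for feature '%s', sample '%s'",
                 ids[bad[1]], colnames(tab)[-1][bad[2]]))
  }
  off <- which(mat != round(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(off)) {
    stop(sprintf("validation error: cell (%s, %s) = %s is not a non-negative integer",
                 ids[off[1, 1]], colnames(mat)[off[1, 2]], mat[off[1, 1], off[1, 2]]))
  }
  rownames(mat) <- ids
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  count_matrix(mat, meta)
}

#' Construct a motif model (position probability matrix)
#'
#' @param name motif identifier.
#' @param probs position x alphabet (A, C, G, T) probability matrix; each row
#'   must sum to 1 within 1e-6 (rows are renormalized exactly).
#' @param background alphabet background probabilities (must sum to 1).
#' @param pseudocount small positive smoothing constant applied as
#'   `(p + pseudocount * bg) / (1 + pseudocount)` before log-odds scoring.
#' @return A `motif_model` list.
#' @export
motif_model <- function(name, probs, background = rep(0.25, 4),
                        pseudocount = 1e-3) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("probs must have 4 columns (A, C, G, T)")
  colnames(probs) <- c("A", "C", "G", "T")
  if (any(probs < 0)) stop("motif probabilities must be >= 0")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("validation error: motif probability rows must sum to 1")
  }
  probs <- probs / rowSums(probs)
  background <- as.numeric(background)
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  names(background) <- c("A", "C", "G", "T")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  structure(list(name = name, probs = probs, background = background,
                 pseudocount = pseudocount), class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model '%s': %d positions\n", x$name, nrow(x$probs)))
  invisible(x)
}

#' Read motifs from a MEME minimal-format text file
#'
#' Parses every `MOTIF` block with its letter-probability matrix. The
#' background is taken from the `Background letter frequencies` block when
#' present, else uniform 0.25. Probability rows must sum to 1 within 1e-3
#' (then renormalized exactly); alphabets other than ACGT are rejected.
#'
#' @param path MEME file path.
#' @param pseudocount smoothing constant stored in each returned model.
#' @return A named list of [motif_model()] objects.
#' @export
read_meme_motif <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME motif file (no 'MEME version' line): ", path)
  }
  alpha_line <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha_line)) {
    alpha <- gsub("\\s", "", sub("^ALPHABET=?", "", alpha_line[1]))
    if (toupper(alpha) != "ACGT") stop("unknown alphabet: ", alpha)
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    background <- as.numeric(vals[c("A", "C", "G", "T")])
  }
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("no MOTIF block found in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1]][1]
    hdr <- grep("letter-probability matrix", lines[seq(s, length(lines))])[1]
    if (is.na(hdr)) stop("motif '", name, "' lacks a letter-probability matrix")
    hdr <- s + hdr - 1
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])))
    rows <- lines[seq(hdr + 1, hdr + w)]
    probs <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }, numeric(4), USE.NAMES = FALSE))
    if (anyNA(probs)) stop("malformed probability row in motif '", name, "'")
    if (any(abs(rowSums(probs) - 1) > 1e-3)) {
      stop("validation error: probability row of motif '", name,
           "' does not sum to 1 within 1e-3")
    }
    probs <- probs / rowSums(probs)
    out[[name]] <- motif_model(name, probs, background, pseudocount)
  }
  out
}

#' Read a survival table
#'
#' Expects tab-delimited columns `patient_id`, `time` (follow-up, months),
#' `event` (1 = death observed, 0 = censored); any further columns are kept
#' as covariates.
#'
#' @param path TSV path.
#' @return A data frame of survival records.
#' @export
read_survival_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survival table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$time < 0)) stop("follow-up times must be >= 0")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  df
}
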
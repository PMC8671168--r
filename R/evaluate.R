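#' Multiple sequence alignments
#'
#' An `msa` is the query-anchored alignment used for alignment-depth
#' statistics: row 1 is the query, all rows have equal length, `-` is the gap
#' character (lower-case insertion states of A3M-like files are removed on
#' read so columns stay query-anchored).
#'
#' @param rows character vector of aligned sequences, query first.
#' @return An object of class `msa`.
#' @export
msa <- function(rows) {
  rows <- toupper(as.character(rows))
  if (!length(rows)) stop("an MSA needs at least one row")
  if (length(unique(nchar(rows))) != 1L)
    stop("all MSA rows must have equal length")
  structure(list(query = rows[1L], rows = rows), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows x %d columns\n", length(x$rows),
              nchar(x$query)))
  invisible(x)
}

#' Read an aligned FASTA / A3M-like file as an MSA
#'
#' @param path aligned FASTA path, query first. Lower-case (insertion)
#'   columns are dropped, `.` gaps converted to `-`.
#' @return An [msa()].
#' @export
read_msa <- function(path) {
  seqs <- as.character(Biostrings::readBStringSet(path))
  seqs <- gsub("[a-z]", "", seqs)     # A3M insertion states
  seqs <- gsub("\\.", "-", seqs)
  msa(unname(seqs))
}

#' @rdname read_msa
#' @param m an [msa()].
#' @export
write_msa <- function(m, path) {
  n <- length(m$rows)
  writeLines(as.vector(rbind(paste0(">seq", seq_len(n) - 1L), m$rows)), path)
  invisible(path)
}

msa_matrix <- function(m) {
  do.call(rbind, strsplit(m$rows, ""))
}

#' Ranking loss of a quality-assessment selection
#'
#' The true GDT-TS of the best model in the pool minus the true GDT-TS of the
#' model the quality-assessment method ranked first (reported as an absolute
#' value).
#'
#' @param true_scores named numeric vector of true scores per model.
#' @param selected_top1 id of the model the method selected.
#' @return Non-negative loss in GDT-TS units.
#' @export
ranking_loss <- function(true_scores, selected_top1) {
  if (!selected_top1 %in% names(true_scores))
    stop("selected model ", selected_top1, " not among the scored models")
  abs(max(true_scores) - true_scores[[selected_top1]])
}

#' Per-model Z-scores within a target pool
#'
#' `Z_i = (s_i - mean(s)) / sd(s)` with the population (divide-by-n) standard
#' deviation, the CASP convention; set `population = FALSE` for the sample SD.
#' Pools with zero spread get all-zero Z with a warning.
#'
#' @param scores numeric model scores (>= 2).
#' @param population use the population SD (default) or the sample SD.
#' @return A list: `z` (per model, named like `scores`) and `sum_positive_z`.
#' @export
z_scores <- function(scores, population = TRUE) {
  stopifnot(length(scores) >= 2L)
  mu <- mean(scores)
  sd_ <- if (population)
    sqrt(mean((scores - mu)^2)) else stats::sd(scores)
  if (sd_ == 0) {
    warning("zero-variance scores: all Z-scores set to 0")
    z <- rep(0, length(scores))
  } else z <- (scores - mu) / sd_
  names(z) <- names(scores)
  list(z = z, sum_positive_z = sum(pmax(z, 0)))
}

#' Moment-estimator skewness
#'
#' Unadjusted sample skewness `g1 = m3 / m2^(3/2)` from the second and third
#' central moments. Positive skew indicates mean above the median — the
#' few-good-models regime when applied to a pool's quality scores.
#'
#' @param scores numeric vector (>= 3 values).
#' @return `g1`; 0 with a warning when the variance is zero.
#' @export
skewness <- function(scores) {
  stopifnot(length(scores) >= 3L)
  mu <- mean(scores)
  m2 <- mean((scores - mu)^2)
  if (m2 == 0) {
    warning("zero-variance scores: skewness reported as 0")
    return(0)
  }
  mean((scores - mu)^3) / m2^1.5
}

# identity of one aligned row to the query over query non-gap columns,
# divided by the query non-gap length
row_identity <- function(qchr, rchr, qpos) {
  mean(qchr[qpos] == rchr[qpos] & rchr[qpos] != "-")
}

#' Number of effective sequences (Neff) of an MSA
#'
#' Greedy clustering of the alignment rows in file order: a row joins the
#' first existing cluster whose representative shares more than
#' `identity_cut` identity with it (identical residues over the query's
#' non-gap columns, divided by the query non-gap length); otherwise it founds
#' a new cluster. Neff is the number of clusters — the count of non-redundant
#' sequences at the identity threshold.
#'
#' @param m an [msa()].
#' @param identity_cut redundancy identity threshold.
#' @return Integer Neff between 1 and the row count.
#' @export
neff <- function(m, identity_cut = 0.62) {
  stopifnot(inherits(m, "msa"))
  mm <- msa_matrix(m)
  qpos <- which(mm[1L, ] != "-")
  reps <- 1L
  for (r in seq_len(nrow(mm))[-1L]) {
    joined <- FALSE
    for (rep_ in reps) {
      id <- mean(mm[rep_, qpos] == mm[r, qpos] & mm[r, qpos] != "-" &
                   mm[rep_, qpos] != "-")
      if (id > identity_cut) { joined <- TRUE; break }
    }
    if (!joined) reps <- c(reps, r)
  }
  length(reps)
}

#' Fraction of good-quality models in a pool
#'
#' @param scores per-model TM-scores.
#' @param threshold a model is good when its score is strictly above this.
#' @return Fraction in \[0, 1\].
#' @export
good_fraction <- function(scores, threshold = 0.5) {
  stopifnot(length(scores) >= 1L)
  mean(scores > threshold)
}

#' Per-column alignment coverage profile
#'
#' For each query non-gap column, the number of alignment rows (query
#' included) with a residue in that column.
#'
#' @param m an [msa()].
#' @return Integer vector over the query's non-gap positions.
#' @export
coverage_profile <- function(m) {
  mm <- msa_matrix(m)
  qpos <- which(mm[1L, ] != "-")
  colSums(mm[, qpos, drop = FALSE] != "-")
}

#' Pearson correlation, optionally on log-transformed x
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param log_x correlate `y` with `log(x)` instead of `x`.
#' @return Pearson r, or `NA` with a warning when either side has zero
#'   variance.
#' @export
correlate <- function(x, y, log_x = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (log_x) {
    if (any(x <= 0)) stop("log_x requires strictly positive x")
    x <- log(x)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Per-target evaluation report
#'
#' Computes the evaluation statistics for one target pool from its true and
#' predicted scores: ranking loss of the predicted top-1, per-model Z-scores
#' of the true scores with the summed positive Z, the skewness of the true
#' score distribution, and the good-model fraction.
#'
#' @param scores data frame with columns `model_id`, `true_score`,
#'   `predicted_score` (one row per model).
#' @param good_threshold threshold for [good_fraction()] (on `true_score`).
#' @return A list of class `eval_report`: `loss`, `z` (named), `sum_positive_z`,
#'   `skewness`, `good_fraction`, `selected_top1`.
#' @export
eval_report <- function(scores, good_threshold = 0.5) {
  need <- c("model_id", "true_score", "predicted_score")
  stopifnot(all(need %in% names(scores)))
  ts <- stats::setNames(scores$true_score, scores$model_id)
  top1 <- scores$model_id[order(-scores$predicted_score, scores$model_id)][1L]
  zz <- z_scores(ts)
  structure(list(loss = ranking_loss(ts, top1), z = zz$z,
                 sum_positive_z = zz$sum_positive_z,
                 skewness = skewness(unname(ts)),
                 good_fraction = good_fraction(unname(ts), good_threshold),
                 selected_top1 = top1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> loss %.4f (top-1 %s), sum +Z %.3f, ",
                     "skewness %.3f, good fraction %.3f\n"),
              x$loss, x$selected_top1, x$sum_positive_z, x$skewness,
              x$good_fraction))
  invisible(x)
}
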
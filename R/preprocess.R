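#' Per-sample boxplot QC summaries
#'
#' Summarizes each lane's count distribution on the log2(count + 1) scale
#' (median, quartiles, IQR) and flags lanes whose log-median deviates from
#' the cohort median of log-medians by more than `f` times the cohort IQR of
#' log-medians. Flags are advisory only: the pipeline proceeds with all
#' lanes, and flagged lanes are never removed automatically.
#'
#' @param x [ncounter_counts] object.
#' @param f flagging multiplier on the cohort IQR of log-medians.
#' @return data frame with one row per sample: `sample_id`, `log_median`,
#'   `log_q1`, `log_q3`, `log_iqr`, `flagged`.
#' @export
qc_boxplot_stats <- function(x, f = 3) {
  stopifnot(inherits(x, "ncounter_counts"), f >= 0)
  lg <- log2(x$counts + 1)
  q <- apply(lg, 2, stats::quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  med <- q[2, ]
  cohort_med <- stats::median(med)
  cohort_iqr <- stats::IQR(med)
  data.frame(sample_id = colnames(x$counts),
             log_median = med,
             log_q1 = q[1, ],
             log_q3 = q[3, ],
             log_iqr = q[3, ] - q[1, ],
             flagged = abs(med - cohort_med) > f * cohort_iqr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Positive-control lane normalization
#'
#' Each lane is rescaled so that all lanes share the same positive-control
#' geometric mean. The per-lane factor is the arithmetic mean (over lanes)
#' of the per-lane positive-control geometric means, divided by this lane's
#' positive-control geometric mean; every probe count in the lane (controls
#' included) is multiplied by the factor.
#'
#' @param x [ncounter_counts] object; every positive-control count must be
#'   strictly positive.
#' @return `ncounter_norm` object at stage `pos_scaled`, retaining all probes
#'   and carrying the applied `scale_factors`.
#' @export
positive_control_normalize <- function(x) {
  stopifnot(inherits(x, "ncounter_counts"))
  pos <- x$counts[x$probe_class == "Positive", , drop = FALSE]
  zero <- which(pos == 0, arr.ind = TRUE)
  if (nrow(zero) > 0)
    stop("positive-control count of 0 (probe '", rownames(pos)[zero[1, 1]],
         "', sample '", colnames(pos)[zero[1, 2]],
         "'): geometric mean undefined; inspect this lane before analysis")
  geo <- exp(colMeans(log(pos)))
  factors <- mean(geo) / geo
  new_ncounter_norm(sweep(x$counts, 2, factors, `*`), x$probe_class,
                    "pos_scaled", factors)
}

#' Background threshold from negative-control probes
#'
#' The per-sample threshold is the mean of that sample's negative-control
#' values plus `k` times their sample (n-1) standard deviation. With
#' `pooled = TRUE` a single cohort-wide threshold (mean + k*SD over all
#' negative-control values in all samples) is used for every sample.
#' Thresholds are computed on the same scale as the matrix supplied, so pass
#' the positive-control-scaled matrix to compare scaled probes against
#' equally scaled background.
#'
#' @param x [ncounter_counts] or `ncounter_norm` object containing at least
#'   two Negative probes.
#' @param k SD multiplier.
#' @param pooled pool negative controls across samples?
#' @return `background_model` list: `threshold`, `mean`, `sd` (each per
#'   sample), `k`, `pooled`.
#' @export
compute_background <- function(x, k = 2, pooled = FALSE) {
  vals <- if (inherits(x, "ncounter_counts")) x$counts else x$values
  cls <- x$probe_class
  neg <- vals[cls == "Negative", , drop = FALSE]
  if (nrow(neg) < 2)
    stop("at least 2 Negative probes are required to estimate background SD")
  if (pooled) {
    m <- rep(mean(neg), ncol(neg))
    s <- rep(stats::sd(as.vector(neg)), ncol(neg))
  } else {
    m <- colMeans(neg)
    s <- apply(neg, 2, stats::sd)
  }
  names(m) <- names(s) <- colnames(neg)
  structure(list(threshold = m + k * s, mean = m, sd = s, k = k,
                 pooled = pooled),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("Background model (mean + ", x$k, "*SD, ",
      if (x$pooled) "pooled" else "per-sample", "): thresholds ",
      signif(min(x$threshold), 4), " .. ", signif(max(x$threshold), 4),
      " across ", length(x$threshold), " samples\n", sep = "")
  invisible(x)
}

#' Prevalence filter against the background threshold
#'
#' An endogenous probe is dropped iff the fraction of samples in which its
#' value is below that sample's background threshold is strictly greater
#' than `frac` ("more than 90% of samples below background" at the default).
#' Control probes and any non-endogenous classes are removed from the
#' analysis set here regardless of prevalence.
#'
#' @param x `ncounter_norm` object at stage `pos_scaled` (all probes).
#' @param bg `background_model` covering every sample of `x`.
#' @param frac prevalence cutoff in `[0, 1]`; strict inequality.
#' @return `ncounter_norm` object at stage `filtered`, restricted to the
#'   retained endogenous probes (input order preserved), with attribute
#'   `dropped` listing the endogenous probe ids removed.
#' @export
filter_low_expressed <- function(x, bg, frac = 0.90) {
  stopifnot(inherits(x, "ncounter_norm"), inherits(bg, "background_model"))
  if (frac < 0 || frac > 1) stop("`frac` must be in [0, 1]")
  if (!all(colnames(x$values) %in% names(bg$threshold)))
    stop("background model does not cover all samples")
  thr <- bg$threshold[colnames(x$values)]
  endo <- x$probe_class == "Endogenous"
  other <- !endo & !(x$probe_class %in% c("Positive", "Negative"))
  if (any(other))
    warning(sum(other), " probe(s) with non-analysis classes (",
            paste(unique(x$probe_class[other]), collapse = ", "),
            ") excluded from the analysis set")
  e <- x$values[endo, , drop = FALSE]
  below <- rowMeans(sweep(e, 2, thr, `<`))
  drop <- below > frac
  out <- new_ncounter_norm(e[!drop, , drop = FALSE], x$probe_class,
                           "filtered", x$scale_factors)
  attr(out, "dropped") <- rownames(e)[drop]
  out
}

#' Quantile normalization (rank-mean)
#'
#' Classic quantile normalization: the reference distribution at rank r is
#' the mean across samples of each sample's r-th smallest value; each
#' sample's values are replaced by the reference value at their within-sample
#' rank. Ties within a sample receive the mean of the reference values over
#' the tied rank span, so afterwards every column has exactly the same
#' multiset of values.
#'
#' @param x `ncounter_norm` object (or plain numeric matrix) with >= 1 probe
#'   and >= 2 samples.
#' @return same container type at stage `quantile_normalized`.
#' @export
quantile_normalize <- function(x) {
  vals <- if (inherits(x, "ncounter_norm")) x$values else x
  stopifnot(is.matrix(vals), nrow(vals) >= 1)
  if (ncol(vals) < 2)
    stop("quantile normalization needs at least 2 samples")
  ref <- rowMeans(apply(vals, 2, sort))
  out <- apply(vals, 2, function(col) {
    v <- ref[rank(col, ties.method = "first")]
    stats::ave(v, match(col, col), FUN = mean)   # mean of reference over tied span
  })
  dimnames(out) <- dimnames(vals)
  if (inherits(x, "ncounter_norm"))
    new_ncounter_norm(out, x$probe_class, "quantile_normalized", x$scale_factors)
  else out
}
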
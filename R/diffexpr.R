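#' Expected-false-positive significance cutoff
#'
#' With m tests, alpha = 1/m controls the expected number of false positives
#' under the global null at one: of m true-null hypotheses tested at level
#' 1/m, about one is expected to pass. For the 519 miRNAs surviving
#' filtering this gives 1/519 = 0.0019 (4 d.p.); the full-precision value is
#' used in comparisons, the rounded one in logs.
#'
#' @param m number of tested miRNAs, >= 1.
#' @return alpha = 1/m (full precision).
#' @export
expected_fp_cutoff <- function(m) {
  if (length(m) != 1 || !is.finite(m) || m < 1 || m != round(m))
    stop("`m` must be a positive integer count of tested miRNAs")
  1 / m
}

# resolve contrast groups to sample index lists; both groups need >= 2 lanes
contrast_groups <- function(values, metadata, contrast) {
  stopifnot(length(contrast) == 2)
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  if (anyNA(metadata$sample_id))
    stop("metadata missing samples: ",
         paste(setdiff(colnames(values), metadata$sample_id), collapse = ", "))
  idx <- lapply(contrast, function(g) which(metadata$group == g))
  names(idx) <- contrast
  small <- lengths(idx) < 2
  if (any(small))
    stop("contrast group(s) with fewer than 2 samples: ",
         paste(contrast[small], collapse = ", "),
         " (residual variance undefined)")
  idx
}

de_values <- function(x, scale) {
  vals <- if (inherits(x, "ncounter_norm")) x$values else x
  stopifnot(is.matrix(vals))
  if (scale == "log2p1") log2(vals + 1) else vals
}

#' Per-miRNA two-group linear-model test
#'
#' For each miRNA, expression (log2(value + 1) by default) is regressed by
#' ordinary least squares on a 0/1 group indicator (1 = `contrast[1]`).
#' The p-value is the two-sided t-test on the slope with n - 2 residual
#' degrees of freedom, which for a two-group contrast is identical to the
#' pooled-variance two-sample t-test and to one-way ANOVA (F = t^2).
#' Significance uses the expected-false-positive cutoff alpha = 1/m with m =
#' number of miRNAs tested. A miRNA with zero residual variance gets p = 0
#' when the group means differ and p = 1 when they are equal, with a warning.
#'
#' @param x `ncounter_norm` object (typically stage `quantile_normalized`) or
#'   plain matrix, probes x samples.
#' @param metadata data frame with `sample_id`, `group`.
#' @param contrast character of length 2, `c(group_A, group_B)`; the slope
#'   and fold change are A relative to B.
#' @param scale analysis scale: `"log2p1"` (default) or `"linear"`.
#' @param alpha significance cutoff; default [expected_fp_cutoff()] of the
#'   number of rows tested.
#' @return `de_table` data frame, sorted by p-value (ties by probe id), with
#'   columns `probe_id`, `mean_A`, `mean_B` (analysis scale), `slope`,
#'   `p_value`, `fold_change`, `direction` (`up`/`down`/`flat`),
#'   `significant`; attributes `m`, `alpha`, `contrast`, `scale`.
#' @export
fit_linear_de <- function(x, metadata, contrast, scale = c("log2p1", "linear"),
                          alpha = NULL) {
  scale <- match.arg(scale)
  Y <- de_values(x, scale)
  idx <- contrast_groups(Y, metadata, contrast)
  A <- Y[, idx[[1]], drop = FALSE]
  B <- Y[, idx[[2]], drop = FALSE]
  nA <- ncol(A); nB <- ncol(B); df <- nA + nB - 2
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums((A - mA)^2); ssB <- rowSums((B - mB)^2)
  s2 <- (ssA + ssB) / df
  se <- sqrt(s2 * (1 / nA + 1 / nB))
  slope <- mA - mB
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- s2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(slope[degen] == 0, 1, 0)
    warning(sum(degen), " miRNA(s) with zero residual variance; ",
            "p set to 0 (means differ) or 1 (means equal)")
  }
  fc <- fold_change_from_log2(if (scale == "log2p1") slope else
    log2(pmax(mA, 0) + 1) - log2(pmax(mB, 0) + 1))
  m <- nrow(Y)
  if (is.null(alpha)) alpha <- expected_fp_cutoff(m)
  tab <- data.frame(probe_id = rownames(Y),
                    mean_A = mA, mean_B = mB, slope = slope,
                    t = tstat, p_value = p,
                    fold_change = fc,
                    direction = ifelse(fc > 1, "up",
                                       ifelse(fc < -1, "down", "flat")),
                    significant = p < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$p_value, tab$probe_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, m = m, alpha = alpha, contrast = contrast, scale = scale,
            class = c("de_table", "data.frame"))
}

# signed fold change from a log2 mean difference: ratio r = 2^d reported as
# r when r >= 1 and -1/r otherwise, so |fold change| >= 1 always
fold_change_from_log2 <- function(d) ifelse(d >= 0, 2^d, -2^(-d))

#' Signed per-miRNA fold changes
#'
#' The ratio r of group geometric-style means, `2^(mean log2 A - mean log2
#' B)`, reported as `r` when `r >= 1` and `-1/r` otherwise: a halving is -2,
#' not 0.5, matching the usual signed "fold-change OS vs Ob" table
#' convention.
#'
#' @inheritParams fit_linear_de
#' @return named numeric vector of signed fold changes, one per probe.
#' @export
fold_change <- function(x, metadata, contrast) {
  Y <- de_values(x, "log2p1")
  idx <- contrast_groups(Y, metadata, contrast)
  d <- rowMeans(Y[, idx[[1]], drop = FALSE]) - rowMeans(Y[, idx[[2]], drop = FALSE])
  fold_change_from_log2(d)
}

#' Partition significant miRNAs into an up/down signature
#'
#' @param table `de_table` from [fit_linear_de()].
#' @return `de_signature` list: `up` and `down` (significant rows, sorted by
#'   absolute fold change descending), `n_up`, `n_down`, `n_total`.
#' @export
build_signature <- function(table) {
  stopifnot(inherits(table, "de_table"))
  sig <- table[table$significant, , drop = FALSE]
  up <- sig[sig$direction == "up", , drop = FALSE]
  down <- sig[sig$direction == "down", , drop = FALSE]
  up <- up[order(-abs(up$fold_change)), , drop = FALSE]
  down <- down[order(-abs(down$fold_change)), , drop = FALSE]
  structure(list(up = up, down = down,
                 n_up = nrow(up), n_down = nrow(down),
                 n_total = nrow(up) + nrow(down)),
            class = "de_signature")
}

#' @export
print.de_signature <- function(x, ...) {
  cat("miRNA signature: ", x$n_total, " significant (",
      x$n_up, " up, ", x$n_down, " down)\n", sep = "")
  invisible(x)
}

#' @export
print.de_table <- function(x, n = 10, ...) {
  cat("Differential-expression table: ", attr(x, "m"), " miRNAs tested, ",
      "contrast ", attr(x, "contrast")[1], " vs ", attr(x, "contrast")[2],
      ", alpha = 1/m = ", format(round(attr(x, "alpha"), 4), nsmall = 4),
      "\n", sum(x$significant), " significant; top rows:\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}
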
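#' Comparative-Ct (delta-delta-Ct) relative quantification
#'
#' Replicate Ct values are averaged (arithmetic mean) per sample and assay;
#' undetermined wells (`NA` Ct) are excluded with a message giving the
#' count, and a replicate SD above 0.5 cycles triggers a warning. Then, per
#' sample, `dct = mean target Ct - mean reference Ct`; `ddct = dct - mean
#' dct of the calibrator group`; `rq = 2^(-ddct)`. The calibrator group's
#' mean ddct is 0 by construction, anchoring its (geometric-style) mean RQ
#' at 1.
#'
#' @param ct Ct replicate table: `sample_id`, `group`, `target`,
#'   `is_reference`, `replicate`, `ct` (see [read_ct_table()]).
#' @param target target assay name.
#' @param reference reference (normalizer) assay name, e.g. U6 snRNA.
#' @param calibrator_group group label used as calibrator.
#' @return `rel_expression` object: `samples` (per-sample `sample_id`,
#'   `group`, `target_ct`, `reference_ct`, `dct`, `ddct`, `rq`), `groups`
#'   (per-group mean/SD of RQ and ddct), plus the assay names and
#'   calibrator.
#' @export
ddct <- function(ct, target, reference, calibrator_group) {
  stopifnot(is.data.frame(ct))
  need <- c("sample_id", "group", "target", "is_reference", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns ", paste(need, collapse = ", "))
  n_und <- sum(is.na(ct$ct))
  if (n_und > 0) {
    message(n_und, " undetermined Ct well(s) excluded")
    ct <- ct[!is.na(ct$ct), , drop = FALSE]
  }
  tgt <- ct[ct$target == target & !ct$is_reference, , drop = FALSE]
  ref <- ct[ct$target == reference & ct$is_reference, , drop = FALSE]
  if (nrow(tgt) == 0) stop("no wells for target '", target, "'")

  agg <- function(d, what) {
    sds <- tapply(d$ct, d$sample_id, stats::sd)
    noisy <- names(sds)[!is.na(sds) & sds > 0.5]
    if (length(noisy) > 0)
      warning(what, " replicate SD > 0.5 cycles for sample(s): ",
              paste(noisy, collapse = ", "))
    tapply(d$ct, d$sample_id, mean)
  }
  tmean <- agg(tgt, target)
  rmean <- agg(ref, reference)
  samples <- unique(ct[, c("sample_id", "group")])
  samples <- samples[samples$sample_id %in% names(tmean), , drop = FALSE]
  no_ref <- setdiff(samples$sample_id, names(rmean))
  if (length(no_ref) > 0)
    stop("missing reference-gene Ct for sample(s): ",
         paste(no_ref, collapse = ", "))
  if (!any(samples$group == calibrator_group))
    stop("calibrator group '", calibrator_group, "' has no samples")

  dct <- tmean[samples$sample_id] - rmean[samples$sample_id]
  cal_dct <- mean(dct[samples$group == calibrator_group])
  ddct <- dct - cal_dct
  rq <- 2^(-ddct)
  per_sample <- data.frame(sample_id = samples$sample_id,
                           group = samples$group,
                           target_ct = unname(tmean[samples$sample_id]),
                           reference_ct = unname(rmean[samples$sample_id]),
                           dct = unname(dct), ddct = unname(ddct),
                           rq = unname(rq),
                           row.names = NULL, stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(per_sample, per_sample$group), function(g)
    data.frame(group = g$group[1], n = nrow(g),
               mean_rq = mean(g$rq), sd_rq = stats::sd(g$rq),
               mean_ddct = mean(g$ddct), sd_ddct = stats::sd(g$ddct),
               stringsAsFactors = FALSE)))
  rownames(groups) <- NULL
  structure(list(samples = per_sample, groups = groups, target = target,
                 reference = reference, calibrator = calibrator_group),
            class = "rel_expression")
}

#' @export
print.rel_expression <- function(x, ...) {
  cat("Relative expression (2^-ddCt) of ", x$target, " vs ", x$reference,
      ", calibrator '", x$calibrator, "':\n", sep = "")
  print(x$groups, digits = 4)
  invisible(x)
}

#' One-way ANOVA on delta-delta-Ct values
#'
#' Fixed-effects one-way ANOVA comparing groups on the per-sample ddCt scale
#' (a log2-scale quantity; RQ itself is log-normal, so testing is done on
#' ddCt). With two groups, F equals the square of the pooled-variance
#' two-sample t statistic.
#'
#' @param rel `rel_expression` object from [ddct()].
#' @param groups optional subset of group labels to compare; default all.
#' @return list with `F`, `df` (numerator, denominator), `p_value`.
#' @export
anova_compare <- function(rel, groups = NULL) {
  stopifnot(inherits(rel, "rel_expression"))
  d <- rel$samples
  if (!is.null(groups)) d <- d[d$group %in% groups, , drop = FALSE]
  n <- table(d$group)
  if (length(n) < 2) stop("need at least 2 groups to compare")
  if (any(n < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(n)[n < 2], collapse = ", "))
  if (stats::var(d$ddct) == 0)
    return(list(F = 0, df = c(length(n) - 1, nrow(d) - length(n)), p_value = 1))
  ft <- stats::oneway.test(ddct ~ group, data = d, var.equal = TRUE)
  list(F = unname(ft$statistic),
       df = unname(ft$parameter),
       p_value = unname(ft$p.value))
}
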
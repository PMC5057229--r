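#' Fit the full nCounter miRNA differential-expression analysis
#'
#' Runs the complete chain on a raw count matrix: per-lane boxplot QC
#' (advisory flags only), positive-control lane scaling, negative-control
#' background thresholding (mean + k*SD per sample), prevalence filtering
#' (drop a miRNA when more than `frac` of samples fall below background),
#' quantile normalization, and a per-miRNA two-group linear-model test with
#' the expected-false-positive cutoff alpha = 1/m, yielding signed fold
#' changes and an up/down signature.
#'
#' @param counts [ncounter_counts] object, or a path to a count CSV.
#' @param metadata data frame with `sample_id`, `group`, or a path to a
#'   metadata TSV.
#' @param contrast character of length 2, `c(group_A, group_B)`; effects are
#'   reported for A relative to B (e.g. `c("OS", "Ob")`, tumor vs
#'   osteoblast).
#' @param k background SD multiplier (threshold = mean + k*SD).
#' @param frac prevalence-filter cutoff (strict "more than" rule).
#' @param background `"per_sample"` (default) or `"pooled"` negative-control
#'   background.
#' @param scale analysis scale for testing: `"log2p1"` or `"linear"`.
#' @param alpha significance cutoff; defaults to 1/m with m = miRNAs tested.
#' @param qc_f QC flagging multiplier (see [qc_boxplot_stats()]).
#' @return an object of class `ncounter_de`: a list with `qc`,
#'   `scale_factors`, `background`, `dropped` (filtered probe ids), `norm`
#'   (quantile-normalized matrix), `table` (`de_table`), `signature`, `m`,
#'   `alpha`, `contrast`, `scale`, `metadata`, `call`.
#' @examples
#' sim <- simulate_ncounter(sim_config(n_endogenous = 80,
#'                                     group_sizes = c(OS = 8, Ob = 3),
#'                                     seed = 42))
#' fit <- ncounter_de(sim$counts, sim$metadata, contrast = c("OS", "Ob"))
#' fit
#' coef(fit)[1:3]
#' @seealso [fit_linear_de()], [supervised_cluster()], [run_pipeline()]
#' @export
ncounter_de <- function(counts, metadata, contrast, k = 2, frac = 0.90,
                        background = c("per_sample", "pooled"),
                        scale = c("log2p1", "linear"),
                        alpha = NULL, qc_f = 3) {
  background <- match.arg(background)
  scale <- match.arg(scale)
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  metadata <- validate_metadata(counts, metadata)
  if (!all(contrast %in% metadata$group))
    stop("contrast group(s) absent from metadata: ",
         paste(setdiff(contrast, metadata$group), collapse = ", "))

  qc <- qc_boxplot_stats(counts, f = qc_f)
  pos <- positive_control_normalize(counts)
  bg <- compute_background(pos, k = k, pooled = background == "pooled")
  filt <- filter_low_expressed(pos, bg, frac = frac)
  qn <- quantile_normalize(filt)
  de <- fit_linear_de(qn, metadata, contrast, scale = scale, alpha = alpha)
  sig <- build_signature(de)

  structure(list(qc = qc,
                 scale_factors = pos$scale_factors,
                 background = bg,
                 dropped = attr(filt, "dropped"),
                 norm = qn,
                 table = de,
                 signature = sig,
                 m = attr(de, "m"),
                 alpha = attr(de, "alpha"),
                 contrast = contrast,
                 scale = scale,
                 k = k, frac = frac, background_mode = background,
                 metadata = metadata,
                 call = match.call()),
            class = "ncounter_de")
}

#' @export
print.ncounter_de <- function(x, ...) {
  cat("nCounter miRNA differential-expression fit\n")
  cat("  contrast: ", x$contrast[1], " vs ", x$contrast[2], " (",
      sum(x$metadata$group == x$contrast[1]), " vs ",
      sum(x$metadata$group == x$contrast[2]), " samples)\n", sep = "")
  cat("  probes: ", length(x$dropped) + x$m, " endogenous, ",
      length(x$dropped), " filtered below background, ", x$m, " tested\n",
      sep = "")
  cat("  alpha = 1/", x$m, " = ", format(round(x$alpha, 4), nsmall = 4),
      "\n", sep = "")
  cat("  significant: ", x$signature$n_total, " (", x$signature$n_up,
      " up, ", x$signature$n_down, " down)\n", sep = "")
  if (any(x$qc$flagged))
    cat("  QC: ", sum(x$qc$flagged), " lane(s) flagged (advisory)\n", sep = "")
  invisible(x)
}

#' @export
summary.ncounter_de <- function(object, n = 10, ...) {
  print(object)
  cat("\nTop miRNAs by p-value:\n")
  print.data.frame(utils::head(as.data.frame(object$table), n), digits = 4)
  invisible(object)
}

#' @export
coef.ncounter_de <- function(object, ...) {
  stats::setNames(object$table$slope, object$table$probe_id)
}

#' @export
residuals.ncounter_de <- function(object, ...) {
  Y <- de_values(object$norm, object$scale)
  groups <- object$metadata$group[match(colnames(Y), object$metadata$sample_id)]
  keep <- groups %in% object$contrast
  Y <- Y[, keep, drop = FALSE]
  g <- groups[keep]
  for (lev in unique(g)) {
    j <- g == lev
    Y[, j] <- Y[, j, drop = FALSE] - rowMeans(Y[, j, drop = FALSE])
  }
  Y
}

#' @export
plot.ncounter_de <- function(x, ...) {
  if (x$signature$n_total < 2) {
    message("fewer than 2 significant miRNAs; nothing to cluster")
    return(invisible(x))
  }
  cl <- supervised_cluster(x$norm, x$signature, x$metadata,
                           scale = x$scale, group_order = x$contrast)
  plot(cl, ...)
  invisible(cl)
}

# deterministic FNV-1a hash of a character vector, for the run manifest
config_hash <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- bitwXor(h, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Run the pipeline end-to-end and write a run directory
#'
#' Thin orchestrator over [ncounter_de()] and [supervised_cluster()] that
#' writes every stage's artifact (QC table, scale factors, background
#' thresholds, dropped-probe list, normalized matrix, DE table, signature,
#' cluster leaf order and merge table) plus a machine-readable manifest
#' recording m, alpha, per-stage probe counts and the configuration with its
#' hash. Re-running with the same inputs and configuration reproduces the
#' directory byte-for-byte.
#'
#' @inheritParams ncounter_de
#' @param out_dir output directory, created if absent.
#' @param metric,linkage clustering options (see [supervised_cluster()]).
#' @return the `ncounter_de` fit, invisibly, with attribute `out_dir`.
#' @export
run_pipeline <- function(counts, metadata, contrast, out_dir,
                         k = 2, frac = 0.90,
                         background = c("per_sample", "pooled"),
                         scale = c("log2p1", "linear"),
                         metric = c("pearson", "euclidean"),
                         linkage = c("average", "complete"),
                         alpha = NULL) {
  background <- match.arg(background)
  scale <- match.arg(scale)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  fit <- ncounter_de(counts, metadata, contrast, k = k, frac = frac,
                     background = background, scale = scale, alpha = alpha)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(d, file.path(out_dir, f), sep = "\t",
                                          row.names = FALSE, quote = FALSE)
  wt(fit$qc, "qc.tsv")
  wt(data.frame(sample_id = names(fit$scale_factors),
                scale_factor = unname(fit$scale_factors)), "scale_factors.tsv")
  wt(data.frame(sample_id = names(fit$background$threshold),
                mean = unname(fit$background$mean),
                sd = unname(fit$background$sd),
                threshold = unname(fit$background$threshold)), "background.tsv")
  writeLines(fit$dropped, file.path(out_dir, "dropped_probes.txt"))
  wt(data.frame(probe_id = rownames(fit$norm$values), fit$norm$values,
                check.names = FALSE), "normalized_matrix.tsv")
  write_de_table(fit$table, file.path(out_dir, "de_table.tsv"))
  wt(rbind(fit$signature$up, fit$signature$down), "signature.tsv")
  if (fit$signature$n_total >= 2) {
    cl <- supervised_cluster(fit$norm, fit$signature, fit$metadata,
                             metric = metric, linkage = linkage,
                             scale = scale, group_order = contrast)
    writeLines(cl$leaf_order, file.path(out_dir, "cluster_leaf_order.txt"))
    wt(data.frame(node1 = cl$hclust$merge[, 1], node2 = cl$hclust$merge[, 2],
                  height = cl$hclust$height), "cluster_merges.tsv")
  }
  cfg <- c(sprintf("contrast=%s,%s", contrast[1], contrast[2]),
           sprintf("k=%g", k), sprintf("frac=%g", frac),
           sprintf("background=%s", background), sprintf("scale=%s", scale),
           sprintf("metric=%s", metric), sprintf("linkage=%s", linkage))
  manifest <- c(sprintf("package_version=%s",
                        as.character(utils::packageVersion("ncounterDE"))),
                cfg,
                sprintf("n_samples=%d", nrow(fit$metadata)),
                sprintf("n_endogenous=%d", fit$m + length(fit$dropped)),
                sprintf("n_dropped=%d", length(fit$dropped)),
                sprintf("m=%d", fit$m),
                sprintf("alpha=%.10g", fit$alpha),
                sprintf("n_significant=%d", fit$signature$n_total),
                sprintf("n_up=%d", fit$signature$n_up),
                sprintf("n_down=%d", fit$signature$n_down),
                sprintf("config_hash=%s", config_hash(cfg)))
  writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  attr(fit, "out_dir") <- out_dir
  invisible(fit)
}
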
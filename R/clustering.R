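#' Supervised hierarchical clustering of a miRNA signature
#'
#' "Supervised" here means only the miRNAs (rows) are clustered; the samples
#' (columns) keep their known class labels and are ordered by group, then by
#' sample id, giving the familiar two-block signature heatmap. Rows are
#' restricted to the signature miRNAs and z-scored per row on the analysis
#' scale; the default row distance is 1 - Pearson correlation with average
#' linkage.
#'
#' Correlation with a constant row is undefined; its distance to every other
#' row is set to 1 (message emitted). Merge heights are checked for
#' monotonicity and a violation is reported via a message, never silently
#' reordered.
#'
#' @param x `ncounter_norm` object or plain matrix, probes x samples.
#' @param signature `de_signature` from [build_signature()], or a character
#'   vector of probe ids (>= 2).
#' @param metadata data frame with `sample_id`, `group`.
#' @param metric row distance: `"pearson"` (1 - correlation) or
#'   `"euclidean"` (on z-scored rows).
#' @param linkage `"average"` or `"complete"`.
#' @param scale analysis scale before z-scoring.
#' @param group_order optional character vector giving the display order of
#'   groups (e.g. the contrast); defaults to sorted unique labels.
#' @return `supervised_cluster` object: `hclust` (row dendrogram),
#'   `leaf_order` (probe ids in dendrogram order), `col_order` (sample ids,
#'   group-blocked), `z` (z-scored display matrix), `groups` (named by
#'   sample id).
#' @export
supervised_cluster <- function(x, signature, metadata,
                               metric = c("pearson", "euclidean"),
                               linkage = c("average", "complete"),
                               scale = c("log2p1", "linear"),
                               group_order = NULL) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  scale <- match.arg(scale)
  probes <- if (inherits(signature, "de_signature"))
    c(signature$up$probe_id, signature$down$probe_id) else as.character(signature)
  Y <- de_values(x, scale)
  missing <- setdiff(probes, rownames(Y))
  if (length(missing) > 0)
    stop("signature miRNA(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  if (length(probes) < 2) stop("need at least 2 signature miRNAs to cluster")
  Y <- Y[probes, , drop = FALSE]

  sds <- apply(Y, 1, stats::sd)
  const <- sds == 0
  z <- (Y - rowMeans(Y)) / ifelse(const, 1, sds)
  z[const, ] <- 0
  if (any(const))
    message(sum(const), " constant row(s); correlation undefined, distance set to 1")

  if (metric == "pearson") {
    C <- suppressWarnings(stats::cor(t(Y)))
    C[!is.finite(C)] <- 0          # constant rows: d = 1 - 0 = 1
    D <- stats::as.dist(1 - C)
  } else {
    D <- stats::dist(z)
  }
  hc <- stats::hclust(D, method = linkage)
  if (any(diff(hc$height) < -1e-8))
    message("non-monotone merge heights detected (inversion in ", linkage,
            " linkage dendrogram)")

  metadata <- metadata[match(colnames(Y), metadata$sample_id), , drop = FALSE]
  if (is.null(group_order)) group_order <- sort(unique(metadata$group))
  ord <- order(match(metadata$group, group_order), metadata$sample_id)
  structure(list(hclust = hc,
                 leaf_order = probes[hc$order],
                 col_order = colnames(Y)[ord],
                 z = z[, ord, drop = FALSE],
                 groups = stats::setNames(metadata$group, metadata$sample_id)[ord]),
            class = "supervised_cluster")
}

#' @export
print.supervised_cluster <- function(x, ...) {
  cat("Supervised clustering: ", length(x$leaf_order), " miRNAs x ",
      length(x$col_order), " samples (groups: ",
      paste(unique(x$groups), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Heatmap of a supervised clustering result
#'
#' Rows in dendrogram leaf order, columns in group-blocked order, colors on
#' the row z-score scale.
#'
#' @param x `supervised_cluster` object.
#' @param col color ramp.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.supervised_cluster <- function(x, col = grDevices::hcl.colors(51, "Blue-Red 2"),
                                    ...) {
  m <- x$z[x$leaf_order, , drop = FALSE]
  lim <- max(abs(m), 1e-9)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m), zlim = c(-lim, lim), col = col,
                  xlab = "", ylab = "", axes = FALSE, ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m),
                 las = 2, cex.axis = 0.5, tick = FALSE)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m),
                 las = 2, cex.axis = 0.5, tick = FALSE)
  breaks <- which(diff(as.integer(factor(x$groups,
                                         levels = unique(x$groups)))) != 0)
  graphics::abline(v = breaks + 0.5, lwd = 2)
  invisible(x)
}
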
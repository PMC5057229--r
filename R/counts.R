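#' Raw nCounter-style count matrix
#'
#' Container for a probes x samples matrix of non-negative integer counts with
#' a per-probe class label. The three canonical nCounter classes are
#' `"Positive"` (spike-in controls at known concentrations, used for lane
#' scaling), `"Negative"` (no-target probes, used for background estimation)
#' and `"Endogenous"` (the miRNA probes under study). Other class labels
#' (e.g. `"Housekeeping"`, `"SpikeIn"`) are accepted and carried through
#' untouched; they are excluded from the analysis set during preprocessing,
#' with a warning.
#'
#' @param counts numeric matrix (probes x samples) of non-negative whole
#'   numbers, with unique non-empty row and column names.
#' @param probe_class character vector, one class label per probe row.
#' @return an object of class `ncounter_counts`: a list with elements
#'   `counts` (integer-valued matrix) and `probe_class` (character, named by
#'   probe id).
#' @examples
#' m <- matrix(c(100L, 5L, 40L, 120L, 7L, 55L), nrow = 3,
#'             dimnames = list(c("POS_A", "NEG_01", "miR-1"), c("s1", "s2")))
#' x <- ncounter_counts(m, c("Positive", "Negative", "Endogenous"))
#' x
#' @export
ncounter_counts <- function(counts, probe_class) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have probe (row) and sample (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("counts must be non-negative integers; offending cell: probe '",
         rownames(counts)[bad[1, 1]], "', sample '", colnames(counts)[bad[1, 2]],
         "' (value ", counts[bad[1, , drop = FALSE]], ")")
  probe_class <- as.character(probe_class)
  if (length(probe_class) != nrow(counts))
    stop("`probe_class` must have one entry per probe row")
  if (anyNA(probe_class) || any(!nzchar(probe_class)))
    stop("probe classes must be non-empty strings")
  names(probe_class) <- rownames(counts)
  if (!any(probe_class == "Positive"))
    stop("no Positive control probes present")
  if (!any(probe_class == "Negative"))
    stop("no Negative control probes present")
  structure(list(counts = counts, probe_class = probe_class),
            class = "ncounter_counts")
}

#' @export
print.ncounter_counts <- function(x, ...) {
  tab <- table(x$probe_class)
  cat("nCounter count matrix: ", nrow(x$counts), " probes x ",
      ncol(x$counts), " samples\n", sep = "")
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ncounter_counts <- function(x) dim(x$counts)

#' Check sample metadata against a count matrix
#'
#' Every sample column in the counts must have exactly one metadata row.
#'
#' @param x `ncounter_counts` object.
#' @param metadata data frame with columns `sample_id` and `group`
#'   (optionally `batch`).
#' @return `metadata`, invisibly, with rows ordered as the samples in `x`.
#' @export
validate_metadata <- function(x, metadata) {
  stopifnot(inherits(x, "ncounter_counts"), is.data.frame(metadata))
  if (!all(c("sample_id", "group") %in% names(metadata)))
    stop("metadata must have columns 'sample_id' and 'group'")
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]), collapse = ", "))
  missing <- setdiff(colnames(x$counts), metadata$sample_id)
  if (length(missing) > 0)
    stop("metadata missing ", length(missing), " sample(s) present in counts: ",
         paste(missing, collapse = ", "))
  invisible(metadata[match(colnames(x$counts), metadata$sample_id), , drop = FALSE])
}

# Expression matrix at a named preprocessing stage. Stages, in pipeline
# order: pos_scaled (all probes, positive-control scaled), filtered
# (endogenous survivors only), quantile_normalized.
new_ncounter_norm <- function(values, probe_class, stage, scale_factors) {
  stopifnot(is.matrix(values),
            stage %in% c("pos_scaled", "filtered", "quantile_normalized"))
  structure(list(values = values,
                 probe_class = probe_class[rownames(values)],
                 stage = stage,
                 scale_factors = scale_factors),
            class = "ncounter_norm")
}

#' @export
print.ncounter_norm <- function(x, ...) {
  cat("nCounter expression matrix [stage: ", x$stage, "]: ",
      nrow(x$values), " probes x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.ncounter_norm <- function(x) dim(x$values)

# run `code` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
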
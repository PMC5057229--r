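#' Read a count matrix from CSV
#'
#' The dialect is one probe per row with header
#' `probe_id,probe_class,<sample_id_1>,...`; UTF-8, comma-separated, ids
#' restricted to `[A-Za-z0-9._+-]` so no quoting is needed.
#'
#' @param path path to a CSV file in the dialect above.
#' @return validated [ncounter_counts] object; probe row order as in the file.
#' @seealso [write_counts()], [read_rcc()]
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || names(df)[1] != "probe_id" || names(df)[2] != "probe_class")
    stop("expected header 'probe_id,probe_class,<sample ids...>' in ", path)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(counts)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -(1:2), drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric count in ", path, if (nrow(bad) > 0)
      paste0(": probe '", df$probe_id[bad[1, 1]], "', sample '",
             names(df)[-(1:2)][bad[1, 2]], "'"))
  }
  rownames(counts) <- df$probe_id
  ncounter_counts(counts, df$probe_class)
}

#' Write a count matrix to CSV
#'
#' @param x [ncounter_counts] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "ncounter_counts"))
  df <- data.frame(probe_id = rownames(x$counts),
                   probe_class = unname(x$probe_class),
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read nCounter lane files (minimal RCC support)
#'
#' Reads only the `Code_Summary` section — `CodeClass,Name[,Accession],Count`
#' rows between `<Code_Summary>` and `</Code_Summary>` tags — of one
#' sectioned-CSV lane file per sample, and merges the lanes into a single
#' count matrix. All other sections are ignored. Sample ids default to the
#' file names without extension.
#'
#' @param paths character vector of lane file paths, one per sample.
#' @param sample_ids sample ids, same length as `paths`.
#' @return [ncounter_counts] object; probe order as in the first lane file.
#' @export
read_rcc <- function(paths, sample_ids = sub("\\.[^.]*$", "", basename(paths))) {
  stopifnot(length(paths) >= 1, length(sample_ids) == length(paths))
  lanes <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    lines <- readLines(p, warn = FALSE)
    open <- grep("^<Code_Summary>$", lines)
    close <- grep("^</Code_Summary>$", lines)
    if (length(open) != 1 || length(close) != 1 || close <= open)
      stop("no Code_Summary section in ", p)
    body <- lines[(open + 1):(close - 1)]
    body <- body[nzchar(trimws(body))]
    fields <- strsplit(body, ",", fixed = TRUE)
    header <- fields[[1]]
    if (header[1] != "CodeClass" || header[2] != "Name" ||
        header[length(header)] != "Count")
      stop("unexpected Code_Summary header in ", p, ": ",
           paste(header, collapse = ","))
    rows <- fields[-1]
    cls <- vapply(rows, `[`, "", 1)
    name <- vapply(rows, `[`, "", 2)
    cnt <- suppressWarnings(as.numeric(vapply(rows, function(f) f[length(f)], "")))
    if (anyNA(cnt))
      stop("non-numeric Count in ", p, " for probe '", name[which(is.na(cnt))[1]], "'")
    list(class = stats::setNames(cls, name), count = stats::setNames(cnt, name))
  })
  probes <- names(lanes[[1]]$count)
  for (i in seq_along(lanes)[-1]) {
    if (!setequal(names(lanes[[i]]$count), probes))
      stop("lane ", paths[i], " has a different probe set than ", paths[1])
  }
  counts <- vapply(lanes, function(l) l$count[probes], numeric(length(probes)))
  dimnames(counts) <- list(probes, sample_ids)
  ncounter_counts(counts, lanes[[1]]$class[probes])
}

#' Read a sample metadata table
#'
#' Tab-separated, columns `sample_id`, `group` and optionally `batch`.
#'
#' @param path path to the TSV file.
#' @return data frame with character columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata must have columns 'sample_id' and 'group': ", path)
  df
}

#' Write a differential-expression table to TSV
#'
#' Rows are sorted by p-value ascending, ties broken by probe id.
#'
#' @param table a `de_table` data frame, as returned by [fit_linear_de()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) > 0)
    table <- table[order(table$p_value, table$probe_id), , drop = FALSE]
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a qPCR Ct replicate table
#'
#' Tab-separated with columns `sample_id`, `group`, `target`, `is_reference`
#' (logical), `replicate`, `ct`. A `ct` of `"Undetermined"` (any case) is
#' read as `NA` and later excluded from replicate averaging, with a message
#' giving the count.
#'
#' @param path path to the TSV file.
#' @return data frame; `ct` numeric with `NA` for undetermined wells.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "target", "is_reference", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns ", paste(need, collapse = ", "), ": ", path)
  if (is.character(df$ct)) {
    und <- grepl("^undetermined$", trimws(df$ct), ignore.case = TRUE)
    df$ct[und] <- NA
    df$ct <- as.numeric(df$ct)
  }
  df$is_reference <- as.logical(df$is_reference)
  df
}

#' Write a qPCR Ct replicate table to TSV
#'
#' @param ct data frame as produced by [simulate_qpcr()] or [read_ct_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
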
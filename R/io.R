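#' Write a multi-channel measurement to the curve CSV dialect
#'
#' The repository's curve format: comment header lines
#' `# sampling_rate_hz=<rate>` and `# channels=<c1>,<c2>,...`, then a CSV
#' table with column `time_s` followed by one column per channel. UTF-8,
#' LF line endings, '.' decimal separator, full double precision (17
#' significant digits) so write/read round-trips are lossless at text
#' precision.
#'
#' @param curves A named list of [response_curve()] objects sharing one time
#'   base, or a single `response_curve`.
#' @param path Output file path.
#' @param extra_header Optional named character vector of additional
#'   `# key=value` header lines (e.g. sample id, group).
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path, extra_header = NULL) {
  if (inherits(curves, "response_curve")) {
    curves <- stats::setNames(list(curves), curves$channel_label)
  }
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "response_curve")))
  t0 <- curves[[1L]]$times
  for (cu in curves) {
    if (length(cu$times) != length(t0) || max(abs(cu$times - t0)) > 1e-9)
      stop("all channels must share the same time base")
  }
  labels <- vapply(curves, `[[`, character(1), "channel_label")
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(sprintf("# sampling_rate_hz=%.17g", curves[[1L]]$sampling_rate),
           sprintf("# channels=%s", paste(labels, collapse = ",")))
  if (!is.null(extra_header))
    hdr <- c(hdr, sprintf("# %s=%s", names(extra_header), extra_header))
  writeLines(hdr, con, sep = "\n")
  df <- data.frame(time_s = t0)
  for (i in seq_along(curves)) df[[labels[i]]] <- curves[[i]]$values
  writeLines(paste(colnames(df), collapse = ","), con, sep = "\n")
  body <- do.call(paste, c(lapply(df, function(col) sprintf("%.17g", col)),
                           sep = ","))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Read a multi-channel measurement from the curve CSV dialect
#'
#' @param path File written by [write_curves_csv()].
#' @return A named list of [response_curve()] objects (one per channel) with
#'   attribute `header`: the parsed `# key=value` pairs.
#' @export
read_curves_csv <- function(path) {
  lines <- readLines(path, n = 64L)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  header <- stats::setNames(as.list(vals), keys)
  if (is.null(header$sampling_rate_hz))
    stop("malformed curve file (missing '# sampling_rate_hz=' header): ", path)
  rate <- as.numeric(header$sampling_rate_hz)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% colnames(df))
    stop("malformed curve file (no time_s column): ", path)
  if (anyNA(df)) {
    bad <- which(!stats::complete.cases(df))[1L]
    stop(sprintf("NaN/NA in curve file %s at data row %d", path, bad))
  }
  channels <- setdiff(colnames(df), "time_s")
  out <- lapply(channels, function(ch)
    response_curve(df$time_s, df[[ch]], rate, ch))
  names(out) <- channels
  attr(out, "header") <- header
  out
}

#' Write a feature matrix to CSV
#'
#' Header row `sample_id, group, replicate, <channel>_S1 ... <channel>_S5`,
#' channel-major feature order.
#'
#' @param fm A `feature_matrix` (see [assemble_feature_matrix()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- cbind(fm$meta, as.data.frame(fm$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path File written by [write_feature_matrix_csv()].
#' @return A `feature_matrix`.
#' @export
read_feature_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- intersect(c("sample_id", "group", "replicate"), colnames(df))
  vals <- as.matrix(df[, setdiff(colnames(df), meta_cols), drop = FALSE])
  structure(list(meta = df[, meta_cols, drop = FALSE], values = vals),
            class = "feature_matrix")
}
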
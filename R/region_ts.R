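#' Regional timeseries for one imaging session
#'
#' A light container for one session's parcellated BOLD data: a T x R matrix
#' of timepoints by regions, the sampling interval, and region identifiers.
#'
#' @param values numeric T x R matrix (rows are timepoints).
#' @param tr sampling interval in seconds.
#' @param region_ids character vector of R unique region labels; defaults to
#'   the matrix column names, or `"R1"..."RR"`.
#' @return An object of class `region_ts` with fields `values`, `tr`,
#'   `duration` (seconds, `T * tr`) and `region_ids`.
#' @examples
#' ts <- region_ts(matrix(rnorm(200), 50, 4), tr = 0.72)
#' dim(ts$values)
#' ts$duration
#' @export
region_ts <- function(values, tr, region_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (anyNA(values)) stop("timeseries contains missing values")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("`tr` must be a positive scalar")
  if (is.null(region_ids)) {
    region_ids <- colnames(values) %||% paste0("R", seq_len(ncol(values)))
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != ncol(values)) {
    stop("`region_ids` length must match the number of columns")
  }
  if (anyDuplicated(region_ids)) stop("`region_ids` must be unique")
  colnames(values) <- region_ids
  structure(
    list(values = values, tr = tr, duration = nrow(values) * tr,
         region_ids = region_ids),
    class = "region_ts"
  )
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> %d timepoints x %d regions, tr = %.4g s (%.4g s total)\n",
              nrow(x$values), ncol(x$values), x$tr, x$duration))
  invisible(x)
}

#' @export
dim.region_ts <- function(x) dim(x$values)

#' Write / read a session matrix as delimited text
#'
#' Sessions are stored as tab-separated matrices with a header of region ids;
#' the sampling interval travels in a `# tr=<seconds>` comment on line one.
#'
#' @param ts a [region_ts].
#' @param path file path.
#' @return `read_session_tsv` returns a [region_ts]; `write_session_tsv`
#'   returns `path` invisibly.
#' @export
write_session_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "region_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr=%.17g", ts$tr), con)
  utils::write.table(ts$values, con, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_tsv
#' @export
read_session_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  tr <- as.numeric(sub("^#\\s*tr=", "", first))
  if (!is.finite(tr)) stop("missing `# tr=` header in ", path)
  vals <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                            check.names = FALSE)
  region_ts(as.matrix(vals), tr = tr, region_ids = colnames(vals))
}
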
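#' Construct a multivariate time-series object
#'
#' Bundles a numeric time-by-variable matrix with variable names and an
#' optional trial structure. Rows are time bins, columns are variables;
#' binary spike rasters (0/1 per bin) are a special case. When the data
#' consist of repeated trials (as in task-locked electrophysiology), the
#' trial starts are recorded so that downstream embedding never builds
#' state vectors straddling a trial boundary.
#'
#' @param values Numeric matrix, time points in rows, variables in columns.
#'   Missing values are rejected, not imputed.
#' @param names Optional character vector of variable labels; defaults to
#'   existing column names or `V1, V2, ...`.
#' @param trial_bounds Optional integer vector of trial start rows
#'   (1-based, strictly increasing, first element 1). The file format read
#'   by [read_trial_bounds()] uses 0-based offsets; the reader converts.
#' @return An object of class `mvts`: the matrix plus `names` and
#'   `trial_bounds` attributes.
#' @seealso [embed_series()], [read_series()]
#' @examples
#' x <- multivariate_series(matrix(rbinom(40, 1, 0.3), ncol = 2),
#'                          names = c("n1", "n2"))
#' print(x)
#' @export
multivariate_series <- function(values, names = NULL, trial_bounds = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (nrow(values) < 2) stop("a series needs at least 2 time points")
  if (anyNA(values)) stop("missing values are not allowed (no imputation)")
  if (is.null(names)) {
    names <- colnames(values)
    if (is.null(names)) names <- paste0("V", seq_len(ncol(values)))
  }
  if (length(names) != ncol(values)) {
    stop("`names` must have one label per column")
  }
  colnames(values) <- names
  if (!is.null(trial_bounds)) {
    trial_bounds <- as.integer(trial_bounds)
    if (length(trial_bounds) == 0 || trial_bounds[1] != 1L) {
      stop("`trial_bounds` must start at 1 (first trial begins at row 1)")
    }
    if (is.unsorted(trial_bounds, strictly = TRUE)) {
      stop("`trial_bounds` must be strictly increasing")
    }
    if (max(trial_bounds) > nrow(values)) {
      stop("a trial start lies beyond the end of the series")
    }
  }
  structure(values, trial_bounds = trial_bounds, class = c("mvts", "matrix"))
}

#' @export
print.mvts <- function(x, ...) {
  tb <- attr(x, "trial_bounds")
  cat(sprintf("<mvts> %d time points x %d variables", nrow(x), ncol(x)))
  if (is.null(tb)) {
    cat(" (single trial)\n")
  } else {
    cat(sprintf(" (%d trials)\n", length(tb)))
  }
  cat("variables:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

# (start, end) rows of each trial, 1-based inclusive
.trial_spans <- function(series) {
  tb <- attr(series, "trial_bounds")
  n <- nrow(series)
  if (is.null(tb)) tb <- 1L
  data.frame(start = tb, end = c(tb[-1] - 1L, n))
}

#' Read a multivariate series from delimited text
#'
#' Reads a plain-text table of time points (rows) by variables (columns).
#' The delimiter (comma or tab) and the presence of a header row of
#' variable names are sniffed from the first line.
#'
#' @param file Path to a delimited text file.
#' @param trial_file Optional path to a trial-boundary file (one column of
#'   0-based trial start offsets, first entry 0); see [read_trial_bounds()].
#' @return An [multivariate_series()] object.
#' @export
read_series <- function(file, trial_file = NULL) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  tokens <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- anyNA(suppressWarnings(as.numeric(tokens)))
  df <- utils::read.table(file, sep = sep, header = header)
  tb <- if (!is.null(trial_file)) read_trial_bounds(trial_file) else NULL
  multivariate_series(as.matrix(df),
                      names = if (header) names(df) else NULL,
                      trial_bounds = tb)
}

#' Read trial boundaries from a one-column text file
#'
#' The file holds one trial start offset per line, 0-based (the first line
#' must be 0), matching the convention of row offsets into the raster file.
#' Offsets are converted to the package's 1-based row indices.
#'
#' @param file Path to the boundary file.
#' @return Integer vector of 1-based trial start rows.
#' @export
read_trial_bounds <- function(file) {
  v <- scan(file, what = integer(), quiet = TRUE)
  if (length(v) == 0) stop("empty trial-boundary file")
  if (v[1] != 0L) stop("trial-boundary files are 0-based: first entry must be 0")
  if (is.unsorted(v, strictly = TRUE)) {
    stop("trial start offsets must be strictly increasing")
  }
  as.integer(v) + 1L
}

#' Write a multivariate series (and optional trial bounds) to text
#'
#' @param series An [multivariate_series()] object.
#' @param file Output path for the tab-separated raster (header row of
#'   variable names included).
#' @param trial_file Optional output path for the 0-based trial-boundary
#'   file.
#' @return `file`, invisibly.
#' @export
write_series <- function(series, file, trial_file = NULL) {
  utils::write.table(as.data.frame(unclass(series)), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tb <- attr(series, "trial_bounds")
  if (!is.null(trial_file)) {
    if (is.null(tb)) tb <- 1L
    writeLines(as.character(tb - 1L), trial_file)
  }
  invisible(file)
}
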
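#' Time-delay embed a multivariate series around a target variable
#'
#' Builds the aligned sample sets consumed by every dynamical measure in
#' the package: for each driver variable k a matrix of state vectors
#' `X_k(t) = (x_k(t), x_k(t-1), ..., x_k(t-m+1))`, the target future
#' `Y(t) = y(t+1)`, and the target past `Y0(t) = (y(t), ..., y(t-m+1))`.
#' Internally rows are 1-based; a valid sample index t runs from the m-th
#' row of a trial to its second-to-last row, so a single trial of length T
#' yields `T - m` samples. With trial boundaries present, embedding is done
#' per trial and samples never straddle a boundary.
#'
#' @param series An [multivariate_series()] object.
#' @param m Embedding order (number of past bins per state vector),
#'   a positive integer. Binned spike data at coarse resolution is
#'   typically well served by `m = 1` (one past bin).
#' @param target Target variable, as a column index or name. The target is
#'   excluded from the driver set.
#' @return An object of class `embedded_dataset` with elements `m`,
#'   `target` (column index), `driver_index`, `drivers` (named list of
#'   n-by-m matrices), `target_future`, `target_past`, `n_samples`, and
#'   the originating `series` (kept for surrogate regeneration).
#' @examples
#' x <- multivariate_series(matrix(rbinom(60, 1, 0.5), ncol = 3))
#' d <- embed_series(x, m = 1, target = 3)
#' d$n_samples  # 20 - 1 = 19
#' @export
embed_series <- function(series, m, target) {
  if (!inherits(series, "mvts")) series <- multivariate_series(series)
  m <- as.integer(m)
  if (length(m) != 1 || is.na(m) || m < 1) {
    stop("`m` must be a positive integer")
  }
  if (is.character(target)) {
    ti <- match(target, colnames(series))
    if (is.na(ti)) stop(sprintf("target '%s' is not a variable name", target))
    target <- ti
  }
  target <- as.integer(target)
  if (target < 1 || target > ncol(series)) {
    stop(sprintf("target index %d out of range (1..%d)", target, ncol(series)))
  }
  spans <- .trial_spans(series)
  len <- spans$end - spans$start + 1L
  short <- which(len < m + 1L)
  if (length(short) > 0) {
    stop(sprintf(
      "trial %d (rows %d..%d, length %d) is too short for m = %d (needs > m + 1 rows)",
      short[1], spans$start[short[1]], spans$end[short[1]], len[short[1]], m))
  }
  drv_idx <- setdiff(seq_len(ncol(series)), target)
  y <- series[, target]
  emb_y <- .embed_column(y, m, spans)
  drivers <- lapply(drv_idx, function(k) .embed_column(series[, k], m, spans)$state)
  names(drivers) <- colnames(series)[drv_idx]
  structure(list(
    m = m,
    target = target,
    target_name = colnames(series)[target],
    driver_index = drv_idx,
    driver_names = colnames(series)[drv_idx],
    drivers = drivers,
    target_future = emb_y$future,
    target_past = emb_y$state,
    n_samples = length(emb_y$future),
    series = series,
    weights = NULL
  ), class = "embedded_dataset")
}

# Embed one raw column: state vectors (lag 0..m-1) and the one-step future,
# per trial. Returns list(state = n x m matrix, future = length-n vector).
.embed_column <- function(x, m, spans) {
  idx <- unlist(lapply(seq_len(nrow(spans)), function(i) {
    seq.int(spans$start[i] + m - 1L, spans$end[i] - 1L)
  }))
  state <- vapply(0:(m - 1L), function(j) x[idx - j], numeric(length(idx)))
  if (length(idx) == 1L) state <- matrix(state, nrow = 1L)
  list(state = as.matrix(state), future = x[idx + 1L])
}

#' @export
print.embedded_dataset <- function(x, ...) {
  cat(sprintf("<embedded_dataset> target '%s', m = %d, %d drivers, %d samples%s\n",
              x$target_name, x$m, length(x$drivers), x$n_samples,
              if (is.null(x$weights)) "" else " (weighted distribution)"))
  invisible(x)
}

# resolve user-supplied driver references (original column indices or
# names) to positions within dataset$drivers
.resolve_drivers <- function(dataset, drivers) {
  if (is.null(drivers)) return(seq_along(dataset$drivers))
  if (is.character(drivers)) {
    pos <- match(drivers, dataset$driver_names)
    bad <- drivers[is.na(pos)]
  } else {
    pos <- match(as.integer(drivers), dataset$driver_index)
    bad <- drivers[is.na(pos)]
  }
  if (length(bad) > 0) {
    stop(sprintf("not a driver of this dataset: %s (the target itself is excluded)",
                 paste(bad, collapse = ", ")))
  }
  pos
}
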
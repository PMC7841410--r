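#' @name measures
#' @title Static and dynamic O-information, transfer entropy
#' @description
#' The O-information of n variables,
#' \deqn{\Omega_n = (n-2)H(X) + \sum_j [H(X_j) - H(X \setminus X_j)],}
#' is positive for redundancy-dominated and negative for
#' synergy-dominated equal-time structure. Adding a variable Y changes it
#' by the increment
#' \deqn{\Delta_n = (1-n) I(Y;X) + \sum_j I(Y; X \setminus X_j),}
#' and conditioning every term on the target's own past turns the
#' increment into the dynamic O-information
#' \deqn{d\Omega_n = (1-n) I(Y;X|Y_0) + \sum_j I(Y; X \setminus X_j | Y_0),}
#' the package's central quantity: positive values flag dynamically
#' redundant driver multiplets, negative values dynamically synergistic
#' ones. For two drivers it equals
#' \eqn{TE(x_1) + TE(x_2) - I(Y; X_1 X_2 | Y_0)}, a past-conditioned
#' interaction information.
NULL

.doi_measure <- function(value, measure, variables, target, n_samples) {
  structure(list(value = value, measure = measure, variables = variables,
                 target = target, n_samples = n_samples),
            class = "doi_measure")
}

#' @export
print.doi_measure <- function(x, ...) {
  cat(sprintf("<%s> %.6g bits  (n_samples = %d%s)\n", x$measure, x$value,
              x$n_samples,
              if (length(x$variables))
                paste0("; variables: ", paste(x$variables, collapse = ", "))
              else ""))
  invisible(x)
}

# normalize a variable specification into a list of sample matrices
.as_blocks <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(x, as.matrix)
  } else {
    x <- as.matrix(x)
    lapply(seq_len(ncol(x)), function(j) x[, j, drop = FALSE])
  }
}

#' O-information of a set of variables
#'
#' Equal-time measure of high-order statistical structure; exactly 0 for
#' n = 2 (the sum telescopes). See [measures] for the formula and sign
#' convention.
#'
#' @param x Variables: a matrix (one variable per column) or a list of
#'   matrices (multi-column blocks are treated as joint variables, e.g.
#'   state vectors of order m).
#' @param config An [estimator_config()].
#' @param weights Optional probability weights (plug-in backend), for
#'   exactly enumerated distributions.
#' @return A `doi_measure` object; the estimate in bits is `$value`.
#' @examples
#' x1 <- rbinom(200, 1, 0.5); x2 <- rbinom(200, 1, 0.5)
#' o_information(cbind(x1, x2, xor = as.numeric(xor(x1, x2))),
#'               estimator_config("plugin"))
#' @export
o_information <- function(x, config = estimator_config(), weights = NULL) {
  blocks <- .as_blocks(x)
  n <- length(blocks)
  if (n < 2) stop("the O-information needs at least 2 variables")
  master <- do.call(cbind, blocks)
  ctx <- .make_ctx(master, config, weights)
  cols <- .block_cols(blocks)
  all_cols <- unlist(cols)
  loo <- vapply(seq_len(n), function(j) {
    .ctx_H(ctx, cols[[j]]) - .ctx_H(ctx, unlist(cols[-j]))
  }, numeric(1))
  value <- sum(loo) + (n - 2) * .ctx_H(ctx, all_cols)
  .doi_measure(value, "o_information",
               variables = .block_names(blocks), target = NA,
               n_samples = nrow(master))
}

#' O-information increment from adding a variable
#'
#' The change in O-information when variable `y` joins the set `x`;
#' positive when `y` receives mostly redundant information from `x`,
#' negative when synergistic. Satisfies
#' `o_information(c(x, y)) = o_information(x) + delta_n(y, x)`.
#'
#' @param y The added variable (vector or matrix block).
#' @inheritParams o_information
#' @return A `doi_measure` object (bits in `$value`).
#' @export
delta_n <- function(y, x, config = estimator_config(), weights = NULL) {
  blocks <- .as_blocks(x)
  n <- length(blocks)
  if (n < 1) stop("need at least 1 existing variable")
  y <- as.matrix(y)
  if (nrow(y) != nrow(blocks[[1]])) stop("sample counts of `y` and `x` differ")
  master <- cbind(y, do.call(cbind, blocks))
  ctx <- .make_ctx(master, config, weights)
  ycols <- seq_len(ncol(y))
  cols <- lapply(.block_cols(blocks), function(cc) cc + ncol(y))
  loo <- vapply(seq_len(n), function(j) {
    rest <- unlist(cols[-j])
    if (length(rest) == 0) 0 else .ctx_mi(ctx, ycols, rest)
  }, numeric(1))
  value <- sum(loo) + (1 - n) * .ctx_mi(ctx, ycols, unlist(cols))
  .doi_measure(value, "delta_n", variables = .block_names(blocks),
               target = NA, n_samples = nrow(master))
}

.block_cols <- function(blocks) {
  widths <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(widths)
  mapply(function(e, w) seq.int(e - w + 1L, e), ends, widths, SIMPLIFY = FALSE)
}

.block_names <- function(blocks) {
  nm <- names(blocks)
  if (is.null(nm)) nm <- paste0("X", seq_along(blocks))
  nm
}

# master layout for embedded datasets: [Y | Y0 | driver blocks], with the
# memoised entropy context shared by every measure and by the search
.measure_ctx <- function(dataset, config, positions = seq_along(dataset$drivers)) {
  m <- dataset$m
  blocks <- dataset$drivers[positions]
  master <- cbind(dataset$target_future, dataset$target_past,
                  do.call(cbind, blocks))
  ctx <- .make_ctx(master, config, dataset$weights)
  list(ctx = ctx,
       ycols = 1L,
       y0cols = 1L + seq_len(m),
       dcols = lapply(seq_along(positions), function(i) {
         1L + m + (i - 1L) * m + seq_len(m)
       }),
       positions = positions)
}

# dynamic O-information from cached entropies; dcols = list of driver
# column sets within the context master
.doi_value <- function(mc, sel = seq_along(mc$dcols)) {
  n <- length(sel)
  all_cols <- unlist(mc$dcols[sel])
  loo <- vapply(seq_len(n), function(j) {
    .ctx_cmi(mc$ctx, mc$ycols, unlist(mc$dcols[sel[-j]]), mc$y0cols)
  }, numeric(1))
  sum(loo) + (1 - n) * .ctx_cmi(mc$ctx, mc$ycols, all_cols, mc$y0cols)
}

#' Dynamic O-information of a driver multiplet toward a target
#'
#' Past-conditioned O-information increment of the target's future given
#' the drivers' state vectors (see [measures]). Exactly 0 for a single
#' driver; for two drivers it equals the past-conditioned interaction
#' information. Positive values indicate a dynamically redundant
#' multiplet, negative values a dynamically synergistic one. An
#' independently generated extra driver leaves the value unchanged, so the
#' measure is insensitive to pure pairwise coupling.
#'
#' @param dataset An [embed_series()] result (or [toy_exact_joint()]).
#' @param drivers Driver variables (original column indices or names);
#'   default all drivers in the dataset.
#' @param config An [estimator_config()].
#' @return A `doi_measure` object (bits in `$value`).
#' @examples
#' p <- toy_model_params(a = 0.7, b = 0.2)
#' d <- toy_exact_joint(0.7, 0.2)
#' d_o_information(d, drivers = c(1, 2), estimator_config("plugin"))
#' @export
d_o_information <- function(dataset, drivers = NULL,
                            config = estimator_config()) {
  pos <- .resolve_drivers(dataset, drivers)
  if (length(pos) < 1) stop("the driver set must not be empty")
  mc <- .measure_ctx(dataset, config, pos)
  .doi_measure(.doi_value(mc), "d_o_information",
               variables = dataset$driver_names[pos],
               target = dataset$target_name,
               n_samples = dataset$n_samples)
}

#' Pairwise transfer entropy toward the embedded target
#'
#' `TE(x_i -> y) = I(Y; X_i | Y0)`: the information the driver's state
#' vector carries about the target's next bin beyond the target's own
#' past. Nonnegative up to estimator noise.
#'
#' @param driver A single driver (original column index or name).
#' @inheritParams d_o_information
#' @return A `doi_measure` object (bits in `$value`).
#' @export
transfer_entropy <- function(dataset, driver, config = estimator_config()) {
  pos <- .resolve_drivers(dataset, driver)
  if (length(pos) != 1) stop("`driver` must name exactly one variable")
  mc <- .measure_ctx(dataset, config, pos)
  .doi_measure(.ctx_cmi(mc$ctx, mc$ycols, mc$dcols[[1]], mc$y0cols),
               "transfer_entropy",
               variables = dataset$driver_names[pos],
               target = dataset$target_name,
               n_samples = dataset$n_samples)
}

#' Global transfer entropy toward the embedded target
#'
#' Transfer entropy with all drivers simultaneously taken as the driving
#' set: `I(Y; X_1 ... X_n | Y0)`. With a single driver it coincides with
#' [transfer_entropy()] bit-for-bit.
#'
#' @inheritParams d_o_information
#' @return A `doi_measure` object (bits in `$value`).
#' @export
global_transfer_entropy <- function(dataset, config = estimator_config()) {
  mc <- .measure_ctx(dataset, config)
  .doi_measure(.ctx_cmi(mc$ctx, mc$ycols, unlist(mc$dcols), mc$y0cols),
               "global_transfer_entropy",
               variables = dataset$driver_names,
               target = dataset$target_name,
               n_samples = dataset$n_samples)
}
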
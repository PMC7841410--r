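#' Configure circular-shift surrogate testing
#'
#' Null distributions throughout the package are built from circular
#' shifts, which preserve a series' marginal distribution and
#' autocorrelation while destroying its cross-dependencies. For
#' trial-structured data the blockwise variant rotates the order of whole
#' trials, keeping within-trial structure intact.
#'
#' @param n_realizations Number of surrogate realizations (>= 19 for a
#'   5\% test). Default 1000; increase (the reference protocol for
#'   per-target significance used 30000) when precise tail p-values are
#'   needed.
#' @param shift_type `"auto"` (blockwise when trial bounds are present,
#'   whole-series otherwise), `"circular"`, or `"blockwise_circular"`.
#' @param min_shift Exclusion margin, in time bins, around the unshifted
#'   alignment: random shifts are drawn uniformly from
#'   `[min_shift, length - min_shift]`. Default `m + 1`, so surrogate
#'   past/future pairs can never realign with the originals.
#' @param alpha Significance level (default 0.05).
#' @param correction Multiple-comparison handling for the greedy stopping
#'   rule: `"bonferroni-step"` (divide `alpha` by the number of stopping
#'   tests performed so far; default), `"bonferroni-kmax"` (divide by the
#'   full planned family `k_max - 1`), or `"none"`.
#' @param seed Integer seed for reproducible surrogate draws.
#' @return An object of class `surrogate_config`.
#' @export
surrogate_config <- function(n_realizations = 1000,
                             shift_type = c("auto", "circular",
                                            "blockwise_circular"),
                             min_shift = NULL,
                             alpha = 0.05,
                             correction = c("bonferroni-step",
                                            "bonferroni-kmax", "none"),
                             seed = NULL) {
  n_realizations <- as.integer(n_realizations)
  if (n_realizations < 19) stop("`n_realizations` must be at least 19")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  structure(list(n_realizations = n_realizations,
                 shift_type = match.arg(shift_type),
                 min_shift = min_shift,
                 alpha = alpha,
                 correction = match.arg(correction),
                 seed = seed),
            class = "surrogate_config")
}

#' Circularly shift a series column
#'
#' Whole-series mode rotates the column right by `shift` positions (a
#' shift of 1 turns `(a, b, c, d)` into `(d, a, b, c)`); the multiset of
#' values is preserved exactly. Blockwise mode rotates the order of whole
#' trial blocks, leaving within-trial order intact.
#'
#' @param x Numeric vector (one series column).
#' @param shift Integer: positions (whole-series) or blocks (blockwise);
#'   must satisfy `1 <= shift <= length - 1` (or number of trials - 1).
#' @param trial_bounds Optional 1-based trial start rows; when supplied
#'   the shift is blockwise.
#' @return The shifted vector.
#' @export
circular_shift <- function(x, shift, trial_bounds = NULL) {
  shift <- as.integer(shift)
  if (is.null(trial_bounds)) {
    n <- length(x)
    if (shift < 1 || shift > n - 1) {
      stop(sprintf("shift must lie in [1, %d] (a full rotation is the identity)",
                   n - 1))
    }
    return(c(x[(n - shift + 1L):n], x[1:(n - shift)]))
  }
  nb <- length(trial_bounds)
  if (shift < 1 || shift > nb - 1) {
    stop(sprintf("blockwise shift must lie in [1, %d]", nb - 1))
  }
  ends <- c(trial_bounds[-1] - 1L, length(x))
  ord <- ((seq_len(nb) - 1L - shift) %% nb) + 1L
  unlist(lapply(ord, function(i) x[trial_bounds[i]:ends[i]]), use.names = FALSE)
}

# draw n distinct random shifts honoring the exclusion margin (whole-series)
# or distinct block rotations (blockwise); consumes the current RNG stream
.draw_shifts <- function(n_real, dataset, surr) {
  tb <- attr(dataset$series, "trial_bounds")
  blockwise <- switch(surr$shift_type,
                      auto = !is.null(tb) && length(tb) > 1,
                      circular = FALSE,
                      blockwise_circular = TRUE)
  if (blockwise) {
    if (is.null(tb) || length(tb) < 2) {
      stop("blockwise_circular shifts require trial bounds with >= 2 trials")
    }
    pool <- seq_len(length(tb) - 1L)
  } else {
    L <- nrow(dataset$series)
    ms <- if (is.null(surr$min_shift)) dataset$m + 1L else as.integer(surr$min_shift)
    if (ms < 1 || ms > L - ms) {
      stop(sprintf("shift margin %d leaves no admissible shifts for a series of length %d",
                   ms, L))
    }
    pool <- seq.int(ms, L - ms)
  }
  shifts <- if (length(pool) >= n_real) {
    sample(pool, n_real)
  } else {
    sample(pool, n_real, replace = TRUE)
  }
  list(shifts = shifts, blockwise = blockwise, trial_bounds = tb)
}

# rebuild one raw column shifted and re-embedded; returns the n x m state
# block (and future vector for the target column)
.shifted_embed <- function(dataset, column, shift, blockwise, tb) {
  x <- dataset$series[, column]
  xs <- circular_shift(x, shift, if (blockwise) tb else NULL)
  .embed_column(xs, dataset$m, .trial_spans(dataset$series))
}

#' Surrogate significance of pairwise transfer entropy
#'
#' Builds the null by circularly shifting the target series (blockwise on
#' trial-structured data), re-embedding its past and future, and
#' recomputing the transfer entropy for each realization. The empirical
#' p-value uses the add-one convention `(r + 1) / (N + 1)`, so it is never
#' exactly zero. A non-zero transfer entropy is reported only when
#' `p < alpha`; otherwise the reported value is 0 with the p-value
#' retained.
#'
#' @param dataset An [embed_series()] result (must carry its raw series).
#' @param driver A single driver (original column index or name).
#' @param config An [estimator_config()].
#' @param surr A [surrogate_config()].
#' @return A list of class `te_significance`: `te_bits` (measured value),
#'   `p_value`, `passed`, `te_reported` (thresholded), `n_realizations`.
#' @export
te_significance <- function(dataset, driver, config = estimator_config(),
                            surr = surrogate_config()) {
  if (is.null(dataset$series)) {
    stop("surrogate testing needs the raw series (weighted distributions have no time axis)")
  }
  pos <- .resolve_drivers(dataset, driver)
  if (length(pos) != 1) stop("`driver` must name exactly one variable")
  .seeded(surr$seed, {
    mc <- .measure_ctx(dataset, config, pos)
    te_obs <- .ctx_cmi(mc$ctx, mc$ycols, mc$dcols[[1]], mc$y0cols)
    dr <- .draw_shifts(surr$n_realizations, dataset, surr)
    te_null <- vapply(dr$shifts, function(s) {
      emb <- .shifted_embed(dataset, dataset$target, s, dr$blockwise,
                            dr$trial_bounds)
      ctx2 <- .ctx_replace_cols(mc$ctx, c(mc$ycols, mc$y0cols),
                                cbind(emb$future, emb$state))
      .ctx_cmi(ctx2, mc$ycols, mc$dcols[[1]], mc$y0cols)
    }, numeric(1))
    p <- (sum(te_null >= te_obs) + 1) / (surr$n_realizations + 1)
    structure(list(driver = dataset$driver_names[pos],
                   target = dataset$target_name,
                   te_bits = te_obs,
                   p_value = p,
                   passed = p < surr$alpha,
                   te_reported = if (p < surr$alpha) te_obs else 0,
                   n_realizations = surr$n_realizations,
                   alpha = surr$alpha),
              class = "te_significance")
  })
}

#' @export
print.te_significance <- function(x, ...) {
  cat(sprintf("TE(%s -> %s) = %.6g bits, p = %.4g (%d surrogates) -> %s\n",
              x$driver, x$target, x$te_bits, x$p_value, x$n_realizations,
              if (x$passed) "significant" else "not significant (reported 0)"))
  invisible(x)
}
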
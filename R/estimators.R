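#' Configure the information estimation backend
#'
#' All information quantities in the package are estimated either with the
#' Gaussian-copula approach (each margin is rank-transformed to normal
#' scores, then Gaussian closed forms are applied to the score covariance)
#' or with the discrete plug-in estimator (empirical joint frequencies over
#' a finite alphabet). Outputs are always in bits.
#'
#' The copula backend is designed for continuous-valued data; on heavily
#' tied data (binary spike bins) the default average-rank tie handling is
#' deterministic but the Gaussian closed form is only an approximation —
#' the plug-in backend is exact there.
#'
#' @param method `"gaussian_copula"` (alias `"copula"`) or
#'   `"discrete_plugin"` (alias `"plugin"`).
#' @param bias_correction Logical; copula backend only. Applies the
#'   digamma-based parametric correction of the Gaussian entropy estimator
#'   to every block entropy. Default `TRUE`.
#' @param ties Rank tie handling for the copula transform: `"average"`
#'   (deterministic, default) or `"random"` (seeded).
#' @param seed Integer seed used only when `ties = "random"`.
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(method = c("gaussian_copula", "discrete_plugin",
                                        "copula", "plugin"),
                             bias_correction = TRUE,
                             ties = c("average", "random"),
                             seed = NULL) {
  method <- match.arg(method)
  method <- switch(method, copula = "gaussian_copula",
                   plugin = "discrete_plugin", method)
  ties <- match.arg(ties)
  structure(list(method = method,
                 bias_correction = isTRUE(bias_correction),
                 ties = ties, seed = seed,
                 log_base = 2),
            class = "estimator_config")
}

#' Gaussian copula transform
#'
#' Rank-transforms each column to the open unit interval via the
#' `rank/(n+1)` convention, then maps through the inverse standard normal
#' CDF. Strictly monotone transforms of a column leave its output
#' unchanged (ranks are invariant).
#'
#' @param x Numeric vector or matrix (samples in rows).
#' @param ties `"average"` or `"random"` rank tie-breaking.
#' @param seed Seed for random tie-breaking.
#' @return Matrix of normal scores, same shape as `x`.
#' @export
copula_transform <- function(x, ties = c("average", "random"), seed = NULL) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("copula transform needs at least 2 samples")
  .seeded(if (ties == "random") seed else NULL, {
    n <- nrow(x)
    out <- x
    for (j in seq_len(ncol(x))) {
      col <- x[, j]
      if (length(unique(col)) < 2) {
        nm <- colnames(x)[j]
        stop(sprintf("column %s is constant: zero rank spread, cannot copula-transform",
                     if (is.null(nm) || nm == "") j else sprintf("'%s'", nm)))
      }
      r <- rank(col, ties.method = if (ties == "random") "random" else "average")
      out[, j] <- stats::qnorm(r / (n + 1))
    }
    out
  })
}

# ---- internal primitives ------------------------------------------------

# evaluate expr under a temporary seed, restoring the caller's RNG state
.seeded <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
    old <- get(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# mixed-radix integer codes for the rows of a discrete matrix
.row_codes <- function(x) {
  n <- nrow(x)
  key <- rep(1, n)
  radix <- 1
  for (j in seq_len(ncol(x))) {
    lev <- sort(unique(x[, j]))
    key <- key + (match(x[, j], lev) - 1) * radix
    radix <- radix * length(lev)
  }
  list(key = key, size = radix)
}

# plug-in Shannon entropy in bits; optional probability weights per row
.entropy_plugin <- function(x, weights = NULL) {
  x <- as.matrix(x)
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty input to entropy")
  if (any(x != round(x))) {
    stop("discrete_plugin requires integer-valued input with a finite alphabet")
  }
  rc <- .row_codes(x)
  if (is.null(weights)) {
    p <- tabulate(rc$key, nbins = rc$size)
    p <- p[p > 0] / nrow(x)
  } else {
    p <- rowsum(weights, rc$key)
    p <- p[p > 0]
    p <- p / sum(p)
  }
  -sum(p * log2(p))
}

# Gaussian differential entropy (bits) of copula-transformed data G,
# with the digamma-based parametric bias correction
.entropy_copula <- function(G, bias_correction = TRUE) {
  G <- as.matrix(G)
  n <- nrow(G)
  d <- ncol(G)
  if (n < max(10, d + 2)) {
    stop(sprintf("copula backend needs >= max(10, dim + 2) = %d samples, got %d",
                 max(10, d + 2), n))
  }
  C <- stats::cov(G)
  ch <- tryCatch(chol(C), error = function(e) {
    stop("singular joint correlation matrix (duplicated or collinear columns?)")
  })
  h <- sum(log(diag(ch))) + 0.5 * d * log(2 * pi * exp(1))
  if (bias_correction) {
    psiterms <- digamma((n - seq_len(d)) / 2) / 2
    dterm <- (log(2) - log(n - 1)) / 2
    h <- h - d * dterm - sum(psiterms)
  }
  h / log(2)
}

#' Entropy of a sample block
#'
#' Plug-in backend: Shannon entropy of the empirical joint distribution of
#' the rows (exact on fully enumerated finite distributions, optionally
#' weighted). Copula backend: multivariate Gaussian differential entropy of
#' the normal scores, with optional parametric bias correction.
#'
#' @param x Numeric vector or matrix (samples in rows; a multi-column block
#'   is treated as one joint variable).
#' @param config An [estimator_config()].
#' @param weights Optional probability weights over rows (plug-in backend
#'   only), for exactly enumerated distributions.
#' @return Entropy in bits.
#' @examples
#' entropy(rep(0:1, 4), estimator_config("plugin"))  # 1 bit
#' @export
entropy <- function(x, config = estimator_config(), weights = NULL) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty input to entropy")
  if (config$method == "discrete_plugin") {
    .entropy_plugin(x, weights)
  } else {
    if (!is.null(weights)) {
      stop("probability weights are only supported by the discrete_plugin backend")
    }
    .entropy_copula(copula_transform(x, config$ties, config$seed),
                    config$bias_correction)
  }
}

# entropy-combination helpers shared by both backends --------------------
#
# A "context" wraps one master sample matrix (or its copula scores) with a
# memoised block-entropy function keyed on sorted column subsets, so that
# leave-one-out sums reuse every shared term and repeated evaluation is
# bit-reproducible.

# 0-based integer codes per column (levels from the column itself)
.code_column <- function(col) {
  lev <- sort(unique(col))
  list(code = match(col, lev) - 1L, size = length(lev))
}

.make_ctx <- function(master, config, weights = NULL) {
  master <- as.matrix(master)
  ctx <- new.env(parent = emptyenv())
  ctx$config <- config
  ctx$n <- nrow(master)
  ctx$weights <- weights
  if (config$method == "gaussian_copula") {
    if (!is.null(weights)) {
      stop("probability weights are only supported by the discrete_plugin backend")
    }
    ctx$data <- copula_transform(master, config$ties, config$seed)
  } else {
    ctx$data <- master
    if (any(master != round(master))) {
      stop("discrete_plugin requires integer-valued input with a finite alphabet")
    }
    coded <- lapply(seq_len(ncol(master)), function(j) .code_column(master[, j]))
    ctx$codes <- vapply(coded, `[[`, integer(nrow(master)), "code")
    if (nrow(master) == 1L) ctx$codes <- matrix(ctx$codes, nrow = 1L)
    ctx$sizes <- vapply(coded, `[[`, integer(1), "size")
    ctx$partial <- new.env(parent = emptyenv())  # fixed-column key cache
    ctx$replaced <- integer(0)
    ctx$base <- ctx
  }
  ctx$cache <- new.env(parent = emptyenv())
  ctx
}

# pack selected columns into mixed-radix row keys (0-based)
.pack_cols <- function(codes, sizes, cols) {
  key <- 0
  radix <- 1
  for (j in cols) {
    key <- key + codes[, j] * radix
    radix <- radix * sizes[j]
  }
  list(key = key, radix = radix)
}

.entropy_from_key <- function(key0, radix, n) {
  cnt <- if (radix <= 4e6) {
    tabulate(key0 + 1, nbins = radix)
  } else {
    tabulate(match(key0, unique(key0)))
  }
  p <- cnt[cnt > 0] / n
  -sum(p * log2(p))
}

.ctx_H <- function(ctx, cols) {
  cols <- sort(unique(cols))
  key <- paste(cols, collapse = ",")
  got <- ctx$cache[[key]]
  if (!is.null(got)) return(got)
  val <- if (ctx$config$method == "gaussian_copula") {
    .entropy_copula(ctx$data[, cols, drop = FALSE], ctx$config$bias_correction)
  } else if (!is.null(ctx$weights)) {
    .entropy_plugin(ctx$data[, cols, drop = FALSE], ctx$weights)
  } else {
    moving <- intersect(cols, ctx$replaced)
    if (length(moving) == 0) {
      pk <- .pack_cols(ctx$codes, ctx$sizes, cols)
      .entropy_from_key(pk$key, pk$radix, ctx$n)
    } else {
      # columns replaced by a surrogate: combine their fresh codes with a
      # cached packing of the untouched columns (persisted on the base
      # context so it is shared across surrogate realizations)
      fixed <- setdiff(cols, moving)
      pm <- .pack_cols(ctx$codes, ctx$sizes, moving)
      if (length(fixed) == 0) {
        .entropy_from_key(pm$key, pm$radix, ctx$n)
      } else {
        fk <- paste(fixed, collapse = ",")
        pf <- ctx$base$partial[[fk]]
        if (is.null(pf)) {
          pf <- .pack_cols(ctx$base$codes, ctx$base$sizes, fixed)
          ctx$base$partial[[fk]] <- pf
        }
        .entropy_from_key(pf$key + pm$key * pf$radix, pf$radix * pm$radix, ctx$n)
      }
    }
  }
  ctx$cache[[key]] <- val
  val
}

# replace a set of master columns (e.g. a surrogate-shifted driver block),
# keeping cache entries that do not involve them
.ctx_replace_cols <- function(ctx, cols, new_values) {
  new_values <- as.matrix(new_values)
  out <- new.env(parent = emptyenv())
  out$config <- ctx$config
  out$n <- ctx$n
  out$weights <- ctx$weights
  if (ctx$config$method == "gaussian_copula") {
    out$data <- ctx$data
    out$data[, cols] <- copula_transform(new_values,
                                         ctx$config$ties, ctx$config$seed)
  } else if (!is.null(ctx$weights)) {
    out$data <- ctx$data
    out$data[, cols] <- new_values
  } else {
    # unweighted plug-in entropies read only the integer codes
    out$codes <- ctx$codes
    out$sizes <- ctx$sizes
    for (i in seq_along(cols)) {
      cc <- .code_column(new_values[, i])
      out$codes[, cols[i]] <- cc$code
      out$sizes[cols[i]] <- cc$size
    }
    out$replaced <- sort(unique(c(ctx$replaced, cols)))
    out$base <- ctx$base
    out$partial <- new.env(parent = emptyenv())
  }
  out$cache <- new.env(parent = emptyenv())
  for (key in ls(ctx$cache)) {
    kc <- as.integer(strsplit(key, ",")[[1]])
    if (!any(kc %in% cols)) out$cache[[key]] <- ctx$cache[[key]]
  }
  out
}

# I(Y; X) from cached block entropies
.ctx_mi <- function(ctx, ycols, xcols) {
  .ctx_H(ctx, ycols) + .ctx_H(ctx, xcols) - .ctx_H(ctx, c(ycols, xcols))
}

# I(Y; X | Z) computed as I(Y; X,Z) - I(Y; Z) so that the chain rule
# I(Y; X,Z) = I(Y; Z) + I(Y; X|Z) holds exactly for both backends
.ctx_cmi <- function(ctx, ycols, xcols, zcols) {
  if (length(xcols) == 0) return(0)
  if (length(zcols) == 0) return(.ctx_mi(ctx, ycols, xcols))
  .ctx_mi(ctx, ycols, c(xcols, zcols)) - .ctx_mi(ctx, ycols, zcols)
}

#' Mutual information between two sample blocks
#'
#' Computed as `H(X) + H(Y) - H(X,Y)` under the chosen backend. The
#' plug-in version matches hand-computed Shannon quantities exactly on
#' fully enumerated finite distributions; the copula version is invariant
#' under strictly monotone marginal transforms.
#'
#' @param x,y Numeric vectors or matrices with equal sample counts.
#' @inheritParams entropy
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, config = estimator_config(),
                               weights = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("sample counts of `x` and `y` differ")
  ctx <- .make_ctx(cbind(x, y), config, weights)
  .ctx_mi(ctx, ncol(x) + seq_len(ncol(y)), seq_len(ncol(x)))
}

#' Conditional mutual information I(Y; X | Z)
#'
#' Computed as `I(Y; X,Z) - I(Y; Z)` so the chain rule holds exactly under
#' either backend; with `z = NULL` it reduces bit-for-bit to
#' [mutual_information()].
#'
#' @param x,y Sample blocks (equal sample counts).
#' @param z Optional conditioning block.
#' @inheritParams entropy
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(x, y, z = NULL,
                                           config = estimator_config(),
                                           weights = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(z) || (is.matrix(z) && ncol(z) == 0)) {
    return(mutual_information(x, y, config, weights))
  }
  z <- as.matrix(z)
  if (nrow(x) != nrow(y) || nrow(x) != nrow(z)) {
    stop("sample counts of `x`, `y`, `z` differ")
  }
  ctx <- .make_ctx(cbind(x, y, z), config, weights)
  xc <- seq_len(ncol(x))
  yc <- ncol(x) + seq_len(ncol(y))
  zc <- ncol(x) + ncol(y) + seq_len(ncol(z))
  .ctx_cmi(ctx, yc, xc, zc)
}
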
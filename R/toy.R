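#' @name toy_model
#' @title Four-variable binary benchmark system
#' @description
#' An exactly solvable system of four binary variables used to validate
#' every dynamical measure in the package. Three drivers `sigma1..sigma3`
#' are i.i.d. fair coins at each time step; the target's next state
#' `sigma4(t+1)` is drawn from a conditional table parameterized by two
#' probability weights: `a` controls a triplet circuit (with probability
#' `a` the target follows the majority of the three drivers, unless all
#' three agree, in which case it takes their opposite), and `b` controls a
#' pair circuit (an XOR of the first two drivers). Both circuits are
#' purely synergistic: no single driver carries any information about the
#' target, and with `b = 0` no pair does either. All equal-time
#' correlations are null, so the static O-information sees nothing while
#' the dynamic O-information detects both circuits — closed forms:
#' \deqn{d\Omega_2 = -(1 - h_2(1/2 + b))}
#' \deqn{d\Omega_3 = -2[1 - (h_2(a-b) + h_2(a+b))/2] + (1 - h_2(1/2+b))}
#' with `h2` the binary entropy in bits.
NULL

#' Parameters of the binary benchmark system
#'
#' Validates that every entry of the conditional table is a probability,
#' which requires `0 <= b <= a` and `a + b <= 1`.
#'
#' @param a Weight of the triplet (majority/anti-majority) circuit.
#' @param b Weight of the pair (XOR) circuit.
#' @param n_steps Simulation length in time steps.
#' @param seed Optional integer seed.
#' @return An object of class `toy_model_params`.
#' @export
toy_model_params <- function(a, b, n_steps = 10000, seed = NULL) {
  if (a < 0 || a > 1) stop("invalid parameters: need 0 <= a <= 1")
  if (b < 0) stop("invalid parameters: need b >= 0")
  if (b > a) stop(sprintf(
    "invalid parameters: b (%.3g) > a (%.3g) makes table entries a - b negative", b, a))
  if (a + b > 1) stop(sprintf(
    "invalid parameters: a + b = %.3g > 1 makes table entries 1 - a - b negative", a + b))
  structure(list(a = a, b = b, n_steps = as.integer(n_steps), seed = seed),
            class = "toy_model_params")
}

# P(sigma4' = 0 | s1, s2, s3), vectorized over states
.toy_p0 <- function(s1, s2, s3, a, b) {
  ifelse(s3 == 0,
         ifelse(s1 == s2, 1 - a + b, a - b),
         ifelse(s1 == s2, a + b, 1 - a - b))
}

#' Simulate the binary benchmark system
#'
#' Drivers are i.i.d. fair coins per step; the target's next state is
#' drawn from the conditional table given the drivers' current states
#' (the target's own past never enters the transition). The first target
#' state is uniform.
#'
#' @param params A [toy_model_params()] object.
#' @return An [multivariate_series()] with columns
#'   `sigma1, sigma2, sigma3, sigma4`.
#' @export
simulate_toy <- function(params) {
  stopifnot(inherits(params, "toy_model_params"))
  .seeded(params$seed, {
    n <- params$n_steps
    s <- matrix(stats::rbinom(3L * n, 1, 0.5), nrow = n, ncol = 3)
    s4 <- numeric(n)
    s4[1] <- stats::rbinom(1, 1, 0.5)
    p1 <- 1 - .toy_p0(s[-n, 1], s[-n, 2], s[-n, 3], params$a, params$b)
    s4[-1] <- as.numeric(stats::runif(n - 1) < p1)
    multivariate_series(cbind(s, s4),
                        names = c("sigma1", "sigma2", "sigma3", "sigma4"))
  })
}

#' Exact joint distribution of the benchmark system
#'
#' Enumerates the stationary joint distribution of the three driver
#' states, the target's current state, and the target's next state
#' (32 support points: drivers uniform with probability 1/8, target past
#' uniform and independent of everything by construction, next state from
#' the conditional table). The result is packaged as a weighted
#' `embedded_dataset` so the plug-in backend computes information
#' quantities on it exactly — the target past is carried along to
#' exercise the full conditioning code path even though it is
#' uninformative here.
#'
#' @param a,b Circuit weights (validated via [toy_model_params()]).
#' @return A weighted `embedded_dataset` (plug-in backend only).
#' @examples
#' d <- toy_exact_joint(0.7, 0)
#' d_o_information(d, config = estimator_config("plugin"))$value  # ~ -0.2374
#' @export
toy_exact_joint <- function(a, b) {
  toy_model_params(a, b)  # validation only
  g <- expand.grid(s1 = 0:1, s2 = 0:1, s3 = 0:1, y0 = 0:1, y = 0:1)
  p0 <- .toy_p0(g$s1, g$s2, g$s3, a, b)
  w <- (1 / 8) * (1 / 2) * ifelse(g$y == 0, p0, 1 - p0)
  structure(list(
    m = 1L,
    target = 4L,
    target_name = "sigma4",
    driver_index = 1:3,
    driver_names = c("sigma1", "sigma2", "sigma3"),
    drivers = list(sigma1 = matrix(g$s1), sigma2 = matrix(g$s2),
                   sigma3 = matrix(g$s3)),
    target_future = g$y,
    target_past = matrix(g$y0),
    n_samples = nrow(g),
    series = NULL,
    weights = w
  ), class = "embedded_dataset")
}

#' Binary entropy in bits
#'
#' `h2(p) = -p log2 p - (1-p) log2 (1-p)`, with `0 log 0 = 0`.
#'
#' @param p Probability (vectorized).
#' @return Entropy in bits.
#' @export
binary_entropy <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  term <- function(q) ifelse(q > 0, -q * log2(q), 0)
  term(p) + term(1 - p)
}

#' Closed-form dynamic O-information of the benchmark circuits
#'
#' Exact values for the pair `{sigma1, sigma2}` and the triplet
#' `{sigma1, sigma2, sigma3}` driving the benchmark target (see
#' [toy_model]); used as independent references for the estimators.
#'
#' @param a,b Circuit weights.
#' @return dΩ in bits.
#' @export
toy_doi2_closed <- function(b) {
  -(1 - binary_entropy(0.5 + b))
}

#' @rdname toy_doi2_closed
#' @export
toy_doi3_closed <- function(a, b) {
  -2 * (1 - (binary_entropy(a - b) + binary_entropy(a + b)) / 2) +
    (1 - binary_entropy(0.5 + b))
}

#' Pair and triplet dynamic O-information across circuit strengths
#'
#' Computes, from the exactly enumerated joint distribution (no
#' simulation), the dynamic O-information of the pair circuit and of the
#' triplet circuit for a grid of `b` values at fixed `a` — the benchmark
#' system's signature curves: the triplet is detected at every `b`
#' (non-increasing in `b`), the pair only once `b > 0`.
#'
#' @param b_grid Numeric vector of pair-circuit weights.
#' @param a Triplet-circuit weight (default 0.7).
#' @return A data frame with columns `b`, `doi2`, `doi3` (bits).
#' @export
doi_curves <- function(b_grid = seq(0, 0.3, by = 0.05), a = 0.7) {
  cfg <- estimator_config("discrete_plugin")
  res <- vapply(b_grid, function(b) {
    d <- toy_exact_joint(a, b)
    c(d_o_information(d, drivers = c(1, 2), cfg)$value,
      d_o_information(d, drivers = 1:3, cfg)$value)
  }, numeric(2))
  data.frame(b = b_grid, doi2 = res[1, ], doi3 = res[2, ])
}
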
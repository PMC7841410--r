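# shared fixtures, all generated in code

plugin_cfg <- estimator_config("discrete_plugin")
copula_cfg <- estimator_config("gaussian_copula")

# random discrete multivariate series
rand_discrete <- function(n, k, alphabet = 0:1, rate = NULL, seed = 1) {
  set.seed(seed)
  v <- if (is.null(rate)) {
    matrix(sample(alphabet, n * k, replace = TRUE), ncol = k)
  } else {
    matrix(rbinom(n * k, 1, rate), ncol = k)
  }
  multivariate_series(v)
}

# full enumeration of a finite joint distribution as equal-frequency samples:
# feeding these to the plug-in backend yields exact Shannon quantities
enum_grid <- function(...) as.matrix(expand.grid(...))

# append an independent uniform binary driver to a weighted exact-joint
# dataset (product-measure extension)
extend_with_independent <- function(dataset, name = "noise") {
  n <- dataset$n_samples
  rep2 <- function(x) if (is.matrix(x)) rbind(x, x) else c(x, x)
  drivers <- lapply(dataset$drivers, rep2)
  drivers[[name]] <- matrix(rep(0:1, each = n))
  out <- dataset
  out$drivers <- drivers
  out$driver_index <- c(dataset$driver_index, max(dataset$driver_index) + 1L)
  out$driver_names <- c(dataset$driver_names, name)
  out$target_future <- rep2(dataset$target_future)
  out$target_past <- rep2(dataset$target_past)
  out$weights <- c(dataset$weights, dataset$weights) / 2
  out$n_samples <- 2L * n
  out
}

# brute-force count of valid embedding time points, enumerating each trial
count_valid_t <- function(lengths, m) {
  total <- 0L
  for (L in lengths) {
    for (t in seq_len(L)) {
      if (t >= m && t + 1 <= L) total <- total + 1L
    }
  }
  total
}
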
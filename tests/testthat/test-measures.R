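test_that("the O-information of any two variables vanishes identically", {
  set.seed(1)
  for (cfg in list(plugin_cfg, copula_cfg)) {
    x <- if (cfg$method == "discrete_plugin") {
      cbind(sample(0:2, 100, TRUE), sample(0:3, 100, TRUE))
    } else {
      matrix(rnorm(200), ncol = 2)
    }
    expect_identical(o_information(x, cfg)$value, 0)
  }
})

test_that("O-information signs match canonical synergy and redundancy", {
  # XOR triple on the full 4-state distribution: pure synergy, -1 bit
  g <- enum_grid(x1 = 0:1, x2 = 0:1)
  xor3 <- cbind(g, (g[, 1] + g[, 2]) %% 2)
  expect_equal(o_information(xor3, plugin_cfg)$value, -1.0)
  # three copies of one fair bit: pure redundancy, +1 bit
  copies <- cbind(0:1, 0:1, 0:1)
  expect_equal(o_information(copies, plugin_cfg)$value, 1.0)
  # a duplicated pair plus an independent bit carries no 3-way interaction
  g3 <- enum_grid(x1 = 0:1, x2 = 0:1)
  dup <- cbind(g3[, 1], g3[, 2], g3[, 1])
  expect_equal(o_information(dup, plugin_cfg)$value, 0)
})

test_that("the increment delta_n tracks the O-information exactly", {
  g <- enum_grid(x1 = 0:1, x2 = 0:1, y = 0:1)  # y independent
  expect_equal(delta_n(g[, 3], g[, 1:2], plugin_cfg)$value, 0)

  g2 <- enum_grid(x1 = 0:1, x2 = 0:1)
  y_xor <- (g2[, 1] + g2[, 2]) %% 2
  expect_equal(delta_n(y_xor, g2, plugin_cfg)$value, -1.0)

  # additivity anchor on random discrete data, growing set sizes
  set.seed(2)
  for (n_vars in 2:4) {
    x <- matrix(sample(0:1, 150 * n_vars, TRUE), ncol = n_vars)
    y <- sample(0:1, 150, TRUE)
    om_n <- o_information(x, plugin_cfg)$value
    om_n1 <- o_information(cbind(x, y), plugin_cfg)$value
    dn <- delta_n(y, x, plugin_cfg)$value
    expect_equal(om_n1, om_n + dn, tolerance = 1e-12)
  }
})

test_that("a single driver carries zero dynamic O-information, always", {
  s <- rand_discrete(200, 3, seed = 3)
  d <- embed_series(s, m = 2, target = 3)
  expect_identical(d_o_information(d, drivers = 1, plugin_cfg)$value, 0)
  set.seed(4)
  sc <- multivariate_series(matrix(rnorm(600), ncol = 3))
  dc <- embed_series(sc, m = 2, target = 3)
  expect_identical(d_o_information(dc, drivers = 2, copula_cfg)$value, 0)
  expect_error(d_o_information(d, drivers = integer(0)), "empty")
  expect_error(d_o_information(d, drivers = 3), "not a driver")
})

test_that("two-driver dynamic O-information is the TE interaction identity", {
  for (s in 1:6) {
    set.seed(s)
    v <- matrix(sample(0:2, 3 * 250, TRUE), ncol = 3)
    e <- embed_series(multivariate_series(v), m = 1, target = 3)
    for (cfg in list(plugin_cfg, copula_cfg)) {
      lhs <- d_o_information(e, config = cfg)$value
      rhs <- transfer_entropy(e, 1, cfg)$value +
        transfer_entropy(e, 2, cfg)$value -
        global_transfer_entropy(e, cfg)$value
      expect_identical(lhs, rhs)
    }
  }
})

test_that("transfer entropy vanishes under independence, is exact on oracles", {
  # independent driver on the fully enumerated joint
  g <- enum_grid(x = 0:1, y0 = 0:1, y1 = 0:1)
  d <- structure(list(
    m = 1L, target = 2L, target_name = "y", driver_index = 1L,
    driver_names = "x", drivers = list(x = matrix(g[, 1])),
    target_future = g[, 3], target_past = matrix(g[, 2]),
    n_samples = nrow(g), series = NULL, weights = rep(1 / 8, 8)
  ), class = "embedded_dataset")
  expect_equal(transfer_entropy(d, 1, plugin_cfg)$value, 0)

  # benchmark system at b = 0: no single driver informs the target
  tj <- toy_exact_joint(0.7, 0)
  for (k in 1:3) {
    expect_equal(transfer_entropy(tj, k, plugin_cfg)$value, 0)
  }
  # but the driver set jointly does: closed-form global transfer entropy
  expect_equal(global_transfer_entropy(tj, plugin_cfg)$value,
               1 - binary_entropy(0.7), tolerance = 1e-12)
})

test_that("a deterministic lagged copy yields exactly the oracle TE", {
  # driver x(t) determines y(t + 1) = x(t); past of y is fresh noise
  g <- enum_grid(x = 0:1, y0 = 0:1)
  d <- structure(list(
    m = 1L, target = 2L, target_name = "y", driver_index = 1L,
    driver_names = "x", drivers = list(x = matrix(g[, 1])),
    target_future = g[, 1], target_past = matrix(g[, 2]),
    n_samples = nrow(g), series = NULL, weights = rep(1 / 4, 4)
  ), class = "embedded_dataset")
  expect_equal(transfer_entropy(d, 1, plugin_cfg)$value, 1.0)
})

test_that("global TE equals pairwise TE for a single-driver system", {
  s <- rand_discrete(300, 2, seed = 6)
  e <- embed_series(s, m = 1, target = 2)
  expect_identical(global_transfer_entropy(e, plugin_cfg)$value,
                   transfer_entropy(e, 1, plugin_cfg)$value)
})

test_that("global TE upper-bounds each pairwise TE on full distributions", {
  tj <- toy_exact_joint(0.6, 0.2)
  gte <- global_transfer_entropy(tj, plugin_cfg)$value
  for (k in 1:3) {
    expect_lte(transfer_entropy(tj, k, plugin_cfg)$value, gte + 1e-12)
  }
})

test_that("an independently generated driver never changes the measure", {
  # exact product-measure extension: plug-in value unchanged to precision
  tj <- toy_exact_joint(0.7, 0.15)
  base_val <- d_o_information(tj, config = plugin_cfg)$value
  ext <- extend_with_independent(tj)
  expect_equal(d_o_information(ext, config = plugin_cfg)$value, base_val,
               tolerance = 1e-12)
})
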
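test_that("pair search is exhaustive, extremal, and deterministically tied", {
  # C(3, 2) = 3 evaluations
  s <- rand_discrete(200, 4, seed = 1)
  e <- embed_series(s, m = 1, target = 4)
  ps <- exhaustive_pair_search(e, "synergistic", plugin_cfg)
  expect_identical(ps$n_evaluated, 3L)

  # on the exact b = 0 joint every pair is exactly 0: the tie breaks to
  # the lowest index pair
  tj <- toy_exact_joint(0.7, 0)
  ps0 <- exhaustive_pair_search(tj, "synergistic", plugin_cfg)
  expect_identical(ps0$pair, c(1L, 2L))
  expect_equal(ps0$value, 0)

  # at b = 0.2 only {sigma1, sigma2} is non-null
  tj2 <- toy_exact_joint(0.7, 0.2)
  ps2 <- exhaustive_pair_search(tj2, "synergistic", plugin_cfg)
  expect_identical(ps2$pair, c(1L, 2L))
  expect_equal(ps2$value, toy_doi2_closed(0.2), tolerance = 1e-12)
  # the redundant search must not pick the synergistic pair
  psr <- exhaustive_pair_search(tj2, "redundant", plugin_cfg)
  expect_false(all(psr$pair == c(1L, 2L)))
})

test_that("greedy extension adds the extremal candidate, or is forced", {
  sim <- simulate_toy(toy_model_params(0.7, 0.2, n_steps = 3e4, seed = 2))
  e <- embed_series(sim, m = 1, target = 4)
  sr <- search_multiplets(e, "synergistic", plugin_cfg, k_max = 2,
                          significance = FALSE)
  expect_identical(sort(sr$selected[1:2]), c(1L, 2L))
  ext <- greedy_extend(e, sr, plugin_cfg)
  expect_identical(ext$selected[3], 3L)         # the only (forced) candidate
  expect_lt(ext$trajectory[2], ext$trajectory[1])  # dOmega3 < dOmega2
  # no candidates remain: unchanged with a notice
  expect_message(ext2 <- greedy_extend(e, ext, plugin_cfg), "no candidate")
  expect_identical(ext2$selected, ext$selected)
})

test_that("duplicated drivers are skipped under the copula backend", {
  set.seed(3)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- c(0, 2 * x1[-n] * x2[-n]) + 0.3 * rnorm(n)  # jointly driven target
  s <- multivariate_series(cbind(x1 = x1, x2 = x2, x1_copy = x1, x3 = x3,
                                 y = y))
  e <- embed_series(s, m = 1, target = 5)
  # start from the known pair; extension must skip the singular duplicate
  res <- list(mode = "synergistic", selected = c(1L, 2L),
              selected_names = c("x1", "x2"),
              trajectory = d_o_information(e, drivers = c(1, 2),
                                           copula_cfg)$value)
  expect_message(ext <- greedy_extend(e, res, copula_cfg), "skipping")
  expect_identical(length(ext$selected), 3L)
  expect_false("x1_copy" %in% ext$selected_names)
})

test_that("search results are reproducible and internally consistent", {
  sim <- simulate_toy(toy_model_params(0.7, 0.2, n_steps = 2e4, seed = 4))
  e <- embed_series(sim, m = 1, target = 4)
  surr <- surrogate_config(n_realizations = 49, seed = 11)
  a <- search_multiplets(e, "synergistic", plugin_cfg, surr, k_max = 3)
  b <- search_multiplets(e, "synergistic", plugin_cfg, surr, k_max = 3)
  expect_identical(a$selected, b$selected)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$step_p_values, b$step_p_values)

  # recomputing dOmega_k from scratch on the stored sets matches the
  # trajectory to machine precision
  for (k in 2:3) {
    v <- d_o_information(e, drivers = a$selected[1:k], plugin_cfg)$value
    expect_equal(unname(a$trajectory[k - 1]), v, tolerance = 1e-12)
  }
})

test_that("the stopping rule accepts planted structure and reports k_stop", {
  sim <- simulate_toy(toy_model_params(0.7, 0.2, n_steps = 5e4, seed = 6))
  e <- embed_series(sim, m = 1, target = 4)
  sr <- search_multiplets(e, "synergistic", plugin_cfg,
                          surrogate_config(n_realizations = 49, seed = 7),
                          k_max = 3)
  expect_identical(sr$k_stop, 3L)
  expect_true(all(sr$step_accepted))
  expect_equal(sr$reported_value, -unname(sr$trajectory[2]))
  expect_length(sr$step_p_values, 2)

  # standalone stopping test on a hand-built multiplet under the null
  v <- rand_discrete(500, 4, rate = 0.3, seed = 8)
  en <- embed_series(v, m = 1, target = 4)
  doi2 <- d_o_information(en, drivers = c(1, 2), plugin_cfg)$value
  res <- list(selected = c(1L, 2L), trajectory = doi2, mode = "synergistic")
  st <- stopping_test(en, res, plugin_cfg,
                      surrogate_config(n_realizations = 49, seed = 9))
  expect_true(st$p_value > 0 && st$p_value <= 1)
  expect_identical(st$threshold, 0.05)
})

test_that("stop_at = 'rejection' halts after the first failed addition", {
  v <- rand_discrete(400, 5, rate = 0.3, seed = 10)
  e <- embed_series(v, m = 1, target = 5)
  sr <- search_multiplets(e, "synergistic", plugin_cfg,
                          surrogate_config(n_realizations = 49, seed = 12),
                          k_max = 4, stop_at = "rejection")
  if (!sr$step_accepted[1]) {
    expect_length(sr$trajectory, 1)
    expect_identical(sr$k_stop, 1L)
    expect_identical(sr$reported_value, 0)
  } else {
    expect_gte(sr$k_stop, 2L)
  }
})

test_that("searching a weighted exact joint without significance works", {
  tj <- toy_exact_joint(0.7, 0.2)
  sr <- search_multiplets(tj, "synergistic", plugin_cfg, k_max = 3,
                          significance = FALSE)
  expect_identical(sort(sr$selected), 1:3)
  expect_true(is.na(sr$k_stop))
  expect_equal(unname(sr$trajectory[2]), toy_doi3_closed(0.7, 0.2),
               tolerance = 1e-12)
})
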
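test_that("config validation guards ground truth and probabilities", {
  circ <- function(...) list(...)
  expect_error(synthetic_spiking_config(4, 2, 50, circuits = list(
    circ(drivers = 1:2, target = 2, type = "xor_parity", coupling = 0.5))),
    "disjoint")
  expect_error(synthetic_spiking_config(4, 2, 50, circuits = list(
    circ(drivers = 1:2, target = 3, type = "xor_parity", coupling = 1.5))),
    "\\[0, 1\\]")
  expect_error(synthetic_spiking_config(4, 2, 50, circuits = list(
    circ(drivers = 1:2, target = 3, type = "xor_parity", coupling = 0.5),
    circ(drivers = c(1, 4), target = 3, type = "majority", coupling = 0.5))),
    "overlapping targets")
  expect_error(synthetic_spiking_config(4, 2, 50, circuits = list(
    circ(drivers = 1:2, target = 3, type = "nope", coupling = 0.5))),
    "unknown circuit type")
  expect_error(synthetic_spiking_config(4, 2, 50, baseline_rate = 0), "probability")
})

test_that("the raster is binary with the right shape and firing rates", {
  cfg <- synthetic_spiking_config(8, n_trials = 20, trial_length = 100,
    baseline_rate = 0.3,
    circuits = list(list(drivers = 1:3, target = 4, type = "xor_parity",
                         coupling = 0.5)),
    class_labels = c(rep("L", 3), "H", rep("M", 4)), seed = 21)
  r <- generate_spiking(cfg)
  v <- unclass(r$series)
  expect_identical(dim(v), c(2000L, 8L))
  expect_true(all(v %in% c(0, 1)))
  expect_identical(attr(r$series, "trial_bounds"),
                   seq.int(1L, 2000L, by = 100L))
  # non-circuit neurons fire at baseline within 3 binomial SE
  se <- sqrt(0.3 * 0.7 / 2000)
  for (k in 5:8) expect_lt(abs(mean(v[, k]) - 0.3), 3 * se)
})

test_that("zero coupling produces a fully i.i.d. raster", {
  cfg <- synthetic_spiking_config(4, n_trials = 10, trial_length = 200,
    circuits = list(list(drivers = 1:2, target = 3, type = "xor_parity",
                         coupling = 0)), seed = 22)
  e <- embed_series(generate_spiking(cfg)$series, m = 1, target = 3)
  # reduced null calibration: rejection rate near alpha across seeds
  rej <- 0
  for (s in 1:30) {
    cfg_s <- synthetic_spiking_config(2, n_trials = 5, trial_length = 101,
      circuits = list(list(drivers = 1, target = 2, type = "majority",
                           coupling = 0)), seed = s)
    es <- embed_series(generate_spiking(cfg_s)$series, m = 1, target = 2)
    ts <- te_significance(es, 1, plugin_cfg,
                          surrogate_config(n_realizations = 49,
                                           shift_type = "circular",
                                           seed = 400 + s))
    if (ts$passed) rej <- rej + 1
  }
  expect_lte(rej, 6)
  # and the planted-but-uncoupled driver set is not synergistic
  v <- d_o_information(e, drivers = 1:2, plugin_cfg)$value
  expect_lt(abs(v), 0.01)
})

test_that("planted xor circuits are recovered by the synergistic search", {
  rec <- 0
  for (s in 1:5) {
    cfg <- synthetic_spiking_config(12, n_trials = 40, trial_length = 501,
      circuits = list(list(drivers = 1:3, target = 4, type = "xor_parity",
                           coupling = 0.4)), seed = s)
    e <- embed_series(generate_spiking(cfg)$series, m = 1, target = 4)
    sr <- search_multiplets(e, "synergistic", plugin_cfg, k_max = 3,
                            significance = FALSE)
    if (setequal(sr$selected, 1:3)) rec <- rec + 1
  }
  expect_gte(rec, 4)
})

test_that("redundant broadcast circuits are positive and found as such", {
  cfg <- synthetic_spiking_config(8, n_trials = 40, trial_length = 501,
    circuits = list(list(drivers = 1:3, target = 4,
                         type = "redundant_broadcast", coupling = 0.5)),
    seed = 31)
  e <- embed_series(generate_spiking(cfg)$series, m = 1, target = 4)
  expect_gt(d_o_information(e, drivers = 1:3, plugin_cfg)$value, 0.01)
  sr <- search_multiplets(e, "redundant", plugin_cfg, k_max = 3,
                          significance = FALSE)
  expect_true(setequal(sr$selected, 1:3))
})

test_that("the manifest records the planted ground truth and round-trips", {
  cfg <- synthetic_spiking_config(5, n_trials = 3, trial_length = 60,
    circuits = list(list(drivers = c(1, 2), target = 5, type = "majority",
                         coupling = 0.7)),
    class_labels = c("H", "H", "M", "L", "H"), seed = 13)
  r <- generate_spiking(cfg)
  expect_identical(r$manifest$circuits[[1]]$drivers, c(1L, 2L))
  expect_identical(r$manifest$circuits[[1]]$target, 5L)
  expect_identical(r$manifest$class_labels, cfg$class_labels)

  raster_f <- tempfile(fileext = ".tsv")
  trial_f <- tempfile()
  man_f <- tempfile(fileext = ".json")
  write_spiking(r, raster_f, trial_f, man_f)
  back <- read_series(raster_f, trial_f)
  expect_equal(unclass(back)[, ], unclass(r$series)[, ], ignore_attr = TRUE)
  man <- jsonlite::read_json(man_f)
  expect_identical(man$circuits[[1]]$type, "majority")
  expect_identical(as.integer(unlist(man$circuits[[1]]$drivers)), c(1L, 2L))
})
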
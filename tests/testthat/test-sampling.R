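test_that("scenario indicators match their definitions", {
  ds <- mol_dataset(list(path3_single(), mixed_bond_graph()),
                    data.frame(id = c("p3", "mix"),
                               gap = c(1.5, -0.25), y = c(2.7, 0.1)))
  s1 <- scenario_config(1)
  s2 <- scenario_config(2)
  s3 <- scenario_config(3, aux_property = "gap")
  s4 <- scenario_config(4, target_property = "y")

  expect_equal(indicator_value(path3_single(), ds$properties, s1), 3)
  expect_equal(indicator_value(path3_single(), ds$properties, s2), 0.0)
  expect_equal(indicator_value(mixed_bond_graph(), ds$properties, s2), 0.5)
  expect_equal(indicator_value(mixed_bond_graph(), ds$properties, s3), -0.25)
  expect_equal(indicator_value(path3_single(), ds$properties, s4), 2.7)

  # bondless graph: non-single fraction defined as 0
  expect_equal(indicator_value(mol_graph("C", id = "x"), ds$properties, s2), 0)

  # scenario/direction consistency is enforced by construction
  expect_identical(s1$direction, "smaller_preferred")
  expect_identical(s2$direction, "larger_preferred")
  expect_error(scenario_config(3), "gap-like")
})

test_that("inclusion probabilities are monotone sigmoids of the indicator", {
  cfg <- scenario_config(1)
  xs <- c(3, 5, 9, 14, 20, 27)
  p <- inclusion_probabilities(xs, gain = 5, cfg)
  expect_true(all(diff(p) < 0))  # smaller preferred
  expect_true(all(p > 0 & p < 1))

  # gain -> 0 gives 1/2 everywhere
  p0 <- inclusion_probabilities(xs, gain = 1e-9, cfg)
  expect_equal(p0, rep(0.5, length(xs)), tolerance = 1e-6)

  cfg2 <- scenario_config(2)
  p2 <- inclusion_probabilities(seq(0, 1, 0.25), gain = 3, cfg2)
  expect_true(all(diff(p2) > 0))  # larger preferred

  expect_error(inclusion_probabilities(rep(1, 5), 2, cfg), "constant")
})

test_that("tune_gain calibrates the mean inclusion probability", {
  cfg <- scenario_config(1)
  xs <- seq(0, 1, length.out = 500)  # fine uniform grid
  cal <- tune_gain(xs, cfg)
  expect_lt(abs(cal$mean_prob - 0.10), 1e-4)

  # brute-force grid over log-gain agrees to 3 significant figures
  grid <- exp(seq(log(1e-6), log(1e6), length.out = 10000))
  mp <- vapply(grid, function(g)
    mean(inclusion_probabilities(xs, g, cfg, pivot = cal$pivot)),
    numeric(1))
  g_grid <- grid[which.min(abs(mp - 0.10))]
  expect_equal(cal$gain, g_grid, tolerance = 5e-3)

  # invariance to affine rescaling of the indicator
  cal2 <- tune_gain(3 + 10 * xs, cfg)
  expect_equal(cal2$gain, cal$gain, tolerance = 1e-6)

  # target rate 0.5 is rejected
  cfg5 <- scenario_config(1, target_rate = 0.499)
  expect_silent(tune_gain(xs, cfg5))
  cfg5$target_rate <- 0.5
  expect_error(tune_gain(xs, cfg5), "0.5")
})

test_that("make_trial follows the split protocol and is reproducible", {
  ds <- default_benchmark(seed = 1, n_molecules = 1000)
  cfg <- scenario_config(1)
  tr <- make_trial(ds, cfg, seed = 4)
  expect_equal(length(tr$test_ids), 100L)          # 10% of the dataset
  expect_length(intersect(tr$train_ids, tr$test_ids), 0)
  expect_true(all(tr$train_ids %in% names(tr$inclusion_probs)))

  tr2 <- make_trial(ds, cfg, seed = 4)
  expect_identical(tr, tr2)
  tr3 <- make_trial(ds, cfg, seed = 5)
  expect_false(identical(tr$train_ids, tr3$train_ids))
})

test_that("realized train fraction matches the tuned rate on average", {
  ds <- default_benchmark(seed = 1, n_molecules = 600)
  cfg <- scenario_config(1, n_trials = 15)
  splits <- run_trials(ds, cfg, base_seed = 11)
  expect_length(splits, 15L)
  fracs <- vapply(splits, function(s)
    length(s$train_ids) / length(s$pool_ids), numeric(1))
  n_pool <- length(splits[[1]]$pool_ids)
  se <- sqrt(0.1 * 0.9 / (n_pool * length(splits)))
  expect_lt(abs(mean(fracs) - 0.10), 3 * se)
})

test_that("biased sampling shifts the train indicator toward the preferred end", {
  ds <- default_benchmark(seed = 1, n_molecules = 800)
  for (sc in list(scenario_config(1, n_trials = 5),
                  scenario_config(2, n_trials = 5),
                  scenario_config(3, aux_property = "gap_like", n_trials = 5),
                  scenario_config(4, target_property = "target_self",
                                  n_trials = 5))) {
    splits <- run_trials(ds, sc, base_seed = 21)
    shift <- vapply(splits, function(s) {
      mean(indicator_values(ds, sc, s$train_ids)) -
        mean(indicator_values(ds, sc, s$pool_ids))
    }, numeric(1))
    if (sc$direction == "smaller_preferred") {
      expect_true(all(shift < 0))
    } else {
      expect_true(all(shift > 0))
    }
  }
})
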
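#' Configure a biased-sampling scenario
#'
#' The four scenarios prefer, respectively: (1) molecules with fewer
#' atoms, (2) molecules with a smaller proportion of single bonds, i.e. a
#' larger proportion of double/triple/aromatic bonds, (3) molecules with
#' a higher gap-like auxiliary property, (4) molecules with a higher
#' target value. Each molecule's inclusion chance is a sigmoid of its
#' (min-max normalized) indicator, with the sigmoid gain calibrated so
#' the average inclusion probability equals `target_rate`.
#'
#' @param scenario integer 1-4.
#' @param aux_property auxiliary property name used as scenario 3's
#'   indicator (the gap-like column); required for scenario 3.
#' @param target_property target property name; required for scenario 4
#'   (and used by training code for all scenarios).
#' @param target_rate average inclusion probability the gain is tuned to
#'   (default 0.10).
#' @param test_fraction uniform test split fraction (default 0.10).
#' @param n_trials number of repeated samplings (default 30).
#' @return a `scenario_config` object with fields `indicator` and
#'   `direction` filled in from the scenario number.
#' @export
scenario_config <- function(scenario, aux_property = NULL,
                            target_property = NULL,
                            target_rate = 0.10, test_fraction = 0.10,
                            n_trials = 30L) {
  stopifnot(scenario %in% 1:4, target_rate > 0, target_rate < 1,
            test_fraction > 0, test_fraction < 1, n_trials >= 1L)
  indicator <- switch(scenario, "n_atoms", "frac_nonsingle",
                      "aux_property", "target_property")
  direction <- switch(scenario, "smaller_preferred", "larger_preferred",
                      "larger_preferred", "larger_preferred")
  if (scenario == 3L && is.null(aux_property))
    stop("scenario 3 needs an auxiliary (gap-like) property column; ",
         "datasets without one cannot run this scenario")
  if (scenario == 4L && is.null(target_property))
    stop("scenario 4 needs the target property name")
  structure(list(scenario = as.integer(scenario), indicator = indicator,
                 direction = direction, aux_property = aux_property,
                 target_property = target_property,
                 target_rate = target_rate, test_fraction = test_fraction,
                 n_trials = as.integer(n_trials)),
            class = "scenario_config")
}

#' Scenario indicator for one molecule
#'
#' @param g a [mol_graph].
#' @param props the dataset property table (data.frame with `id`), used
#'   for scenarios 3-4.
#' @param cfg a [scenario_config].
#' @return the scalar selection indicator: atom count (scenario 1),
#'   fraction of non-single bonds (scenario 2; 0 for bondless graphs),
#'   auxiliary property (3), or target value (4).
#' @export
indicator_value <- function(g, props, cfg) {
  switch(cfg$indicator,
         n_atoms = length(g$nodes),
         frac_nonsingle = graph_functional(g, "frac_nonsingle"),
         aux_property = lookup_prop(props, g$id, cfg$aux_property),
         target_property = lookup_prop(props, g$id, cfg$target_property))
}

lookup_prop <- function(props, id, col) {
  if (is.null(col) || !col %in% names(props))
    stop("required property column missing: ", col)
  props[[col]][match(id, props$id)]
}

#' Scenario indicators for a whole dataset
#' @param ds a [mol_dataset].
#' @param cfg a [scenario_config].
#' @param ids molecule ids (default: all, in dataset order).
#' @export
indicator_values <- function(ds, cfg, ids = dataset_ids(ds)) {
  sub <- match(ids, dataset_ids(ds))
  vapply(ds$graphs[sub], indicator_value, numeric(1),
         props = ds$properties, cfg = cfg)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

minmax_normalize <- function(xs) {
  r <- range(xs)
  if (r[2] - r[1] <= 0) stop("constant indicator vector: normalization undefined")
  (xs - r[1]) / (r[2] - r[1])
}

#' Sigmoid inclusion probabilities
#'
#' Indicators are min-max normalized to `[0, 1]`; the inclusion chance of
#' molecule `i` is `sigmoid(gain * (pivot - x_i))` when smaller values
#' are preferred and `sigmoid(gain * (x_i - pivot))` when larger values
#' are preferred, where `pivot` is the empirical quantile of the
#' normalized indicator at level `target_rate / 2` from the preferred
#' end (see [tune_gain()]). Probabilities are strictly monotone in the
#' indicator in the preferred direction for any positive gain.
#'
#' @param xs raw indicator vector (at least two distinct values).
#' @param gain positive sigmoid gain.
#' @param cfg a [scenario_config] (supplies direction and target rate).
#' @param pivot optional pivot on the normalized scale; computed from
#'   `cfg$target_rate` if omitted.
#' @return vector of inclusion probabilities in (0, 1).
#' @export
inclusion_probabilities <- function(xs, gain, cfg, pivot = NULL) {
  stopifnot(gain > 0)
  xn <- minmax_normalize(xs)
  if (is.null(pivot)) pivot <- scenario_pivot(xn, cfg)
  if (cfg$direction == "smaller_preferred") {
    sigmoid(gain * (pivot - xn))
  } else {
    sigmoid(gain * (xn - pivot))
  }
}

scenario_pivot <- function(xn, cfg) {
  lvl <- if (cfg$direction == "smaller_preferred") {
    cfg$target_rate / 2
  } else {
    1 - cfg$target_rate / 2
  }
  unname(quantile(xn, lvl, type = 7))
}

#' Calibrate the sigmoid gain to the target average inclusion rate
#'
#' Bisection on `gain` in `[1e-6, 1e6]` for
#' `mean(inclusion_probabilities(xs, gain)) = target_rate`. As the gain
#' goes to zero every probability tends to 1/2; as it grows the mean
#' tends to the indicator mass beyond the pivot quantile
#' (about `target_rate / 2`), so a root exists for any
#' `target_rate < 0.5` and the bisection converges to
#' `|mean(p) - target_rate| < tol`.
#'
#' @param xs raw indicator vector.
#' @param cfg a [scenario_config] with `target_rate < 0.5`.
#' @param tol calibration tolerance on the mean probability (default 1e-5).
#' @return list with `gain`, `pivot` (normalized scale) and the achieved
#'   `mean_prob`.
#' @export
tune_gain <- function(xs, cfg, tol = 1e-5) {
  if (cfg$target_rate >= 0.5)
    stop("target_rate must be below 0.5 (gain -> 0 gives mean 0.5)")
  xn <- minmax_normalize(xs)
  pivot <- scenario_pivot(xn, cfg)
  mean_p <- function(gain)
    mean(inclusion_probabilities(xs, gain, cfg, pivot = pivot))
  lo <- 1e-6; hi <- 1e6
  f_lo <- mean_p(lo) - cfg$target_rate
  f_hi <- mean_p(hi) - cfg$target_rate
  if (f_lo * f_hi > 0) {
    stop(sprintf(paste0("target rate %.4f not achievable: mean probability ",
                        "ranges over [%.4f, %.4f] for gains in [1e-6, 1e6]"),
                 cfg$target_rate, min(mean_p(hi), mean_p(lo)),
                 max(mean_p(hi), mean_p(lo))))
  }
  for (it in 1:200) {
    mid <- sqrt(lo * hi)  # bisection in log-gain
    f_mid <- mean_p(mid) - cfg$target_rate
    if (abs(f_mid) < tol) break
    if (f_mid * f_lo <= 0) { hi <- mid; f_hi <- f_mid } else { lo <- mid; f_lo <- f_mid }
  }
  list(gain = mid, pivot = pivot, mean_prob = mean_p(mid))
}

#' Draw one biased train / unbiased test split
#'
#' Protocol: (1) a uniform random test set of `round(test_fraction * n)`
#' molecules; (2) scenario indicators on the remaining pool; (3) gain
#' calibration on the pool; (4) one independent Bernoulli(p_i) inclusion
#' draw per pool molecule (sampling without replacement: each molecule
#' is drawn at most once, so train and test are disjoint). All
#' randomness derives from `seed`.
#'
#' @param ds a [mol_dataset].
#' @param cfg a [scenario_config].
#' @param seed integer seed.
#' @return a `trial_split`: `train_ids`, `test_ids`, `pool_ids`,
#'   `inclusion_probs` (named, over the pool), `gain`, `seed`.
#' @export
make_trial <- function(ds, cfg, seed = 1L) {
  ids <- dataset_ids(ds)
  n <- length(ids)
  n_test <- round(cfg$test_fraction * n)
  with_seed(seed, {
    test_ids <- sample(ids, n_test)
    pool_ids <- setdiff(ids, test_ids)
    xs <- indicator_values(ds, cfg, pool_ids)
    cal <- tune_gain(xs, cfg)
    p <- inclusion_probabilities(xs, cal$gain, cfg, pivot = cal$pivot)
    names(p) <- pool_ids
    train_ids <- pool_ids[runif(length(pool_ids)) < p]
    if (length(train_ids) == 0L)
      stop("empty biased train draw for seed ", seed,
           "; increase the dataset size or target rate")
    structure(list(train_ids = train_ids, test_ids = test_ids,
                   pool_ids = pool_ids, inclusion_probs = p,
                   gain = cal$gain, seed = as.integer(seed)),
              class = "trial_split")
  })
}

#' @export
print.trial_split <- function(x, ...) {
  cat(sprintf("<trial_split: %d train / %d test (pool %d), gain %.3g, seed %d>\n",
              length(x$train_ids), length(x$test_ids), length(x$pool_ids),
              x$gain, x$seed))
  invisible(x)
}

#' Repeat the biased-sampling procedure
#'
#' Produces `cfg$n_trials` independent splits with seeds
#' `base_seed + 0, ..., base_seed + n_trials - 1`.
#'
#' @param ds a [mol_dataset].
#' @param cfg a [scenario_config].
#' @param base_seed first trial seed.
#' @return list of `trial_split` objects.
#' @export
run_trials <- function(ds, cfg, base_seed = 1L) {
  lapply(seq_len(cfg$n_trials) - 1L,
         function(k) make_trial(ds, cfg, seed = base_seed + k))
}
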
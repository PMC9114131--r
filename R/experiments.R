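#' Configure an end-to-end scenario experiment
#'
#' One config drives the full protocol: repeated biased sampling,
#' training of the requested methods (an uncorrected baseline, IPS,
#' CFR), test-set evaluation, aggregation with paired significance
#' testing, and indicator-binned diagnostics.
#'
#' @param target property column to predict.
#' @param scenario a [scenario_config].
#' @param methods subset of `c("baseline", "ips", "cfr")`; the baseline
#'   is required whenever significance stars are wanted.
#' @param mpnn an [mpnn_config] shared by all methods.
#' @param train a [train_config] (its seed field is overridden per
#'   trial).
#' @param alpha CFR IPM weight.
#' @param n_trials number of sampling/training repetitions.
#' @param base_seed master seed; every random draw in the experiment
#'   derives from it.
#' @param output_dir optional directory for per-trial checkpoint files
#'   (JSON) enabling resumption; `NULL` keeps everything in memory.
#' @param propensity_clip lower clipping bound of propensity scores.
#' @export
experiment_config <- function(target, scenario,
                              methods = c("baseline", "ips", "cfr"),
                              mpnn = mpnn_config(),
                              train = train_config(),
                              alpha = 10, n_trials = scenario$n_trials,
                              base_seed = 1L, output_dir = NULL,
                              propensity_clip = 0.01) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(length(methods) >= 1L)
  if (length(setdiff(methods, "baseline")) > 0 && !"baseline" %in% methods)
    stop("baseline is required to compute significance stars for ",
         paste(setdiff(methods, "baseline"), collapse = ", "))
  structure(list(target = target, scenario = scenario, methods = methods,
                 mpnn = mpnn, train = train, alpha = alpha,
                 n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed),
                 output_dir = output_dir,
                 propensity_clip = propensity_clip),
            class = "experiment_config")
}

run_one_trial <- function(ds, cfg, trial_seed) {
  sc <- cfg$scenario
  split <- make_trial(ds, sc, seed = trial_seed)
  train_ds <- subset_dataset(ds, split$train_ids)
  test_ds <- subset_dataset(ds, split$test_ids)
  y_train <- property_values(ds, cfg$target, split$train_ids)
  y_test <- property_values(ds, cfg$target, split$test_ids)
  tcfg <- cfg$train
  tcfg$seed <- as.integer(derive_seed(trial_seed, 77L) %% 2147483L)
  res <- list(seed = trial_seed,
              n_train = length(split$train_ids),
              n_test = length(split$test_ids),
              gain = split$gain,
              train_indicator = indicator_values(ds, sc, split$train_ids),
              test_indicator = indicator_values(ds, sc, split$test_ids),
              y_test = y_test,
              mae = list(), pred = list())
  for (method in cfg$methods) {
    pred <- switch(method,
      baseline = {
        m <- mpnn_init(cfg$mpnn, ds$atom_vocab,
                       seed = derive_seed(tcfg$seed, 4L),
                       bond_vocab = ds$bond_vocab)
        m <- mpnn_train(m, train_ds$graphs, y_train, tcfg)
        mpnn_predict(m, test_ds$graphs)
      },
      ips = {
        pcfg <- cfg$mpnn; pcfg$head <- "binary_classification"
        prop <- fit_propensity(train_ds$graphs, test_ds$graphs, pcfg, tcfg,
                               ds$atom_vocab,
                               clip_floor = cfg$propensity_clip,
                               bond_vocab = ds$bond_vocab)
        rcfg <- cfg$mpnn; rcfg$head <- "regression"
        m <- fit_ips_regressor(train_ds$graphs, y_train, prop, rcfg, tcfg,
                               ds$atom_vocab, bond_vocab = ds$bond_vocab)
        res$propensity_accuracy <- prop$accuracy
        mpnn_predict(m, test_ds$graphs)
      },
      cfr = {
        m <- cfr_init(cfg$mpnn, ds$atom_vocab, alpha = cfg$alpha,
                      seed = derive_seed(tcfg$seed, 6L),
                      bond_vocab = ds$bond_vocab)
        m <- train_cfr(m, train_ds$graphs, y_train, test_ds$graphs, tcfg)
        res$domain_accuracy <- m$domain_accuracy
        cfr_predict(m, test_ds$graphs)
      })
    res$pred[[method]] <- pred
    res$mae[[method]] <- mae(y_test, pred)
  }
  res
}

#' Run a full biased-sampling experiment
#'
#' For each trial seed: draw the biased train / unbiased test split,
#' train every requested method, predict on the test set and record the
#' MAE. Aggregates mean and standard deviation per method, paired
#' t-statistics and stars against the baseline, indicator-binned MAE
#' tables, and averaged train/test indicator densities. If
#' `cfg$output_dir` is set, each trial is checkpointed to a JSON file
#' and finished trials are reused on rerun.
#'
#' @param ds a [mol_dataset].
#' @param cfg an [experiment_config].
#' @param n_bins number of indicator bins for the diagnostics.
#' @return an `eval_report`.
#' @export
run_experiment <- function(ds, cfg, n_bins = 8L) {
  trials <- vector("list", cfg$n_trials)
  failures <- character(0)
  for (k in seq_len(cfg$n_trials)) {
    trial_seed <- cfg$base_seed + k - 1L
    ckpt <- NULL
    if (!is.null(cfg$output_dir)) {
      dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
      ckpt <- file.path(cfg$output_dir, sprintf("trial_%04d.json", k))
      if (file.exists(ckpt)) {
        trials[[k]] <- jsonlite::fromJSON(ckpt, simplifyVector = TRUE)
        trials[[k]]$mae <- as.list(trials[[k]]$mae)
        trials[[k]]$pred <- as.list(trials[[k]]$pred)
        next
      }
    }
    res <- tryCatch(run_one_trial(ds, cfg, trial_seed),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("trial %d: %s", k, conditionMessage(res)))
      next
    }
    trials[[k]] <- res
    if (!is.null(ckpt))
      jsonlite::write_json(res, ckpt, auto_unbox = TRUE, digits = NA)
  }
  done <- !vapply(trials, is.null, logical(1))
  if (!any(done)) stop("every trial failed:\n", paste(failures, collapse = "\n"))
  trials <- trials[done]

  methods <- cfg$methods
  mae_tab <- sapply(methods, function(m)
    vapply(trials, function(tr) tr$mae[[m]], numeric(1)))
  mae_tab <- matrix(mae_tab, ncol = length(methods),
                    dimnames = list(NULL, methods))
  summary <- data.frame(method = methods,
                        mean_mae = colMeans(mae_tab),
                        sd_mae = apply(mae_tab, 2, sd),
                        row.names = NULL)
  tests <- list()
  if ("baseline" %in% methods) {
    for (m in setdiff(methods, "baseline")) {
      tests[[m]] <- paired_test(mae_tab[, "baseline"], mae_tab[, m])
    }
  }
  binned <- lapply(stats::setNames(methods, methods), function(m) {
    tabs <- lapply(trials, function(tr)
      binned_mae(tr$y_test, tr$pred[[m]], tr$test_indicator, n_bins))
    agg <- tabs[[1]][c("bin_low", "bin_high", "mid")]
    err_sum <- Reduce(`+`, lapply(tabs, function(b)
      ifelse(is.na(b$mae), 0, b$mae * b$n)))
    n_sum <- Reduce(`+`, lapply(tabs, function(b) b$n))
    agg$n <- n_sum
    agg$mae <- ifelse(n_sum > 0, err_sum / pmax(n_sum, 1), NA_real_)
    agg
  })
  dens <- density_summary(lapply(trials, `[[`, "train_indicator"),
                          lapply(trials, `[[`, "test_indicator"), n_bins)
  report <- structure(list(config = cfg, n_trials_done = length(trials),
                           per_trial_mae = mae_tab, summary = summary,
                           tests = tests, binned_mae = binned,
                           densities = dens, trials = trials,
                           failures = failures,
                           partial = length(failures) > 0),
                      class = "eval_report")
  if (!is.null(cfg$output_dir)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_to_json <- function(report) {
  list(target = report$config$target,
       scenario = report$config$scenario$scenario,
       n_trials = report$n_trials_done,
       per_trial_mae = as.data.frame(report$per_trial_mae),
       summary = report$summary,
       tests = lapply(report$tests, function(t)
         list(t = t$t, p = t$p, stars = t$stars)),
       binned_mae = report$binned_mae,
       densities = report$densities,
       failures = report$failures)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: scenario %d, target '%s', %d trial(s)%s>\n",
              x$config$scenario$scenario, x$config$target, x$n_trials_done,
              if (x$partial) " [PARTIAL]" else ""))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    stars <- if (!is.null(x$tests[[s$method[i]]]))
      x$tests[[s$method[i]]]$stars else ""
    cat(sprintf("  %-9s MAE %.4f +/- %.4f %s\n",
                s$method[i], s$mean_mae[i], s$sd_mae[i], stars))
  }
  invisible(x)
}
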
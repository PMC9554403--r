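#' Run configuration for an end-to-end synthetic study
#'
#' @param n_lambs number of lambs.
#' @param schedule a [pressure_schedule()].
#' @param sim_config a [simulation_config()].
#' @param feat_config a [feature_config()].
#' @param alpha backward-elimination threshold.
#' @param seed master integer seed, recorded in every output's metadata.
#' @param out_dir output directory for the report bundle.
#' @param make_plot write an observed-vs-predicted SVG plot.
#' @return a list of class `run_config`.
#' @export
run_config <- function(n_lambs = 7L,
                       schedule = default_pressure_schedule(),
                       sim_config = simulation_config(),
                       feat_config = feature_config(),
                       alpha = 0.05,
                       seed = 1L,
                       out_dir = tempfile("lusaer_run_"),
                       make_plot = TRUE) {
  structure(list(n_lambs = as.integer(n_lambs), schedule = schedule,
                 sim_config = sim_config, feat_config = feat_config,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir,
                 make_plot = isTRUE(make_plot)),
            class = "run_config")
}

#' Read/write a run configuration as YAML
#'
#' The file representation round-trips losslessly through
#' [read_run_config()].
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- list(
    n_lambs = config$n_lambs,
    schedule = list(pressure_cmH2O = config$schedule$pressure_cmH2O,
                    phase = config$schedule$phase),
    sim_config = unclass(config$sim_config),
    feat_config = unclass(config$feat_config),
    alpha = config$alpha, seed = config$seed, out_dir = config$out_dir,
    make_plot = config$make_plot
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    n_lambs = x$n_lambs,
    schedule = pressure_schedule(unlist(x$schedule$pressure_cmH2O),
                                 unlist(x$schedule$phase)),
    sim_config = do.call(simulation_config, x$sim_config),
    feat_config = do.call(feature_config, x$feat_config),
    alpha = x$alpha, seed = x$seed, out_dir = x$out_dir,
    make_plot = x$make_plot
  )
}

# assemble the merged per-observation analysis table for a cohort,
# streaming clips/phantoms one at a time (images are never all in memory)
cohort_analysis_table <- function(n_lambs, schedule, sim_config, feat_config,
                                  seed, verbose = FALSE) {
  plan <- cohort_plan(n_lambs, schedule, seed)
  rois <- default_rois(sim_config)
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    clip <- generate_clip(sim_config, plan$true_air_fraction[i],
                          plan$phase[i], plan$obs_seed[i])
    feats <- clip_features(clip, rois, feat_config)
    ct <- generate_ct_phantom(sim_config, plan$true_air_fraction[i],
                              derive_seed(plan$obs_seed[i], 101L))
    meas <- measure_ct_aeration(ct, sim_config$air_threshold, depth_mm = 10)
    rows[[i]] <- cbind(
      plan[i, c("lamb_id", "lung_side", "pressure_cmH2O", "phase",
                "true_air_fraction")],
      grade = clip$true_grade,
      feats,
      ct_air_proportion = meas$proportion,
      percent_air = meas$proportion * 100,
      row.names = NULL)
    if (verbose && i %% 20 == 0)
      message(sprintf("  observation %d / %d", i, nrow(plan)))
  }
  do.call(rbind, rows)
}

# the four simple models of the reporting grid, each against percent air
simple_model_grid <- function(tab, subsets = c("all", "inflation", "deflation")) {
  stats_def <- list(
    mpi = function(d) d$mpi,
    cov = function(d) d$cov,
    auc_parallel_log = function(d) log_linearize(d$auc_parallel),
    auc_perpendicular = function(d) d$auc_perpendicular
  )
  out <- list()
  for (st in names(stats_def)) {
    xall <- stats_def[[st]](tab)
    for (ss in subsets) {
      fit <- tryCatch(
        fit_simple_regression(xall, tab$percent_air, phase = tab$phase,
                              subset = ss, covariate_name = st),
        error = function(e) e)
      if (inherits(fit, "error")) {
        out[[length(out) + 1L]] <- data.frame(
          statistic = st, subset = ss, n = NA_integer_, r_squared = NA_real_,
          slope = NA_real_, intercept = NA_real_, slope_p = NA_real_,
          pi95_halfwidth_pct = NA_real_, note = conditionMessage(fit),
          stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          statistic = st, subset = ss, n = fit$n, r_squared = fit$r_squared,
          slope = unname(fit$slopes[1]), intercept = fit$intercept,
          slope_p = unname(fit$coefficient_p_values[2]),
          pi95_halfwidth_pct = fit$pi95_halfwidth_at_mean, note = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Run the full synthetic study end to end
#'
#' Generates a cohort (streaming one observation at a time), extracts the
#' four image statistics per clip, measures the CT superficial air
#' proportion, summarises air proportion by grade, fits the four simple
#' regressions on the type-1/2 observations for all/inflation/deflation
#' subsets, fits the multivariate model with backward elimination, and
#' writes the report bundle (CSV tables, JSON model report, optional SVG
#' plot) to `config$out_dir`. Reruns with an identical configuration are
#' bit-identical for all tables.
#'
#' @param config a [run_config()].
#' @param verbose log per-stage progress to stderr.
#' @return (invisibly) a list with `table` (merged per-observation data),
#'   `grade_summary`, `simple_models`, `multivariate` (fit + trace),
#'   `predictions` and the output paths.
#' @export
run_end_to_end <- function(config, verbose = FALSE) {
  if (!inherits(config, "run_config")) stop_domain("config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    t0 <- Sys.time()
    r <- tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    if (verbose)
      message(sprintf("[%s] %.1f s", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }

  tab <- stage("simulate+features+ct", cohort_analysis_table(
    config$n_lambs, config$schedule, config$sim_config, config$feat_config,
    config$seed, verbose = verbose))

  grade_summary <- stage("grade summary",
    grade_vs_air_summary(tab$grade, tab$ct_air_proportion))

  reg <- tab[tab$grade %in% c(1, 2), , drop = FALSE]
  simple_models <- stage("simple models", simple_model_grid(reg))

  reg_feats <- if (nrow(reg))
    data.frame(mpi = reg$mpi, cov = reg$cov,
               auc_parallel_log = log_linearize(reg$auc_parallel),
               auc_perpendicular = reg$auc_perpendicular,
               grade = reg$grade) else NULL

  multivariate <- stage("multivariate model", {
    if (is.null(reg_feats) || nrow(reg) < 8L) {
      warning("too few type-1/2 observations for the multivariate model; skipped")
      NULL
    } else fit_multivariate(reg_feats, reg$percent_air, alpha = config$alpha)
  })

  predictions <- stage("predictions", {
    if (is.null(multivariate)) NULL else
      cbind(reg[, c("lamb_id", "lung_side", "pressure_cmH2O", "phase",
                    "percent_air")],
            predict_air_proportion(multivariate$fit, reg_feats))
  })

  paths <- stage("write bundle", {
    p <- list(
      manifest = file.path(config$out_dir, "cohort_manifest.csv"),
      features = file.path(config$out_dir, "features.csv"),
      grade_summary = file.path(config$out_dir, "grade_summary.csv"),
      simple_models = file.path(config$out_dir, "simple_models.csv"),
      multivariate = file.path(config$out_dir, "multivariate_model.json"),
      predictions = file.path(config$out_dir, "predictions.csv"),
      run_meta = file.path(config$out_dir, "run_metadata.json")
    )
    man <- tab[, c("lamb_id", "lung_side", "pressure_cmH2O", "phase",
                   "true_air_fraction", "grade", "ct_air_proportion")]
    names(man) <- c("lamb_id", "lung_side", "pressure_cmH2O", "phase",
                    "true_air_fraction", "lus_grade",
                    "ct_air_proportion")
    write_csv_plain(man, p$manifest)
    write_csv_plain(tab, p$features)
    gs <- grade_summary
    gs[, 3:5] <- round(gs[, 3:5], 1)              # percentages to 1 decimal
    write_csv_plain(gs, p$grade_summary)
    sm <- simple_models
    sm$pi95_halfwidth_pct <- round(sm$pi95_halfwidth_pct, 1)
    write_csv_plain(sm, p$simple_models)
    mv_report <- if (is.null(multivariate))
      list(seed = config$seed, alpha = config$alpha, skipped = TRUE)
    else list(
      seed = config$seed,
      alpha = config$alpha,
      retained = names(multivariate$fit$slopes),
      intercept = multivariate$fit$intercept,
      slopes = as.list(multivariate$fit$slopes),
      r_squared = multivariate$fit$r_squared,
      pi95_halfwidth_pct = multivariate$fit$pi95_halfwidth_at_mean,
      n = multivariate$fit$n,
      elimination_trace = multivariate$trace
    )
    jsonlite::write_json(mv_report, p$multivariate, auto_unbox = TRUE,
                         digits = NA)
    if (!is.null(predictions)) write_csv_plain(predictions, p$predictions)
    jsonlite::write_json(list(seed = config$seed, n_lambs = config$n_lambs,
                              n_observations = nrow(tab),
                              package_version = "0.1.0"),
                         p$run_meta, auto_unbox = TRUE, digits = NA)
    if (config$make_plot && !is.null(predictions) && capabilities("cairo")) {
      p$plot <- file.path(config$out_dir, "observed_vs_predicted.svg")
      plot_observed_vs_predicted(predictions, p$plot)
    }
    p
  })

  invisible(list(table = tab, grade_summary = grade_summary,
                 simple_models = simple_models, multivariate = multivariate,
                 predictions = predictions, paths = paths))
}

# CSV writer with deterministic formatting; headers carry units
write_csv_plain <- function(df, path) {
  utils::write.csv(format(df, trim = TRUE, digits = 10, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Observed-vs-predicted plot with 95% prediction interval bars
#'
#' @param predictions prediction table from [run_end_to_end()].
#' @param path output SVG path.
#' @return `path`, invisibly.
#' @export
plot_observed_vs_predicted <- function(predictions, path) {
  grDevices::svg(path, width = 6, height = 6)
  on.exit(grDevices::dev.off())
  obs <- predictions$percent_air
  est <- predictions$point_estimate
  graphics::plot(obs, est, pch = 19, cex = 0.6, col = "grey30",
                 xlab = "Actual proportion of air by CT (%)",
                 ylab = "Estimated proportion of air (%)",
                 xlim = c(0, 100), ylim = range(c(0, 100, predictions$pi95_low,
                                                  predictions$pi95_high)))
  graphics::segments(obs, predictions$pi95_low, obs, predictions$pi95_high,
                     col = grDevices::adjustcolor("darkorange", 0.5))
  graphics::abline(0, 1, col = "steelblue", lwd = 2)
  invisible(path)
}
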
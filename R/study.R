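# Batch simulation studies: episode generation across tasks, detection,
# emission, evaluation, ablations, and the per-marker report.

.marker_scope <- list(
  Sigma1 = c("motor_control", "inhibition", "overload"),
  AcceptH1 = c("motor_control", "inhibition", "overload"),
  RejectH1 = c("inhibition", "overload"),
  DriftEvent = c("motor_control", "overload"),
  ConflictEscalate = c("inhibition", "overload"))

#' Run a simulation study
#'
#' Simulates `n_episodes_per_task` episodes for each task (each fault-bearing
#' with probability `fault_rate`), runs detection and symbolic emission
#' (honouring ablation flags), scores every trace against ground truth, and
#' aggregates traceability, anticipation latency and per-marker statistics.
#' Fully reproducible from `root_seed`.
#'
#' Per-marker statistics are reported over each marker's task scope
#' (commitment over all tasks; drift over motor control and overload;
#' rejection and conflict over inhibition and overload), matching how the
#' markers partition across fault regimes.
#'
#' @param config a [study_config()].
#' @param overrides named list of episode-level overrides applied to every
#'   episode (any of `noise_sd`, `behavior_lag_mean`, `behavior_lag_sd`);
#'   used by [calibrate_study()].
#' @param output_dir optional directory; when given, traces, the report and
#'   a checksummed run manifest are written there.
#' @return A `cog_study` list: `report` (aggregates and the per-marker
#'   table), `episodes` (per-episode data.frame), `traces`, `truths`,
#'   `config`.
#' @examples
#' st <- run_study(study_config(n_episodes_per_task = 3, root_seed = 7))
#' st$report$t_trace_mean
#' @export
run_study <- function(config, overrides = NULL, output_dir = NULL) {
  if (!inherits(config, "cog_study_config"))
    stop_config("config must be a study_config()")
  if (!length(config$tasks)) stop_config("task set must be non-empty")
  ok_over <- c("noise_sd", "behavior_lag_mean", "behavior_lag_sd")
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), ok_over)
    if (length(bad)) stop_config("unsupported override(s): ",
                                 paste(bad, collapse = ", "))
  }
  dparams <- config$discriminator
  dis <- dparams$disable
  if ("discriminator_drift" %in% config$ablation) dis <- c(dis, "drift")
  if ("discriminator_conflict" %in% config$ablation) dis <- c(dis, "conflict")
  dparams$disable <- unique(dis)
  emit_on <- !("emitter" %in% config$ablation)

  n <- config$n_episodes_per_task
  rows <- list(); traces <- list(); truths <- list()
  k <- 0L
  for (task in config$tasks) {
    for (i in seq_len(n)) {
      k <- k + 1L
      seed_i <- derive_seed(config$root_seed, paste0("episode.", task), i)
      faulted <- with_seed(derive_seed(config$root_seed,
                                       paste0("faultflag.", task), i),
                           stats::runif(1) < config$fault_rate)
      args <- c(list(task_type = task, seed = seed_i, faulted = faulted),
                overrides)
      ep_cfg <- do.call(task_scenario, args)
      ep <- simulate_episode(ep_cfg)
      events <- detect_events(ep, dparams)
      eid <- sprintf("%s-%04d", task, i)
      trace <- if (emit_on) emit_trace(events, episode_id = eid)
               else emit_trace(events[0, , drop = FALSE], episode_id = eid)
      ts <- traceability_score(trace, ep$truth, config$tolerance)
      lat <- anticipation_latency(trace, ep$truth)
      s1 <- trace$hypothesis[trace$type == "Sigma1"]
      rows[[k]] <- data.frame(
        task = task, index = i, episode_id = eid, seed = seed_i,
        faulted = faulted,
        fault_onset = ep$truth$fault_onset %||% NA_real_,
        error_onset = ep$truth$error_onset %||% NA_real_,
        n_markers = nrow(trace),
        t_trace = as.numeric(ts),
        anticipation = lat %||% NA_real_,
        sigma1_correct = if (length(s1))
          identical(s1[1], ep$truth$true_intent) else NA,
        stringsAsFactors = FALSE)
      traces[[k]] <- trace
      truths[[k]] <- ep$truth
    }
  }
  episodes <- do.call(rbind, rows)

  per_task <- vapply(config$tasks, function(task)
    mean(episodes$t_trace[episodes$task == task]), numeric(1))
  lat <- episodes$anticipation[!is.na(episodes$anticipation)]
  marker_table <- do.call(rbind, lapply(names(.marker_scope), function(ty) {
    scope <- intersect(.marker_scope[[ty]], config$tasks)
    if (!length(scope)) return(NULL)
    sel <- episodes$task %in% scope
    ms <- marker_stats(traces[sel], truths[sel], config$tolerance)
    row <- ms[ms$marker == ty, ]
    row$tasks <- paste(scope, collapse = "+")
    row
  }))
  report <- list(
    n_episodes = nrow(episodes),
    t_trace_mean = mean(episodes$t_trace),
    t_trace_per_task = per_task,
    anticipation_mean = if (length(lat)) mean(lat) else NA_real_,
    anticipation_sd = if (length(lat) > 1) stats::sd(lat) else NA_real_,
    anticipation_n = length(lat),
    marker_table = marker_table,
    ablation = config$ablation,
    config_fingerprint = fingerprint(config[setdiff(names(config),
                                                    "discriminator")]))
  out <- structure(list(report = report, episodes = episodes,
                        traces = traces, truths = truths, config = config),
                   class = "cog_study")
  if (!is.null(output_dir)) .write_study(out, output_dir)
  out
}

.write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tdir <- file.path(dir, "traces")
  dir.create(tdir, showWarnings = FALSE)
  for (tr in study$traces)
    write_trace(tr, file.path(tdir, paste0(attr(tr, "episode_id"),
                                           ".jsonl")))
  utils::write.csv(study$episodes, file.path(dir, "episodes.csv"),
                   row.names = FALSE)
  utils::write.csv(study$report$marker_table, file.path(dir, "marker_stats.csv"),
                   row.names = FALSE)
  rep <- study$report
  rep$marker_table <- NULL
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  write_manifest(dir, seeds = study$config$root_seed,
                 config_fingerprint = study$report$config_fingerprint)
  invisible(dir)
}

#' @export
print.cog_study <- function(x, ...) {
  r <- x$report
  cat(sprintf("<cog_study> %d episodes (%s), fault rate %.2f, seed %d\n",
              r$n_episodes, paste(x$config$tasks, collapse = ", "),
              x$config$fault_rate, x$config$root_seed))
  cat(sprintf("  mean traceability: %.3f (per task: %s)\n", r$t_trace_mean,
              paste(sprintf("%s=%.3f", names(r$t_trace_per_task),
                            r$t_trace_per_task), collapse = ", ")))
  if (!is.na(r$anticipation_mean))
    cat(sprintf("  anticipation latency: %.2f +/- %.2f s (n=%d)\n",
                r$anticipation_mean, r$anticipation_sd, r$anticipation_n))
  cat("  per-marker statistics:\n")
  t4 <- r$marker_table
  print.data.frame(data.frame(
    marker = t4$marker, tasks = t4$tasks,
    activation = sprintf("%.1f%%", 100 * t4$activation_frequency),
    correct = ifelse(is.na(t4$correct_prediction_rate), "-",
                     sprintf("%.1f%%", 100 * t4$correct_prediction_rate)),
    false_pos = ifelse(is.na(t4$false_positive_rate), "-",
                       sprintf("%.1f%%", 100 * t4$false_positive_rate)),
    lead_s = ifelse(is.na(t4$mean_lead_time), "-",
                    sprintf("%.2f", t4$mean_lead_time))),
    row.names = FALSE)
  invisible(x)
}

#' @export
summary.cog_study <- function(object, ...) print(object)

# named study statistics used as calibration targets
.study_stat <- function(study, name) {
  r <- study$report
  t4 <- function(ty, col) {
    v <- r$marker_table[r$marker_table$marker == ty, col]
    if (length(v)) v else NA_real_
  }
  switch(name,
    t_trace = r$t_trace_mean,
    anticipation_mean = r$anticipation_mean,
    anticipation_sd = r$anticipation_sd,
    sigma1_activation = t4("Sigma1", "activation_frequency"),
    sigma1_correct = t4("Sigma1", "correct_prediction_rate"),
    drift_activation = t4("DriftEvent", "activation_frequency"),
    drift_correct = t4("DriftEvent", "correct_prediction_rate"),
    drift_lead = t4("DriftEvent", "mean_lead_time"),
    reject_activation = t4("RejectH1", "activation_frequency"),
    conflict_activation = t4("ConflictEscalate", "activation_frequency"),
    stop_config("unknown study statistic: ", name))
}

.calibration_bounds <- list(
  noise_sd = c(0.1, 1.2),
  behavior_lag_mean = c(0.5, 8),
  behavior_lag_sd = c(0.05, 1.5),
  commit_confidence = c(0.5, 0.95),
  tolerance = c(0.25, 3))

#' Calibrate free study parameters against target statistics
#'
#' Seeded random search over a box of free parameters, minimising the mean
#' squared relative error between study statistics and targets. Used once to
#' fix the generator's free parameters; the shipped defaults are the frozen
#' result.
#'
#' @param targets named numeric vector of target statistics; names from
#'   `t_trace`, `anticipation_mean`, `anticipation_sd`, `sigma1_activation`,
#'   `sigma1_correct`, `drift_activation`, `drift_correct`, `drift_lead`,
#'   `reject_activation`, `conflict_activation` (rates as fractions).
#' @param free_params subset of `noise_sd`, `behavior_lag_mean`,
#'   `behavior_lag_sd`, `commit_confidence`, `tolerance`.
#' @param budget number of candidate evaluations beyond the initial
#'   parameters (0 returns the initial parameters with diagnostics).
#' @param config study configuration evaluated per candidate (use small
#'   `n_episodes_per_task` — each evaluation runs a full study).
#' @param init optional named initial values (defaults: package defaults).
#' @param seed integer seed for the search.
#' @return List with `par` (best parameters), `objective`, `achieved`
#'   (statistics at the optimum), `evaluations`, and the search `history`.
#' @examples
#' \donttest{
#' cal <- calibrate_study(c(anticipation_mean = 2.3),
#'                        free_params = "behavior_lag_mean", budget = 3,
#'                        config = study_config(n_episodes_per_task = 5,
#'                                              root_seed = 1))
#' }
#' @export
calibrate_study <- function(targets, free_params, budget = 20,
                            config = study_config(n_episodes_per_task = 50),
                            init = NULL, seed = 1L) {
  if (!length(targets)) stop_contract("target table must be non-empty")
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    stop_contract("targets must be named")
  bad <- setdiff(free_params, names(.calibration_bounds))
  if (length(bad)) stop_config("unsupported free parameter(s): ",
                               paste(bad, collapse = ", "))
  defaults <- list(noise_sd = 0.45,
                   behavior_lag_mean = NA_real_,  # task-specific default
                   behavior_lag_sd = 0.28,
                   commit_confidence = config$discriminator$commit_confidence,
                   tolerance = config$tolerance)
  start <- defaults[free_params]
  if (!is.null(init)) start[names(init)] <- init

  evaluate <- function(par) {
    cfg <- config
    over <- par[intersect(names(par),
                          c("noise_sd", "behavior_lag_mean",
                            "behavior_lag_sd"))]
    over <- over[!is.na(unlist(over))]
    if ("commit_confidence" %in% names(par))
      cfg$discriminator$commit_confidence <- par$commit_confidence
    if ("tolerance" %in% names(par)) cfg$tolerance <- par$tolerance
    st <- run_study(cfg, overrides = if (length(over)) over else NULL)
    achieved <- vapply(names(targets), function(nm) .study_stat(st, nm),
                       numeric(1))
    denom <- ifelse(abs(targets) > 1e-9, abs(targets), 1)
    obj <- mean(((achieved - targets) / denom)^2, na.rm = TRUE)
    if (all(is.na(achieved - targets))) obj <- Inf
    list(objective = obj, achieved = achieved)
  }

  best <- evaluate(start)
  best_par <- start
  history <- data.frame(eval = 0, objective = best$objective)
  if (budget > 0) {
    cand <- with_seed(seed, lapply(seq_len(budget), function(b)
      stats::setNames(lapply(free_params, function(p) {
        bd <- .calibration_bounds[[p]]
        stats::runif(1, bd[1], bd[2])
      }), free_params)))
    for (b in seq_len(budget)) {
      res <- evaluate(cand[[b]])
      history <- rbind(history,
                       data.frame(eval = b, objective = res$objective))
      if (res$objective < best$objective) {
        best <- res
        best_par <- cand[[b]]
      }
    }
  }
  structure(list(par = best_par, objective = best$objective,
                 achieved = best$achieved, targets = targets,
                 evaluations = nrow(history), history = history),
            class = "cog_calibration")
}

#' @export
print.cog_calibration <- function(x, ...) {
  cat("<cog_calibration>", x$evaluations, "evaluation(s), objective",
      format(x$objective, digits = 4), "\n")
  cat("  parameters:",
      paste(sprintf("%s=%.4g", names(x$par), unlist(x$par)),
            collapse = ", "), "\n")
  ach <- data.frame(target = names(x$targets), wanted = unname(x$targets),
                    achieved = unname(x$achieved[names(x$targets)]))
  print.data.frame(ach, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cog_study <- function(x, ...) {
  t4 <- x$report$marker_table
  graphics::barplot(100 * t4$activation_frequency, names.arg = t4$marker,
                    las = 2, ylab = "activation frequency (%)",
                    main = "per-marker activation", ...)
  invisible(x)
}
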
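# Readers/writers for signals, ground truth and configurations, plus the
# checksummed run manifest.

#' Write / read a multichannel signal as long-format CSV
#'
#' The CSV dialect is long format with header row `time,channel,value` and a
#' leading metadata comment line `# sampling_rate=<Hz>`; times are seconds
#' since episode start (sample 0 at t = 0).
#'
#' @param signal channels x samples numeric matrix (or a `cog_episode`).
#' @param path file path.
#' @param sampling_rate Hz (taken from the episode when one is given).
#' @return `write_signal` returns `path` invisibly; `read_signal` returns a
#'   channels x samples matrix with attribute `sampling_rate`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_signal(matrix(rnorm(20), 2), f, sampling_rate = 10)
#' dim(read_signal(f))
#' @export
write_signal <- function(signal, path, sampling_rate = 256) {
  if (inherits(signal, "cog_episode")) {
    sampling_rate <- signal$config$sampling_rate
    signal <- signal$signal
  }
  if (!is.matrix(signal)) stop_contract("signal must be a matrix")
  nc <- nrow(signal); n <- ncol(signal)
  df <- data.frame(
    time = rep((seq_len(n) - 1) / sampling_rate, each = nc),
    channel = rep(seq_len(nc), times = n),
    value = as.vector(signal))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate=%.10g", sampling_rate), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @param format input format; the core build reads the CSV dialect
#'   (NumPy `.npz` archives are not supported in this build and raise a
#'   format error pointing at the CSV path).
#' @export
read_signal <- function(path, format = c("csv", "npz")) {
  format <- match.arg(format)
  if (format == "npz")
    stop("format error: npz signals are not supported by this build; ",
         "export the array as long-format csv (time,channel,value)")
  if (!file.exists(path)) stop("format error: no such file: ", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^# *sampling_rate=([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2)
    stop("format error: missing sampling-rate metadata line ",
         "(expected '# sampling_rate=<Hz>')")
  fs <- as.numeric(m[2])
  df <- utils::read.csv(path, comment.char = "#")
  if (!identical(names(df), c("time", "channel", "value")))
    stop("format error: expected header 'time,channel,value'")
  counts <- table(df$channel)
  if (length(unique(as.integer(counts))) != 1L)
    stop("format error: ragged channels (unequal sample counts)")
  chans <- sort(unique(df$channel))
  n <- as.integer(counts[1])
  sig <- matrix(NA_real_, length(chans), n)
  for (i in seq_along(chans)) {
    sub <- df[df$channel == chans[i], ]
    sig[i, ] <- sub$value[order(sub$time)]
  }
  structure(sig, sampling_rate = fs)
}

#' Write / read episode ground truth as JSON
#'
#' Sidecar serialization of the ground-truth timeline accompanying exported
#' signals.
#'
#' @param truth ground truth (`$truth` of a `cog_episode`).
#' @param path file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the truth
#'   list.
#' @examples
#' ep <- simulate_episode(task_scenario("motor_control", seed = 4))
#' f <- tempfile(fileext = ".json")
#' write_truth(ep$truth, f)
#' read_truth(f)$fault_kind
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::fromJSON(path)
  truth$state_timeline <- as.data.frame(truth$state_timeline)
  truth
}

#' Validate a raw configuration mapping
#'
#' Turns a list parsed from YAML/JSON into a typed configuration, applying
#' the documented defaults. Unknown keys are rejected by name; out-of-range
#' values raise validation errors naming the key.
#'
#' @param raw named list (e.g. from [yaml::read_yaml()]); a `study` key or
#'   `n_episodes_per_task` selects a study configuration, otherwise an
#'   episode configuration is built. A nested `fault` mapping configures the
#'   [fault_spec()].
#' @return An [episode_config()] or [study_config()].
#' @examples
#' validate_config(list(duration = 10, fault = list(kind = "gradual_drift")))
#' @export
validate_config <- function(raw) {
  if (!is.list(raw)) stop_config("configuration must be a mapping")
  if ("n_episodes_per_task" %in% names(raw) ||
      identical(raw$kind, "study")) {
    raw$kind <- NULL
    known <- setdiff(names(formals(study_config)), "discriminator")
    extra <- setdiff(names(raw), c(known, "discriminator"))
    if (length(extra))
      stop_config("unknown configuration key(s): ",
                  paste(extra, collapse = ", "))
    disc <- raw$discriminator
    raw$discriminator <- NULL
    if (!is.null(disc)) {
      dk <- setdiff(names(disc), names(formals(discriminator_params)))
      if (length(dk))
        stop_config("unknown configuration key(s): ",
                    paste(dk, collapse = ", "))
      raw$discriminator <- do.call(discriminator_params, disc)
    }
    return(do.call(study_config, raw))
  }
  known <- setdiff(names(formals(episode_config)), c("fault", "calibration"))
  extra <- setdiff(names(raw), c(known, "fault"))
  if (length(extra))
    stop_config("unknown configuration key(s): ",
                paste(extra, collapse = ", "))
  fl <- raw$fault
  raw$fault <- NULL
  if (!is.null(fl)) {
    fk <- setdiff(names(fl), names(formals(fault_spec)))
    if (length(fk))
      stop_config("unknown configuration key(s): ",
                  paste(fk, collapse = ", "))
    raw$fault <- do.call(fault_spec, fl)
  }
  do.call(episode_config, raw)
}

#' Read a scenario configuration from YAML or JSON
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A validated configuration, see [validate_config()].
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("duration: 10\nseed: 3", f)
#' read_config(f)
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$fault) && !is.null(raw$fault$decision_delay))
    raw$fault$decision_delay <- as.numeric(raw$fault$decision_delay)
  validate_config(raw)
}

#' Write a checksummed run manifest
#'
#' Records the artifact version, configuration fingerprint, seeds and an
#' md5-checksummed inventory of every file under a run directory, supporting
#' fixed-seed, version-controlled reproducibility of study outputs.
#'
#' @param dir run directory.
#' @param seeds integer seeds used for the run.
#' @param config_fingerprint configuration hash string.
#' @return Path of the written `manifest.json`, invisibly.
#' @examples
#' d <- tempfile(); dir.create(d)
#' writeLines("x", file.path(d, "a.txt"))
#' write_manifest(d, seeds = 1L)
#' @export
write_manifest <- function(dir, seeds, config_fingerprint = NA_character_) {
  files <- list.files(dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    artifact_version = as.character(utils::packageVersion("cogtrace")),
    config_fingerprint = config_fingerprint,
    seeds = as.integer(seeds),
    files = lapply(seq_along(files), function(i)
      list(path = files[i], md5 = unname(sums[i]))))
  out <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, out, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Verify a run manifest
#'
#' @param dir run directory containing `manifest.json`.
#' @return TRUE invisibly if all checksums match; otherwise an error naming
#'   the first mismatching file.
#' @examples
#' d <- tempfile(); dir.create(d)
#' writeLines("x", file.path(d, "a.txt"))
#' write_manifest(d, seeds = 1L)
#' verify_manifest(d)
#' @export
verify_manifest <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  for (f in man$files) {
    sum_now <- unname(tools::md5sum(file.path(dir, f$path)))
    if (is.na(sum_now) || !identical(sum_now, f$md5))
      stop("manifest mismatch for file: ", f$path)
  }
  invisible(TRUE)
}
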
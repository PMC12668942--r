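# Internal helpers: argument checking, deterministic seed derivation, misc.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("cogtrace_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_contract <- function(...) {
  stop(structure(class = c("cogtrace_contract_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a finite numeric scalar")
  if (strict_lower && x <= lower)
    stop_config(name, " must be > ", lower, " (got ", x, ")")
  if (!strict_lower && x < lower)
    stop_config(name, " must be >= ", lower, " (got ", x, ")")
  if (strict_upper && x >= upper)
    stop_config(name, " must be < ", upper, " (got ", x, ")")
  if (!strict_upper && x > upper)
    stop_config(name, " must be <= ", upper, " (got ", x, ")")
  x
}

# Deterministic sub-stream seeds: a 31-bit multiplicative hash of the root
# seed and a stream label, so adding channels or reordering draws in one
# stream never perturbs another (onset draws, noise, lags are independent).
derive_seed <- function(seed, label, index = 0L) {
  m <- 2147483647
  s <- as.double(seed) %% m
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  s <- (s * 48271) %% m
  s <- (s + h) %% m
  s <- (s * 69621 + as.double(index) * 7919 + 1) %% m
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded from `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# md5 fingerprint of an R object via its canonical JSON form (tools::md5sum
# works on files, so serialize to a tempfile).
fingerprint <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE), f)
  unname(tools::md5sum(f))
}

round_samples <- function(seconds, fs) as.integer(round(seconds * fs))
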
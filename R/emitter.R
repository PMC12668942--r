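# Symbolic feedback emitter: event -> user-facing marker mapping and the
# JSON-lines trace format.

#' Symbolic vocabulary
#'
#' The fixed mapping from detector event types to user-facing symbolic labels
#' and glyph codes. The initial-commitment marker carries the sigma-1 glyph;
#' the conflict glyph defaults to a warning sign and is configurable.
#'
#' @param conflict_code glyph used for the conflict marker.
#' @return data.frame with columns `type`, `label`, `code`.
#' @examples
#' symbol_vocabulary()
#' @export
symbol_vocabulary <- function(conflict_code = "\u26a0") {
  data.frame(
    type = c("Sigma1", "DriftEvent", "ConflictEscalate", "RejectH1",
             "AcceptH1", "NoEvent"),
    label = c("Intent committed", "System diverging", "Conflict rising",
              "Hypothesis rejected", "Hypothesis accepted", "Stable state"),
    code = c("\u03c31", "\u0394", conflict_code, "\u2298", "\u2713",
             "\u2022"),
    stringsAsFactors = FALSE)
}

#' Emit a symbolic trace from detected events
#'
#' Maps each cognitive event to its symbolic marker. `NoEvent` windows are
#' suppressed unless `verbose = TRUE`, keeping traces sparse; all other event
#' types are always emitted. Marker order equals event order.
#'
#' @param events a `cog_events` data.frame (see [detect_events()]), ordered
#'   by timestamp.
#' @param episode_id identifier recorded in the trace.
#' @param verbose emit `Stable state` markers for `NoEvent` windows.
#' @param vocabulary a [symbol_vocabulary()].
#' @param config_fingerprint optional parameter-hash string.
#' @return A `cog_trace`: data.frame of markers (`t`, `type`, `label`,
#'   `code`, `hypothesis`) with `episode_id` and `config_fingerprint`
#'   attributes.
#' @examples
#' ev <- data.frame(t = 12, type = "DriftEvent",
#'                  hypothesis = NA_character_)
#' emit_trace(ev, episode_id = "ep1")
#' @export
emit_trace <- function(events, episode_id = "episode",
                       verbose = FALSE, vocabulary = symbol_vocabulary(),
                       config_fingerprint = NA_character_) {
  if (!is.data.frame(events) || !all(c("t", "type") %in% names(events)))
    stop_contract("events must be a data.frame with columns t and type")
  if (is.unsorted(events$t)) stop_contract("events must be ordered by t")
  unknown <- setdiff(unique(events$type), vocabulary$type)
  if (length(unknown))
    stop(sprintf("no symbolic mapping for event type(s): %s",
                 paste(unknown, collapse = ", ")))
  keep <- if (verbose) rep(TRUE, nrow(events)) else events$type != "NoEvent"
  ev <- events[keep, , drop = FALSE]
  idx <- match(ev$type, vocabulary$type)
  markers <- data.frame(
    t = ev$t, type = ev$type,
    label = vocabulary$label[idx], code = vocabulary$code[idx],
    hypothesis = if ("hypothesis" %in% names(ev)) ev$hypothesis
                 else NA_character_,
    stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  structure(markers, class = c("cog_trace", "data.frame"),
            episode_id = as.character(episode_id),
            config_fingerprint = as.character(config_fingerprint),
            schema_version = 1L)
}

#' Write / read a symbolic trace as JSON-lines
#'
#' One UTF-8 JSON object per line: a header line
#' (`{"kind":"trace_header", "schema_version":1, "episode_id":..., ...}`)
#' followed by one line per marker with fields `episode_id`, `t`,
#' `event_type`, `label`, `code` (plus `hypothesis` when known). Timestamps
#' are plain seconds since episode start. The round trip is lossless.
#'
#' @param trace a `cog_trace` (markers must be time-ordered).
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   `cog_trace`.
#' @examples
#' tr <- emit_trace(data.frame(t = c(2, 5), type = c("Sigma1", "DriftEvent"),
#'                             hypothesis = c("intent_a", NA)), "ep1")
#' f <- tempfile(fileext = ".jsonl")
#' write_trace(tr, f)
#' identical(read_trace(f), tr)
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "cog_trace"))
    stop_contract("trace must be a cog_trace")
  if (nrow(trace) && is.unsorted(trace$t))
    stop("trace timestamps must be non-decreasing; refusing to write")
  eid <- attr(trace, "episode_id")
  header <- jsonlite::toJSON(list(
    kind = "trace_header", schema_version = attr(trace, "schema_version"),
    episode_id = eid,
    config_fingerprint = attr(trace, "config_fingerprint")),
    auto_unbox = TRUE, na = "null", digits = NA)
  lines <- character(nrow(trace))
  for (i in seq_len(nrow(trace)))
    lines[i] <- jsonlite::toJSON(list(
      episode_id = eid, t = trace$t[i], event_type = trace$type[i],
      label = trace$label[i], code = trace$code[i],
      hypothesis = trace$hypothesis[i]),
      auto_unbox = TRUE, na = "null", digits = NA)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, lines), con, useBytes = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param source file path to read.
#' @export
read_trace <- function(source) {
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty trace file: ", source)
  parsed <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) || !is.list(rec))
      stop(sprintf("parse error in %s at line %d", source, i))
    parsed[[i]] <- rec
  }
  hdr <- parsed[[1]]
  if (!identical(hdr$kind, "trace_header"))
    stop(sprintf("parse error in %s at line 1: missing trace header", source))
  body <- parsed[-1]
  markers <- data.frame(
    t = vapply(body, function(r) as.numeric(r$t), numeric(1)),
    type = vapply(body, function(r) as.character(r$event_type), character(1)),
    label = vapply(body, function(r) as.character(r$label), character(1)),
    code = vapply(body, function(r) as.character(r$code), character(1)),
    hypothesis = vapply(body, function(r)
      if (is.null(r$hypothesis)) NA_character_ else as.character(r$hypothesis),
      character(1)),
    stringsAsFactors = FALSE)
  structure(markers, class = c("cog_trace", "data.frame"),
            episode_id = as.character(hdr$episode_id),
            config_fingerprint = as.character(hdr$config_fingerprint %||%
                                                NA_character_),
            schema_version = as.integer(hdr$schema_version %||% 1L))
}

#' Textual replay of a trace
#'
#' Renders an aligned timeline of the markers (glyph, time, label), the
#' console analogue of a user-interface overlay.
#'
#' @param trace a `cog_trace`.
#' @return Character vector of display lines, invisibly; printed as a side
#'   effect.
#' @examples
#' tr <- emit_trace(data.frame(t = 2, type = "Sigma1",
#'                             hypothesis = "intent_a"), "ep1")
#' replay_trace(tr)
#' @export
replay_trace <- function(trace) {
  if (!nrow(trace)) {
    cat("(empty trace)\n")
    return(invisible(character()))
  }
  lines <- sprintf("%7.2fs  %-3s %-20s%s", trace$t, trace$code, trace$label,
                   ifelse(is.na(trace$hypothesis), "",
                          paste0(" [", trace$hypothesis, "]")))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.cog_trace <- function(x, ...) {
  cat(sprintf("<cog_trace> episode %s: %d marker(s)\n",
              attr(x, "episode_id"), nrow(x)))
  replay_trace(x)
  invisible(x)
}

#' @export
plot.cog_trace <- function(x, ...) {
  if (!nrow(x)) {
    graphics::plot.new()
    graphics::title("empty trace")
    return(invisible(x))
  }
  types <- unique(x$type)
  y <- match(x$type, types)
  graphics::plot(x$t, y, pch = NA, yaxt = "n", xlab = "time (s)",
                 ylab = "", ylim = c(0.5, length(types) + 0.5), ...)
  graphics::axis(2, at = seq_along(types), labels = types, las = 1)
  graphics::text(x$t, y, labels = x$code)
  invisible(x)
}
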
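# Trace and stimulus-time file I/O.
#
# The CSV dialect is self-describing and diff-able: '#'-prefixed metadata
# header (sampling_rate_hz, t0_s, units, channel) followed by two columns
# time_s,current_pA. Values are printed with 17 significant digits so a
# write/read round trip reproduces doubles bitwise.

#' Read a current trace from file
#'
#' @param path file path.
#' @param dialect file format. Only `"csv"` (the package's self-describing
#'   two-column dialect) is supported.
#' @return a [trace()]. The sampling rate declared in the header is
#'   validated against the time column: sampling must be uniform within a
#'   relative tolerance of 1e-6, otherwise a sampling error is raised.
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, dialect = c("csv", "hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5") {
    rrp_abort("the hdf5 dialect is not available in this build; use csv",
              "rrpool_format_error")
  }
  if (!file.exists(path)) {
    rrp_abort(sprintf("file not found: %s", path), "rrpool_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) {
    rrp_abort("trace file has no data rows", "rrpool_format_error")
  }
  cols <- strsplit(body[1], ",")[[1]]
  ti <- match("time_s", trimws(cols))
  ci <- match("current_pA", trimws(cols))
  if (is.na(ti) || is.na(ci)) {
    rrp_abort("trace file must have columns time_s and current_pA",
              "rrpool_format_error")
  }
  dat <- utils::read.csv(text = paste(body, collapse = "\n"))
  t <- as.numeric(dat[[ti]])
  i <- as.numeric(dat[[ci]])
  if (length(t) < 2) {
    rrp_abort("trace file must contain at least 2 samples",
              "rrpool_format_error")
  }
  d <- diff(t)
  dt <- mean(d)
  if (dt <= 0 || max(abs(d - dt)) > 1e-6 * dt) {
    rrp_abort("time column is not uniformly sampled (relative tolerance 1e-6)",
              "rrpool_sampling_error")
  }
  fs_time <- 1 / dt
  fs <- if (!is.null(meta$sampling_rate_hz)) {
    as.numeric(meta$sampling_rate_hz)
  } else {
    fs_time
  }
  if (abs(fs - fs_time) > 1e-6 * fs) {
    rrp_abort("declared sampling_rate_hz disagrees with the time column",
              "rrpool_sampling_error")
  }
  trace(i, sampling_rate = fs,
        t0 = if (!is.null(meta$t0_s)) as.numeric(meta$t0_s) else t[1],
        channel_label = if (!is.null(meta$channel)) meta$channel else "Im")
}

#' Write a current trace to file
#'
#' Writes the package's self-describing CSV dialect. Round-trips losslessly
#' through [read_trace()] (bitwise-identical samples).
#'
#' @param x a [trace()].
#' @param path destination file path.
#' @param dialect file format; only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, dialect = c("csv", "hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5") {
    rrp_abort("the hdf5 dialect is not available in this build; use csv",
              "rrpool_format_error")
  }
  if (!inherits(x, "trace")) {
    rrp_abort("x must be a trace object", "rrpool_parameter_error")
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    rrp_abort(sprintf("cannot open '%s' for writing: %s",
                      path, conditionMessage(e)), "rrpool_io_error")
  })
  on.exit(close(con))
  t <- trace_times(x)
  writeLines(c("# rrpool trace v1",
               sprintf("# sampling_rate_hz: %.17g", x$sampling_rate),
               sprintf("# t0_s: %.17g", x$t0),
               "# units: pA",
               sprintf("# channel: %s", x$channel_label),
               "time_s,current_pA",
               sprintf("%.17g,%.17g", t, x$samples)), con)
  invisible(path)
}

#' Read stimulus times from a text file
#'
#' One time (in seconds) per line; blank lines and `#` comments are
#' ignored. Times must be strictly increasing.
#'
#' @param path file path.
#' @return a [stimulus_train()]; the nominal frequency is inferred when the
#'   spacing is uniform.
#' @export
read_stimulus_times <- function(path) {
  if (!file.exists(path)) {
    rrp_abort(sprintf("file not found: %s", path), "rrpool_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    rrp_abort("stimulus-time file contains no times", "rrpool_validation_error")
  }
  times <- suppressWarnings(as.numeric(lines))
  if (any(is.na(times))) {
    rrp_abort("stimulus-time file contains non-numeric entries",
              "rrpool_validation_error")
  }
  stimulus_train(times)
}

#' Write stimulus times to a text file
#'
#' @param train a [stimulus_train()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_stimulus_times <- function(train, path) {
  stopifnot(inherits(train, "stimulus_train"))
  writeLines(sprintf("%.17g", train$times), path)
  invisible(path)
}
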
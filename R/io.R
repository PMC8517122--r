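#' Continuous ventilator record
#'
#' A possibly multi-breath stretch of sampled traces on a strictly
#' increasing time axis, as read from a waveform file. Segment into
#' individual [breath_record()]s with [segment_breaths()].
#'
#' @param time Strictly increasing time, s.
#' @param pressure Airway pressure, cmH2O.
#' @param volume Volume, ml.
#' @param flow Optional flow, ml/s.
#' @param meta Free-form metadata list.
#' @return An object of class `ventilator_record`.
#' @export
ventilator_record <- function(time, pressure, volume, flow = NULL, meta = list()) {
  n <- length(time)
  assert_that(is.numeric(time) && n >= 2 && all(is.finite(time)),
              "`time` must be a finite numeric vector of length >= 2")
  if (any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1] + 1
    stop_dilvr(sprintf("`time` must be strictly increasing (violated at sample %d)", bad),
               "dilvr_format_error")
  }
  for (nm in c("pressure", "volume")) {
    v <- get(nm)
    assert_that(is.numeric(v) && length(v) == n && all(is.finite(v)),
                sprintf("`%s` must be finite numeric of the same length as `time`", nm))
  }
  if (!is.null(flow)) {
    assert_that(is.numeric(flow) && length(flow) == n && all(is.finite(flow)),
                "`flow` must be finite numeric of the same length as `time`")
  }
  structure(list(time = time, pressure = pressure, volume = volume,
                 flow = flow, meta = meta),
            class = "ventilator_record")
}

#' @export
print.ventilator_record <- function(x, ...) {
  cat(sprintf("<ventilator_record> %d samples over %.4g s (median step %.4g s)\n",
              length(x$time), max(x$time) - min(x$time), median(diff(x$time))))
  invisible(x)
}

WAVEFORM_COLS <- c("time_s", "pressure_cmH2O", "volume_ml")

#' Write a waveform file
#'
#' Comma-separated text with header columns `time_s`, `pressure_cmH2O`,
#' `volume_ml` and optionally `flow_ml_s`; metadata is written as leading
#' `# key=value` comment lines.
#'
#' @param record A [ventilator_record()] or [breath_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path) {
  if (inherits(record, "breath_record")) {
    record <- ventilator_record(grid_times(record$grid), record$pressure,
                                record$volume, record$flow, record$meta)
  }
  stopifnot(inherits(record, "ventilator_record"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- record$meta
  scalars <- meta[vapply(meta, function(v) is.atomic(v) && length(v) == 1, TRUE)]
  for (k in names(scalars)) writeLines(sprintf("# %s=%s", k, format(scalars[[k]], digits = 15)), con)
  df <- data.frame(time_s = record$time, pressure_cmH2O = record$pressure,
                   volume_ml = record$volume)
  if (!is.null(record$flow)) df$flow_ml_s <- record$flow
  writeLines(paste(names(df), collapse = ","), con)
  write.table(format(df, digits = 15, trim = TRUE, scientific = TRUE),
              con, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a waveform file
#'
#' Parses the delimited format written by [write_waveform()]: leading
#' `# key=value` metadata, then a CSV with columns `time_s`,
#' `pressure_cmH2O`, `volume_ml` and optionally `flow_ml_s`. Time must be
#' strictly increasing; if the sampling step varies by more than 1% (or a
#' target `dt` is given), traces are resampled by linear interpolation onto
#' a uniform grid.
#'
#' @param path File path.
#' @param dt Optional target sampling step, s.
#' @return A [ventilator_record()].
#' @export
read_waveform <- function(path, dt = NULL) {
  if (!file.exists(path)) {
    stop_dilvr(sprintf("waveform file not found: %s", path), "dilvr_format_error")
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- sub("^#\\s*", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(kv, 1, eq - 1))
      val <- trimws(substr(kv, eq + 1, nchar(kv)))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  df <- tryCatch(
    read.csv(text = lines[!grepl("^#", lines)], header = TRUE),
    error = function(e) stop_dilvr(sprintf("cannot parse waveform file %s: %s",
                                           path, conditionMessage(e)),
                                   "dilvr_format_error"))
  missing <- setdiff(WAVEFORM_COLS, names(df))
  if (length(missing)) {
    stop_dilvr(sprintf("waveform file %s lacks required column(s): %s",
                       path, paste(missing, collapse = ", ")),
               "dilvr_format_error")
  }
  for (nm in intersect(c(WAVEFORM_COLS, "flow_ml_s"), names(df))) {
    if (!is.numeric(df[[nm]]) || anyNA(df[[nm]])) {
      stop_dilvr(sprintf("column %s of %s contains non-numeric or missing values",
                         nm, path), "dilvr_format_error")
    }
  }
  rec <- ventilator_record(df$time_s, df$pressure_cmH2O, df$volume_ml,
                           flow = df$flow_ml_s, meta = meta)
  steps <- diff(rec$time)
  step0 <- median(steps)
  if (!is.null(dt)) {
    if (abs(step0 - dt) > 1e-12 || any(abs(steps - dt) > 0.01 * dt)) {
      rec <- resample_record(rec, dt)
    }
  } else if (any(abs(steps - step0) > 0.01 * step0)) {
    rec <- resample_record(rec, step0)
  }
  rec
}

#' Resample a continuous record by linear interpolation
#'
#' @param record A [ventilator_record()].
#' @param dt Target uniform sampling step, s.
#' @return A [ventilator_record()] on the uniform grid.
#' @export
resample_record <- function(record, dt) {
  stopifnot(inherits(record, "ventilator_record"))
  t_new <- seq(record$time[1], record$time[length(record$time)], by = dt)
  res <- function(x) if (is.null(x)) NULL else approx(record$time, x, xout = t_new)$y
  ventilator_record(t_new, res(record$pressure), res(record$volume),
                    flow = res(record$flow), meta = record$meta)
}

#' Split a continuous record into breaths at volume troughs
#'
#' Breath boundaries are placed at local minima of the volume trace that lie
#' below `trough_fraction` of the volume amplitude and are separated by at
#' least `min_period_s`. A record with no internal troughs yields a single
#' breath.
#'
#' @param record A [ventilator_record()].
#' @param min_period_s Minimum breath duration, s.
#' @param trough_fraction Fraction of the volume amplitude below which a
#'   sample counts as a trough candidate.
#' @return List of [breath_record()]s; each has `meta$breath_index` and
#'   breath-relative time (`t = 0` at segment start, so phase parameters are
#'   estimable per breath).
#' @export
segment_breaths <- function(record, min_period_s = 0.5, trough_fraction = 0.15) {
  stopifnot(inherits(record, "ventilator_record"))
  v <- record$volume
  n <- length(v)
  dur <- record$time[n] - record$time[1]
  if (dur < 2 * min_period_s) {
    stop_dilvr(sprintf("record spans %.3g s; need at least 2 * min_period_s = %.3g s",
                       dur, 2 * min_period_s), "dilvr_segmentation_error")
  }
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps^0.5 * max(1, abs(rng[2]))) {
    stop_dilvr("segmentation failure: volume trace is constant (no breaths to find)",
               "dilvr_segmentation_error")
  }
  thr <- rng[1] + trough_fraction * diff(rng)
  below <- v <= thr
  if (all(below)) {
    stop_dilvr(sprintf(
      "segmentation failure: entire volume trace lies below the trough threshold %.3g; no breaths detected",
      thr), "dilvr_segmentation_error")
  }
  # runs of below-threshold samples that do not touch the record edges
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cuts <- integer(0)
  for (k in seq_along(r$values)) {
    if (r$values[k] && starts[k] > 1 && ends[k] < n) {
      run <- starts[k]:ends[k]
      cuts <- c(cuts, run[which.min(v[run])])
    }
  }
  # cuts must leave room for a breath on both sides of the record
  if (length(cuts)) {
    cuts <- cuts[record$time[cuts] >= record$time[1] + min_period_s &
                   record$time[cuts] <= record$time[n] - min_period_s]
  }
  # enforce minimum separation (keep the deeper trough of close pairs)
  if (length(cuts) > 1) {
    keep <- cuts[1]
    for (c2 in cuts[-1]) {
      if (record$time[c2] - record$time[keep[length(keep)]] >= min_period_s) {
        keep <- c(keep, c2)
      } else if (v[c2] < v[keep[length(keep)]]) {
        keep[length(keep)] <- c2
      }
    }
    cuts <- keep
  }
  bounds <- c(1, cuts, n + 1L)
  segs <- list()
  dt0 <- median(diff(record$time))
  for (j in seq_len(length(bounds) - 1)) {
    idx <- bounds[j]:(bounds[j + 1] - 1L)
    if (length(idx) < 3) next
    g <- sample_grid(dt0, length(idx), t_start = 0)
    segs[[length(segs) + 1]] <- breath_record(
      g, pressure = record$pressure[idx], volume = record$volume[idx],
      flow = if (is.null(record$flow)) NULL else record$flow[idx],
      meta = c(record$meta, list(breath_index = length(segs) + 1)))
  }
  if (!length(segs)) {
    stop_dilvr("segmentation failure: no segments of usable length found",
               "dilvr_segmentation_error")
  }
  segs
}
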
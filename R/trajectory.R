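#' Photoperiod specification
#'
#' Describes the light:dark cycle in zeitgeber time (ZT, hours since lights
#' on). The default is the 14:10 LD cycle used for Astyanax behavior work:
#' lights on at ZT0, lights off at ZT14, 24-h period. Phase intervals are
#' half-open: lights-on covers [lights_on_zt, lights_off_zt), dark covers
#' [lights_off_zt, period).
#'
#' @param lights_on_zt Hours, ZT of lights on (default 0).
#' @param lights_off_zt Hours, ZT of lights off (default 14).
#' @param period Cycle length in hours (default 24).
#' @return An object of class `photoperiod`.
#' @export
photoperiod <- function(lights_on_zt = 0, lights_off_zt = 14, period = 24) {
  stopifnot(is.numeric(lights_on_zt), is.numeric(lights_off_zt), is.numeric(period))
  if (!(0 <= lights_on_zt && lights_on_zt < lights_off_zt && lights_off_zt <= period)) {
    stop("photoperiod requires 0 <= lights_on_zt < lights_off_zt <= period")
  }
  structure(list(lights_on_zt = lights_on_zt, lights_off_zt = lights_off_zt,
                 period = period), class = "photoperiod")
}

#' Construct a calibrated trajectory
#'
#' Canonical per-fish position time series: time in seconds from recording
#' start, positions in millimeters, a per-frame missing mask, and the
#' metadata needed downstream (morph, treatment, ZT of the first frame).
#' Normally produced by [read_tracking()] or [simulate_activity()].
#'
#' @param t Numeric vector, seconds from recording start, strictly increasing.
#' @param x,y Numeric vectors, positions in mm (NA where missing).
#' @param subject_id Opaque fish label.
#' @param population `"surface"` or `"cavefish"`.
#' @param treatment Opaque treatment label (e.g. `"control"`, `"TCS_10uM"`).
#' @param frame_rate Frames per second; inferred from the median inter-frame
#'   interval when `NULL`.
#' @param zt_start ZT (hours, in `[0, 24)`) of the first frame.
#' @param missing Logical per-frame mask; defaults to `!is.finite(x) | !is.finite(y)`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(t, x, y, subject_id = "fish", population = "surface",
                       treatment = "control", frame_rate = NULL, zt_start = 0,
                       missing = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (length(x) != n || length(y) != n) stop("t, x, y must have equal length")
  dt <- if (n >= 2) diff(t) else numeric(0)
  if (n >= 2 && any(dt <= 0)) {
    bad <- which(dt <= 0)[1]
    stop(sprintf("time not strictly increasing: first offending row %d (t=%g after t=%g)",
                 bad + 1L, t[bad + 1L], t[bad]))
  }
  if (is.null(missing)) missing <- !is.finite(x) | !is.finite(y)
  missing <- as.logical(missing)
  if (length(missing) != n) stop("missing mask length mismatch")
  if (any(!missing & (!is.finite(x) | !is.finite(y)))) {
    stop("non-finite coordinates on frames not flagged missing")
  }
  if (is.null(frame_rate)) {
    if (n < 2) stop("frame_rate must be given for a trajectory with < 2 frames")
    frame_rate <- 1 / stats::median(dt)
  }
  if (n >= 2) {
    med_dt <- stats::median(dt)
    if (abs(med_dt - 1 / frame_rate) > 0.01 / frame_rate) {
      stop(sprintf("median inter-frame interval %.6gs not within 1%% of 1/frame_rate (%.6gs)",
                   med_dt, 1 / frame_rate))
    }
  }
  if (!(zt_start >= 0 && zt_start < 24)) stop("zt_start must lie in [0, 24)")
  structure(list(subject_id = as.character(subject_id),
                 population = as.character(population),
                 treatment = as.character(treatment),
                 t = t, x = x, y = y,
                 frame_rate = frame_rate, zt_start = as.numeric(zt_start),
                 missing = missing),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s (%s, %s): %d frames @ %.3g Hz, %.2f h, ZT start %.2f, %.1f%% missing\n",
              x$subject_id, x$population, x$treatment, length(x$t), x$frame_rate,
              diff(range(x$t)) / 3600, x$zt_start, 100 * mean(x$missing)))
  invisible(x)
}

# internal: parse a numeric field, returning NA for anything unparseable
.num_or_na <- function(v) suppressWarnings(as.numeric(v))

#' Read a tracking export into a trajectory
#'
#' Reads a per-fish tracking file, converts pixel coordinates to mm with the
#' supplied calibration, and validates the result. Two dialects are
#' supported: `"generic"` (UTF-8 CSV with columns `time_s,x,y`, optional
#' `#` comment lines) and `"ethovision_export"` (a preamble of metadata
#' lines, then a header row containing "Trial time" with columns
#' "X center"/"Y center"; a units row after the header is skipped).
#'
#' Rows whose coordinates cannot be parsed are flagged missing rather than
#' dropped, so frame indexing is preserved. Metadata written by
#' [write_tracking()] as `# key: value` comments is picked up for the
#' generic dialect unless overridden by explicit arguments.
#'
#' @param path File path.
#' @param dialect `"generic"` or `"ethovision_export"`.
#' @param calibration mm per pixel (> 0); positions are multiplied by it.
#' @param subject_id,population,treatment,zt_start Metadata for the fish;
#'   `NULL` values fall back to file comments (generic dialect) or defaults.
#' @param frame_rate Frames per second, inferred from timestamps when `NULL`.
#' @param max_missing Maximum tolerated missing-frame fraction (default 0.2);
#'   recordings above it are rejected as unusable.
#' @return A [trajectory()].
#' @export
read_tracking <- function(path, dialect = c("generic", "ethovision_export"),
                          calibration = 1, subject_id = NULL, population = NULL,
                          treatment = NULL, zt_start = NULL, frame_rate = NULL,
                          max_missing = 0.2) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(calibration) || calibration <= 0) stop("calibration must be > 0")

  lines <- readLines(path, warn = FALSE)
  meta <- list()
  if (dialect == "generic") {
    cm <- grep("^#", lines, value = TRUE)
    for (ln in cm) {
      m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
      if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
    }
    body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    if (!length(body)) stop("no data rows in ", path)
    hdr <- strsplit(body[1], ",")[[1]]
    cols <- match(c("time_s", "x", "y"), trimws(hdr))
    if (anyNA(cols)) stop("generic dialect requires columns time_s,x,y in ", path)
    rows <- strsplit(body[-1], ",")
    get <- function(i) vapply(rows, function(r) if (length(r) >= i) r[i] else NA_character_, "")
    tt <- .num_or_na(get(cols[1])); xx <- .num_or_na(get(cols[2])); yy <- .num_or_na(get(cols[3]))
  } else { # ethovision_export
    sep <- if (any(grepl(";", lines[1:min(5, length(lines))], fixed = TRUE))) ";" else ","
    hdr_i <- grep("Trial time", lines)[1]
    if (is.na(hdr_i)) stop("ethovision_export dialect: no 'Trial time' header row in ", path)
    hdr <- trimws(strsplit(lines[hdr_i], sep, fixed = TRUE)[[1]])
    ci <- function(nm) {
      j <- grep(nm, hdr, ignore.case = TRUE)[1]
      if (is.na(j)) stop("ethovision_export dialect: column '", nm, "' not found in ", path)
      j
    }
    cols <- c(ci("Trial time"), ci("X center"), ci("Y center"))
    rows <- strsplit(lines[seq(hdr_i + 1L, length(lines))], sep, fixed = TRUE)
    get <- function(i) vapply(rows, function(r) if (length(r) >= i) trimws(r[i]) else NA_character_, "")
    tt <- .num_or_na(get(cols[1])); xx <- .num_or_na(get(cols[2])); yy <- .num_or_na(get(cols[3]))
    keep <- !is.na(tt)              # drops the units row and blank trailing lines
    tt <- tt[keep]; xx <- xx[keep]; yy <- yy[keep]
  }
  if (!length(tt) || all(is.na(tt))) stop("no parseable data rows in ", path)
  if (anyNA(tt)) stop("unparseable time values in ", path)

  missing <- is.na(xx) | is.na(yy)
  if (mean(missing) > max_missing) {
    stop(sprintf("recording unusable: %.1f%% missing frames exceeds %.0f%% in %s",
                 100 * mean(missing), 100 * max_missing, path))
  }
  pick <- function(arg, key, default) {
    if (!is.null(arg)) arg else if (!is.null(meta[[key]])) meta[[key]] else default
  }
  trajectory(tt, xx * calibration, yy * calibration,
             subject_id = pick(subject_id, "subject_id", basename(path)),
             population = pick(population, "population", "surface"),
             treatment  = pick(treatment, "treatment", "control"),
             zt_start   = as.numeric(pick(zt_start, "zt_start", 0)),
             frame_rate = if (!is.null(frame_rate)) frame_rate else
               if (!is.null(meta$frame_rate)) as.numeric(meta$frame_rate) else NULL,
             missing = missing)
}

#' Write a trajectory in the generic dialect
#'
#' Emits a UTF-8 CSV with columns `time_s,x,y` (mm) preceded by `# key: value`
#' comment lines carrying the metadata, so that re-reading with
#' [read_tracking()] round-trips both positions and labels. Missing frames
#' are written with empty coordinate fields.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.12g", v))
  hdr <- c(sprintf("# subject_id: %s", traj$subject_id),
           sprintf("# population: %s", traj$population),
           sprintf("# treatment: %s", traj$treatment),
           sprintf("# zt_start: %.12g", traj$zt_start),
           sprintf("# frame_rate: %.12g", traj$frame_rate),
           "time_s,x,y")
  xx <- ifelse(traj$missing, NA_real_, traj$x)
  yy <- ifelse(traj$missing, NA_real_, traj$y)
  writeLines(c(hdr, paste(sprintf("%.12g", traj$t), fmt(xx), fmt(yy), sep = ",")), path)
  invisible(path)
}

#' Interpolate short tracking dropouts
#'
#' Runs of missing frames whose span is at most `max_gap_s` seconds are
#' linearly interpolated (per coordinate, against time) and unflagged;
#' longer runs, and runs touching the start or end of the recording, are
#' left missing. Resolved samples are never modified, so the operation is
#' idempotent.
#'
#' @param traj A [trajectory()].
#' @param max_gap_s Maximum gap span to fill, seconds (`0` = fill nothing).
#' @return The trajectory with short gaps filled.
#' @export
fill_gaps <- function(traj, max_gap_s = 1) {
  stopifnot(inherits(traj, "trajectory"), is.numeric(max_gap_s), max_gap_s >= 0)
  if (max_gap_s == 0 || !any(traj$missing)) return(traj)
  r <- rle(traj$missing)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  n <- length(traj$t)
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L || i1 == n) next                      # no flanking sample on one side
    span <- traj$t[i1 + 1L] - traj$t[i0 - 1L] - 1 / traj$frame_rate
    if (span > max_gap_s + 1e-9) next
    idx <- i0:i1
    traj$x[idx] <- stats::approx(traj$t[c(i0 - 1L, i1 + 1L)], traj$x[c(i0 - 1L, i1 + 1L)],
                                 xout = traj$t[idx])$y
    traj$y[idx] <- stats::approx(traj$t[c(i0 - 1L, i1 + 1L)], traj$y[c(i0 - 1L, i1 + 1L)],
                                 xout = traj$t[idx])$y
    traj$missing[idx] <- FALSE
  }
  traj
}

#' Zeitgeber time of a frame
#'
#' Maps a frame index to ZT hours, `(zt_start + t/3600) mod period`, and
#' reports whether the lights are on there. The light phase is the half-open
#' interval `[lights_on_zt, lights_off_zt)`, so a frame exactly at lights-off
#' belongs to the dark phase.
#'
#' @param traj A [trajectory()].
#' @param frame_index 1-based frame index (vectorized).
#' @param pp A [photoperiod()].
#' @return Data frame with columns `zt` (hours) and `lights_on` (logical).
#' @export
zt_of <- function(traj, frame_index, pp = photoperiod()) {
  stopifnot(inherits(traj, "trajectory"), inherits(pp, "photoperiod"))
  if (any(frame_index < 1 | frame_index > length(traj$t))) {
    stop("frame_index out of range")
  }
  zt <- (traj$zt_start + traj$t[frame_index] / 3600) %% pp$period
  data.frame(zt = zt, lights_on = zt >= pp$lights_on_zt & zt < pp$lights_off_zt)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with one row per fish and columns
#' `file,subject_id,population,treatment,zt_start,calibration_mm_per_px`.
#' Relative `file` paths are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return Data frame with the resolved file paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("file", "subject_id", "population", "treatment", "zt_start",
            "calibration_mm_per_px")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$file)
  m$file[rel] <- file.path(dirname(path), m$file[rel])
  m
}
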
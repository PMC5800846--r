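#' Sleep scoring parameters
#'
#' Tunables of the immobility-based sleep definition. Sleep is a maximal run
#' of behavioral immobility lasting at least `min_sleep_s` (default 60 s,
#' the arousal-threshold-validated rule for Astyanax). The remaining knobs
#' operationalize "immobility" from 15 Hz tracking:
#'
#' * `speed_threshold` — a frame is immobile when its smoothed speed is
#'   strictly below this (mm/s). The value is not dictated by the sleep
#'   definition itself; the default 4 mm/s is on the order of a tenth of a
#'   body length per second for adult fish and is logged in every report.
#' * `smooth_window_s` — width of the rolling-median speed filter; 1 s
#'   suppresses single-frame tracker jitter without masking real swimming.
#' * `min_interrupt_s` — a supra-threshold run shorter than this does not
#'   terminate an immobility run (it is absorbed); set 0 for the strictest
#'   reading in which any movement ends a bout.
#'
#' @param speed_threshold mm/s (default 4).
#' @param smooth_window_s Seconds of rolling median (default 1).
#' @param min_sleep_s Minimum sleep-bout duration, seconds (default 60).
#' @param min_interrupt_s Minimum movement run that interrupts immobility,
#'   seconds (default 1).
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(speed_threshold = 4, smooth_window_s = 1,
                           min_sleep_s = 60, min_interrupt_s = 1) {
  v <- c(speed_threshold, smooth_window_s, min_sleep_s, min_interrupt_s)
  if (any(!is.finite(v)) || any(v < 0)) stop("scoring parameters must be finite and >= 0")
  if (min_sleep_s <= 0) stop("min_sleep_s must be > 0")
  structure(list(speed_threshold = speed_threshold,
                 smooth_window_s = smooth_window_s,
                 min_sleep_s = min_sleep_s,
                 min_interrupt_s = min_interrupt_s),
            class = "scoring_params")
}

# rolling median with odd width k applied within each non-NA segment;
# segments shorter than k use the largest odd width that fits
.segment_runmed <- function(v, k) {
  if (k <= 1 || !length(v)) return(v)
  if (k %% 2 == 0) k <- k + 1L
  ok <- !is.na(v)
  if (!any(ok)) return(v)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (s in which(r$values)) {
    idx <- starts[s]:ends[s]
    kk <- min(k, length(idx))
    if (kk %% 2 == 0) kk <- kk - 1L
    if (kk >= 3) v[idx] <- stats::runmed(v[idx], kk)
  }
  v
}

#' Per-frame swimming speed
#'
#' Speed is the Euclidean displacement between consecutive resolved frames
#' divided by their time separation, assigned to the later frame; a rolling
#' median of width `round(smooth_window_s * frame_rate)` frames (bumped to
#' odd) is then applied within each contiguous resolved stretch. The first
#' frame, and frames inside unresolved gaps, carry no speed value (`NA`).
#'
#' @param traj A [trajectory()].
#' @param smooth_window_s Rolling-median width in seconds; 0 disables smoothing.
#' @return Numeric vector of mm/s, one element per frame.
#' @export
compute_speed <- function(traj, smooth_window_s = 1) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- which(!traj$missing)
  if (length(idx) < 2) stop("need at least 2 resolved frames to compute speed")
  sp <- rep(NA_real_, length(traj$t))
  d <- sqrt(diff(traj$x[idx])^2 + diff(traj$y[idx])^2)
  sp[idx[-1]] <- d / diff(traj$t[idx])
  k <- as.integer(round(smooth_window_s * traj$frame_rate))
  .segment_runmed(sp, k)
}

#' Per-frame immobility calls
#'
#' A frame is immobile when its speed is strictly below
#' `params$speed_threshold` (so speeds exactly at the threshold count as
#' mobile). Frames without a speed value inherit the preceding frame's call;
#' leading frames before the first call inherit the first one.
#'
#' @param speed Numeric speed vector from [compute_speed()].
#' @param params A [scoring_params()].
#' @return Logical vector, `TRUE` = immobile.
#' @export
classify_immobility <- function(speed, params = scoring_params()) {
  stopifnot(inherits(params, "scoring_params"))
  imm <- speed < params$speed_threshold
  if (all(is.na(imm))) stop("no speed values to classify")
  # last-observation-carried-forward, then backfill the leading run
  ind <- cumsum(!is.na(imm))
  first <- which(ind > 0)[1]
  ind[ind == 0] <- 1L
  out <- imm[!is.na(imm)][ind]
  out
}

# internal bout-series constructor with invariant checks
.bout_series <- function(intervals, recording_span, min_sleep_s) {
  stopifnot(nrow(intervals) >= 1)
  if (abs(intervals$start_s[1]) > 1e-9 ||
      abs(intervals$end_s[nrow(intervals)] - recording_span) > 1e-9)
    stop("intervals do not span the recording")
  if (nrow(intervals) > 1) {
    if (any(abs(intervals$start_s[-1] - intervals$end_s[-nrow(intervals)]) > 1e-9))
      stop("intervals have gaps or overlaps")
    if (any(intervals$label[-1] == intervals$label[-nrow(intervals)]))
      stop("adjacent intervals share a label")
  }
  sl <- intervals$label == "sleep"
  if (any(sl & (intervals$end_s - intervals$start_s) < min_sleep_s - 1e-9))
    stop("sleep interval shorter than min_sleep_s")
  structure(list(intervals = intervals, recording_span = recording_span),
            class = "bout_series")
}

#' @export
print.bout_series <- function(x, ...) {
  sl <- x$intervals$label == "sleep"
  cat(sprintf("<bout_series> %.1f s span, %d sleep bouts, %.1f min total sleep\n",
              x$recording_span, sum(sl),
              sum(x$intervals$end_s[sl] - x$intervals$start_s[sl]) / 60))
  invisible(x)
}

#' Detect sleep and wake bouts
#'
#' Partitions the recording into alternating sleep/wake intervals from the
#' per-frame immobility calls:
#'
#' 1. mobile runs shorter than `min_interrupt_s` that are flanked by
#'    immobility on both sides are absorbed into it;
#' 2. maximal immobility runs lasting at least `min_sleep_s` become sleep;
#' 3. everything else is wake.
#'
#' Interval boundaries are frame-edge aligned and half-open: frame `i`
#' covers `[(i-1)/frame_rate, i/frame_rate)`.
#'
#' @param immobility Logical per-frame vector from [classify_immobility()].
#' @param frame_rate Frames per second.
#' @param params A [scoring_params()].
#' @return An object of class `bout_series` with elements `intervals`
#'   (data frame `start_s,end_s,label`) and `recording_span` (seconds).
#' @export
detect_bouts <- function(immobility, frame_rate, params = scoring_params()) {
  stopifnot(length(immobility) > 0, !anyNA(immobility), frame_rate > 0,
            inherits(params, "scoring_params"))
  n <- length(immobility)
  imm <- as.logical(immobility)

  r <- rle(imm)
  if (params$min_interrupt_s > 0 && length(r$lengths) > 2) {
    interior <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    absorb <- !r$values & interior & (r$lengths / frame_rate < params$min_interrupt_s - 1e-9)
    if (any(absorb)) {
      r$values[absorb] <- TRUE
      imm <- inverse.rle(r)
      r <- rle(imm)
    }
  }
  # immobility runs long enough to qualify as sleep
  sleep_run <- r$values & (r$lengths / frame_rate >= params$min_sleep_s - 1e-9)
  rl <- rle(inverse.rle(list(lengths = r$lengths, values = sleep_run)))
  rl$values <- ifelse(rl$values, "sleep", "wake")
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  intervals <- data.frame(start_s = (starts - 1L) / frame_rate,
                          end_s = ends / frame_rate,
                          label = rl$values, stringsAsFactors = FALSE)
  .bout_series(intervals, n / frame_rate, params$min_sleep_s)
}

# overlap of [a0,a1) with [b0,b1)
.overlap <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))

#' Sleep-architecture summary for one fish
#'
#' Computes, over an analysis window, the figure-level metrics: total sleep
#' (minutes), sleep bout count, mean bout duration (s), waking activity
#' (time-weighted mean speed over wake intervals, mm/s) and a binned sleep
#' profile. Bouts straddling the window or a bin edge contribute only their
#' overlapping portion to totals and profile, but count once toward the bout
#' count (and the bout-duration mean, with their full duration) if their
#' midpoint lies inside the window. With zero counted bouts the mean bout
#' duration is reported as `NA`.
#'
#' @param bouts A `bout_series` from [detect_bouts()].
#' @param speed Speed vector from [compute_speed()] (same recording).
#' @param window `c(start_s, end_s)` within the recording; `NULL` = full span.
#' @param bin_minutes Profile bin width (default 60); the last bin is
#'   truncated if it does not divide the window.
#' @param frame_rate Frames per second (needed to place speed frames).
#' @return List of class `sleep_metrics`.
#' @export
summarize_sleep <- function(bouts, speed, window = NULL, bin_minutes = 60,
                            frame_rate) {
  stopifnot(inherits(bouts, "bout_series"))
  if (is.null(window)) window <- c(0, bouts$recording_span)
  if (!(window[1] < window[2]) || window[1] < -1e-9 ||
      window[2] > bouts$recording_span + 1e-9) stop("invalid analysis window")

  iv <- bouts$intervals
  sl <- iv[iv$label == "sleep", , drop = FALSE]
  ov <- .overlap(sl$start_s, sl$end_s, window[1], window[2])
  total_sleep_min <- sum(ov) / 60
  mid_in <- (sl$start_s + sl$end_s) / 2 >= window[1] &
            (sl$start_s + sl$end_s) / 2 < window[2]
  bout_count <- sum(mid_in)
  mean_bout_s <- if (bout_count > 0) mean(sl$end_s[mid_in] - sl$start_s[mid_in]) else NA_real_

  # waking activity: frames whose span midpoint falls in a wake interval & window
  # (intervals are frame-aligned and contiguous, so expand by run lengths)
  frame_mid <- (seq_along(speed) - 0.5) / frame_rate
  iv_frames <- as.integer(round((iv$end_s - iv$start_s) * frame_rate))
  in_wake <- rep(iv$label == "wake", iv_frames)
  if (length(in_wake) != length(speed)) {  # non frame-aligned edge case
    in_wake <- rep(FALSE, length(speed))
    wk <- iv[iv$label == "wake", , drop = FALSE]
    for (j in seq_len(nrow(wk))) {
      in_wake <- in_wake | (frame_mid >= wk$start_s[j] & frame_mid < wk$end_s[j])
    }
  }
  use <- in_wake & frame_mid >= window[1] & frame_mid < window[2] & !is.na(speed)
  waking_mm_s <- if (any(use)) mean(speed[use]) else NA_real_

  bw <- bin_minutes * 60
  edges <- seq(window[1], window[2], by = bw)
  if (edges[length(edges)] < window[2] - 1e-9) edges <- c(edges, window[2])
  profile <- vapply(seq_len(length(edges) - 1L), function(b) {
    sum(.overlap(sl$start_s, sl$end_s, edges[b], edges[b + 1L])) / 60
  }, 0)
  names(profile) <- sprintf("bin%02d", seq_along(profile))

  structure(list(total_sleep_min = total_sleep_min,
                 sleep_bout_count = bout_count,
                 mean_bout_duration_s = mean_bout_s,
                 waking_activity_mm_per_s = waking_mm_s,
                 profile = profile,
                 window = window, bin_minutes = bin_minutes),
            class = "sleep_metrics")
}

#' @export
print.sleep_metrics <- function(x, ...) {
  cat(sprintf("<sleep_metrics> total %.1f min | %d bouts | mean bout %.1f s | waking %.2f mm/s\n",
              x$total_sleep_min, x$sleep_bout_count, x$mean_bout_duration_s,
              x$waking_activity_mm_per_s))
  invisible(x)
}

# full per-fish scoring chain on one trajectory
.score_one <- function(traj, params, windows, bin_minutes, max_gap_s) {
  traj <- fill_gaps(traj, max_gap_s)
  sp <- compute_speed(traj, params$smooth_window_s)
  imm <- classify_immobility(sp, params)
  bouts <- detect_bouts(imm, traj$frame_rate, params)
  rows <- lapply(names(windows), function(wn) {
    m <- summarize_sleep(bouts, sp, windows[[wn]], bin_minutes, traj$frame_rate)
    cbind(data.frame(subject_id = traj$subject_id, population = traj$population,
                     treatment = traj$treatment, window = wn,
                     total_sleep_min = m$total_sleep_min,
                     bout_count = m$sleep_bout_count,
                     mean_bout_s = m$mean_bout_duration_s,
                     waking_mm_s = m$waking_activity_mm_per_s,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(m$profile)))
  })
  do.call(rbind, rows)
}

#' Score a cohort of recordings
#'
#' Reads every fish listed in a manifest (see [read_manifest()]), runs the
#' scoring chain (gap filling, speed, immobility, bout detection, summary)
#' and returns one tidy row per fish and analysis window. Per-fish failures
#' are reported in the `failures` attribute, never silently dropped.
#'
#' @param manifest Manifest data frame or path to a manifest CSV.
#' @param params A [scoring_params()].
#' @param windows Named list of analysis windows (`c(start_s, end_s)` or
#'   `NULL` for the full recording); default a single full-recording window.
#' @param bin_minutes Profile bin width, minutes.
#' @param max_gap_s Gap-fill limit passed to [fill_gaps()].
#' @return Data frame of per-fish metrics with attribute `failures`
#'   (data frame `file,error`) and attribute `params`.
#' @export
score_cohort <- function(manifest, params = scoring_params(),
                         windows = list(full = NULL), bin_minutes = 60,
                         max_gap_s = 1) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0)
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      traj <- read_tracking(manifest$file[i], dialect = "generic",
                            calibration = manifest$calibration_mm_per_px[i],
                            subject_id = manifest$subject_id[i],
                            population = manifest$population[i],
                            treatment = manifest$treatment[i],
                            zt_start = manifest$zt_start[i])
      .score_one(traj, params, windows, bin_minutes, max_gap_s)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(file = manifest$file[i],
                                                error = conditionMessage(res),
                                                stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("all recordings failed to score")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(file = character(), error = character())
  attr(out, "params") <- params
  out
}
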
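#' Activity simulator parameters
#'
#' Two-state semi-Markov model of fish locomotion: the animal alternates
#' between wake and rest bouts with exponentially distributed durations
#' (truncated at one frame), swims with gamma-distributed frame speeds and
#' a smoothly drifting heading inside a rectangular arena while awake, and
#' jitters around an anchor point (Gaussian positional noise) while at
#' rest. Rest bouts of 60 s and longer are the generator's ground-truth
#' sleep; the probability that a rest bout reaches 60 s is emergent and is
#' reported in the ground truth, not set.
#'
#' @param mean_sleep_bout_s,mean_wake_bout_s Mean rest/wake bout durations (s).
#' @param wake_speed_shape,wake_speed_scale Gamma parameters of frame speeds
#'   while awake (mm/s); defaults give a 20 mm/s mean swim speed.
#' @param rest_jitter_sd Positional noise while at rest (mm).
#' @param duration_h Recording length (hours).
#' @param frame_rate Frames per second (default 15).
#' @param arena_mm Arena width/height in mm.
#' @return Object of class `activity_params`.
#' @export
activity_params <- function(mean_sleep_bout_s, mean_wake_bout_s,
                            wake_speed_shape = 4, wake_speed_scale = 5,
                            rest_jitter_sd = 0.1, duration_h = 24,
                            frame_rate = 15, arena_mm = c(250, 120)) {
  v <- c(mean_sleep_bout_s, mean_wake_bout_s, wake_speed_shape, wake_speed_scale,
         duration_h, frame_rate, arena_mm)
  if (any(!is.finite(v)) || any(v <= 0)) stop("activity parameters must be positive")
  if (rest_jitter_sd < 0) stop("rest_jitter_sd must be >= 0")
  structure(list(mean_sleep_bout_s = mean_sleep_bout_s,
                 mean_wake_bout_s = mean_wake_bout_s,
                 wake_speed_shape = wake_speed_shape,
                 wake_speed_scale = wake_speed_scale,
                 rest_jitter_sd = rest_jitter_sd,
                 duration_h = duration_h, frame_rate = frame_rate,
                 arena_mm = arena_mm),
            class = "activity_params")
}

#' Population/treatment presets for the simulator
#'
#' Parameter sets emulating the study's phenotypes, as plausibility anchors
#' for testing (not estimates of real fish): surface controls sleep roughly
#' 45% of the day while cavefish controls sleep under 10%; the orexin
#' receptor antagonist raises cavefish sleep through both shorter wake
#' bouts and longer rest bouts while leaving surface fish essentially
#' unchanged; starvation and lateral-line ablation act in the same
#' direction as the antagonist, in cavefish only; the agonist suppresses
#' surface sleep and leaves already-sleepless cavefish unchanged.
#'
#' @param population `"surface"` or `"cavefish"`.
#' @param treatment One of `"control"`, `"antagonist"`, `"agonist"`,
#'   `"starvation"`, `"lateral_line_ablation"`.
#' @param ... Overrides passed to [activity_params()] (e.g. `duration_h`).
#' @return An [activity_params()] object.
#' @export
preset <- function(population = c("surface", "cavefish"),
                   treatment = c("control", "antagonist", "agonist",
                                 "starvation", "lateral_line_ablation"),
                   ...) {
  population <- match.arg(population)
  treatment <- match.arg(treatment)
  base <- list(
    surface = c(sleep = 250, wake = 280),   # ~45% of time at rest, mostly >60 s bouts
    cavefish = c(sleep = 60, wake = 420)    # short rest, long wake: <10% sleep
  )[[population]]
  rescued <- c(sleep = 150, wake = 210)     # cavefish under sleep-restoring treatment
  p <- switch(treatment,
    control = base,
    antagonist = if (population == "cavefish") rescued else base,
    starvation = if (population == "cavefish") rescued else base,
    lateral_line_ablation = if (population == "cavefish") rescued else base,
    agonist = if (population == "surface") c(sleep = 100, wake = 420) else base
  )
  activity_params(mean_sleep_bout_s = unname(p["sleep"]),
                  mean_wake_bout_s = unname(p["wake"]), ...)
}

# fold a coordinate into [0, L] (reflecting boundaries)
.reflect <- function(p, L) {
  q <- p %% (2 * L)
  L - abs(q - L)
}

#' Simulate one activity recording
#'
#' Draws alternating wake/rest bouts, renders a frame-by-frame bounded
#' random walk, and returns both the trajectory and the generator's ground
#' truth. Identical `(params, seed)` give bit-identical output.
#'
#' @param params An [activity_params()] (see also [preset()]).
#' @param seed Integer seed.
#' @param subject_id,population,treatment,zt_start Metadata attached to the
#'   trajectory.
#' @return List with `trajectory` (a [trajectory()]) and `truth`: data frame
#'   of true bouts (`start_s, end_s, state, is_sleep`), `sleep_fraction`
#'   (fraction of recorded time in rest bouts >= 60 s), `p_rest_epoch`
#'   (fraction of rest bouts reaching 60 s), `params`, `seed`.
#' @export
simulate_activity <- function(params, seed = 1, subject_id = "sim",
                              population = "surface", treatment = "control",
                              zt_start = 0) {
  stopifnot(inherits(params, "activity_params"))
  set.seed(as.integer(seed))
  fr <- params$frame_rate
  n <- as.integer(round(params$duration_h * 3600 * fr))

  # bout skeleton: alternate wake/rest, exponential durations, >= 1 frame
  # (drawn in batches until the recording is covered, then trimmed)
  states <- character(0); lens <- integer(0)
  batch <- max(16L, ceiling(2 * params$duration_h * 3600 /
                              (params$mean_wake_bout_s + params$mean_sleep_bout_s)))
  while (sum(lens) < n) {
    w <- pmax(1L, as.integer(round(stats::rexp(batch, 1 / params$mean_wake_bout_s) * fr)))
    r <- pmax(1L, as.integer(round(stats::rexp(batch, 1 / params$mean_sleep_bout_s) * fr)))
    lens <- c(lens, as.vector(rbind(w, r)))
    states <- c(states, rep(c("wake", "rest"), batch))
  }
  cut_at <- which(cumsum(lens) >= n)[1]
  lens <- lens[seq_len(cut_at)]; states <- states[seq_len(cut_at)]
  lens[cut_at] <- lens[cut_at] - (sum(lens) - n)
  keep <- lens > 0
  states <- states[keep]; lens <- lens[keep]

  lab <- rep(states, lens)
  wake <- lab == "wake"

  # wake kinematics: gamma frame speeds, drifting heading; rest: hold anchor
  step_len <- numeric(n)
  nw <- sum(wake)
  if (nw > 0) step_len[wake] <- stats::rgamma(nw, shape = params$wake_speed_shape,
                                              scale = params$wake_speed_scale) / fr
  theta <- cumsum(stats::rnorm(n, 0, 0.4))
  dx <- step_len * cos(theta); dy <- step_len * sin(theta)
  x <- .reflect(params$arena_mm[1] / 2 + cumsum(dx), params$arena_mm[1])
  y <- .reflect(params$arena_mm[2] / 2 + cumsum(dy), params$arena_mm[2])
  if (params$rest_jitter_sd > 0 && any(!wake)) {
    nr <- sum(!wake)
    x[!wake] <- x[!wake] + stats::rnorm(nr, 0, params$rest_jitter_sd)
    y[!wake] <- y[!wake] + stats::rnorm(nr, 0, params$rest_jitter_sd)
  }

  ends <- cumsum(lens); starts <- ends - lens + 1L
  truth_bouts <- data.frame(start_s = (starts - 1L) / fr, end_s = ends / fr,
                            state = states, stringsAsFactors = FALSE)
  dur <- truth_bouts$end_s - truth_bouts$start_s
  truth_bouts$is_sleep <- truth_bouts$state == "rest" & dur >= 60
  rest <- truth_bouts$state == "rest"

  traj <- trajectory(t = (seq_len(n) - 1L) / fr, x = x, y = y,
                     subject_id = subject_id, population = population,
                     treatment = treatment, frame_rate = fr, zt_start = zt_start)
  list(trajectory = traj,
       truth = list(bouts = truth_bouts,
                    sleep_fraction = sum(dur[truth_bouts$is_sleep]) / (n / fr),
                    p_rest_epoch = if (any(rest)) mean(dur[rest] >= 60) else NA_real_,
                    params = params, seed = as.integer(seed)))
}

#' Score a single in-memory trajectory
#'
#' Runs the full scoring chain (gap filling, speed, immobility, bout
#' detection, summary) on one trajectory without touching disk — the
#' per-fish unit that [score_cohort()] applies to every manifest entry.
#'
#' @inheritParams score_cohort
#' @param traj A [trajectory()].
#' @return One-row-per-window data frame of metrics (see [score_cohort()]).
#' @export
score_trajectory <- function(traj, params = scoring_params(),
                             windows = list(full = NULL), bin_minutes = 60,
                             max_gap_s = 1) {
  .score_one(traj, params, windows, bin_minutes, max_gap_s)
}

#' Simulate a qPCR plate with known fold changes
#'
#' Reference-gene Cts are drawn per sample from Normal(15, 0.2); target Cts
#' are the sample's reference Ct plus the group's true delta-Ct; technical
#' replicates add Normal(0, replicate_sd) noise per well, and each run adds
#' its additive offset to every Ct it contains. A shared inter-run
#' calibrator sample (`sample_id "IRC"`, group `"calibrator"`) is measured
#' on every run. True fold changes relative to the first group in
#' `group_delta_ct` are recorded in the ground truth.
#'
#' @param group_delta_ct Named numeric vector: true delta-Ct (target minus
#'   reference) per group; the first name is the calibrator group.
#' @param n_per_group Biological samples per group.
#' @param n_replicates Technical replicates per sample and gene.
#' @param replicate_sd Replicate noise SD, cycles.
#' @param run_offsets Numeric vector of additive per-run Ct offsets; its
#'   length sets the number of runs (samples are spread round-robin).
#' @param seed Integer seed.
#' @param target,reference Gene labels to emit.
#' @return List: `plate` (long data frame), `truth` (`fold` per group,
#'   `run_offsets`, `delta_ct`).
#' @export
simulate_qpcr <- function(group_delta_ct, n_per_group = 4, n_replicates = 3,
                          replicate_sd = 0.15, run_offsets = 0, seed = 1,
                          target = "hcrt", reference = "gapdh") {
  stopifnot(length(group_delta_ct) >= 1, !is.null(names(group_delta_ct)))
  set.seed(as.integer(seed))
  groups <- names(group_delta_ct)
  n_runs <- length(run_offsets)
  rows <- list()
  emit <- function(sample_id, group, run, ref_ct, dct) {
    off <- run_offsets[run]
    rbind(
      data.frame(sample_id = sample_id, group = group,
                 run_id = sprintf("run%d", run), gene = reference,
                 ct = ref_ct + off + stats::rnorm(n_replicates, 0, replicate_sd),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = sample_id, group = group,
                 run_id = sprintf("run%d", run), gene = target,
                 ct = ref_ct + dct + off + stats::rnorm(n_replicates, 0, replicate_sd),
                 stringsAsFactors = FALSE))
  }
  k <- 0L
  for (g in groups) for (i in seq_len(n_per_group)) {
    k <- k + 1L
    run <- ((k - 1L) %% n_runs) + 1L
    rows[[length(rows) + 1L]] <-
      emit(sprintf("%s_%02d", g, i), g, run, stats::rnorm(1, 15, 0.2),
           group_delta_ct[[g]])
  }
  # shared calibrator measured on every run (fresh replicate noise per run,
  # same underlying sample, so runs differ only by their offsets + noise)
  irc_ref <- stats::rnorm(1, 15, 0.2)
  irc_dct <- group_delta_ct[[1]]
  for (run in seq_len(n_runs)) {
    rows[[length(rows) + 1L]] <- emit("IRC", "calibrator", run, irc_ref, irc_dct)
  }
  plate <- do.call(rbind, rows)
  truth <- list(fold = stats::setNames(2^(-(group_delta_ct - group_delta_ct[[1]])), groups),
                run_offsets = run_offsets,
                delta_ct = group_delta_ct)
  list(plate = plate, truth = truth)
}

#' Simulate a fluorescence z-stack with planted somata
#'
#' Places `n_cells` Gaussian-profile somata (in-plane sigma =
#' `soma_radius_px / 2`, axial sigma 1.5 slices, centers on the slice grid)
#' at rejection-sampled positions honoring `min_separation`, on a uniform
#' background, and adds Gaussian noise of SD `noise_sd` (the high-count
#' approximation to Poisson shot noise). Ground truth records positions,
#' amplitudes, and each cell's integrated in-plane intensity (the sum of
#' its noiseless contribution to the maximum projection).
#'
#' @param n_cells Number of somata (0 allowed).
#' @param soma_radius_px Apparent soma radius in pixels.
#' @param intensity_mean Mean peak amplitude above background.
#' @param background Uniform background level.
#' @param noise_sd Per-voxel noise SD.
#' @param min_separation Minimum center-to-center distance, px.
#' @param size `c(ny, nx)` image size.
#' @param n_slices Number of z slices (2 um steps).
#' @param seed Integer seed.
#' @return List: `stack` (`image_stack`), `truth` (data frame `y, x, z,
#'   amplitude, integrated_int`), `seed`.
#' @export
simulate_stack <- function(n_cells = 10, soma_radius_px = 4, intensity_mean = 400,
                           background = 30, noise_sd = 6, min_separation = 16,
                           size = c(160, 160), n_slices = 9, seed = 1) {
  set.seed(as.integer(seed))
  ny <- size[1]; nx <- size[2]
  margin <- ceiling(3 * soma_radius_px)
  centers <- matrix(numeric(0), 0, 2)
  guard <- 0
  while (nrow(centers) < n_cells) {
    cand <- c(stats::runif(1, margin, ny - margin), stats::runif(1, margin, nx - margin))
    ok <- !nrow(centers) ||
      all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >= min_separation)
    if (ok) centers <- rbind(centers, cand)
    guard <- guard + 1
    if (guard > 10000 * max(1, n_cells)) stop("cannot place somata at this min_separation")
  }
  zc <- if (n_cells) sample(seq(2, max(2, n_slices - 1)), n_cells, replace = TRUE) else integer(0)
  amp <- if (n_cells) pmax(stats::rnorm(n_cells, intensity_mean, 0.1 * intensity_mean),
                           0.3 * intensity_mean) else numeric(0)

  sigma <- soma_radius_px / 2
  sigma_z <- 1.5
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  clean_proj <- matrix(background, ny, nx)
  stack <- array(background, dim = c(ny, nx, n_slices))
  truth <- data.frame(y = numeric(0), x = numeric(0), z = integer(0),
                      amplitude = numeric(0), integrated_int = numeric(0))
  for (i in seq_len(n_cells)) {
    plane <- amp[i] * exp(-((yy - centers[i, 1])^2 + (xx - centers[i, 2])^2) / (2 * sigma^2))
    for (z in seq_len(n_slices)) {
      stack[, , z] <- stack[, , z] + plane * exp(-(z - zc[i])^2 / (2 * sigma_z^2))
    }
    clean_proj <- clean_proj + plane
    truth <- rbind(truth, data.frame(y = centers[i, 1], x = centers[i, 2], z = zc[i],
                                     amplitude = amp[i], integrated_int = sum(plane)))
  }
  if (noise_sd > 0) {
    stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd), dim = dim(stack))
    stack[stack < 0] <- 0
  }
  truth <- truth[order(truth$y, truth$x), ]
  rownames(truth) <- NULL
  list(stack = as_image_stack(stack), truth = truth, seed = as.integer(seed))
}

#' Emit a complete synthetic study to a directory
#'
#' Writes everything the pipeline consumes, with ground truth alongside:
#' per-fish trajectory CSVs plus a cohort manifest (a 2x2
#' population-by-treatment behavioral design), a long-format qPCR CSV with
#' planted group fold changes and inter-run offsets, per-brain TIFF stacks
#' with planted somata, and a `ground_truth.json`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; every file is a deterministic function
#'   of it.
#' @param n_per_cell Fish per population-by-treatment cell.
#' @param duration_h Recording length per fish, hours.
#' @param treatment Treated-arm label (default `"antagonist"`).
#' @param n_brains_per_group Brains (stacks) per population for cell counts.
#' @param frame_rate Frames per second.
#' @return The directory path, invisibly; side effect: files on disk.
#' @export
simulate_study <- function(dir, seed = 1, n_per_cell = 12, duration_h = 2,
                           treatment = "antagonist", n_brains_per_group = 4,
                           frame_rate = 15) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  man <- list(); truth_beh <- list()
  k <- 0L
  for (pop in c("surface", "cavefish")) for (tr in c("control", treatment)) {
    for (i in seq_len(n_per_cell)) {
      k <- k + 1L
      sid <- sprintf("%s_%s_%02d", pop, tr, i)
      sim <- simulate_activity(preset(pop, tr, duration_h = duration_h,
                                      frame_rate = frame_rate),
                               seed = seed * 1000L + k, subject_id = sid,
                               population = pop, treatment = tr, zt_start = 0)
      f <- sprintf("traj_%s.csv", sid)
      write_tracking(sim$trajectory, file.path(dir, f))
      man[[k]] <- data.frame(file = f, subject_id = sid, population = pop,
                             treatment = tr, zt_start = 0,
                             calibration_mm_per_px = 1, stringsAsFactors = FALSE)
      truth_beh[[k]] <- data.frame(subject_id = sid, population = pop, treatment = tr,
                                   sleep_fraction = sim$truth$sleep_fraction,
                                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, man)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)

  # qPCR: cavefish controls ~3-fold over surface controls; treatment restores
  dct <- c(surface_control = 5, surface_treated = 5,
           cavefish_control = 5 - log2(3), cavefish_treated = 5 - log2(1.2))
  qp <- simulate_qpcr(dct, n_per_group = 4, run_offsets = c(0, 0.5),
                      seed = seed + 17L)
  utils::write.csv(qp$plate, file.path(dir, "qpcr.csv"), row.names = FALSE)

  stacks <- list(); j <- 0L
  cell_n <- c(surface = 6, cavefish = 12)   # cavefish carry more HCRT somata
  for (pop in c("surface", "cavefish")) for (i in seq_len(n_brains_per_group)) {
    j <- j + 1L
    st <- simulate_stack(n_cells = cell_n[[pop]], seed = seed * 100L + j)
    f <- sprintf("stack_%s_%02d.tif", pop, i)
    write_stack(st$stack, file.path(dir, f))
    stacks[[j]] <- list(file = f, population = pop, n_cells = cell_n[[pop]])
  }
  jsonlite::write_json(
    list(seed = seed,
         behavior = do.call(rbind, truth_beh),
         qpcr = list(fold = as.list(qp$truth$fold), run_offsets = qp$truth$run_offsets),
         stacks = stacks),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
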
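make_traj <- function(x, y = NULL, fr = 15) {
  n <- length(x)
  if (is.null(y)) y <- rep(0, n)
  trajectory((0:(n - 1)) / fr, x, y, frame_rate = fr)
}

test_that("compute_speed handles constant, linear and unsmoothed cases", {
  tr <- make_traj(rep(2, 100))
  expect_equal(compute_speed(tr, 1)[-1], rep(0, 99))

  tr2 <- make_traj(seq_len(100))     # 1 mm per frame at 15 Hz
  sp <- compute_speed(tr2, 0)
  expect_equal(sp[-1], rep(15, 99))
  expect_true(is.na(sp[1]))

  set.seed(21)
  tr3 <- make_traj(cumsum(rnorm(500)), cumsum(rnorm(500)))
  raw <- compute_speed(tr3, 0)
  expect_equal(compute_speed(tr3, 1 / 15), raw)  # width-1 median is identity

  expect_error(compute_speed(make_traj(c(NA, NA, 1), y = c(NA, NA, 1))), "2 resolved")
})

test_that("speed spans unresolved gaps and leaves gap frames without values", {
  x <- c(0, 1, NA, NA, 4, 5)
  tr <- make_traj(x)
  sp <- compute_speed(tr, 0)
  expect_true(all(is.na(sp[c(1, 3, 4)])))
  # frames 2 and 5: displacement / elapsed time (3 mm over 3 frames)
  expect_equal(sp[2], 15)
  expect_equal(sp[5], 3 / (3 / 15))
  expect_equal(sp[6], 15)
})

test_that("immobility calls use strict threshold and inherit across gaps", {
  p <- scoring_params(speed_threshold = 4)
  expect_true(all(classify_immobility(c(NA, rep(0, 9)), p)))
  expect_false(any(classify_immobility(c(NA, rep(4, 9)), p)))  # at threshold = mobile

  set.seed(3)
  sp <- c(NA, runif(999, 0, 8))
  expect_identical(classify_immobility(sp, p)[-1], sp[-1] < 4)

  # NA frames inherit the preceding call; leading NAs inherit the first call
  sp2 <- c(NA, 1, NA, NA, 6, NA)
  expect_identical(classify_immobility(sp2, p),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("detect_bouts applies the 60 s rule at frame resolution", {
  fr <- 15
  p <- scoring_params()
  # 120 s immobility inside a 300 s record
  imm <- rep(FALSE, 300 * fr)
  imm[1001:(1000 + 120 * fr)] <- TRUE
  b <- detect_bouts(imm, fr, p)
  sl <- b$intervals[b$intervals$label == "sleep", ]
  expect_equal(nrow(sl), 1)
  expect_equal(sl$end_s - sl$start_s, 120)

  # 59 s run misses the threshold, 60 s run meets it
  imm59 <- rep(FALSE, 300 * fr); imm59[101:(100 + 59 * fr)] <- TRUE
  b59 <- detect_bouts(imm59, fr, p)
  expect_equal(sum(b59$intervals$label == "sleep"), 0)
  imm60 <- rep(FALSE, 300 * fr); imm60[101:(100 + 60 * fr)] <- TRUE
  b60 <- detect_bouts(imm60, fr, p)
  expect_equal(sum(b60$intervals$label == "sleep"), 1)
})

test_that("brief movement is absorbed, sustained movement splits bouts", {
  fr <- 15
  imm <- rep(TRUE, 150 * fr)
  imm[70 * fr + 1:10] <- FALSE                 # 0.67 s of movement
  b <- detect_bouts(imm, fr, scoring_params(min_interrupt_s = 1))
  expect_equal(sum(b$intervals$label == "sleep"), 1)
  # with min_interrupt_s = 0 (strictest reading) the movement splits the bout
  b0 <- detect_bouts(imm, fr, scoring_params(min_interrupt_s = 0))
  expect_equal(sum(b0$intervals$label == "sleep"), 2)
  # edge movement is never absorbed
  imm2 <- c(rep(FALSE, 5), rep(TRUE, 90 * fr))
  b2 <- detect_bouts(imm2, fr, scoring_params(min_interrupt_s = 1))
  expect_equal(b2$intervals$label[1], "wake")
})

test_that("detect_bouts matches the brute-force enumerator on random series", {
  set.seed(42)
  fr <- 15
  for (rep_i in 1:25) {
    n <- sample(500:4000, 1)
    imm <- runif(n) < runif(1, 0.3, 0.98)
    mi <- sample(c(0, 1, 2), 1)
    b <- detect_bouts(imm, fr, scoring_params(min_interrupt_s = mi))
    sl <- b$intervals[b$intervals$label == "sleep", c("start_s", "end_s")]
    rownames(sl) <- NULL
    orc <- oracle_bouts(imm, fr, 60, mi)
    expect_equal(nrow(sl), nrow(orc))
    if (nrow(orc)) expect_equal(as.matrix(sl), as.matrix(orc), ignore_attr = TRUE)
  }
})

test_that("bout series partitions the recording exactly", {
  set.seed(9)
  for (i in 1:10) {
    imm <- runif(2000) < 0.9
    b <- detect_bouts(imm, 15, scoring_params())
    iv <- b$intervals
    expect_equal(sum(iv$end_s - iv$start_s), b$recording_span, tolerance = 1e-9)
    expect_true(all(iv$start_s[-1] == iv$end_s[-nrow(iv)]))
    expect_true(all(iv$label[-1] != iv$label[-nrow(iv)]))
  }
})

test_that("summaries report totals, counts, durations and binned profiles", {
  fr <- 15
  # one 120 s bout in a 24 h window
  n <- 24 * 3600 * fr
  imm <- rep(FALSE, n); imm[1501:(1500 + 120 * fr)] <- TRUE
  b <- detect_bouts(imm, fr, scoring_params())
  sp <- rep(5, n); sp[1] <- NA
  m <- summarize_sleep(b, sp, NULL, 60, fr)
  expect_equal(m$total_sleep_min, 2)
  expect_equal(m$sleep_bout_count, 1)
  expect_equal(m$mean_bout_duration_s, 120)
  expect_equal(sum(m$profile), m$total_sleep_min, tolerance = 1e-6)
  expect_equal(m$waking_activity_mm_per_s, 5)

  # 90 s bout straddling an hourly bin edge 30 s before it
  imm2 <- rep(FALSE, 2 * 3600 * fr)
  start <- (3600 - 30) * fr + 1
  imm2[start:(start + 90 * fr - 1)] <- TRUE
  b2 <- detect_bouts(imm2, fr, scoring_params())
  m2 <- summarize_sleep(b2, rep(5, length(imm2)), NULL, 60, fr)
  expect_equal(unname(m2$profile), c(0.5, 1.0))

  # zero bouts -> missing mean duration
  b3 <- detect_bouts(rep(FALSE, 3000), fr, scoring_params())
  m3 <- summarize_sleep(b3, rep(5, 3000), NULL, 60, fr)
  expect_equal(m3$sleep_bout_count, 0)
  expect_true(is.na(m3$mean_bout_duration_s))
})

test_that("total sleep equals the interval-sum oracle on a simulated fish", {
  sim <- simulate_activity(preset("surface", "control", duration_h = 0.5), seed = 5)
  sp <- compute_speed(sim$trajectory, 1)
  imm <- classify_immobility(sp, scoring_params())
  b <- detect_bouts(imm, 15, scoring_params())
  m <- summarize_sleep(b, sp, NULL, 60, 15)
  sl <- b$intervals[b$intervals$label == "sleep", ]
  expect_equal(m$total_sleep_min, sum(sl$end_s - sl$start_s) / 60, tolerance = 1e-9)
})

test_that("window edges use overlap for totals and midpoints for counts", {
  fr <- 15
  imm <- rep(FALSE, 3600 * fr)
  imm[(1800 - 50) * fr + 1:(100 * fr)] <- TRUE    # 100 s bout centred on t=1800
  b <- detect_bouts(imm, fr, scoring_params())
  sp <- rep(5, length(imm))
  # window ends at the bout midpoint: half the bout's time, but count 0
  m_left <- summarize_sleep(b, sp, c(0, 1800), 60, fr)
  expect_equal(m_left$total_sleep_min, 50 / 60, tolerance = 1e-9)
  expect_equal(m_left$sleep_bout_count, 0)
  # right half: midpoint rule assigns the bout (and its full duration) here
  m_right <- summarize_sleep(b, sp, c(1800, 3600), 60, fr)
  expect_equal(m_right$total_sleep_min, 50 / 60, tolerance = 1e-9)
  expect_equal(m_right$sleep_bout_count, 1)
  expect_equal(m_right$mean_bout_duration_s, 100)
  # partition conservation inside a window
  iv <- b$intervals
  wake_min <- sum(pmax(0, pmin(iv$end_s, 1800) - pmax(iv$start_s, 0))[iv$label == "wake"]) / 60
  expect_equal(wake_min + m_left$total_sleep_min, 1800 / 60, tolerance = 1e-9)
})

test_that("score_cohort propagates labels, records failures, ignores file order", {
  dir <- withr::local_tempdir()
  mp <- make_disk_cohort(dir, n_per_cell = 1, duration_h = 0.1)
  man <- read.csv(mp)
  out <- score_cohort(man)
  expect_equal(nrow(out), 4)
  expect_setequal(out$subject_id, man$subject_id)
  expect_equal(nrow(attr(out, "failures")), 0)

  # one unreadable file of 4: 3 rows + 1 recorded failure
  man_bad <- man
  man_bad$file[2] <- file.path(dir, "nope.csv")
  out2 <- score_cohort(man_bad)
  expect_equal(nrow(out2), 3)
  expect_equal(nrow(attr(out2, "failures")), 1)
  expect_match(attr(out2, "failures")$error, "not found")

  # permuting manifest order leaves per-fish metrics unchanged
  out3 <- score_cohort(man[c(3, 1, 4, 2), ])
  a <- out[order(out$subject_id), ]; b <- out3[order(out3$subject_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)

  man_none <- man; man_none$file <- paste0(man$file, ".gone")
  expect_error(score_cohort(man_none), "all recordings failed")
})

test_that("total sleep is monotone in the scoring thresholds", {
  set.seed(77)
  for (i in 1:5) {
    sim <- simulate_activity(preset("cavefish", "control", duration_h = 0.2),
                             seed = 300 + i)
    sp <- compute_speed(sim$trajectory, 1)
    totals <- sapply(c(1, 2, 4, 8, 16), function(thr) {
      p <- scoring_params(speed_threshold = thr)
      b <- detect_bouts(classify_immobility(sp, p), 15, p)
      iv <- b$intervals
      sum((iv$end_s - iv$start_s)[iv$label == "sleep"])
    })
    expect_true(all(diff(totals) >= 0))
    imm <- classify_immobility(sp, scoring_params())
    by_min <- sapply(c(20, 40, 60, 120), function(ms) {
      p <- scoring_params(min_sleep_s = ms)
      b <- detect_bouts(imm, 15, p)
      iv <- b$intervals
      c(total = sum((iv$end_s - iv$start_s)[iv$label == "sleep"]),
        count = sum(iv$label == "sleep"))
    })
    expect_true(all(diff(by_min["total", ]) <= 0))
    expect_true(all(diff(by_min["count", ]) <= 0))
  }
})
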
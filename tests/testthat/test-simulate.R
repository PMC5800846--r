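test_that("the activity generator is bit-reproducible from (params, seed)", {
  p <- preset("cavefish", "control", duration_h = 0.2)
  a <- simulate_activity(p, seed = 123)
  b <- simulate_activity(p, seed = 123)
  expect_identical(a$trajectory$x, b$trajectory$x)
  expect_identical(a$truth$bouts, b$truth$bouts)
  c <- simulate_activity(p, seed = 124)
  expect_false(identical(a$trajectory$x, c$trajectory$x))
})

test_that("ground truth partitions the recording and reports the 60 s rule", {
  sim <- simulate_activity(preset("surface", "control", duration_h = 0.5), seed = 2)
  tb <- sim$truth$bouts
  expect_equal(tb$start_s[1], 0)
  expect_equal(tb$end_s[nrow(tb)], 0.5 * 3600)
  expect_true(all(abs(tb$start_s[-1] - tb$end_s[-nrow(tb)]) < 1e-9))
  dur <- tb$end_s - tb$start_s
  expect_identical(tb$is_sleep, tb$state == "rest" & dur >= 60)
  expect_equal(sim$truth$sleep_fraction, sum(dur[tb$is_sleep]) / 1800, tolerance = 1e-12)
})

test_that("vanishing rest bouts yield essentially no scorable sleep", {
  p <- activity_params(mean_sleep_bout_s = 1, mean_wake_bout_s = 120, duration_h = 1)
  sim <- simulate_activity(p, seed = 10)
  m <- score_trajectory(sim$trajectory)
  expect_lt(m$total_sleep_min / 60, 0.01)
})

test_that("noiseless rest has exactly zero speed away from transitions", {
  p <- activity_params(mean_sleep_bout_s = 120, mean_wake_bout_s = 120,
                       rest_jitter_sd = 0, duration_h = 0.2)
  sim <- simulate_activity(p, seed = 3)
  sp <- compute_speed(sim$trajectory, 0)
  lab <- rep(sim$truth$bouts$state,
             round((sim$truth$bouts$end_s - sim$truth$bouts$start_s) * 15))
  inside_rest <- lab == "rest" & c("wake", lab[-length(lab)]) == "rest"
  expect_true(all(sp[inside_rest] == 0, na.rm = TRUE))
})

test_that("rest-bout durations follow the exponential law", {
  mu <- 60
  durs <- c()
  s <- 0
  while (length(durs) < 10000) {
    s <- s + 1
    sim <- simulate_activity(activity_params(mean_sleep_bout_s = mu,
                                             mean_wake_bout_s = 20,
                                             duration_h = 24, frame_rate = 5),
                             seed = 500 + s)
    tb <- sim$truth$bouts
    keep <- tb$state == "rest"
    if (nrow(tb) > 2) keep[c(1, nrow(tb))] <- FALSE   # drop truncated edge bouts
    durs <- c(durs, (tb$end_s - tb$start_s)[keep])
  }
  expect_lt(abs(mean(durs) - mu) / mu, 0.02)
})

test_that("presets encode the study's orderings", {
  sc <- preset("surface", "control"); cc <- preset("cavefish", "control")
  ca <- preset("cavefish", "antagonist"); sa <- preset("surface", "antagonist")
  expect_lt(sc$mean_wake_bout_s, cc$mean_wake_bout_s)
  expect_gt(sc$mean_sleep_bout_s, cc$mean_sleep_bout_s)
  # antagonist rescues cavefish through both margins
  expect_lt(ca$mean_wake_bout_s, cc$mean_wake_bout_s)
  expect_gt(ca$mean_sleep_bout_s, cc$mean_sleep_bout_s)
  # but leaves surface fish alone
  expect_identical(sa[c("mean_sleep_bout_s", "mean_wake_bout_s")],
                   sc[c("mean_sleep_bout_s", "mean_wake_bout_s")])
  # starvation / lateral-line ablation mirror the antagonist direction
  for (tr in c("starvation", "lateral_line_ablation")) {
    expect_identical(preset("cavefish", tr)$mean_sleep_bout_s, ca$mean_sleep_bout_s)
    expect_identical(preset("surface", tr)$mean_wake_bout_s, sc$mean_wake_bout_s)
  }
  expect_error(preset("cavefish", "espresso"), "arg")
})

test_that("qPCR generator plants exact folds when noise is off", {
  dmap <- c(cal = 5, test = 5 - log2(3))
  sim <- simulate_qpcr(dmap, n_per_group = 3, replicate_sd = 0, run_offsets = 0,
                       seed = 7)
  expect_equal(unname(sim$truth$fold["test"]), 3, tolerance = 1e-12)
  fc <- relative_expression(collapse_replicates(sim$plate, "hcrt", "gapdh"), "cal")
  expect_equal(fc$fold[fc$group == "test"], rep(3, 3), tolerance = 1e-9)
  expect_equal(fc$fold[fc$group == "cal"], rep(1, 3), tolerance = 1e-9)
})

test_that("stack generator honors counts, separation and intensity linearity", {
  empty <- simulate_stack(n_cells = 0, seed = 1)
  expect_warning(r0 <- detect_cells(max_project(empty$stack)), NA)
  expect_equal(nrow(r0$rois), 0)

  sim <- simulate_stack(n_cells = 5, seed = 21)
  d <- as.matrix(dist(sim$truth[, c("y", "x")]))
  expect_true(all(d[upper.tri(d)] >= 16))

  s1 <- simulate_stack(n_cells = 4, intensity_mean = 300, seed = 33)
  s2 <- simulate_stack(n_cells = 4, intensity_mean = 600, seed = 33)
  q1 <- quantify_cells(max_project(s1$stack), detect_cells(max_project(s1$stack)))
  q2 <- quantify_cells(max_project(s2$stack), detect_cells(max_project(s2$stack)))
  expect_equal(q1$count, 4); expect_equal(q2$count, 4)
  ratio <- sum(q2$cells$integrated_int) / sum(q1$cells$integrated_int)
  expect_lt(abs(ratio - 2), 0.12)
})

test_that("simulate_study writes a complete, internally consistent bundle", {
  dir <- withr::local_tempdir()
  simulate_study(dir, seed = 5, n_per_cell = 2, duration_h = 0.1,
                 n_brains_per_group = 1)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 8)          # 2 populations x 2 treatments x 2 fish
  expect_true(all(file.exists(man$file)))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  expect_equal(nrow(truth$behavior), 8)
  qp <- read.csv(file.path(dir, "qpcr.csv"))
  expect_setequal(unique(qp$gene), c("hcrt", "gapdh"))
  stack_files <- if (is.data.frame(truth$stacks)) truth$stacks$file else
    vapply(truth$stacks, function(s) s$file, "")
  expect_true(all(file.exists(file.path(dir, stack_files))))
})
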
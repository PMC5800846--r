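plate_row <- function(sample_id, group, run_id, gene, ct) {
  data.frame(sample_id = sample_id, group = group, run_id = run_id,
             gene = gene, ct = ct, stringsAsFactors = FALSE)
}

two_gene_sample <- function(sample_id, group, ct_t, ct_r, run_id = "run1") {
  rbind(plate_row(sample_id, group, run_id, "target", ct_t),
        plate_row(sample_id, group, run_id, "reference", ct_r))
}

test_that("replicates collapse to means with SD-based quality flags", {
  plate <- rbind(two_gene_sample("s1", "cal", c(20, 20, 20), c(15, 15, 15)),
                 two_gene_sample("s2", "cal", c(20, 21), c(15, 15)))
  out <- collapse_replicates(plate)
  expect_equal(out$ct_target, c(20, 20.5))
  expect_equal(out$sd_target, c(0, sd(c(20, 21))))
  expect_identical(out$flagged, c(FALSE, TRUE))   # SD 0.707 > 0.5 cutoff

  # relaxing the cutoff above the observed SD unflags the sample
  out2 <- collapse_replicates(plate, sd_flag = 0.71)
  expect_identical(out2$flagged, c(FALSE, FALSE))

  bad <- plate[plate$gene == "target" | plate$sample_id == "s1", ]
  expect_error(collapse_replicates(bad), "s2")
  expect_error(validate_plate(plate_row("s", "g", "r", "target", 50)), "\\(0, 45\\)")

  set.seed(6)
  big <- do.call(rbind, lapply(1:8, function(i) {
    two_gene_sample(sprintf("s%d", i), "g", rnorm(3, 20, 0.1), rnorm(3, 15, 0.1))
  }))
  got <- collapse_replicates(big)
  for (i in 1:8) {
    sid <- sprintf("s%d", i)
    expect_equal(got$ct_target[got$sample_id == sid],
                 mean(big$ct[big$sample_id == sid & big$gene == "target"]),
                 tolerance = 1e-12)
  }
})

test_that("delta-delta-Ct arithmetic and calibrator anchoring are exact", {
  plate <- rbind(two_gene_sample("c1", "surface_control", 22, 15),
                 two_gene_sample("c2", "surface_control", 22, 15),
                 two_gene_sample("t1", "cavefish_control", 20, 15))
  fc <- relative_expression(collapse_replicates(plate), "surface_control")
  # ddCt = (20-15) - (22-15) = -2 -> fold 4
  expect_equal(fc$fold[fc$sample_id == "t1"], 4, tolerance = 1e-12)
  expect_equal(fc$fold[fc$group == "surface_control"], c(1, 1), tolerance = 1e-12)
  # sample sitting at the calibrator mean has fold exactly 1
  expect_equal(fc$ddct[fc$sample_id == "c1"], 0)

  expect_error(relative_expression(collapse_replicates(plate), "nope"), "absent")
  expect_error(relative_expression(collapse_replicates(plate), "surface_control",
                                   efficiency = 0.5), "efficiency")
})

test_that("fold changes obey the efficiency law and gene-shift invariance", {
  set.seed(31)
  plate <- do.call(rbind, lapply(1:9, function(i) {
    g <- c("cal", "g2", "g3")[(i - 1) %/% 3 + 1]
    two_gene_sample(sprintf("s%d", i), g, rnorm(3, 20 + (i %% 3), 0.2), rnorm(3, 15, 0.2))
  }))
  mct <- collapse_replicates(plate)
  fc <- relative_expression(mct, "cal", efficiency = 1.0)
  # row-wise formula oracle at 100% efficiency
  dct <- mct$ct_target - mct$ct_reference
  ddct <- dct - mean(dct[mct$group == "cal"])
  expect_equal(fc$fold, 2^(-ddct), tolerance = 1e-12)
  # geometric mean of calibrator folds is exactly 1 in log space
  expect_equal(mean(log(fc$fold[fc$group == "cal"])), 0, tolerance = 1e-9)
  expect_true(all(fc$fold > 0))

  # adding a constant to every Ct of one gene changes nothing
  shifted <- plate
  shifted$ct[shifted$gene == "reference"] <- shifted$ct[shifted$gene == "reference"] + 3.7
  fc2 <- relative_expression(collapse_replicates(shifted), "cal")
  expect_equal(fc2$fold, fc$fold, tolerance = 1e-12)

  # alternative efficiency uses (1 + E) as the base
  fc9 <- relative_expression(mct, "cal", efficiency = 0.9)
  expect_equal(fc9$fold, 1.9^(-ddct), tolerance = 1e-12)
})

test_that("inter-run calibration aligns runs on the shared calibrator", {
  base <- rbind(two_gene_sample("IRC", "cal", 20, 15, "runA"),
                two_gene_sample("a1", "cal", 22, 15, "runA"),
                two_gene_sample("b1", "trt", 21, 15, "runB"),
                two_gene_sample("IRC", "cal", 20.5, 15.5, "runB"))
  mct <- interrun_calibrate(collapse_replicates(base), "IRC")
  offs <- attr(mct, "offsets")
  expect_equal(offs$offset_target, c(0, 0.5))
  expect_equal(offs$offset_reference, c(0, 0.5))
  # run B shifted down by 0.5: equals the single-run computation
  expect_equal(mct$ct_target[mct$sample_id == "b1"], 20.5)
  irc <- mct[mct$sample_id == "IRC", ]
  expect_equal(unique(round(irc$ct_target, 9)), 20)

  # single run is the identity
  one <- collapse_replicates(two_gene_sample("IRC", "cal", 20, 15))
  expect_equal(interrun_calibrate(one, "IRC")$ct_target, one$ct_target)

  no_cal <- base[base$run_id == "runA" | base$sample_id != "IRC", ]
  expect_error(interrun_calibrate(collapse_replicates(no_cal), "IRC"), "runB")
})

test_that("planted run offsets are recovered from a noiseless plate", {
  offs <- c(0, 0.8, -0.35)
  sim <- simulate_qpcr(c(cal = 5, hi = 5 - log2(3)), n_per_group = 3,
                       replicate_sd = 0, run_offsets = offs, seed = 44)
  mct <- interrun_calibrate(collapse_replicates(sim$plate, "hcrt", "gapdh"), "IRC")
  rec <- attr(mct, "offsets")
  expect_equal(rec$offset_target, offs, tolerance = 1e-9)
  expect_equal(rec$offset_reference, offs, tolerance = 1e-9)
  # folds after calibration equal the planted truth exactly
  fc <- relative_expression(mct, "cal")
  hi <- fc$fold[fc$group == "hi"]
  expect_equal(hi, rep(3, 3), tolerance = 1e-9)
})
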
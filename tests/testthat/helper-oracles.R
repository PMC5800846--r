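# Independent oracles used across the suite. Each re-derives its answer by
# the most literal route available (explicit enumeration, textbook formula),
# deliberately sharing no code with the implementation under test.

# brute-force bout enumerator: walks the immobility series frame by frame,
# absorbs interior mobile runs shorter than min_interrupt_s, then marks every
# maximal immobile run of >= min_sleep_s as one sleep bout
oracle_bouts <- function(imm, fr, min_sleep_s = 60, min_interrupt_s = 0) {
  n <- length(imm)
  work <- imm
  if (min_interrupt_s > 0) {
    i <- 1
    while (i <= n) {
      if (!work[i]) {
        j <- i
        while (j < n && !work[j + 1]) j <- j + 1
        interior <- i > 1 && j < n
        if (interior && (j - i + 1) / fr < min_interrupt_s - 1e-9) work[i:j] <- TRUE
        i <- j + 1
      } else i <- i + 1
    }
  }
  bouts <- list()
  i <- 1
  while (i <= n) {
    if (work[i]) {
      j <- i
      while (j < n && work[j + 1]) j <- j + 1
      if ((j - i + 1) / fr >= min_sleep_s - 1e-9) {
        bouts[[length(bouts) + 1]] <- c(start_s = (i - 1) / fr, end_s = j / fr)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(bouts)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  as.data.frame(do.call(rbind, bouts))
}

# textbook balanced two-way ANOVA from cell and grand means
oracle_anova_balanced <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  stopifnot(length(unique(table(A, B))) == 1)  # balanced only
  n <- unique(table(A, B))
  a <- nlevels(A); b <- nlevels(B)
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  ss_a <- n * b * sum((mA - grand)^2)
  ss_b <- n * a * sum((mB - grand)^2)
  cell_of <- interaction(A, B)
  ss_ab <- n * sum((mAB - rep(mA, times = b) - mB[rep(seq_len(b), each = a)] + grand)^2)
  ss_err <- sum((y - mAB[cell_of])^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1))
  df_err <- length(y) - a * b
  ms <- c(ss_a, ss_b, ss_ab) / df
  f <- ms / (ss_err / df_err)
  list(F = f, df1 = df, df2 = df_err,
       p = stats::pf(f, df, df_err, lower.tail = FALSE),
       ss = c(A = ss_a, B = ss_b, AB = ss_ab, err = ss_err, tot = sum((y - grand)^2)))
}

# direct evaluation of the step-down Sidak formula
oracle_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    v <- 1 - (1 - p[o[i]])^(m - i + 1)
    running <- max(running, v)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# write a trajectory data frame as a generic-dialect CSV
write_generic_csv <- function(path, t, x, y, comments = character()) {
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.12g", v))
  writeLines(c(comments, "time_s,x,y", paste(fmt(t), fmt(x), fmt(y), sep = ",")), path)
  path
}

# small 2x2 cohort written to disk; returns the manifest path
make_disk_cohort <- function(dir, n_per_cell = 2, duration_h = 0.25, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); k <- 0
  for (pop in c("surface", "cavefish")) for (tr in c("control", "antagonist")) {
    for (i in seq_len(n_per_cell)) {
      k <- k + 1
      sid <- sprintf("%s_%s_%d", pop, tr, i)
      sim <- simulate_activity(preset(pop, tr, duration_h = duration_h),
                               seed = seed * 100 + k, subject_id = sid,
                               population = pop, treatment = tr)
      f <- file.path(dir, paste0(sid, ".csv"))
      write_tracking(sim$trajectory, f)
      rows[[k]] <- data.frame(file = f, subject_id = sid, population = pop,
                              treatment = tr, zt_start = 0, calibration_mm_per_px = 1)
    }
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), mp, row.names = FALSE)
  mp
}
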
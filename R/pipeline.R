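#' Validate a pipeline run configuration
#'
#' Reads a YAML run configuration and checks it against the expected
#' schema, collecting every problem before failing so a config is fixed in
#' one pass, not one error at a time. An annotated example ships at
#' `system.file("extdata", "example_config.yaml", package = "cavesleepr")`;
#' the main blocks are
#' `output_dir`, `seed`, `manifest`, `scoring` (speed_threshold,
#' smooth_window_s, min_sleep_s, min_interrupt_s, max_gap_s, bin_minutes),
#' `photoperiod`, `stats` (response, method, contrasts), `qpcr` (file,
#' target, reference, calibrator_group, calibrator_sample) and `cells`
#' (manifest plus detection parameters).
#'
#' @param path YAML file path, or an already-parsed list.
#' @return The validated configuration (list) with defaults filled in;
#'   errors carry all messages, one per line.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else path
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  if (is.null(cfg$output_dir)) note("output_dir: required")
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (!is.numeric(cfg$seed)) note("seed: must be an integer")

  sc <- cfg$scoring
  defaults <- list(speed_threshold = 4, smooth_window_s = 1, min_sleep_s = 60,
                   min_interrupt_s = 1, max_gap_s = 1, bin_minutes = 60)
  for (nm in names(defaults)) if (is.null(sc[[nm]])) sc[[nm]] <- defaults[[nm]]
  for (nm in names(defaults)) {
    v <- sc[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      note(sprintf("scoring.%s: must be a single finite number >= 0", nm))
    }
  }
  if (is.numeric(sc$min_sleep_s) && sc$min_sleep_s <= 0) note("scoring.min_sleep_s: must be > 0")
  cfg$scoring <- sc

  pp <- cfg$photoperiod
  if (is.null(pp)) pp <- list(lights_on_zt = 0, lights_off_zt = 14, period = 24)
  ok_pp <- tryCatch({photoperiod(pp$lights_on_zt, pp$lights_off_zt, pp$period); TRUE},
                    error = function(e) {note(paste0("photoperiod: ", conditionMessage(e))); FALSE})
  cfg$photoperiod <- pp

  if (is.character(path)) {  # resolve relative paths against the config file
    rebase <- function(p) {
      if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(dirname(path), p)
    }
    cfg$manifest <- rebase(cfg$manifest)
    cfg$output_dir <- rebase(cfg$output_dir)
    if (!is.null(cfg$qpcr)) cfg$qpcr$file <- rebase(cfg$qpcr$file)
    if (!is.null(cfg$cells)) cfg$cells$manifest <- rebase(cfg$cells$manifest)
  }
  if (!is.null(cfg$manifest) && !file.exists(cfg$manifest)) {
    note(paste0("manifest: file not found: ", cfg$manifest))
  }
  st <- cfg$stats
  if (is.null(st)) st <- list()
  if (is.null(st$response)) st$response <- "total_sleep_min"
  if (is.null(st$method)) st$method <- "t_unpaired"
  if (!st$method %in% c("t_unpaired", "rank_nonparametric")) {
    note("stats.method: must be t_unpaired or rank_nonparametric")
  }
  cfg$stats <- st
  if (!is.null(cfg$qpcr)) {
    for (nm in c("file", "calibrator_group")) {
      if (is.null(cfg$qpcr[[nm]])) note(sprintf("qpcr.%s: required when qpcr block present", nm))
    }
    if (is.null(cfg$qpcr$target)) cfg$qpcr$target <- "target"
    if (is.null(cfg$qpcr$reference)) cfg$qpcr$reference <- "reference"
  }
  if (length(errs)) stop("invalid configuration:\n", paste0("  - ", errs, collapse = "\n"))
  cfg
}

# group-mean hourly sleep profile figure + total-sleep bar summary
.report_figures <- function(metrics, dir) {
  bins <- grep("^bin", names(metrics), value = TRUE)
  if (length(bins)) {
    prof <- do.call(rbind, lapply(split(metrics, paste(metrics$population,
                                                       metrics$treatment)), function(g) {
      data.frame(group = paste(g$population[1], g$treatment[1]),
                 bin = seq_along(bins),
                 sleep_min = colMeans(g[, bins, drop = FALSE], na.rm = TRUE))
    }))
    p1 <- ggplot2::ggplot(prof, ggplot2::aes(x = bin, y = sleep_min, colour = group)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "profile bin", y = "sleep (min/bin)",
                    title = "Group-mean sleep profile") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(dir, "sleep_profile.pdf"), p1, width = 7, height = 4)
  }
  p2 <- ggplot2::ggplot(metrics, ggplot2::aes(x = interaction(population, treatment),
                                              y = total_sleep_min)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "total sleep (min)", title = "Total sleep by group") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(dir, "total_sleep.pdf"), p2, width = 6, height = 4)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — behavior scoring, factorial
#' statistics (population x treatment ANOVA with Holm-Sidak adjustment plus
#' any explicit two-group contrasts), relative expression, and cell
#' quantification — writing tidy CSVs, report figures and a provenance
#' record into `output_dir`. Any stage failure halts the run naming the
#' stage. Re-running with the same configuration and seed reproduces the
#' CSV outputs byte for byte.
#'
#' @param config Path to a YAML configuration or a config list; validated
#'   with [validate_config()] first.
#' @return Invisible list of the in-memory stage results (`metrics`,
#'   `effects`, `contrasts`, `folds`, `cells`, `counts`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(cfg$seed))
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  params <- scoring_params(cfg$scoring$speed_threshold, cfg$scoring$smooth_window_s,
                           cfg$scoring$min_sleep_s, cfg$scoring$min_interrupt_s)
  if (!is.null(cfg$manifest)) {
    res$metrics <- stage("score", {
      m <- score_cohort(cfg$manifest, params, bin_minutes = cfg$scoring$bin_minutes,
                        max_gap_s = cfg$scoring$max_gap_s)
      utils::write.csv(m, file.path(cfg$output_dir, "sleep_metrics.csv"), row.names = FALSE)
      fails <- attr(m, "failures")
      utils::write.csv(fails, file.path(cfg$output_dir, "scoring_failures.csv"),
                       row.names = FALSE)
      m
    })
    res <- c(res, stage("stats", {
      out <- list()
      m <- res$metrics
      resp <- m[[cfg$stats$response]]
      if (length(unique(m$population)) >= 2 && length(unique(m$treatment)) >= 2) {
        eff <- anova_with_adjustment(data.frame(response = resp,
                                                factorA = m$population,
                                                factorB = m$treatment))
        eff$effect <- c("population", "treatment", "population:treatment")
        utils::write.csv(eff, file.path(cfg$output_dir, "effects.csv"), row.names = FALSE)
        out$effects <- eff
      }
      if (!is.null(cfg$stats$contrasts)) {
        grp <- paste(m$population, m$treatment, sep = ":")
        rows <- lapply(cfg$stats$contrasts, function(cc) {
          r <- two_group_test(resp[grp == cc[[1]]], resp[grp == cc[[2]]],
                              method = cfg$stats$method)
          r$effect <- paste(cc[[1]], "vs", cc[[2]])
          r
        })
        ct <- do.call(rbind, rows)
        ct$p_adj <- holm_sidak(ct$p_raw)
        utils::write.csv(ct, file.path(cfg$output_dir, "contrasts.csv"), row.names = FALSE)
        out$contrasts <- ct
      }
      out
    }))
    stage("figures", .report_figures(res$metrics, cfg$output_dir))
  }

  if (!is.null(cfg$qpcr)) {
    res$folds <- stage("qpcr", {
      if (!file.exists(cfg$qpcr$file)) stop("qPCR table not found: ", cfg$qpcr$file)
      plate <- utils::read.csv(cfg$qpcr$file, stringsAsFactors = FALSE)
      mct <- collapse_replicates(plate, cfg$qpcr$target, cfg$qpcr$reference)
      if (!is.null(cfg$qpcr$calibrator_sample)) {
        mct <- interrun_calibrate(mct, cfg$qpcr$calibrator_sample)
      }
      fc <- relative_expression(mct, cfg$qpcr$calibrator_group)
      utils::write.csv(fc, file.path(cfg$output_dir, "fold_changes.csv"), row.names = FALSE)
      fc
    })
  }

  if (!is.null(cfg$cells)) {
    res <- c(res, stage("cells", {
      sm <- utils::read.csv(cfg$cells$manifest, stringsAsFactors = FALSE)
      rel <- !grepl("^(/|[A-Za-z]:)", sm$file)
      sm$file[rel] <- file.path(dirname(cfg$cells$manifest), sm$file[rel])
      k <- if (is.null(cfg$cells$threshold_k)) 3 else cfg$cells$threshold_k
      per_cell <- list(); counts <- list()
      for (i in seq_len(nrow(sm))) {
        stk <- read_stack(sm$file[i])
        img <- max_project(stk)
        rois <- detect_cells(img, threshold_k = k)
        # background from the full stack: a projection inflates background
        # pixels by the maximum of the per-slice noise, soma pixels not
        q <- quantify_cells(img, rois, background = stats::median(stk))
        if (q$count > 0) {
          per_cell[[i]] <- cbind(data.frame(brain_id = sm$brain_id[i],
                                            group = sm$group[i]), q$cells)
        }
        counts[[i]] <- data.frame(brain_id = sm$brain_id[i], group = sm$group[i],
                                  n_cells = q$count)
      }
      cells <- if (length(per_cell)) do.call(rbind, per_cell) else
        data.frame(brain_id = character(), group = character(), cell_id = integer(),
                   area = integer(), mean_int = numeric(), integrated_int = numeric())
      counts <- do.call(rbind, counts)
      utils::write.csv(cells, file.path(cfg$output_dir, "cell_intensities.csv"),
                       row.names = FALSE)
      utils::write.csv(counts, file.path(cfg$output_dir, "cell_counts.csv"),
                       row.names = FALSE)
      list(cells = cells, counts = counts)
    }))
  }

  prov <- list(config = cfg,
               scoring_params = unclass(params),
               package_version = as.character(utils::packageVersion("cavesleepr")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(cfg$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
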
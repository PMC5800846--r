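#' Validate a long-format qPCR plate table
#'
#' A plate is a long data frame with one row per technical replicate:
#' `sample_id, group, run_id, gene, ct`, where `gene` distinguishes the
#' target transcript from the reference (housekeeping) gene, e.g. hcrt vs
#' gapdh. Every sample must carry at least one Ct for both genes, and all
#' Ct values must be finite cycles in (0, 45).
#'
#' @param plate Data frame as above.
#' @param target,reference Gene labels used in the `gene` column.
#' @return The plate, invisibly, after validation.
#' @export
validate_plate <- function(plate, target = "target", reference = "reference") {
  need <- c("sample_id", "group", "run_id", "gene", "ct")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stop("plate missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(plate$ct)) || any(plate$ct <= 0 | plate$ct >= 45)) {
    stop("Ct values must be finite cycles in (0, 45)")
  }
  unknown <- setdiff(unique(plate$gene), c(target, reference))
  if (length(unknown)) stop("unknown gene labels: ", paste(unknown, collapse = ", "))
  for (s in unique(plate$sample_id)) {
    g <- plate$gene[plate$sample_id == s]
    if (!(target %in% g)) stop("sample ", s, " has no Ct for target gene ", target)
    if (!(reference %in% g)) stop("sample ", s, " has no Ct for reference gene ", reference)
  }
  invisible(plate)
}

#' Collapse technical replicates to per-sample mean Ct
#'
#' Arithmetic mean of replicate Cts per sample, run and gene, with the
#' replicate SD reported; samples whose replicate SD exceeds `sd_flag`
#' cycles on either gene are flagged (`flagged = TRUE`) but never dropped.
#' A shared inter-run calibrator sample measured on several runs yields one
#' row per run, which is what [interrun_calibrate()] aligns on.
#'
#' @param plate Long plate table (see [validate_plate()]).
#' @param target,reference Gene labels.
#' @param sd_flag Replicate-SD quality cutoff in cycles (default 0.5).
#' @return Data frame: one row per sample x run with `sample_id, group,
#'   run_id, ct_target, ct_reference, sd_target, sd_reference, flagged`.
#' @export
collapse_replicates <- function(plate, target = "target", reference = "reference",
                                sd_flag = 0.5) {
  validate_plate(plate, target, reference)
  key <- interaction(plate$sample_id, plate$run_id, drop = TRUE, sep = "\r")
  agg <- function(gene) {
    sub <- plate[plate$gene == gene, ]
    k <- key[plate$gene == gene]
    mean_ct <- tapply(sub$ct, k, mean)
    sd_ct <- tapply(sub$ct, k, function(v) if (length(v) > 1) stats::sd(v) else 0)
    data.frame(key = names(mean_ct), mean_ct = as.numeric(mean_ct),
               sd_ct = as.numeric(sd_ct), stringsAsFactors = FALSE)
  }
  ta <- agg(target); rf <- agg(reference)
  meta <- unique(data.frame(key = as.character(key), sample_id = plate$sample_id,
                            group = plate$group, run_id = plate$run_id,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(unique(meta[, c("sample_id", "group")])$sample_id)) {
    stop("a sample is assigned to multiple groups")
  }
  out <- merge(meta, stats::setNames(ta, c("key", "ct_target", "sd_target")), by = "key")
  out <- merge(out, stats::setNames(rf, c("key", "ct_reference", "sd_reference")), by = "key")
  out$key <- NULL
  out$flagged <- out$sd_target > sd_flag | out$sd_reference > sd_flag
  out <- out[order(out$sample_id, out$run_id), ]
  rownames(out) <- NULL
  out
}

#' Inter-run Ct calibration
#'
#' Aligns runs on a shared calibrator sample: for each gene, every run's
#' Cts are shifted by a constant so that the calibrator reads identically
#' across runs (the first run, in run-id order, is the anchor). This is the
#' gene-study-style correction for plate-to-plate offsets.
#'
#' @param mean_ct Per-sample table from [collapse_replicates()].
#' @param calibrator_sample `sample_id` of the shared inter-run calibrator,
#'   which must appear in every run.
#' @return The table with adjusted `ct_target`/`ct_reference`; the applied
#'   per-run offsets are in attribute `offsets` (data frame
#'   `run_id, offset_target, offset_reference`).
#' @export
interrun_calibrate <- function(mean_ct, calibrator_sample) {
  runs <- sort(unique(mean_ct$run_id))
  if (length(runs) == 1) {
    attr(mean_ct, "offsets") <- data.frame(run_id = runs, offset_target = 0,
                                           offset_reference = 0)
    return(mean_ct)
  }
  cal <- mean_ct[mean_ct$sample_id == calibrator_sample, ]
  if (!all(runs %in% cal$run_id)) {
    stop("calibrator sample ", calibrator_sample, " missing from run(s): ",
         paste(setdiff(runs, cal$run_id), collapse = ", "))
  }
  anchor <- cal[cal$run_id == runs[1], ]
  offs <- data.frame(run_id = runs,
                     offset_target = cal$ct_target[match(runs, cal$run_id)] - anchor$ct_target,
                     offset_reference = cal$ct_reference[match(runs, cal$run_id)] - anchor$ct_reference)
  i <- match(mean_ct$run_id, offs$run_id)
  mean_ct$ct_target <- mean_ct$ct_target - offs$offset_target[i]
  mean_ct$ct_reference <- mean_ct$ct_reference - offs$offset_reference[i]
  attr(mean_ct, "offsets") <- offs
  mean_ct
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt = dCt - mean dCt` of
#' the calibrator group (surface-fish controls in the study design); fold
#' change `= (1 + efficiency)^(-ddCt)`, which at 100% efficiency is
#' `2^(-ddCt)`. Anchoring on the calibrator group's mean dCt makes the
#' calibrator group's geometric-mean fold exactly 1.
#'
#' @param mean_ct Per-sample table from [collapse_replicates()] (optionally
#'   after [interrun_calibrate()]).
#' @param calibrator_group Group label whose mean dCt defines fold = 1.
#' @param efficiency Amplification efficiency as a fraction in (0.8, 1.2]
#'   (1.0 = perfect doubling).
#' @return Data frame `sample_id, group, dct, ddct, fold`.
#' @export
relative_expression <- function(mean_ct, calibrator_group, efficiency = 1.0) {
  if (!(efficiency > 0.8 && efficiency <= 1.2)) stop("efficiency must lie in (0.8, 1.2]")
  if (!calibrator_group %in% mean_ct$group) {
    stop("calibrator group '", calibrator_group, "' absent from the plate")
  }
  dct <- mean_ct$ct_target - mean_ct$ct_reference
  cal_mean <- mean(dct[mean_ct$group == calibrator_group])
  ddct <- dct - cal_mean
  data.frame(sample_id = mean_ct$sample_id, group = mean_ct$group,
             dct = dct, ddct = ddct, fold = (1 + efficiency)^(-ddct),
             stringsAsFactors = FALSE)
}
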
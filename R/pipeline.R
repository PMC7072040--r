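#' Process one scan through the full pipeline
#'
#' Runs standardise -> segment -> mid-spine map -> midline -> curvature ->
#' scores on a single image and returns a flat record. Stage failures are
#' captured in the record's `status` field rather than raised, so batch
#' processing continues past individual bad scans. Excluded scans
#' (positioning score above the exclusion threshold) carry no binary call.
#'
#' @param image a [dxa_image()], a `dxa_phantom`, or a path to a PNG/TIFF.
#' @param config a [dsm_config()].
#' @return Object of class `scan_record` (one-row data frame): `image_id`,
#'   `status`, `angle_deg`, `n_curves`, `grade`, `suspiciousness`,
#'   `positioning_score`, `excluded`, `binary_call`.
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sigma = 0))
#' process_scan(ph)
#' @export
process_scan <- function(image, config = dsm_config()) {
  if (inherits(image, "dxa_phantom")) image <- image$image
  if (is.character(image)) image <- read_dxa(image)
  id <- attr(image, "image_id")
  rec <- data.frame(image_id = id, status = "ok", angle_deg = NA_real_,
                    n_curves = NA_integer_, grade = NA_character_,
                    suspiciousness = NA_real_, positioning_score = NA_real_,
                    excluded = NA, binary_call = NA)
  res <- tryCatch({
    std <- standardize_height(image, config$preprocessing$target_height_px)
    seg <- segment_body(std, config)
    pos <- positioning_error_score(seg, config)
    msm <- compute_midspine_map(std, seg, config)
    ml <- extract_midline(msm, config)
    cm <- measure_curvature(ml, config)
    susp <- suspiciousness(cm, config$suspiciousness$midpoint_deg,
                           config$suspiciousness$steepness_per_deg)
    rec$angle_deg <- cm$angle_deg
    rec$n_curves <- cm$n_curves
    rec$grade <- as.character(cm$grade)
    rec$suspiciousness <- susp
    rec$positioning_score <- pos$score
    rec$excluded <- pos$excluded
    rec$binary_call <- if (pos$excluded) NA else
      binarize(susp, config$classification$cutoff)
    rec
  }, dxascol_error = function(e) {
    rec$status <- conditionMessage(e)
    rec
  })
  class(res) <- c("scan_record", "data.frame")
  res
}

#' Process a batch of scans and evaluate against truth
#'
#' Applies [process_scan()] to every image, then (when a truth table is
#' supplied) computes the evaluation report on the non-excluded,
#' successfully processed scans: the cut-off sweep with population
#' projections, the score AUC, and the three-class distribution. Excluded
#' scans never enter any diagnostic statistic. Unreadable or failed images
#' are logged, skipped and counted.
#'
#' @param images a `dxa_cohort`, a list of `dxa_phantom`/[dxa_image()]
#'   objects, a character vector of paths, or a directory containing
#'   PNG/TIFF images.
#' @param truth optional truth table (data frame or CSV path) with columns
#'   `image_id` and `true_class` (and optionally `true_angle_deg`); a
#'   `dxa_cohort` supplies its own.
#' @param config a [dsm_config()].
#' @param output_dir optional directory to write `records.csv` and
#'   `report.json`.
#' @param verbose print one log line per scan stage outcome.
#' @return Object of class `batch_result`: `records` (data frame),
#'   `report` (list: counts, sweep data frame, `auc`), `config`.
#' @export
run_batch <- function(images, truth = NULL, config = dsm_config(),
                      output_dir = NULL, verbose = FALSE) {
  if (inherits(images, "dxa_cohort")) {
    if (is.null(truth)) truth <- images$truth
    images <- images$phantoms
  }
  if (is.character(images) && length(images) == 1L && dir.exists(images))
    images <- list.files(images, pattern = "\\.(png|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE)
  if (is.character(truth)) truth <- utils::read.csv(truth)
  if (length(images) < 1)
    stop_dxascol("invalid_input", "need at least one readable image")
  recs <- lapply(images, function(im) {
    r <- tryCatch(process_scan(im, config),
                  error = function(e) {
                    data.frame(image_id = if (is.character(im)) basename(im) else "?",
                               status = conditionMessage(e), angle_deg = NA_real_,
                               n_curves = NA_integer_, grade = NA_character_,
                               suspiciousness = NA_real_,
                               positioning_score = NA_real_,
                               excluded = NA, binary_call = NA)
                  })
    if (verbose)
      message(sprintf("[dxascol] %s: %s%s", r$image_id,
                      if (r$status == "ok") sprintf("angle %.1f deg", r$angle_deg)
                      else r$status,
                      if (isTRUE(r$excluded)) " (excluded)" else ""))
    r
  })
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  report <- list(n = nrow(records),
                 n_failed = sum(records$status != "ok"),
                 n_excluded = sum(records$excluded, na.rm = TRUE))
  if (!is.null(truth)) {
    ok <- records$status == "ok" & !records$excluded
    ev <- merge(records[ok, ], truth, by = "image_id")
    truth_pos <- ev$true_class != "none"
    if (nrow(ev) >= 2 && any(truth_pos) && !all(truth_pos)) {
      report$sweep <- sweep_cutoffs(ev$suspiciousness, truth_pos,
                                    cutoffs = config$classification$cutoff_sweep,
                                    prevalence = config$projection$prevalence,
                                    n = config$projection$n_population,
                                    seed = config$seed)
      auc <- roc_auc(ev$suspiciousness, truth_pos, seed = config$seed)
      report$auc <- auc$auc
      report$auc_ci <- c(auc$ci_low, auc$ci_high)
      report$confusion_at_cutoff <- unclass(
        confusion(binarize(ev$suspiciousness, config$classification$cutoff),
                  truth_pos))
    }
    report$grade_table <- table(predicted = ev$grade, truth = ev$true_class)
  }
  out <- structure(list(records = records, report = report, config = config),
                   class = "batch_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_records(records, file.path(output_dir, "records.csv"))
    rep_json <- report
    rep_json$grade_table <- if (!is.null(report$grade_table))
      as.data.frame(report$grade_table)
    jsonlite::write_json(rep_json, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d scans: %d failed, %d excluded\n",
              x$report$n, x$report$n_failed, x$report$n_excluded))
  if (!is.null(x$report$auc))
    cat(sprintf("  score AUC %.3f (95%%CI %.3f-%.3f)\n", x$report$auc,
                x$report$auc_ci[1], x$report$auc_ci[2]))
  if (!is.null(x$report$sweep)) {
    cat("  cut-off sweep (percent):\n")
    sw <- x$report$sweep
    print(data.frame(cutoff = sw$cutoff, sens = pct1(sw$sensitivity),
                     spec = pct1(sw$specificity), ppv = pct1(sw$ppv),
                     npv = pct1(sw$npv),
                     prev = pct1(sw$predicted_prevalence)), row.names = FALSE)
  }
  invisible(x)
}

#' Write / read scan records
#'
#' CSV round-trip for the per-scan records produced by [run_batch()]
#' (UTF-8, header row, one record per scan).
#'
#' @param records the `records` data frame of a `batch_result`.
#' @param path CSV path.
#' @return `write_records` returns `path` invisibly; `read_records` returns
#'   the records data frame.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, fileEncoding = "UTF-8")
  rec$excluded <- as.logical(rec$excluded)
  rec$binary_call <- as.logical(rec$binary_call)
  class(rec) <- c("scan_record", "data.frame")
  rec
}
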
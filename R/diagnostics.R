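#' Confusion table from binary predictions
#'
#' @param predicted,truth logical (or 0/1) vectors of equal length.
#' @return Object of class `diagnostic_table`: list with counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @examples
#' confusion(c(1, 1, 0, 0, 1, 0), c(1, 0, 0, 1, 1, 0))  # tp 2, fp 1, fn 1, tn 2
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 1)
    stop_dxascol("invalid_input", "predicted and truth must have equal length >= 1")
  p <- as.logical(predicted); t <- as.logical(truth)
  if (any(is.na(p)) || any(is.na(t)))
    stop_dxascol("invalid_input", "labels must be binary with no missing values")
  diagnostic_table(tp = sum(p & t), fp = sum(p & !t),
                   tn = sum(!p & !t), fn = sum(!p & t))
}

#' @rdname confusion
#' @param tp,fp,tn,fn non-negative counts.
#' @export
diagnostic_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop_dxascol("invalid_input", "counts must be >= 0")
  structure(as.list(counts), class = "diagnostic_table")
}

#' @export
print.diagnostic_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
              dimnames = list(c("pred+", "pred-"), c("true+", "true-")))
  print(m)
  invisible(x)
}

#' Sensitivity and specificity of a confusion table
#'
#' @param table a [diagnostic_table()].
#' @return Named numeric: `sensitivity = tp/(tp+fn)`,
#'   `specificity = tn/(tn+fp)`.
#' @export
sens_spec <- function(table) {
  if (table$tp + table$fn == 0 || table$tn + table$fp == 0)
    stop_dxascol("undefined_margin",
                 "sensitivity/specificity undefined on an empty margin")
  c(sensitivity = table$tp / (table$tp + table$fn),
    specificity = table$tn / (table$tn + table$fp))
}

#' AUC with bootstrap confidence interval
#'
#' The area under the ROC curve computed as the Mann-Whitney pair statistic
#' via midranks (ties count one half), with a stratified bootstrap
#' percentile confidence interval (cases and controls resampled separately).
#'
#' @param scores numeric scores (higher = more suspicious).
#' @param truth binary labels, both classes present.
#' @param n_boot bootstrap resamples for the CI (0 to skip).
#' @param conf_level confidence level.
#' @param seed optional seed for the bootstrap.
#' @return List of class `auc_result`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(.1, .4, .35, .8), c(0, 0, 1, 1), n_boot = 0)$auc  # 0.75
#' @export
roc_auc <- function(scores, truth, n_boot = 2000L, conf_level = 0.95,
                    seed = NULL) {
  t <- as.logical(truth)
  if (length(scores) != length(t))
    stop_dxascol("invalid_input", "scores and truth must have equal length")
  if (!any(t) || all(t))
    stop_dxascol("degenerate_input", "both classes must be present for AUC")
  auc_point <- function(s, lab) {
    r <- rank(s)
    n1 <- sum(lab); n0 <- sum(!lab)
    (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  a <- auc_point(scores, t)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    pos <- which(t); neg <- which(!t)
    boots <- with_seed(if (is.null(seed)) 1L else seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- c(pos[sample.int(length(pos), replace = TRUE)],
                 neg[sample.int(length(neg), replace = TRUE)])
        auc_point(scores[idx], t[idx])
      }, numeric(1))
    })
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  }
  structure(list(auc = a, ci_low = ci[1], ci_high = ci[2],
                 n_pos = sum(t), n_neg = sum(!t), conf_level = conf_level),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%%CI %.3f-%.3f; %d cases / %d controls)\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Project sensitivity and specificity onto a hypothetical population
#'
#' Builds the 2x2 table implied by a test with the given sensitivity and
#' specificity in a population of `n` people at the given disease
#' prevalence, and derives the predictive values. Counts are integerised by
#' rounding the diseased total, the true positives and the true negatives
#' to the nearest integer and obtaining the complements by subtraction, so
#' the table always sums to `n`. With sensitivity 86.5%, specificity 96.9%,
#' prevalence 5.9% and n = 10,000 the projected table is
#' tp 510 / fn 80 / tn 9118 / fp 292, giving PPV 63.6%, NPV 99.1% and a
#' predicted prevalence of 8.0%.
#'
#' @param sensitivity,specificity,prevalence fractions in `[0, 1]`.
#' @param n population size (>= 1).
#' @return Object of class `projection_result`: the input parameters, the
#'   projected [diagnostic_table()], and `ppv`, `npv`,
#'   `predicted_prevalence` as fractions (print shows one-decimal percents).
#' @examples
#' project_population(0.865, 0.969, 0.059, 10000)
#' @export
project_population <- function(sensitivity, specificity,
                               prevalence = dsm_config()$projection$prevalence,
                               n = dsm_config()$projection$n_population) {
  for (v in c(sensitivity, specificity, prevalence))
    if (!is_scalar_num(v) || v < 0 || v > 1)
      stop_dxascol("invalid_input", "fractions must be scalars in [0, 1]")
  if (!is_scalar_num(n) || n < 1)
    stop_dxascol("invalid_input", "population size n must be >= 1")
  pos <- round(n * prevalence)
  tp <- round(pos * sensitivity); fn <- pos - tp
  neg <- n - pos
  tn <- round(neg * specificity); fp <- neg - tn
  if (tp + fp == 0)
    stop_dxascol("undefined_ppv", "no predicted positives; PPV undefined")
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 prevalence = prevalence, n = n,
                 table = diagnostic_table(tp = tp, fp = fp, tn = tn, fn = fn),
                 ppv = tp / (tp + fp), npv = tn / (tn + fn),
                 predicted_prevalence = (tp + fp) / n),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("Projection onto n = %d at prevalence %.1f%% (sens %.1f%%, spec %.1f%%)\n",
              x$n, 100 * x$prevalence, 100 * x$sensitivity, 100 * x$specificity))
  print(x$table)
  cat(sprintf("PPV %.1f%%  NPV %.1f%%  predicted prevalence %.1f%%\n",
              pct1(x$ppv), pct1(x$npv), pct1(x$predicted_prevalence)))
  invisible(x)
}

#' Cut-off sweep over suspiciousness scores
#'
#' Evaluates each cut-off against the reference labels (strict `>`
#' binarisation), projects the resulting sensitivity/specificity onto the
#' hypothetical population, and reports one row per cut-off. The AUC is a
#' property of the scores, not of any cut-off, so the same score-based AUC
#' (with CI) is attached to every row.
#'
#' @param scores suspiciousness scores in `[0, 1]`.
#' @param truth binary reference labels.
#' @param cutoffs strictly increasing cut-offs in `[0, 1]`; default the
#'   operating set `{0.95, 0.98, 0.99, 0.995, 0.999, 0.9995}`.
#' @param prevalence,n projection parameters.
#' @param n_boot,seed forwarded to [roc_auc()].
#' @return Data frame of class `cutoff_sweep`: `cutoff`, `sensitivity`,
#'   `specificity`, `auc`, `auc_ci_low`, `auc_ci_high`, `ppv`, `npv`,
#'   `predicted_prevalence` (fractions) plus the projected counts.
#' @export
sweep_cutoffs <- function(scores, truth,
                          cutoffs = dsm_config()$classification$cutoff_sweep,
                          prevalence = dsm_config()$projection$prevalence,
                          n = dsm_config()$projection$n_population,
                          n_boot = 2000L, seed = 1L) {
  if (is.unsorted(cutoffs, strictly = TRUE) ||
      any(cutoffs < 0 | cutoffs > 1))
    stop_dxascol("invalid_input", "cutoffs must be strictly increasing in [0, 1]")
  auc <- roc_auc(scores, truth, n_boot = n_boot, seed = seed)
  rows <- lapply(cutoffs, function(ct) {
    ss <- sens_spec(confusion(binarize(scores, ct), truth))
    # a cut-off above every score predicts nobody positive; report the
    # sensitivity/specificity row with undefined predictive values
    pr <- tryCatch(project_population(ss["sensitivity"], ss["specificity"],
                                      prevalence, n),
                   dxascol_undefined_ppv = function(e) NULL)
    data.frame(cutoff = ct, sensitivity = unname(ss[1]),
               specificity = unname(ss[2]),
               auc = auc$auc, auc_ci_low = auc$ci_low,
               auc_ci_high = auc$ci_high,
               ppv = if (is.null(pr)) NA_real_ else pr$ppv,
               npv = if (is.null(pr)) NA_real_ else pr$npv,
               predicted_prevalence = if (is.null(pr)) NA_real_ else
                 pr$predicted_prevalence,
               tp = if (is.null(pr)) NA_real_ else pr$table$tp,
               fp = if (is.null(pr)) NA_real_ else pr$table$fp,
               tn = if (is.null(pr)) NA_real_ else pr$table$tn,
               fn = if (is.null(pr)) NA_real_ else pr$table$fn)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_sweep", "data.frame")
  out
}

#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement between two categorical ratings:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' marginal-product expected agreement `p_e`. The confidence interval uses
#' the large-sample standard error
#' `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))` with a normal interval clipped
#' to `[-1, 1]`. Agreement bands follow the conventional scale (0.81-1.00
#' "almost perfect"). If both raters are constant and identical, `p_e = 1`
#' and kappa is undefined (`NA`); percent agreement is still returned.
#'
#' @param ratings_a,ratings_b equal-length rating vectors (>= 2).
#' @param conf_level confidence level.
#' @return Object of class `agreement_result`: `kappa`, `ci_low`,
#'   `ci_high`, `percent_agreement`, `band`, `n`.
#' @examples
#' a <- rep(c("yes", "no"), c(25, 75))
#' b <- rep(c("yes", "no", "yes", "no"), c(20, 5, 5, 70))
#' cohen_kappa(a, b)$kappa  # 0.7333
#' @export
cohen_kappa <- function(ratings_a, ratings_b, conf_level = 0.95) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 2)
    stop_dxascol("invalid_input", "ratings must have equal length >= 2")
  if (anyNA(ratings_a) || anyNA(ratings_b))
    stop_dxascol("invalid_input",
                 "ratings contain NA; drop excluded scans before computing kappa")
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  tab <- table(factor(ratings_a, lev), factor(ratings_b, lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    return(structure(list(kappa = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, percent_agreement = p_o,
                          band = NA_character_, n = n,
                          note = "expected agreement is 1; kappa undefined"),
                     class = "agreement_result"))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(kappa + c(-1, 1) * z * se, -1), 1)
  structure(list(kappa = kappa, ci_low = ci[1], ci_high = ci[2],
                 percent_agreement = p_o, band = kappa_band(kappa), n = n),
            class = "agreement_result")
}

kappa_band <- function(k) {
  if (k <= 0) "poor"
  else if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

#' @export
print.agreement_result <- function(x, ...) {
  if (is.na(x$kappa))
    cat(sprintf("kappa undefined (%s); percent agreement %.1f%%\n",
                x$note, 100 * x$percent_agreement))
  else
    cat(sprintf("kappa %.2f (95%%CI %.2f-%.2f), %s agreement; percent agreement %.1f%% (n = %d)\n",
                x$kappa, x$ci_low, x$ci_high, x$band,
                100 * x$percent_agreement, x$n))
  invisible(x)
}

#' Chi-squared test of association
#'
#' Pearson chi-squared statistic on an r x c contingency table with
#' `(r-1)(c-1)` degrees of freedom, without continuity correction by
#' default.
#'
#' @param contingency matrix (or table) of counts with positive margins.
#' @param correct apply Yates continuity correction (2x2 only).
#' @return `htest` object from [stats::chisq.test()].
#' @export
chi2_association <- function(contingency, correct = FALSE) {
  m <- as.matrix(contingency)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_dxascol("invalid_table", "contingency table has a zero margin")
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  if (any(res$expected <= 0))
    stop_dxascol("invalid_table", "all expected counts must be > 0")
  res
}

#' Row percentages of a contingency table
#'
#' @param contingency matrix of counts with positive row totals.
#' @return Matrix of per-row percentages rounded to one decimal.
#' @examples
#' row_percentages(matrix(c(1709, 1526, 313, 136), 2))  # female/male rows
#' @export
row_percentages <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(rowSums(m) <= 0))
    stop_dxascol("invalid_row", "all row totals must be positive")
  round(100 * sweep(m, 1, rowSums(m), "/"), 1)
}

#' Unpaired t test
#'
#' Welch's unequal-variance form by default; set `pooled = TRUE` for the
#' classical equal-variance test. Symmetric under group swap up to the sign
#' of the statistic.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values.
#' @param pooled use the pooled-variance test.
#' @return List: `statistic`, `p_value`, `df`, `mean_a`, `mean_b`, `sd_a`,
#'   `sd_b`, and the underlying `htest`.
#' @export
unpaired_t_test <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_dxascol("invalid_input", "each group needs >= 2 observations")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    stop_dxascol("undefined_test", "both groups have zero variance")
  ht <- stats::t.test(group_a, group_b, var.equal = pooled)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(group_a), mean_b = mean(group_b),
       sd_a = stats::sd(group_a), sd_b = stats::sd(group_b), htest = ht)
}

#' Percent agreement between two label vectors
#'
#' @param labels_t1,labels_t2 equal-length vectors.
#' @return Fraction of positions with equal labels.
#' @export
percent_agreement <- function(labels_t1, labels_t2) {
  if (length(labels_t1) != length(labels_t2) || length(labels_t1) < 1)
    stop_dxascol("invalid_input", "label vectors must have equal length >= 1")
  mean(labels_t1 == labels_t2)
}
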
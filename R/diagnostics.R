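# Diagnostic-evaluation statistics: confusion metrics with exact binomial
# CIs, ROC/AUC with DeLong variance and paired comparison, Bland-Altman,
# absolute-agreement ICC, dependent-correlation and accuracy comparisons,
# and cohort exclusion accounting.

# Clopper-Pearson exact binomial CI for x successes of n.
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Confusion-matrix diagnostic metrics with exact binomial CIs
#'
#' Positive = reference standard positive (here FFR <= 0.80).  Proportion
#' CIs are exact binomial (Clopper-Pearson); likelihood-ratio CIs use the
#' log method.  Metrics with a zero denominator are reported as `NA`, not
#' 0.  Values are stored unrounded (percent scale); rounding to one
#' decimal happens only in the print method.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @param conf Confidence level.
#' @return An object of class `"diagnostic_report"`: a data frame with
#'   columns `metric`, `estimate`, `lo`, `hi` (percent for proportions,
#'   plain ratios for the LRs) plus the counts as an attribute.
#' @examples
#' confusion_metrics(108, 138, 10, 13)
#' @export
confusion_metrics <- function(tp, tn, fp, fn, conf = 0.95) {
  cnt <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("confusion_metrics: counts must be non-negative integers",
         call. = FALSE)
  total <- sum(cnt)
  if (total == 0) stop("confusion_metrics: empty table", call. = FALSE)
  z <- qnorm(1 - (1 - conf) / 2)

  prop <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(x / n, clopper_pearson(x, n, conf)) * 100
  }
  sens <- prop(tp, tp + fn)
  spec <- prop(tn, tn + fp)
  acc <- prop(tp + tn, total)
  ppv <- prop(tp, tp + fp)
  npv <- prop(tn, tn + fn)

  # likelihood ratios with log-method CIs (Simel); fractions, not percent
  se <- sens[1L] / 100; sp <- spec[1L] / 100
  plr <- plr_ci <- nlr <- nlr_ci <- c(NA_real_, NA_real_, NA_real_)
  if (!is.na(se) && !is.na(sp)) {
    if (sp < 1) {
      est <- se / (1 - sp)
      if (tp > 0 && fp > 0) {
        v <- (1 - se) / tp + sp / fp
        plr <- c(est, est * exp(c(-1, 1) * z * sqrt(v)))
      } else plr <- c(est, NA_real_, NA_real_)
    } else plr <- c(Inf, NA_real_, NA_real_)
    if (sp > 0) {
      est <- (1 - se) / sp
      if (fn > 0 && tn > 0) {
        v <- se / fn + (1 - sp) / tn
        nlr <- c(est, est * exp(c(-1, 1) * z * sqrt(v)))
      } else nlr <- c(est, NA_real_, NA_real_)
    }
  }

  out <- data.frame(
    metric = c("accuracy", "sensitivity", "specificity", "ppv", "npv",
               "plr", "nlr"),
    estimate = c(acc[1L], sens[1L], spec[1L], ppv[1L], npv[1L],
                 plr[1L], nlr[1L]),
    lo = c(acc[2L], sens[2L], spec[2L], ppv[2L], npv[2L], plr[2L], nlr[2L]),
    hi = c(acc[3L], sens[3L], spec[3L], ppv[3L], npv[3L], plr[3L], nlr[3L]))
  attr(out, "counts") <- cnt
  class(out) <- c("diagnostic_report", "data.frame")
  out
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("Diagnostic performance (TP %d, TN %d, FP %d, FN %d):\n",
              as.integer(cnt["tp"]), as.integer(cnt["tn"]),
              as.integer(cnt["fp"]), as.integer(cnt["fn"])))
  pct <- x$metric %in% c("accuracy", "sensitivity", "specificity",
                         "ppv", "npv")
  for (i in seq_len(nrow(x))) {
    u <- if (pct[i]) "%" else ""
    ci <- if (is.na(x$lo[i])) "" else
      sprintf(" (%.1f-%.1f)", x$lo[i], x$hi[i])
    cat(sprintf("  %-12s %.1f%s%s\n", x$metric[i], x$estimate[i], u, ci))
  }
  invisible(x)
}

# Look up one rendered (1-decimal) metric value from a report.
report_value <- function(report, metric, digits = 1) {
  round(report$estimate[report$metric == metric], digits)
}

# ---- ROC / AUC -------------------------------------------------------------

# Orient scores so that larger = more indicative of the positive class.
orient_scores <- function(scores, direction) {
  if (direction == "lower") -scores else scores
}

#' ROC area under the curve with DeLong variance
#'
#' AUC via the Mann-Whitney statistic with tie correction (ties count
#' 1/2); the variance comes from the DeLong structural components.
#'
#' @param scores Continuous scores, one per case.
#' @param labels Logical (or 0/1): `TRUE` = reference positive.
#' @param direction `"lower"` if smaller scores indicate the positive
#'   class (pressure ratios vs FFR <= 0.80), `"higher"` otherwise (e.g.
#'   percent stenosis).
#' @param conf Confidence level for the Wald CI on the AUC.
#' @return List of class `"roc_auc"`: `auc`, `var`, `se`, `ci`,
#'   `n_pos`, `n_neg`, and the structural components `v10`, `v01`.
#' @export
roc_auc <- function(scores, labels, direction = c("lower", "higher"),
                    conf = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("roc_auc: scores and labels length mismatch", call. = FALSE)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  m <- sum(labels); n <- sum(!labels)
  if (m == 0 || n == 0)
    stop("roc_auc: both classes must be present", call. = FALSE)
  x <- orient_scores(scores, direction)
  pos <- x[labels]; neg <- x[!labels]
  r_all <- rank(c(pos, neg))
  v10 <- (r_all[seq_len(m)] - rank(pos)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg)) / m
  auc <- mean(v10)
  v <- (if (m > 1) var(v10) / m else 0) + (if (n > 1) var(v01) / n else 0)
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(v)))
  structure(list(auc = auc, var = v, se = sqrt(v), ci = ci,
                 n_pos = m, n_neg = n, v10 = v10, v01 = v01,
                 direction = direction),
            class = "roc_auc")
}

#' @export
print.roc_auc <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.3f-%.3f), %d positives / %d negatives\n",
              x$auc, x$ci[1L], x$ci[2L], x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong comparison of two paired AUCs
#'
#' Covariance of the paired AUCs from the shared structural components;
#' `z = dAUC / sqrt(var(dAUC))`, two-sided p.
#'
#' @param scores_a,scores_b Paired score vectors (same cases).
#' @param labels Logical reference labels.
#' @param direction As in [roc_auc()] (applied to both score sets).
#' @return List: `auc_a`, `auc_b`, `delta`, `var`, `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (length(scores_a) != length(scores_b))
    stop("delong_compare: score vectors must be paired (equal length)",
         call. = FALSE)
  ra <- roc_auc(scores_a, labels, direction)
  rb <- roc_auc(scores_b, labels, direction)
  m <- ra$n_pos; n <- ra$n_neg
  vd <- (if (m > 1) var(ra$v10 - rb$v10) / m else 0) +
    (if (n > 1) var(ra$v01 - rb$v01) / n else 0)
  delta <- ra$auc - rb$auc
  if (vd <= 0) {
    z <- if (abs(delta) < 1e-15) 0 else sign(delta) * Inf
  } else z <- delta / sqrt(vd)
  list(auc_a = ra$auc, auc_b = rb$auc, delta = delta, var = vd,
       z = z, p_value = 2 * pnorm(-abs(z)))
}

# ---- agreement -------------------------------------------------------------

#' Bland-Altman agreement analysis
#'
#' Differences `x - y`; bias = mean, SD with n-1 denominator, limits of
#' agreement = bias +/- 1.96 SD.
#'
#' @param x,y Paired measurements.
#' @return List of class `"bland_altman"`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`.
#' @seealso [loa_f_test()] to compare the SDs of two such analyses.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("bland_altman: need >= 2 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d); s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, SD %.4f, LoA [%.4f, %.4f], n = %d\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' F-test comparing two SDs of paired differences
#'
#' Ratio-of-variances test on the standard deviations from two
#' Bland-Altman analyses (limits-of-agreement comparison).
#'
#' @param ba_a,ba_b `"bland_altman"` objects, or numeric SDs (then
#'   `n_a`/`n_b` required).
#' @param n_a,n_b Sample sizes when SDs are given directly.
#' @return List: `f`, `df1`, `df2`, `p_value`.
#' @export
loa_f_test <- function(ba_a, ba_b, n_a = NULL, n_b = NULL) {
  if (inherits(ba_a, "bland_altman")) { n_a <- ba_a$n; ba_a <- ba_a$sd_diff }
  if (inherits(ba_b, "bland_altman")) { n_b <- ba_b$n; ba_b <- ba_b$sd_diff }
  if (is.null(n_a) || is.null(n_b))
    stop("loa_f_test: sample sizes required", call. = FALSE)
  f <- ba_a^2 / ba_b^2
  df1 <- n_a - 1L; df2 <- n_b - 1L
  p <- 2 * min(pf(f, df1, df2), pf(f, df1, df2, lower.tail = FALSE))
  list(f = f, df1 = df1, df2 = df2, p_value = min(p, 1))
}

#' Intraclass correlation for absolute agreement, single measures
#'
#' ICC(A,1): two-way model, absolute agreement, single rater, from the
#' standard mean-squares decomposition with n subjects and k = 2
#' measurements.
#'
#' @param x,y Paired measurements (>= 3 pairs).
#' @return The ICC(A,1) value.
#' @export
icc_absolute <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("icc_absolute: need >= 3 pairs", call. = FALSE)
  m <- cbind(x, y)
  n <- nrow(m); k <- 2
  if (var(as.vector(m)) < 1e-300)
    stop("icc_absolute: zero total variance", call. = FALSE)
  grand <- mean(m)
  msr <- k * var(rowMeans(m))
  msc <- n * var(colMeans(m))
  sst <- sum((m - grand)^2)
  sse <- sst - (n - 1) * msr - (k - 1) * msc
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Compare two dependent overlapping correlations (Steiger's z)
#'
#' Fisher-transform test for `r_a = cor(X, Z)` vs `r_b = cor(Y, Z)`
#' sharing the variable Z, with `r_ab = cor(X, Y)`, using the pooled
#' estimate of the correlation between the two correlations.
#'
#' @param r_a,r_b The two correlations to compare, in (-1, 1).
#' @param r_ab Correlation between the two non-shared variables.
#' @param n Sample size (> 3).
#' @return List: `z`, `p_value`.
#' @export
compare_dependent_correlations <- function(r_a, r_b, r_ab, n) {
  for (r in c(r_a, r_b, r_ab))
    if (!is.finite(r) || abs(r) >= 1)
      stop("compare_dependent_correlations: correlations must be in (-1,1)",
           call. = FALSE)
  if (n <= 3) stop("compare_dependent_correlations: n must exceed 3",
                   call. = FALSE)
  if (r_a == r_b) return(list(z = 0, p_value = 1))
  rb2 <- (r_a^2 + r_b^2) / 2
  cnum <- r_ab * (1 - 2 * rb2) - 0.5 * rb2 * (1 - 2 * rb2 - r_ab^2)
  cc <- cnum / (1 - rb2)^2
  z <- (atanh(r_a) - atanh(r_b)) * sqrt((n - 3) / (2 - 2 * cc))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Compare the diagnostic accuracies of two methods
#'
#' Default: chi-squared test (no continuity correction) on the 2x2
#' correct/incorrect by method table built from the confusion counts.
#' Because the methods are applied to the same cases, a paired McNemar
#' variant is also provided; it requires the per-case correctness
#' vectors.
#'
#' @param counts_a,counts_b `"diagnostic_report"` objects (or lists with
#'   `tp`, `tn`, `fp`, `fn`) for the chi-squared variant.
#' @param correct_a,correct_b Logical per-case correctness vectors for the
#'   McNemar variant.
#' @param method `"chisq"` or `"mcnemar"`.
#' @return List: `statistic`, `p_value`, `method`, `accuracy_a`,
#'   `accuracy_b` (percent).
#' @export
compare_accuracies <- function(counts_a = NULL, counts_b = NULL,
                               correct_a = NULL, correct_b = NULL,
                               method = c("chisq", "mcnemar")) {
  method <- match.arg(method)
  get_counts <- function(x) {
    if (inherits(x, "diagnostic_report")) attr(x, "counts")
    else unlist(x)[c("tp", "tn", "fp", "fn")]
  }
  if (method == "chisq") {
    if (!is.null(correct_a) && is.null(counts_a)) {
      ca <- c(sum(correct_a), sum(!correct_a))
      cb <- c(sum(correct_b), sum(!correct_b))
    } else {
      a <- get_counts(counts_a); b <- get_counts(counts_b)
      if (sum(a) != sum(b))
        stop("compare_accuracies: totals must be equal", call. = FALSE)
      ca <- c(a["tp"] + a["tn"], a["fp"] + a["fn"])
      cb <- c(b["tp"] + b["tn"], b["fp"] + b["fn"])
    }
    tbl <- rbind(ca, cb)
    if (any(colSums(tbl) == 0))
      stop("compare_accuracies: zero margin", call. = FALSE)
    if (identical(unname(ca), unname(cb)))
      return(list(statistic = 0, p_value = 1, method = "chisq",
                  accuracy_a = unname(100 * ca[1L] / sum(ca)),
                  accuracy_b = unname(100 * cb[1L] / sum(cb))))
    ht <- suppressWarnings(chisq.test(tbl, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "chisq",
         accuracy_a = unname(100 * ca[1L] / sum(ca)),
         accuracy_b = unname(100 * cb[1L] / sum(cb)))
  } else {
    if (is.null(correct_a) || is.null(correct_b))
      stop("compare_accuracies: McNemar variant needs per-case correctness vectors",
           call. = FALSE)
    if (length(correct_a) != length(correct_b))
      stop("compare_accuracies: correctness vectors must be paired",
           call. = FALSE)
    b01 <- sum(correct_a & !correct_b)
    b10 <- sum(!correct_a & correct_b)
    if (b01 + b10 == 0)
      return(list(statistic = 0, p_value = 1, method = "mcnemar",
                  accuracy_a = 100 * mean(correct_a),
                  accuracy_b = 100 * mean(correct_b)))
    ht <- mcnemar.test(matrix(c(sum(correct_a & correct_b), b10, b01,
                                sum(!correct_a & !correct_b)), 2L, 2L))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "mcnemar",
         accuracy_a = 100 * mean(correct_a),
         accuracy_b = 100 * mean(correct_b))
  }
}

#' Cohort exclusion-cascade accounting
#'
#' Applies an ordered list of exclusions to an initial count and reports
#' the remainder and its percentage of the initial cohort (one decimal).
#'
#' @param initial Initial count.
#' @param exclusions Named or unnamed numeric vector / list of counts, or
#'   a data frame with columns `label`, `count`.
#' @return List: `remaining`, `percent_of_initial`, `table` (stepwise).
#' @examples
#' cohort_accounting(339, c(predilatation = 41, muqfr = 15, octmufr = 2,
#'                          ffr = 12))
#' @export
cohort_accounting <- function(initial, exclusions) {
  if (is.data.frame(exclusions)) {
    labels <- as.character(exclusions$label)
    counts <- as.numeric(exclusions$count)
  } else {
    counts <- as.numeric(unlist(exclusions))
    labels <- names(unlist(exclusions))
    if (is.null(labels)) labels <- paste0("exclusion_", seq_along(counts))
  }
  if (initial < 0 || any(counts < 0))
    stop("cohort_accounting: counts must be non-negative", call. = FALSE)
  if (!length(counts))
    return(list(remaining = initial, percent_of_initial = 100,
                table = data.frame(label = character(),
                                   excluded = numeric(),
                                   remaining = numeric())))
  remaining <- initial - cumsum(counts)
  if (any(remaining < 0))
    stop("cohort_accounting: exclusions exceed the cohort", call. = FALSE)
  rem <- remaining[length(remaining)]
  list(remaining = rem,
       percent_of_initial = round(rem / initial * 100, 1),
       table = data.frame(label = labels, excluded = counts,
                          remaining = remaining))
}

#' Render a count as a percentage of a total (one decimal)
#'
#' @param count,total Non-negative counts, `total > 0`.
#' @return Percentage rounded to one decimal.
#' @examples
#' percent_of(121, 269) # 45.0
#' @export
percent_of <- function(count, total) {
  if (total <= 0) stop("percent_of: total must be > 0", call. = FALSE)
  round(count / total * 100, 1)
}

# ---- cohort-level evaluation ----------------------------------------------

#' Evaluate computed indices against a reference standard on a cohort
#'
#' Consumes a per-vessel table with the wire-based reference (`ffr`) and
#' any of the computed columns `oct_mufr`, `muqfr` (pressure ratios,
#' positive when `<= cutoff`), `ds_percent`, `as_percent` (anatomic,
#' positive when `> ds_cutoff` / `> as_cutoff`), and produces
#' confusion metrics, AUCs, a paired DeLong comparison of the two
#' pressure-ratio methods, Bland-Altman agreement with the F-test on
#' their SDs, Pearson and ICC(A,1) agreement with a dependent-correlation
#' comparison, and chi-squared plus McNemar accuracy comparisons.
#'
#' @param data Data frame with column `ffr` and at least one computed
#'   index column.
#' @param cutoff Positivity cutoff on pressure ratios (reference and
#'   computed), default 0.80; the boundary value is positive.
#' @param ds_cutoff,as_cutoff Anatomic cutoffs (strict `>`).
#' @return A list of class `"cohort_evaluation"`.
#' @export
evaluate_cohort <- function(data, cutoff = 0.80, ds_cutoff = 50,
                            as_cutoff = 70) {
  if (!"ffr" %in% names(data))
    stop("evaluate_cohort: column 'ffr' required", call. = FALSE)
  labels <- data$ffr <= cutoff
  n <- nrow(data)
  out <- list(n = n, n_pos = sum(labels),
              prevalence_percent = percent_of(sum(labels), n),
              cutoff = cutoff, methods = list())

  spec_tab <- list(
    oct_mufr = list(dir = "lower", pos = function(v) v <= cutoff),
    muqfr = list(dir = "lower", pos = function(v) v <= cutoff),
    ds_percent = list(dir = "higher", pos = function(v) v > ds_cutoff),
    as_percent = list(dir = "higher", pos = function(v) v > as_cutoff))
  for (nm in names(spec_tab)) {
    if (!nm %in% names(data)) next
    v <- data[[nm]]
    pred <- spec_tab[[nm]]$pos(v)
    rep <- confusion_metrics(sum(pred & labels), sum(!pred & !labels),
                             sum(pred & !labels), sum(!pred & labels))
    out$methods[[nm]] <- list(
      report = rep,
      auc = roc_auc(v, labels, spec_tab[[nm]]$dir),
      correct = pred == labels)
  }

  if (all(c("oct_mufr", "muqfr") %in% names(data))) {
    out$delong <- delong_compare(data$oct_mufr, data$muqfr, labels, "lower")
    ba_a <- bland_altman(data$oct_mufr, data$ffr)
    ba_b <- bland_altman(data$muqfr, data$ffr)
    out$agreement <- list(
      oct_mufr = ba_a, muqfr = ba_b,
      loa_f = loa_f_test(ba_a, ba_b),
      r_oct_mufr = cor(data$oct_mufr, data$ffr),
      r_muqfr = cor(data$muqfr, data$ffr),
      icca_oct_mufr = icc_absolute(data$oct_mufr, data$ffr),
      icca_muqfr = icc_absolute(data$muqfr, data$ffr))
    out$agreement$r_compare <- compare_dependent_correlations(
      out$agreement$r_oct_mufr, out$agreement$r_muqfr,
      cor(data$oct_mufr, data$muqfr), n)
    out$accuracy_compare <- list(
      chisq = compare_accuracies(out$methods$oct_mufr$report,
                                 out$methods$muqfr$report),
      mcnemar = compare_accuracies(
        correct_a = out$methods$oct_mufr$correct,
        correct_b = out$methods$muqfr$correct, method = "mcnemar"))
  }
  class(out) <- "cohort_evaluation"
  out
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("Cohort evaluation: %d vessels, %d (%.1f%%) reference-positive at cutoff %.2f\n",
              x$n, x$n_pos, x$prevalence_percent, x$cutoff))
  for (nm in names(x$methods)) {
    m <- x$methods[[nm]]
    cat(sprintf("\n-- %s  [AUC %.2f (%.2f-%.2f)]\n", nm, m$auc$auc,
                m$auc$ci[1L], m$auc$ci[2L]))
    print(m$report)
  }
  if (!is.null(x$delong))
    cat(sprintf("\nDeLong AUC comparison: delta %.3f, z = %.2f, p = %.3f\n",
                x$delong$delta, x$delong$z, x$delong$p_value))
  if (!is.null(x$agreement)) {
    a <- x$agreement
    cat(sprintf("Agreement with reference: r %.3f vs %.3f (p = %.3f), ICCa %.3f vs %.3f\n",
                a$r_oct_mufr, a$r_muqfr, a$r_compare$p_value,
                a$icca_oct_mufr, a$icca_muqfr))
    cat(sprintf("SD of difference %.4f vs %.4f (F-test p = %.3f)\n",
                a$oct_mufr$sd_diff, a$muqfr$sd_diff, a$loa_f$p_value))
  }
  if (!is.null(x$accuracy_compare))
    cat(sprintf("Accuracy %.1f%% vs %.1f%%: chisq p = %.3f, McNemar p = %.3f\n",
                x$accuracy_compare$chisq$accuracy_a,
                x$accuracy_compare$chisq$accuracy_b,
                x$accuracy_compare$chisq$p_value,
                x$accuracy_compare$mcnemar$p_value))
  invisible(x)
}
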
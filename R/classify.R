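#' ROC curve and AUC of a binary classifier of sensitivity
#'
#' The AUC is computed as the Mann-Whitney probability that a randomly chosen
#' positive-class score exceeds a randomly chosen negative-class score, with
#' ties counted half. This equals the trapezoidal area under the empirical
#' ROC staircase, which is also returned. The positive-class orientation is
#' fixed by the caller a priori; no post-hoc flipping toward AUC >= 0.5 is
#' performed, so AUC < 0.5 is reported as such.
#'
#' @param scores Numeric classifier scores (here: peak cross-correlation
#'   coefficients).
#' @param labels Logical vector (or coercible), `TRUE` for the positive class.
#' @return Object of class `classifier_eval`: list with `auc`, `n_pos`,
#'   `n_neg` and `roc_points` (data frame of `fpr`, `tpr`, one point per
#'   distinct threshold, from (0,0) to (1,1)).
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("scores and labels must be complete vectors of equal length")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to evaluate a classifier")
  # Mann-Whitney AUC via midranks (ties count half)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # empirical ROC staircase over decreasing thresholds
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)  # one point per distinct threshold
  tpr <- cumsum(l)[keep] / n_pos
  fpr <- cumsum(!l)[keep] / n_neg
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg, roc_points = roc),
            class = "classifier_eval")
}

# trapezoidal area under an ROC staircase (independent of the rank route)
trapezoid_auc <- function(roc) {
  with(roc, sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2))
}

#' Confidence interval and p-value for an AUC
#'
#' Default inference uses the Hanley-McNeil standard error
#' \deqn{SE^2 = [A(1-A) + (n_+ - 1)(Q_1 - A^2) + (n_- - 1)(Q_2 - A^2)] / (n_+ n_-)}
#' with \eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)}; the 95% CI is
#' `auc +/- z * SE` clipped to \[0, 1\], and the two-sided p-value tests
#' AUC = 0.5 using the null SE evaluated at A = 0.5. A stratified case
#' bootstrap (resampling positives and negatives separately) is available as
#' an alternative CI/p method.
#'
#' @param eval A `classifier_eval` from [roc_auc()], needing `n_pos`,
#'   `n_neg` >= 2. For the bootstrap method, the original `scores` and
#'   `labels` must be supplied.
#' @param level Confidence level (default 0.95).
#' @param method `"hanley_mcneil"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @param scores,labels Original data, required for `method = "bootstrap"`.
#' @return The `classifier_eval` with `ci_low`, `ci_high`, `p_value`, `se`
#'   and `ci_method` added.
#' @export
auc_inference <- function(eval, level = 0.95, method = c("hanley_mcneil", "bootstrap"),
                          n_boot = 2000, seed = NULL,
                          scores = NULL, labels = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(eval, "classifier_eval"))
  if (eval$n_pos < 2L || eval$n_neg < 2L)
    stop("AUC inference needs at least 2 cases per class")
  z <- stats::qnorm(1 - (1 - level) / 2)
  hm_se <- function(a, np, nn) {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    sqrt((a * (1 - a) + (np - 1) * (q1 - a^2) + (nn - 1) * (q2 - a^2)) /
           (np * nn))
  }
  if (method == "hanley_mcneil") {
    se <- hm_se(eval$auc, eval$n_pos, eval$n_neg)
    se0 <- hm_se(0.5, eval$n_pos, eval$n_neg)
    eval$ci_low <- max(0, eval$auc - z * se)
    eval$ci_high <- min(1, eval$auc + z * se)
    eval$p_value <- 2 * stats::pnorm(-abs(eval$auc - 0.5) / se0)
    eval$se <- se
  } else {
    if (is.null(scores) || is.null(labels))
      stop("bootstrap AUC inference needs the original scores and labels")
    labels <- as.logical(labels)
    if (!is.null(seed)) set.seed(seed)
    ip <- which(labels); ineg <- which(!labels)
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- c(sample(ip, length(ip), replace = TRUE),
             sample(ineg, length(ineg), replace = TRUE))
      roc_auc(scores[i], labels[i])$auc
    }, 0)
    alpha <- (1 - level) / 2
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    eval$ci_low <- qs[1]; eval$ci_high <- qs[2]
    eval$p_value <- min(1, 2 * min(mean(boots <= 0.5), mean(boots >= 0.5)))
    eval$se <- stats::sd(boots)
  }
  eval$ci_method <- method
  eval$level <- level
  eval
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("AUC = %.3f (n+ = %d, n- = %d)", x$auc, x$n_pos, x$n_neg))
  if (!is.null(x$ci_low))
    cat(sprintf(", %.0f%% CI [%.3f, %.3f], p = %.3g (%s)",
                100 * (x$level %||% 0.95), x$ci_low, x$ci_high, x$p_value,
                x$ci_method))
  cat("\n")
  invisible(x)
}

#' Evaluate the three binary classifiers of sensitivity
#'
#' Runs, separately for the active and sham response curves, ROC analyses of
#' how well three binary variables classify peak cross-correlation
#' coefficients:
#'
#' * **congruence** — does a coefficient come from the congruent (positive
#'   class) or incongruent reference? Both reference sets enter as scores.
#' * **current_strength** — congruent coefficients only; positive class 2 mA.
#' * **guess_accuracy** — congruent coefficients only, 1 mA and 2 mA pooled;
#'   positive class: participants whose end-of-study guess was correct. A
#'   per-current-strength breakdown is also emitted
#'   (`guess_accuracy_1mA`, `guess_accuracy_2mA`).
#'
#' A stratum in which only one class occurs is flagged (`note` column, `NA`
#' estimates); the remaining evaluations are still produced.
#'
#' @param sensitivity Data frame from [sensitivity_table()].
#' @param records The study records (for current strength and guesses).
#' @param ci_method,level,n_boot,seed Passed to [auc_inference()].
#' @return Data frame with one row per classifier x condition: `classifier`,
#'   `condition`, `auc`, `ci_low`, `ci_high`, `p_value`, `n_pos`, `n_neg`,
#'   `note`; the `classifier_eval` objects (with ROC points) are attached as
#'   the `evals` attribute.
#' @export
run_classifiers <- function(sensitivity, records,
                            ci_method = c("hanley_mcneil", "bootstrap"),
                            level = 0.95, n_boot = 2000, seed = NULL) {
  ci_method <- match.arg(ci_method)
  guesses <- stats::setNames(
    vapply(records, function(r) r$guess, ""),
    vapply(records, function(r) r$participant_id, ""))
  rows <- list(); evals <- list()
  one <- function(classifier, condition, scores, labels) {
    if (length(unique(labels)) < 2L ||
        min(sum(labels), sum(!labels)) < 2L) {
      rows[[length(rows) + 1L]] <<- data.frame(
        classifier = classifier, condition = condition,
        auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, n_pos = sum(labels), n_neg = sum(!labels),
        note = "single-class stratum")
      return(invisible(NULL))
    }
    ev <- roc_auc(scores, labels)
    ev <- auc_inference(ev, level = level, method = ci_method,
                        n_boot = n_boot, seed = seed,
                        scores = scores, labels = labels)
    evals[[paste(classifier, condition, sep = ".")]] <<- ev
    rows[[length(rows) + 1L]] <<- data.frame(
      classifier = classifier, condition = condition,
      auc = ev$auc, ci_low = ev$ci_low, ci_high = ev$ci_high,
      p_value = ev$p_value, n_pos = ev$n_pos, n_neg = ev$n_neg,
      note = "")
  }
  for (cond in c("active", "sham")) {
    rows_cond <- sensitivity[sensitivity$condition == cond, , drop = FALSE]
    one("congruence", cond, rows_cond$peak_r,
        rows_cond$reference == "congruent")
    congr <- rows_cond[rows_cond$reference == "congruent", , drop = FALSE]
    one("current_strength", cond, congr$peak_r, congr$current_mA == 2)
    corr <- guesses[as.character(congr$participant_id)] == "correct"
    one("guess_accuracy", cond, congr$peak_r, corr)
    for (mA in sort(unique(congr$current_mA))) {
      sub <- congr$current_mA == mA
      one(sprintf("guess_accuracy_%gmA", mA), cond,
          congr$peak_r[sub], corr[sub])
    }
  }
  structure(do.call(rbind, rows), evals = evals)
}
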
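#' @name test_result
#' @title Container for one inferential test
#' @description Every test in the battery returns a `test_result`: a list
#' with `name`, `statistic_name` (t, F, Z, W or r), `statistic`, `df`
#' (possibly two numerator/denominator entries), `p_value` (at the requested
#' tails), `p_two_sided`, `effect_size` and `effect_size_name` (Cohen's d,
#' partial eta squared, or r), `tails` and `alpha_adjusted`. Degenerate
#' inputs set `flag` instead of fabricating numbers.
NULL

test_result <- function(name, statistic_name, statistic, df, p_value,
                        effect_size = NA_real_, effect_size_name = NA_character_,
                        tails = "two", alpha_adjusted = 0.05,
                        p_two_sided = NA_real_, flag = NA_character_, ...) {
  structure(list(name = name, statistic_name = statistic_name,
                 statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), p_two_sided = unname(p_two_sided),
                 effect_size = unname(effect_size),
                 effect_size_name = effect_size_name,
                 tails = tails, alpha_adjusted = alpha_adjusted,
                 flag = flag, ...),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  if (!is.na(x$flag)) {
    cat(sprintf("%s: flagged (%s)\n", x$name, x$flag)); return(invisible(x))
  }
  df <- if (length(x$df) == 2) sprintf("(%g, %g)", x$df[1], x$df[2])
        else if (length(x$df) == 1 && !is.na(x$df)) sprintf("(%g)", x$df) else ""
  es <- if (!is.na(x$effect_size))
    sprintf(", %s = %.3g", x$effect_size_name, x$effect_size) else ""
  cat(sprintf("%s: %s%s = %.3g, p = %.3g (%s-tailed)%s\n",
              x$name, x$statistic_name, df, x$statistic, x$p_value, x$tails, es))
  invisible(x)
}

#' Per-block median reaction times of correct trials
#'
#' @param session A [participant_session()].
#' @return Data frame with `block`, `median_rt_ms` (median over correct
#'   trials; `NA` when a block has none) and `n_correct`.
#' @export
rt_block_medians <- function(session) {
  stopifnot(inherits(session, "participant_session"))
  tr <- session$rt_trials
  out <- data.frame(block = 1:4, median_rt_ms = NA_real_, n_correct = 0L)
  for (b in 1:4) {
    rt <- tr$rt_ms[tr$block == b & as.logical(tr$correct)]
    out$n_correct[b] <- length(rt)
    if (length(rt)) out$median_rt_ms[b] <- stats::median(rt)
  }
  out
}

#' Change in median RT from the pre-stimulation baseline
#'
#' Subtracts the block-1 (baseline) median correct-trial RT from each later
#' block's median. A block with zero correct trials yields `NA` and is
#' excluded from group tests downstream rather than imputed.
#'
#' @param session A [participant_session()].
#' @return Named numeric vector `block2`, `block3`, `block4` of delta-RT in ms.
#' @export
delta_rt <- function(session) {
  med <- rt_block_medians(session)$median_rt_ms
  if (is.na(med[1])) stop("baseline block has no correct trials for participant ",
                          session$participant_id)
  stats::setNames(med[2:4] - med[1], paste0("block", 2:4))
}

cohens_d_paired <- function(x, y) {
  d <- x - y
  mean(d) / stats::sd(d)
}

cohens_d_independent <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Paired-samples t test
#'
#' @param x,y Paired numeric vectors (equal length). The one-tailed
#'   alternative is `mean(x) > mean(y)`.
#' @param tails `"two"` or `"one"`.
#' @param name Label for the result.
#' @param alpha_adjusted Adjusted alpha to record (e.g. Bonferroni 0.05/3).
#' @return A `test_result` with Cohen's d for paired data
#'   (mean difference / SD of differences). Both the requested-tails and the
#'   two-sided p-value are reported.
#' @export
paired_t <- function(x, y, tails = c("two", "one"), name = "paired t",
                     alpha_adjusted = 0.05) {
  tails <- match.arg(tails)
  stopifnot(length(x) == length(y))
  if (stats::sd(x - y) == 0) stop("paired t undefined: zero variance of differences")
  tt2 <- stats::t.test(x, y, paired = TRUE)
  p <- if (tails == "one")
    stats::t.test(x, y, paired = TRUE, alternative = "greater")$p.value
  else tt2$p.value
  test_result(name, "t", tt2$statistic, tt2$parameter, p,
              effect_size = cohens_d_paired(x, y), effect_size_name = "d",
              tails = tails, alpha_adjusted = alpha_adjusted,
              p_two_sided = tt2$p.value)
}

#' Welch's unequal-variance t test
#'
#' Degrees of freedom by Welch-Satterthwaite (fractional). The one-tailed
#' alternative is `mean(x) > mean(y)`.
#'
#' @inheritParams paired_t
#' @return A `test_result` with pooled-SD Cohen's d.
#' @export
welch_t <- function(x, y, tails = c("two", "one"), name = "Welch t",
                    alpha_adjusted = 0.05) {
  tails <- match.arg(tails)
  if (length(x) < 2 || length(y) < 2) stop("each group needs at least 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("Welch t undefined: zero variance in both groups")
  tt2 <- stats::t.test(x, y, var.equal = FALSE)
  p <- if (tails == "one")
    stats::t.test(x, y, var.equal = FALSE, alternative = "greater")$p.value
  else tt2$p.value
  test_result(name, "t", tt2$statistic, tt2$parameter, p,
              effect_size = cohens_d_independent(x, y), effect_size_name = "d",
              tails = tails, alpha_adjusted = alpha_adjusted,
              p_two_sided = tt2$p.value)
}

anova_effects <- function(fit, effects, strata, name_prefix) {
  sm <- summary(fit)
  tabs <- list()
  for (st in names(sm)) {
    t <- sm[[st]][[1]]
    rownames(t) <- trimws(rownames(t))
    tabs[[trimws(sub("^Error: ", "", st))]] <- t
  }
  out <- list()
  for (i in seq_along(effects)) {
    eff <- effects[i]; st <- strata[i]
    t <- tabs[[st]]
    if (is.null(t) || !eff %in% rownames(t))
      stop("effect '", eff, "' not found in ANOVA stratum '", st, "'")
    ss <- t[eff, "Sum Sq"]; df1 <- t[eff, "Df"]
    ssr <- t["Residuals", "Sum Sq"]; df2 <- t["Residuals", "Df"]
    # sums of squares that are numerically zero (relative to the stratum
    # total) are treated as exactly zero, so noiseless degenerate designs
    # give F = 0 rather than a ratio of rounding errors
    tot <- sum(t[, "Sum Sq"])
    if (ss <= 1e-10 * max(tot, 1)) ss <- 0
    if (ssr <= 1e-10 * max(tot, 1)) ssr <- 0
    Fv <- if (ss == 0) 0 else (ss / df1) / (ssr / df2)
    out[[eff]] <- test_result(
      paste0(name_prefix, ": ", eff), "F", Fv, c(df1, df2),
      stats::pf(Fv, df1, df2, lower.tail = FALSE),
      effect_size = if (ss + ssr > 0) ss / (ss + ssr) else 0,
      effect_size_name = "partial_eta_sq",
      tails = "two", p_two_sided = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  }
  out
}

#' Mixed-design 2 x 2 ANOVA (one between-, one within-subject factor)
#'
#' Fits the split-plot decomposition via `stats::aov()` with an
#' `Error(id/within)` stratum structure: the between-subjects main effect is
#' tested against the between-subjects residual (df 1, n - 2), the
#' within-subjects main effect and the interaction against the
#' subject-by-within residual (df 1, n - 2). With a balanced design the
#' Type I and Type III sums of squares coincide. Partial eta squared is
#' reported per effect as SS_effect / (SS_effect + SS_error-of-its-stratum).
#'
#' @param data Data frame in long format.
#' @param dv,between,within,id Column names (strings) of the dependent
#'   variable, the between factor, the within factor and the subject id.
#' @param name Label prefix for the results.
#' @return Named list of three `test_result`s: between main effect, within
#'   main effect, interaction.
#' @export
mixed_anova <- function(data, dv, between, within, id, name = "mixed ANOVA") {
  d <- data.frame(y = data[[dv]], B = factor(data[[between]]),
                  W = factor(data[[within]]), id = factor(data[[id]]))
  if (anyNA(d)) stop("mixed_anova: missing cell(s) in the design")
  counts <- table(d$id, d$W)
  if (any(counts != 1L)) stop("mixed_anova: each subject needs exactly one value per within level")
  fit <- stats::aov(y ~ B * W + Error(id / W), data = d)
  res <- anova_effects(fit, c("B", "W", "B:W"), c("id", "id:W", "id:W"), name)
  names(res) <- c(between, within, paste0(between, ":", within))
  for (i in seq_along(res))
    res[[i]]$name <- paste0(name, ": ", names(res)[i])
  res
}

#' Fully within-subject 2 x 2 repeated-measures ANOVA
#'
#' Both factors vary within subjects; each effect is tested against its own
#' subject-by-effect error stratum (df 1, n - 1), as
#' `Error(id/(f1*f2))` in `stats::aov()`.
#'
#' @param data Data frame in long format, one row per subject x cell.
#' @param dv,f1,f2,id Column names (strings).
#' @param name Label prefix.
#' @return Named list of three `test_result`s (two main effects, interaction).
#' @export
repeated_anova_2x2 <- function(data, dv, f1, f2, id, name = "repeated ANOVA") {
  d <- data.frame(y = data[[dv]], A = factor(data[[f1]]),
                  B = factor(data[[f2]]), id = factor(data[[id]]))
  if (anyNA(d)) stop("repeated_anova_2x2: missing cell(s)")
  fit <- stats::aov(y ~ A * B + Error(id / (A * B)), data = d)
  res <- anova_effects(fit, c("A", "B", "A:B"),
                       c("id:A", "id:B", "id:A:B"), name)
  names(res) <- c(f1, f2, paste0(f1, ":", f2))
  for (i in seq_along(res))
    res[[i]]$name <- paste0(name, ": ", names(res)[i])
  res
}

# exact null distribution of W+ under random signs, tie-aware:
# convolve the generating polynomial over doubled ranks (integers even with
# midranks), returning P(W+ = w/2) over w = 0..sum(2r)
signrank_null <- function(ranks2) {
  probs <- c(1)
  for (r in ranks2) {
    new <- c(probs, numeric(r)) / 2
    new[(r + 1):(r + length(probs))] <-
      new[(r + 1):(r + length(probs))] + probs / 2
    probs <- new
  }
  probs
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped (the classical procedure), tied absolute
#' differences receive average ranks, and `W` is the sum of ranks of the
#' positive differences `a - b`. For n <= `exact_max` retained pairs the
#' p-value comes from the exact tie-aware null distribution of `W`
#' (enumerated by convolution over the 2^n sign assignments); above that, a
#' normal approximation with tie-corrected variance and continuity correction
#' is used. `Z` is reported in either case, signed so that `a` tending to
#' exceed `b` gives positive `Z`. Swapping the arguments negates `Z`.
#'
#' @param a,b Paired numeric vectors.
#' @param name Label for the result.
#' @param exact_max Largest n for which the exact null is enumerated
#'   (default 25).
#' @return A `test_result` with `statistic` = W, plus `z` and `n_used`. All
#'   differences zero yields a degenerate-flagged result (p = 1).
#' @export
wilcoxon_signed_rank <- function(a, b, name = "Wilcoxon signed-rank",
                                 exact_max = 25L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L)
    return(test_result(name, "W", NA_real_, NA_real_, 1,
                       tails = "two", p_two_sided = 1,
                       flag = "all differences zero", z = NA_real_,
                       n_used = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- if (W == mu) 0 else 0.5 * sign(W - mu)
  z <- if (sigma2 > 0) (W - mu - cc) / sqrt(sigma2) else 0
  if (n <= exact_max) {
    probs <- signrank_null(as.integer(round(2 * r)))
    w2 <- as.integer(round(2 * W))
    p_lo <- sum(probs[seq_len(w2 + 1L)])
    p_hi <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  test_result(name, "W", W, NA_real_, p, tails = "two", p_two_sided = p,
              z = z, n_used = n,
              effect_size = z / sqrt(n), effect_size_name = "r")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors.
#' @param name Label.
#' @return A `test_result` with `statistic` = r and df = n - 2; degenerate
#'   input (n < 3 or zero variance) is flagged instead of erroring.
#' @export
pearson_cor <- function(x, y, name = "Pearson correlation") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    return(test_result(name, "r", NA_real_, NA_real_, NA_real_,
                       flag = "fewer than 3 complete pairs"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(test_result(name, "r", NA_real_, NA_real_, NA_real_,
                       flag = "zero variance: correlation undefined"))
  ct <- stats::cor.test(x, y)
  test_result(name, "r", ct$estimate, ct$parameter, ct$p.value,
              effect_size = ct$estimate, effect_size_name = "r",
              tails = "two", p_two_sided = ct$p.value)
}

#' Correlations between sensitivity and late-stimulation RT change
#'
#' For each of the four strata (1 mA active, 2 mA active, 1 mA sham,
#' 2 mA sham) correlates the congruent peak cross-correlation coefficient
#' with the block-3 delta-RT — the RT change at the end of the 10-min
#' stimulation period, when any distraction by sustained scalp sensation
#' should be visible.
#'
#' @param sensitivity Data frame from [sensitivity_table()].
#' @param records Study records (for the RT data).
#' @return Named list of four `test_result`s.
#' @export
sensitivity_rt_correlations <- function(sensitivity, records) {
  drt3 <- list()
  for (r in records) for (s in r$sessions)
    drt3[[paste(r$participant_id, s$condition)]] <-
      tryCatch(delta_rt(s)[["block3"]], error = function(e) NA_real_)
  out <- list()
  congr <- sensitivity[sensitivity$reference == "congruent", , drop = FALSE]
  for (mA in sort(unique(congr$current_mA))) for (cond in c("active", "sham")) {
    sub <- congr[congr$current_mA == mA & congr$condition == cond, , drop = FALSE]
    y <- unlist(drt3[paste(sub$participant_id, cond)])
    nm <- sprintf("sensitivity_vs_dRT3_%gmA_%s", mA, cond)
    out[[nm]] <- pearson_cor(sub$peak_r, y, name = nm)
  }
  out
}
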
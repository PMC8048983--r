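#' Assess sham blinding for a whole study
#'
#' Runs the full pipeline over a set of participant records:
#'
#' 1. **Group perception curves** — per condition and current strength, the
#'    median weighted score at each of the 32 probes with participant-
#'    bootstrap 95% confidence bands, and the probes at which the active and
#'    sham bands do not overlap (the signature of a blinding failure).
#' 2. **Sensitivity** — per participant-session, the peak lagged
#'    cross-correlation against the congruent and incongruent ideal response
#'    curves.
#' 3. **Classifiers** — ROC/AUC evaluation of congruence, current strength
#'    and end-of-study-guess accuracy as classifiers of sensitivity.
#' 4. **Inferential battery** — paired t tests of delta-RT (active vs sham,
#'    blocks 2-4, Bonferroni-adjusted alpha 0.05/3), Welch t tests across
#'    current strengths, Wilcoxon signed-rank tests of the five side-effects,
#'    a mixed ANOVA (current strength x stimulation type) and a fully
#'    within-subject ANOVA (stimulation type x congruence) on peak
#'    coefficients, Welch t tests of sensitivity by guess accuracy, and
#'    Pearson correlations between sensitivity and block-3 delta-RT.
#'
#' @param records List of [participant_record()]s (e.g. from [read_study()]
#'   or [simulate_study()]).
#' @param protocols Protocols as in [default_protocols()].
#' @param n_boot Bootstrap resamples for the group curves (default 5000).
#' @param ci_level Confidence level for bands and AUC CIs (default 0.95).
#' @param seed Integer seed for all resampling.
#' @param auc_ci_method `"hanley_mcneil"` (default) or `"bootstrap"`.
#' @param max_lag Maximum cross-correlation lag in probes (default 31).
#' @return Object of class `blinding_assessment` with elements
#'   `group_curves`, `nonoverlap`, `sensitivity`, `classifiers`, `stats`,
#'   `guess_summary` and `design_info`; see [write_results()] for the file
#'   forms.
#' @export
assess_blinding <- function(records, protocols = default_protocols(),
                            n_boot = 5000, ci_level = 0.95, seed = 1,
                            auc_ci_method = c("hanley_mcneil", "bootstrap"),
                            max_lag = 31L) {
  auc_ci_method <- match.arg(auc_ci_method)
  stopifnot(length(records) >= 1)
  strengths <- sort(unique(vapply(records, function(r) r$current_mA, 0)))

  curves <- list(); curve_objs <- list(); nonoverlap <- list()
  for (mA in strengths) {
    for (cond in c("active", "sham")) {
      m <- score_matrix(records, cond, current_mA = mA)
      gc <- bootstrap_group_curve(m, n_boot = n_boot, level = ci_level,
                                  seed = seed, condition = cond,
                                  current_mA = mA)
      curve_objs[[sprintf("%s_%gmA", cond, mA)]] <- gc
      curves[[length(curves) + 1L]] <- as.data.frame(gc)
    }
    nonoverlap[[sprintf("%gmA", mA)]] <- nonoverlap_probes(
      curve_objs[[sprintf("active_%gmA", mA)]],
      curve_objs[[sprintf("sham_%gmA", mA)]])
  }
  group_curves <- do.call(rbind, curves)

  sens <- sensitivity_table(records, protocols, max_lag = max_lag)
  classifiers <- run_classifiers(sens, records, ci_method = auc_ci_method,
                                 level = ci_level, seed = seed)

  congr <- sens[sens$reference == "congruent", , drop = FALSE]
  stats <- list()

  # delta-RT battery
  drt <- list()
  for (r in records) for (s in r$sessions)
    drt[[paste(r$participant_id, s$condition)]] <-
      tryCatch(delta_rt(s), error = function(e)
        stats::setNames(rep(NA_real_, 3), paste0("block", 2:4)))
  pids_of <- function(mA) vapply(
    Filter(function(r) r$current_mA == mA, records),
    function(r) r$participant_id, "")
  for (mA in strengths) {
    pids <- pids_of(mA)
    for (b in paste0("block", 2:4)) {
      x <- vapply(pids, function(p) drt[[paste(p, "active")]][[b]], 0)
      y <- vapply(pids, function(p) drt[[paste(p, "sham")]][[b]], 0)
      ok <- !is.na(x) & !is.na(y)
      nm <- sprintf("dRT_%s_active_vs_sham_%gmA", b, mA)
      stats[[nm]] <- tryCatch(
        paired_t(x[ok], y[ok], tails = "one", name = nm,
                 alpha_adjusted = 0.05 / 3),
        error = function(e) test_result(nm, "t", NA_real_, NA_real_,
                                        NA_real_, flag = conditionMessage(e)))
    }
  }
  if (length(strengths) == 2) {
    hi <- max(strengths); lo <- min(strengths)
    for (cond in c("active", "sham")) for (b in paste0("block", 2:4)) {
      x <- vapply(pids_of(hi), function(p) drt[[paste(p, cond)]][[b]], 0)
      y <- vapply(pids_of(lo), function(p) drt[[paste(p, cond)]][[b]], 0)
      nm <- sprintf("dRT_%s_%s_%gmA_vs_%gmA", b, cond, hi, lo)
      stats[[nm]] <- welch_t(x[!is.na(x)], y[!is.na(y)], tails = "one",
                             name = nm, alpha_adjusted = 0.05 / 3)
    }
  }

  # side-effect ratings, active vs sham within each strength
  for (mA in strengths) {
    pids <- pids_of(mA)
    for (eff in SIDE_EFFECTS) {
      a <- vapply(pids, function(p)
        records[[p]]$sessions$active$side_effects[[eff]], 0)
      s <- vapply(pids, function(p)
        records[[p]]$sessions$sham$side_effects[[eff]], 0)
      nm <- sprintf("side_effect_%s_%gmA", eff, mA)
      stats[[nm]] <- wilcoxon_signed_rank(a, s, name = nm)
    }
  }

  # sensitivity battery
  wide <- stats::reshape(congr[, c("participant_id", "current_mA",
                                   "condition", "peak_r")],
                         idvar = c("participant_id", "current_mA"),
                         timevar = "condition", direction = "wide")
  names(wide) <- sub("^peak_r\\.", "", names(wide))
  stats$peak_r_active_vs_sham <- paired_t(
    wide$active, wide$sham, tails = "two", name = "peak_r_active_vs_sham")
  stats$peak_r_active_sham_correlation <- pearson_cor(
    wide$active, wide$sham, name = "peak_r_active_sham_correlation")
  if (length(strengths) == 2) {
    ma <- mixed_anova(congr, "peak_r", "current_mA", "condition",
                      "participant_id", name = "mixed_anova_peak_r")
    stats$anova_current_strength <- ma$current_mA
    stats$anova_stimulation_type <- ma$condition
    stats$anova_strength_x_type <- ma$`current_mA:condition`
  }
  ra <- repeated_anova_2x2(sens, "peak_r", "condition", "reference",
                           "participant_id", name = "repeated_anova_peak_r")
  stats$anova_congruence <- ra$reference
  stats$anova_type_within <- ra$condition
  stats$anova_type_x_congruence <- ra$`condition:reference`

  # guess accuracy vs sensitivity
  guesses <- vapply(records, function(r) r$guess, "")
  for (cond in c("active", "sham")) {
    v <- congr[congr$condition == cond, , drop = FALSE]
    corr <- guesses[as.character(v$participant_id)] == "correct"
    nm <- sprintf("peak_r_by_guess_%s", cond)
    stats[[nm]] <- tryCatch(
      welch_t(v$peak_r[corr], v$peak_r[!corr], tails = "two", name = nm),
      error = function(e) test_result(nm, "t", NA_real_, NA_real_, NA_real_,
                                      flag = conditionMessage(e)))
  }
  stats <- c(stats, sensitivity_rt_correlations(sens, records))

  guess_summary <- list(
    n_correct = sum(guesses == "correct"), n_total = length(guesses),
    prop_correct = mean(guesses == "correct"))
  for (mA in strengths)
    guess_summary[[sprintf("prop_correct_%gmA", mA)]] <-
      mean(guesses[vapply(records, function(r) r$current_mA, 0) == mA] ==
             "correct")

  structure(list(group_curves = group_curves, curve_objs = curve_objs,
                 nonoverlap = nonoverlap, sensitivity = sens,
                 classifiers = classifiers, stats = stats,
                 guess_summary = guess_summary,
                 design_info = list(n_participants = length(records),
                                    strengths = strengths, n_boot = n_boot,
                                    ci_level = ci_level, seed = seed,
                                    auc_ci_method = auc_ci_method,
                                    max_lag = max_lag)),
            class = "blinding_assessment")
}

#' @export
print.blinding_assessment <- function(x, ...) {
  di <- x$design_info
  cat(sprintf("Sham-blinding assessment: %d participants (%s mA)\n",
              di$n_participants,
              paste(di$strengths, collapse = " & ")))
  for (nm in names(x$nonoverlap))
    cat(sprintf("  %s: %d/32 probes with non-overlapping active vs sham CIs\n",
                nm, length(x$nonoverlap[[nm]])))
  congr <- x$sensitivity[x$sensitivity$reference == "congruent", ]
  for (cond in c("active", "sham"))
    cat(sprintf("  mean congruent peak r (%s): %.2f (SD %.2f)\n", cond,
                mean(congr$peak_r[congr$condition == cond]),
                stats::sd(congr$peak_r[congr$condition == cond])))
  cat(sprintf("  end-of-study guess: %d/%d correct (%.0f%%)\n",
              x$guess_summary$n_correct, x$guess_summary$n_total,
              100 * x$guess_summary$prop_correct))
  cl <- x$classifiers[x$classifiers$classifier %in%
                        c("congruence", "current_strength", "guess_accuracy"), ]
  for (i in seq_len(nrow(cl)))
    cat(sprintf("  %s (%s): AUC = %.2f [%.2f, %.2f], p = %.3g\n",
                cl$classifier[i], cl$condition[i], cl$auc[i],
                cl$ci_low[i], cl$ci_high[i], cl$p_value[i]))
  invisible(x)
}

#' @export
summary.blinding_assessment <- function(object, ...) {
  print(object)
  cat("\nInferential battery:\n")
  for (ts in object$stats) print(ts)
  invisible(object)
}

#' Plot the group perception curves of an assessment
#'
#' Draws, per current strength, the median weighted-score curves for active
#' and sham with their bootstrap confidence bands; probes with
#' non-overlapping bands are marked along the x axis.
#'
#' @param x A `blinding_assessment`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.blinding_assessment <- function(x, ...) {
  strengths <- x$design_info$strengths
  op <- graphics::par(mfrow = c(length(strengths), 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- c(active = "#c03060", sham = "#606060")
  for (mA in strengths) {
    ga <- x$curve_objs[[sprintf("active_%gmA", mA)]]
    gs <- x$curve_objs[[sprintf("sham_%gmA", mA)]]
    graphics::plot(ga$time_s, ga$median, type = "n", ylim = c(-10, 10),
                   xlab = "time since stimulation onset (s)",
                   ylab = "weighted score",
                   main = sprintf("%g mA: active vs sham", mA), ...)
    for (g in list(ga, gs)) {
      cl <- cols[[g$condition[1]]]
      ok <- !g$all_missing
      graphics::polygon(c(g$time_s[ok], rev(g$time_s[ok])),
                        c(g$ci_low[ok], rev(g$ci_high[ok])),
                        col = grDevices::adjustcolor(cl, 0.25), border = NA)
      graphics::lines(g$time_s[ok], g$median[ok], col = cl, lwd = 2)
    }
    non <- x$nonoverlap[[sprintf("%gmA", mA)]]
    if (length(non))
      graphics::points(ga$time_s[non], rep(-10, length(non)), pch = 15,
                       col = "#303030")
    graphics::abline(h = 0, lty = 3)
    graphics::legend("topright", legend = names(cols), col = cols, lwd = 2,
                     bty = "n")
  }
  invisible(x)
}
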
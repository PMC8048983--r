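#' Signed confidence-weighted perception score
#'
#' A "yes" response to "Is the stimulation on?" carries sign +1, a "no" sign
#' -1; the sign is multiplied by the 0-10 confidence rating. Scores therefore
#' range from +10 (high confidence the stimulation is on) to -10 (high
#' confidence it is off); zero confidence annihilates the response sign.
#'
#' @param response Character vector of `"yes"`/`"no"` (`"missing"` yields `NA`).
#' @param confidence Numeric vector of confidence ratings in \[0, 10\].
#' @return Numeric vector of weighted scores in \[-10, 10\].
#' @examples
#' weighted_score("yes", 10)  # +10
#' weighted_score("no", 10)   # -10
#' @export
weighted_score <- function(response, confidence) {
  if (!all(response %in% c("yes", "no", "missing")))
    stop("response must be 'yes', 'no' or 'missing'")
  ok <- response != "missing"
  if (any(is.na(confidence[ok])) ||
      any(confidence[ok] < 0 | confidence[ok] > 10))
    stop("confidence must lie in [0, 10]")
  sign <- ifelse(response == "yes", 1, ifelse(response == "no", -1, NA_real_))
  out <- sign * confidence
  out[!ok] <- NA_real_
  out
}

#' Weighted-score series of one session
#'
#' @param session A [participant_session()].
#' @return Object of class `probe_series`: numeric vector of 32 weighted
#'   scores (`NA` at missing probes) with attributes `participant_id`,
#'   `condition`, `current_mA` and `time_s`.
#' @export
probe_series <- function(session) {
  stopifnot(inherits(session, "participant_session"))
  v <- weighted_score(session$probes$response, session$probes$confidence)
  structure(v,
            participant_id = session$participant_id,
            condition = session$condition,
            current_mA = session$current_mA,
            time_s = session$probes$time_s,
            class = "probe_series")
}

#' Weighted-score matrix of a study stratum
#'
#' @param records List of [participant_record()] objects.
#' @param condition `"active"` or `"sham"`.
#' @param current_mA Optional current strength filter.
#' @return Participants x probes numeric matrix (rows named by participant).
#' @export
score_matrix <- function(records, condition, current_mA = NULL) {
  condition <- match.arg(condition, c("active", "sham"))
  if (!is.null(current_mA))
    records <- Filter(function(r) r$current_mA == current_mA, records)
  if (!length(records)) stop("no records in requested stratum")
  rows <- lapply(records, function(r)
    as.numeric(probe_series(r$sessions[[condition]])))
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(records, function(r) r$participant_id, "")
  m
}

#' Bootstrap confidence band for the group median score curve
#'
#' For each probe point, participants are resampled with replacement `n_boot`
#' times; the median of the available (non-missing) scores is computed on each
#' resample and a percentile interval is reported together with the observed
#' median. One set of participant resamples is shared across probes, so the
#' band reflects between-participant sampling variability.
#'
#' @param scores Participants x probes matrix of weighted scores (`NA` for
#'   missing probes), e.g. from [score_matrix()], or a list of `probe_series`.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95, percentile interval).
#' @param seed Integer seed; the band is reproducible under a fixed seed.
#' @param condition Optional condition label stored in the result.
#' @param current_mA Optional current strength stored in the result.
#' @param time_s Optional probe times (defaults to 30 s spacing).
#' @return Object of class `group_curve`: data frame with one row per probe
#'   (`probe`, `time_s`, `median`, `ci_low`, `ci_high`, `n`, `all_missing`)
#'   and attributes `n_participants`, `n_boot`, `level`, `seed`. Probes where
#'   every participant's response is missing are flagged via `all_missing`
#'   with `NA` estimates, never silently zeroed.
#' @export
bootstrap_group_curve <- function(scores, n_boot = 5000, level = 0.95,
                                  seed = NULL, condition = NA_character_,
                                  current_mA = NA_real_, time_s = NULL) {
  if (is.list(scores) && !is.data.frame(scores)) {
    if (is.null(time_s)) time_s <- attr(scores[[1]], "time_s")
    scores <- do.call(rbind, lapply(scores, as.numeric))
  }
  scores <- as.matrix(scores)
  n <- nrow(scores); p <- ncol(scores)
  if (n < 1L) stop("need at least one participant")
  if (is.null(time_s)) time_s <- 30 * seq_len(p)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  med_na <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else stats::median(x)
  }
  obs <- apply(scores, 2L, med_na)
  all_missing <- apply(scores, 2L, function(x) all(is.na(x)))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  alpha <- (1 - level) / 2
  ci <- matrix(NA_real_, nrow = p, ncol = 2L)
  for (j in seq_len(p)) {
    if (all_missing[j]) next
    v <- scores[, j]
    meds <- apply(matrix(v[idx], nrow = n), 2L, med_na)
    ci[j, ] <- stats::quantile(meds, c(alpha, 1 - alpha), na.rm = TRUE,
                               names = FALSE)
  }
  out <- data.frame(condition = condition, current_mA = current_mA,
                    probe = seq_len(p), time_s = time_s,
                    median = obs, ci_low = ci[, 1L], ci_high = ci[, 2L],
                    n = colSums(!is.na(scores)), all_missing = all_missing)
  structure(out, n_participants = n, n_boot = n_boot, level = level,
            seed = seed, class = c("group_curve", "data.frame"))
}

#' Probes whose confidence intervals do not overlap between two curves
#'
#' A probe is reported when one curve's lower bound lies strictly above the
#' other's upper bound. Intervals are closed: curves that merely touch are
#' counted as overlapping, the conservative convention when claiming a
#' blinding failure. The relation is symmetric in its arguments.
#'
#' @param a,b `group_curve` objects over the identical probe schedule.
#' @return Integer vector of probe indices with non-overlapping intervals.
#' @export
nonoverlap_probes <- function(a, b) {
  stopifnot(inherits(a, "group_curve"), inherits(b, "group_curve"))
  if (nrow(a) != nrow(b) || any(a$time_s != b$time_s))
    stop("curves are not on the same probe schedule")
  apart <- (a$ci_low > b$ci_high) | (b$ci_low > a$ci_high)
  which(!is.na(apart) & apart)
}

#' @export
print.group_curve <- function(x, ...) {
  cat(sprintf(
    "Group median curve (%s%s): %d probes, %d participants, %d bootstrap resamples (%.0f%% CI)\n",
    x$condition[1],
    if (is.na(x$current_mA[1])) "" else sprintf(", %g mA", x$current_mA[1]),
    nrow(x), attr(x, "n_participants"), attr(x, "n_boot"),
    100 * attr(x, "level")))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}
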
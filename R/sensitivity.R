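#' Remove a least-squares linear trend
#'
#' Subtracts the ordinary least-squares straight line fitted against the
#' sample index. The residual is orthogonal to both the constant and the
#' linear ramp, so slow drifts in reported confidence do not masquerade as
#' stimulation tracking in the cross-correlation.
#'
#' @param x Numeric vector, length at least 2, no missing values.
#' @return Detrended numeric vector of the same length.
#' @export
detrend <- function(x) {
  if (length(x) < 2L) stop("detrend needs at least 2 points")
  if (anyNA(x)) stop("detrend: missing values must be handled upstream")
  t <- seq_along(x)
  stats::lsfit(t, x)$residuals
}

#' Fill missing probe responses by linear interpolation
#'
#' Cross-correlation needs complete vectors; missing probes are linearly
#' interpolated from their neighbours (series ends take the nearest valid
#' value). The number of interpolated points is attached as the
#' `n_interpolated` attribute so it can be logged per series.
#'
#' @param x Numeric vector with possible `NA`s; at least one value present.
#' @return Complete numeric vector with attribute `n_interpolated`.
#' @export
interpolate_missing <- function(x) {
  n_missing <- sum(is.na(x))
  if (n_missing == 0L) return(structure(as.numeric(x), n_interpolated = 0L))
  if (n_missing == length(x)) stop("cannot interpolate an all-missing series")
  idx <- seq_along(x)
  out <- stats::approx(idx[!is.na(x)], x[!is.na(x)], xout = idx,
                       method = "linear", rule = 2)$y
  structure(out, n_interpolated = n_missing)
}

#' Lagged normalized cross-correlation
#'
#' Computes, for each lag m in `-max_lag..max_lag`, the zero-padded
#' cross-correlation with global 'coeff' normalization:
#' \deqn{c(m) = \sum_n x(n)\, y(n+m) \; / \; \sqrt{\sum_n x(n)^2 \sum_n y(n)^2}.}
#' A positive lag means `y` lags `x`: if `y` equals `x` delayed by k samples,
#' the peak falls at lag +k. The normalizer is global (no per-lag re-centering
#' or overlap renormalization), so coefficients at large |m| shrink toward 0
#' by construction and |c(m)| <= 1 everywhere (Cauchy-Schwarz). Setting
#' `pearson = TRUE` instead computes a true Pearson correlation on the
#' overlapping segments at each lag (re-centered, overlap-normalized; `NA`
#' where the overlap is shorter than 3 points or degenerate), as a
#' sensitivity-analysis variant.
#'
#' @param x,y Numeric vectors of equal length N.
#' @param max_lag Maximum lag (default N - 1; must be <= N - 1).
#' @param pearson Use per-lag Pearson correlation instead of the global
#'   'coeff' normalization (default `FALSE`).
#' @return Numeric vector of length `2 * max_lag + 1`, named by lag.
#' @export
xcorr_coeff <- function(x, y, max_lag = length(x) - 1L, pearson = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 samples")
  if (anyNA(x) || anyNA(y)) stop("missing values must be handled upstream")
  if (max_lag > n - 1L) stop("max_lag must be at most length(x) - 1")
  lags <- seq.int(-max_lag, max_lag)
  if (!pearson) {
    denom <- sqrt(sum(x^2) * sum(y^2))
    if (denom == 0) stop("cross-correlation undefined for an all-zero series")
    r <- vapply(lags, function(m) {
      ix <- seq_len(n - abs(m))
      if (m >= 0) sum(x[ix] * y[ix + m]) else sum(x[ix - m] * y[ix])
    }, 0) / denom
  } else {
    r <- vapply(lags, function(m) {
      ix <- seq_len(n - abs(m))
      if (length(ix) < 3L) return(NA_real_)
      xs <- if (m >= 0) x[ix] else x[ix - m]
      ys <- if (m >= 0) y[ix + m] else y[ix]
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
      stats::cor(xs, ys)
    }, 0)
  }
  names(r) <- lags
  r
}

# signed maximum with deterministic tie-breaking:
# smallest |lag| first, then the negative lag
pick_peak <- function(r, lags, tol = 1e-12) {
  ok <- !is.na(r)
  rmax <- max(r[ok])
  cand <- which(ok & r >= rmax - tol * max(1, abs(rmax)))
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  cand[1L]
}

#' Peak cross-correlation sensitivity of one response series
#'
#' The participant's weighted-score series and the protocol's ideal response
#' curve are both detrended, cross-correlated over lags `-max_lag..max_lag`,
#' and the signed maximum coefficient extracted together with its lag. A
#' positive lag means the participant's reports lag the ideal curve (they
#' notice transitions late). Ties in the maximum are broken toward the lag
#' smallest in absolute value, then toward the negative lag. Missing probes
#' in the response are linearly interpolated first (count reported).
#'
#' With a 32-probe series, lags beyond +-31 have no overlap and are
#' identically zero, so the full informative range is `max_lag = 31`.
#'
#' @param response A `probe_series` (or numeric vector of weighted scores,
#'   `NA` allowed).
#' @param ideal An `ideal_curve` from [build_ideal_curve()] (or numeric
#'   vector on the same probe schedule).
#' @param max_lag Maximum lag in probes (default `length - 1` = 31).
#' @param pearson Use the per-lag Pearson variant (see [xcorr_coeff()]).
#' @return Object of class `sensitivity_result`: list with `peak_r`,
#'   `peak_lag`, `r_by_lag`, `n_interpolated` plus the series' identifiers.
#' @export
peak_sensitivity <- function(response, ideal, max_lag = NULL, pearson = FALSE) {
  ideal_v <- if (inherits(ideal, "ideal_curve")) ideal$values else as.numeric(ideal)
  resp_v <- as.numeric(response)
  if (length(resp_v) != length(ideal_v))
    stop("response and ideal curve are not on the same probe schedule")
  if (is.null(max_lag)) max_lag <- length(resp_v) - 1L
  filled <- interpolate_missing(resp_v)
  r <- xcorr_coeff(detrend(ideal_v), detrend(as.numeric(filled)),
                   max_lag = max_lag, pearson = pearson)
  lags <- as.integer(names(r))
  k <- pick_peak(r, lags)
  structure(list(participant_id = attr(response, "participant_id"),
                 condition = attr(response, "condition"),
                 current_mA = attr(response, "current_mA"),
                 reference = if (inherits(ideal, "ideal_curve")) ideal$protocol else NA,
                 peak_r = unname(r[k]),
                 peak_lag = lags[k],
                 r_by_lag = r,
                 n_interpolated = attr(filled, "n_interpolated")),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Peak cross-correlation r = %.3f at lag %+d (%s series vs %s ideal%s)\n",
              x$peak_r, x$peak_lag,
              x$condition %||% "?", x$reference %||% "?",
              if (x$n_interpolated > 0)
                sprintf(", %d probes interpolated", x$n_interpolated) else ""))
  invisible(x)
}

#' Congruent and incongruent sensitivity for every participant-session
#'
#' Each session's weighted-score series is cross-correlated with the ideal
#' response curve of its own protocol (the *congruent* reference) and with
#' the ideal curve of the opposite protocol at the same current strength (the
#' *incongruent* reference). Four rows result per participant; similar
#' congruent and incongruent coefficients would indicate that the response
#' curves carry no protocol-specific information.
#'
#' @param records List of [participant_record()] objects.
#' @param protocols Named list of protocols as in [default_protocols()]
#'   (names `active_1mA`, `sham_1mA`, `active_2mA`, `sham_2mA` or, for a
#'   single-strength study, `active`/`sham` entries with matching
#'   `current_mA`).
#' @param max_lag Maximum lag in probes (default 31).
#' @param pearson Use the per-lag Pearson variant.
#' @return Data frame with columns `participant_id`, `current_mA`,
#'   `condition`, `reference` (`"congruent"`/`"incongruent"`), `peak_r`,
#'   `peak_lag`, `n_interpolated`.
#' @export
sensitivity_table <- function(records, protocols = default_protocols(),
                              max_lag = 31L, pearson = FALSE) {
  find_spec <- function(condition, mA) {
    hit <- Filter(function(p) p$name == condition && p$current_mA == mA,
                  protocols)
    if (!length(hit))
      stop("no protocol named '", condition, "' at ", mA, " mA in `protocols`")
    hit[[1L]]
  }
  rows <- list()
  for (rec in records) for (s in rec$sessions) {
    series <- probe_series(s)
    for (ref in c("congruent", "incongruent")) {
      ref_cond <- if (ref == "congruent") s$condition else
        setdiff(c("active", "sham"), s$condition)
      ideal <- build_ideal_curve(find_spec(ref_cond, rec$current_mA))
      res <- peak_sensitivity(series, ideal, max_lag = max_lag,
                              pearson = pearson)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = rec$participant_id, current_mA = rec$current_mA,
        condition = s$condition, reference = ref,
        peak_r = res$peak_r, peak_lag = res$peak_lag,
        n_interpolated = res$n_interpolated)
    }
  }
  do.call(rbind, rows)
}
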
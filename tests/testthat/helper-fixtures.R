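# in-code fixtures shared across test files

active2 <- function() default_protocols()$active_2mA
sham2 <- function() default_protocols()$sham_2mA

# naive O(N * L) reference cross-correlation, written independently of
# xcorr_coeff: explicit double loop over lags and samples
brute_xcorr <- function(x, y, max_lag) {
  n <- length(x)
  denom <- sqrt(sum(x^2) * sum(y^2))
  out <- numeric(2 * max_lag + 1)
  for (k in seq_along(out)) {
    m <- k - max_lag - 1L
    acc <- 0
    for (i in seq_len(n)) {
      j <- i + m
      if (j >= 1 && j <= n) acc <- acc + x[i] * y[j]
    }
    out[k] <- acc / denom
  }
  names(out) <- seq.int(-max_lag, max_lag)
  out
}

# a minimal hand-built session: constant probes, flat RTs, mid-scale ratings
make_session <- function(pid = "P1", condition = "active", current_mA = 2,
                         responses = rep("yes", 32),
                         confidence = rep(5, 32),
                         rt_by_block = c(500, 500, 500, 500),
                         n_trials = c(100, 20, 20, 20),
                         side_effects = stats::setNames(rep(2, 5),
                                                        shamtrack:::SIDE_EFFECTS),
                         session_order = 1) {
  probes <- data.frame(probe = 1:32, time_s = 30 * (1:32),
                       response = responses,
                       confidence = ifelse(responses == "missing", NA_real_,
                                           confidence))
  trials <- do.call(rbind, lapply(1:4, function(b)
    data.frame(block = b, trial = seq_len(n_trials[b]), correct = 1L,
               rt_ms = rep(rt_by_block[b], n_trials[b]))))
  participant_session(pid, current_mA, condition, session_order, probes,
                      trials, side_effects)
}

make_record <- function(pid = "P1", current_mA = 2, guess = "correct",
                        active_responses = rep("yes", 32),
                        sham_responses = rep("no", 32),
                        confidence = rep(5, 32)) {
  participant_record(pid, list(
    make_session(pid, "active", current_mA, active_responses, confidence,
                 session_order = 1),
    make_session(pid, "sham", current_mA, sham_responses, confidence,
                 session_order = 2)), guess)
}

# record whose responses exactly reproduce the ideal curves of both protocols
perfect_record <- function(pid = "P1", current_mA = 2, guess = "correct") {
  prot <- default_protocols()
  resp <- function(cond) {
    ideal <- build_ideal_curve(prot[[sprintf("%s_%gmA", cond, current_mA)]])
    ifelse(ideal$values > 0, "yes", "no")
  }
  make_record(pid, current_mA, guess,
              active_responses = resp("active"),
              sham_responses = resp("sham"),
              confidence = rep(10, 32))
}

tiny_design <- function(seed, n = 4L, ...) {
  study_design(n_per_strength = n, trials_per_block = 10L, seed = seed, ...)
}
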
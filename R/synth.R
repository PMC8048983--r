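#' Perception parameters of one simulated participant
#'
#' The generator models probe responses as noisy logistic detection of a
#' habituating scalp sensation. At probe time t with perceived intensity I(t)
#' (see [perceived_intensity()]), the probability of a "yes" response is
#' `plogis(g * (I - threshold) + e)`, `e ~ N(0, response_noise)`; confidence
#' is `10 * |2 p - 1|` plus `N(0, confidence_noise)`, clipped to \[0, 10\];
#' each probe is independently missing with probability `lapse_rate`
#' (the fixed response window can lapse).
#'
#' @param g Sensitivity gain, >= 0 (0 = random responder).
#' @param threshold Detection threshold in perceived-intensity (mA) units.
#' @param habituation_tau Habituation time constant in seconds: perceived
#'   intensity decays as exp(-t/tau) during sustained current (`Inf` = none).
#' @param persistence_s Seconds of lingering sensation after the plateau ends
#'   (the fade spans the ramp-down plus this persistence).
#' @param confidence_noise SD of the confidence rating noise (0-10 scale).
#' @param response_noise SD of the logit noise on detection.
#' @param lapse_rate Probability a probe response is missing (<= 0.2).
#' @return Object of class `perception_params`.
#' @export
perception_params <- function(g = 1, threshold = 0.4, habituation_tau = 1200,
                              persistence_s = 15, confidence_noise = 1.5,
                              response_noise = 0.7, lapse_rate = 0.02) {
  vals <- c(g, threshold, habituation_tau, persistence_s,
            confidence_noise, response_noise, lapse_rate)
  if (any(is.na(vals)) || any(vals < 0))
    stop("all perception parameters must be non-negative")
  if (lapse_rate > 0.2) stop("lapse_rate must be at most 0.2")
  structure(list(g = g, threshold = threshold,
                 habituation_tau = habituation_tau,
                 persistence_s = persistence_s,
                 confidence_noise = confidence_noise,
                 response_noise = response_noise,
                 lapse_rate = lapse_rate),
            class = "perception_params")
}

#' Population distribution over perception parameters
#'
#' Defaults define the generator's study conditions: the gain g is log-normal
#' with the 2 mA group shifted upward (stronger currents produce stronger
#' scalp sensations, so current strength classifies sensitivity), and each
#' participant's g is shared across their two sessions up to a small
#' log-normal jitter (inducing a positive within-participant active-sham
#' sensitivity correlation). The remaining perception parameters are held at
#' the [perception_params()] defaults.
#'
#' @param g_meanlog_1mA,g_meanlog_2mA Mean log-gain per current strength.
#' @param g_sdlog Between-participant SD of log-gain.
#' @param session_jitter_sdlog SD of the per-session log-gain jitter.
#' @param ... Overrides passed to [perception_params()] (fixed across the
#'   population).
#' @return Object of class `population_params`.
#' @export
population_params <- function(g_meanlog_1mA = log(3.0),
                              g_meanlog_2mA = log(4.2),
                              g_sdlog = 0.9,
                              session_jitter_sdlog = 0.25, ...) {
  structure(list(g_meanlog_1mA = g_meanlog_1mA,
                 g_meanlog_2mA = g_meanlog_2mA,
                 g_sdlog = g_sdlog,
                 session_jitter_sdlog = session_jitter_sdlog,
                 fixed = list(...)),
            class = "population_params")
}

#' Design of a synthetic study
#'
#' Emulates the two-study layout: `n_per_strength` participants per current
#' strength, each completing one active and one sham session in
#' counterbalanced order, with one end-of-study guess each.
#'
#' @param n_per_strength Participants per current strength (default 32).
#' @param strengths Current strengths in mA (default 1 and 2).
#' @param protocols Protocols as in [default_protocols()].
#' @param counterbalance Alternate which condition comes first (default TRUE).
#' @param guess_coupling kappa in \[0, 1\]: 0 makes the end-of-study guess
#'   independent of sensitivity, 1 ties it fully to the participant's mean
#'   tracking accuracy.
#' @param guess_base Baseline probability of a correct guess (default 0.75,
#'   a typical observed correct-guess rate); P(correct) =
#'   clip(guess_base + kappa * (accuracy - 0.5), 0, 1).
#' @param distraction_coupling Slowing of reaction times, in ms per unit of
#'   gain-weighted mean perceived intensity during a block; applied in the
#'   2 mA active sessions only, where sustained strong sensation can distract
#'   from the task.
#' @param trials_per_block Trials in each of blocks 2-4 (baseline block 1 is
#'   always 100).
#' @param seed Integer seed (mandatory; the whole study is reproducible).
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_per_strength = 32L, strengths = c(1, 2),
                         protocols = default_protocols(),
                         counterbalance = TRUE,
                         guess_coupling = 0, guess_base = 0.75,
                         distraction_coupling = 6,
                         trials_per_block = 110L, seed) {
  if (missing(seed) || is.na(seed)) stop("study_design requires a seed")
  if (guess_coupling < 0 || guess_coupling > 1)
    stop("guess_coupling must lie in [0, 1]")
  structure(list(n_per_strength = as.integer(n_per_strength),
                 strengths = strengths, protocols = protocols,
                 counterbalance = counterbalance,
                 guess_coupling = guess_coupling, guess_base = guess_base,
                 distraction_coupling = distraction_coupling,
                 trials_per_block = as.integer(trials_per_block),
                 seed = as.integer(seed)),
            class = "study_design")
}

trapezoid_amplitude <- function(t, spec) {
  ru <- spec$ramp_up_s; pl <- spec$plateau_s; rd <- spec$ramp_down_s
  amp <- numeric(length(t))
  up <- ru > 0 & t >= 0 & t < ru
  amp[up] <- spec$current_mA * t[up] / ru
  flat <- t >= ru & t <= ru + pl
  amp[flat] <- spec$current_mA
  down <- rd > 0 & t > ru + pl & t <= ru + pl + rd
  amp[down] <- spec$current_mA * (1 - (t[down] - ru - pl) / rd)
  amp
}

#' Perceived scalp intensity under a protocol
#'
#' During the ramp-up and plateau, the sensation equals the current amplitude
#' (linear ramps, plateau at `current_mA`) attenuated by habituation
#' `exp(-t / habituation_tau)` (t measured from ramp onset: the scalp is most
#' sensitive shortly after onset). From the end of the plateau, the sensation
#' fades linearly from its plateau-end value, reaching zero at the end of the
#' ramp-down plus `persistence_s` — sensation outlives the current slightly,
#' and is exactly 0 beyond offset + persistence. The function is continuous
#' in t.
#'
#' @param t Time(s) in seconds from stimulation onset (vectorized).
#' @param spec A [protocol_spec()].
#' @param params A [perception_params()].
#' @return Perceived intensity (mA-equivalent units), same length as `t`.
#' @export
perceived_intensity <- function(t, spec, params) {
  stopifnot(inherits(spec, "protocol_spec"), inherits(params, "perception_params"))
  if (any(t < 0)) stop("t must be non-negative")
  tau <- params$habituation_tau
  hab <- if (is.infinite(tau)) rep(1, length(t)) else exp(-t / tau)
  t_pl_end <- spec$ramp_up_s + spec$plateau_s
  out <- trapezoid_amplitude(t, spec) * hab
  fade_w <- spec$ramp_down_s + params$persistence_s
  late <- t > t_pl_end
  if (any(late)) {
    s_end <- spec$current_mA *
      (if (is.infinite(tau)) 1 else exp(-t_pl_end / tau))
    out[late] <- if (fade_w > 0)
      s_end * pmax(0, 1 - (t[late] - t_pl_end) / fade_w) else 0
  }
  out
}

mean_block_intensity <- function(spec, params, from, to, by = 1) {
  mean(perceived_intensity(seq(from, to, by = by), spec, params))
}

# block time windows within the 16-min probed period: blocks 2 and 3 split
# the stimulation window so that block 3 ends with the active ramp-down
# (660 s); block 4 is entirely post-stimulation
block_windows <- function() list(`2` = c(0, 330), `3` = c(330, 660),
                                 `4` = c(660, 960))

simulate_session <- function(pid, design, params, strength, condition,
                             session_order) {
  spec_id <- sprintf("%s_%gmA", condition, strength)
  spec <- design$protocols[[spec_id]]
  if (is.null(spec)) stop("design protocols lack an entry named ", spec_id)
  times <- probe_schedule(spec)
  n <- length(times)
  intensity <- perceived_intensity(times, spec, params)
  eps <- stats::rnorm(n, 0, params$response_noise)
  p_on <- stats::plogis(params$g * (intensity - params$threshold) + eps)
  yes <- stats::runif(n) < p_on
  confidence <- pmin(10, pmax(0, 10 * abs(2 * p_on - 1) +
                                stats::rnorm(n, 0, params$confidence_noise)))
  missing <- stats::runif(n) < params$lapse_rate
  probes <- data.frame(
    probe = seq_len(n), time_s = times,
    response = ifelse(missing, "missing", ifelse(yes, "yes", "no")),
    confidence = ifelse(missing, NA_real_, confidence))
  # reaction times: ex-Gaussian(mu 450 ms, sigma 50 ms, tau 100 ms) per trial,
  # correct with probability 0.95; in 2 mA active sessions blocks 2-4 are
  # slowed by distraction_coupling * g * (mean perceived intensity in block)
  wins <- block_windows()
  shift <- c(`1` = 0, `2` = 0, `3` = 0, `4` = 0)
  if (condition == "active" && strength == 2 && design$distraction_coupling != 0)
    for (b in names(wins))
      shift[b] <- design$distraction_coupling * params$g *
        mean_block_intensity(spec, params, wins[[b]][1], wins[[b]][2])
  n_tr <- c(100L, rep(design$trials_per_block, 3L))
  trial_rows <- lapply(1:4, function(b) {
    k <- n_tr[b]
    data.frame(block = b, trial = seq_len(k),
               correct = as.integer(stats::runif(k) < 0.95),
               rt_ms = stats::rnorm(k, 450, 50) + stats::rexp(k, 1 / 100) +
                 shift[[as.character(b)]])
  })
  # ordinal side-effect ratings: latent normal around a base level raised by
  # on-time exposure; itching rises most with longer stimulation
  exposure <- on_duration(spec) / 660 * strength / 2
  base <- c(headache = 1.3, tingling = 2.0, itching = 1.3, burning = 1.5,
            pain = 1.2)
  slope <- c(headache = 0.3, tingling = 0.8, itching = 1.8, burning = 0.8,
             pain = 0.3)
  se <- pmin(5, pmax(1, round(base + slope * exposure +
                                stats::rnorm(5, 0, 0.8))))
  participant_session(pid, strength, condition, session_order, probes,
                      do.call(rbind, trial_rows),
                      stats::setNames(se, SIDE_EFFECTS),
                      n_probes = spec$n_probes)
}

#' Simulate one participant's two-session record
#'
#' Simulates the active and the sham session under the participant's
#' perception parameters, then the end-of-study guess: correct with
#' probability `clip(guess_base + kappa * (accuracy - 0.5), 0, 1)`, where
#' accuracy is the participant's mean probe-level tracking accuracy (fraction
#' of non-missing probes whose yes/no response matches the congruent ideal
#' curve) across both sessions and kappa is the design's `guess_coupling`.
#'
#' Draws from the current RNG stream; seed the stream (or use
#' [simulate_study()]) for reproducibility.
#'
#' @param pid Participant id label.
#' @param design A [study_design()].
#' @param params A [perception_params()], or a list with elements `active`
#'   and `sham` for session-specific parameters.
#' @param strength Current strength in mA.
#' @param first_condition Which condition came first (`"active"` or `"sham"`).
#' @return A [participant_record()].
#' @export
simulate_participant <- function(pid, design, params, strength,
                                 first_condition = "active") {
  if (inherits(params, "perception_params"))
    params <- list(active = params, sham = params)
  order_of <- function(cond) if (cond == first_condition) 1L else 2L
  sessions <- lapply(c("active", "sham"), function(cond)
    simulate_session(pid, design, params[[cond]], strength, cond,
                     order_of(cond)))
  acc <- mean(vapply(sessions, function(s) {
    spec <- design$protocols[[sprintf("%s_%gmA", s$condition, strength)]]
    ideal <- build_ideal_curve(spec)$values
    ok <- s$probes$response != "missing"
    if (!any(ok)) return(0.5)
    mean((s$probes$response[ok] == "yes") == (ideal[ok] > 0))
  }, 0))
  p_correct <- min(1, max(0, design$guess_base +
                            design$guess_coupling * (acc - 0.5)))
  guess <- if (stats::runif(1) < p_correct) "correct" else "incorrect"
  participant_record(pid, sessions, guess)
}

#' Simulate a full synthetic study
#'
#' Draws a population of participants under `design` and `population`,
#' simulates every session, and (optionally) writes the study to `out_dir`
#' in the [write_study()] CSV layout. With the defaults this yields 64
#' participants (32 per current strength), 128 sessions and 4,096 probe
#' rows. The run is fully determined by `design$seed`.
#'
#' @param design A [study_design()].
#' @param population A [population_params()].
#' @param out_dir Optional output directory for the CSV files.
#' @return Named list of [participant_record()]s with attribute `truth`: a
#'   data frame of each participant's true gains (`g_base`, `g_active`,
#'   `g_sham`) for parameter-recovery checks.
#' @export
simulate_study <- function(design, population = population_params(),
                           out_dir = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(population, "population_params"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(design$seed)
  records <- list(); truth <- list()
  for (strength in design$strengths) {
    meanlog <- if (strength >= 2) population$g_meanlog_2mA else
      population$g_meanlog_1mA
    for (i in seq_len(design$n_per_strength)) {
      pid <- sprintf("P%g_%02d", strength, i)
      g_base <- stats::rlnorm(1, meanlog, population$g_sdlog)
      g_sess <- g_base * exp(stats::rnorm(2, 0, population$session_jitter_sdlog))
      mk <- function(g) do.call(perception_params,
                                c(list(g = g), population$fixed))
      params <- list(active = mk(g_sess[1]), sham = mk(g_sess[2]))
      first <- if (design$counterbalance && i %% 2 == 0) "sham" else "active"
      rec <- simulate_participant(pid, design, params, strength, first)
      records[[pid]] <- rec
      truth[[pid]] <- data.frame(participant_id = pid, current_mA = strength,
                                 g_base = g_base, g_active = g_sess[1],
                                 g_sham = g_sess[2])
    }
  }
  records <- structure(records, truth = do.call(rbind, truth))
  if (!is.null(out_dir)) write_study(records, out_dir)
  records
}
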
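test_that("perceived intensity follows ramp, habituation and persistence", {
  spec <- active2()
  p_inf <- perception_params(habituation_tau = Inf, persistence_s = 0)
  # mid-ramp: half amplitude before habituation
  expect_equal(perceived_intensity(15, spec, p_inf), 1)
  # plateau start without habituation: full current
  expect_equal(perceived_intensity(30, spec, p_inf), 2)
  # with habituation the plateau decays exponentially
  p_hab <- perception_params(habituation_tau = 600, persistence_s = 0)
  expect_equal(perceived_intensity(300, spec, p_hab), 2 * exp(-0.5))
  # beyond offset + persistence the sensation is exactly 0
  p <- perception_params(persistence_s = 20)
  expect_equal(perceived_intensity(on_duration(spec) + 20, spec, p), 0)
  expect_equal(perceived_intensity(2000, spec, p), 0)
  # continuity at the plateau end
  eps <- 1e-6
  expect_equal(perceived_intensity(630 + eps, spec, p_hab),
               perceived_intensity(630 - eps, spec, p_hab), tolerance = 1e-6)
  expect_error(perceived_intensity(-1, spec, p), "non-negative")
})

test_that("parameter constructors validate their domains", {
  expect_error(perception_params(g = -1), "non-negative")
  expect_error(perception_params(lapse_rate = 0.5), "0.2")
  expect_error(study_design(), "seed")
  expect_error(study_design(guess_coupling = 2, seed = 1), "\\[0, 1\\]")
})

test_that("a fixed seed reproduces the study exactly", {
  d <- tiny_design(17)
  r1 <- simulate_study(d)
  r2 <- simulate_study(d)
  expect_identical(r1, r2)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_study(simulate_study(d), dir1)
  write_study(simulate_study(d), dir2)
  for (f in c("participants.csv", "sessions.csv", "probes.csv", "trials.csv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("zero gain produces a base-rate random responder", {
  des <- tiny_design(19, n = 16L)
  rec <- simulate_study(des, population_params(
    g_meanlog_1mA = -Inf, g_meanlog_2mA = -Inf, g_sdlog = 0,
    lapse_rate = 0, response_noise = 1))
  yes <- unlist(lapply(rec, function(r) lapply(r$sessions, function(s)
    s$probes$response == "yes")))
  # P(yes) = E[plogis(e)], e ~ N(0, 1): 0.5 by symmetry; binomial bounds
  n <- length(yes)
  expect_gt(mean(yes), 0.5 - 3 * sqrt(0.25 / n))
  expect_lt(mean(yes), 0.5 + 3 * sqrt(0.25 / n))
})

test_that("saturated noise-free perception reproduces the ideal curves", {
  # active: persistence keeps the final on-probe (660 s) above threshold
  des <- study_design(n_per_strength = 1L, trials_per_block = 5L, seed = 23)
  pa <- perception_params(g = 1e4, threshold = 0.25,
                          habituation_tau = Inf, persistence_s = 30,
                          confidence_noise = 0, response_noise = 0,
                          lapse_rate = 0)
  rec <- simulate_participant("P", des, pa, 2, "active")
  sa <- rec$sessions$active
  ideal_a <- build_ideal_curve(active2())
  expect_equal(ifelse(ideal_a$values > 0, "yes", "no"), sa$probes$response)
  expect_equal(peak_sensitivity(probe_series(sa), ideal_a)$peak_r, 1,
               tolerance = 1e-9)
  # sham: threshold above the lingering tail instead
  ps <- perception_params(g = 1e4, threshold = 0.5,
                          habituation_tau = Inf, persistence_s = 0,
                          confidence_noise = 0, response_noise = 0,
                          lapse_rate = 0)
  rec2 <- simulate_participant("P2", des, ps, 2, "active")
  ss <- rec2$sessions$sham
  ideal_s <- build_ideal_curve(sham2())
  expect_equal(ifelse(ideal_s$values > 0, "yes", "no"), ss$probes$response)
  expect_equal(peak_sensitivity(probe_series(ss), ideal_s)$peak_r, 1,
               tolerance = 1e-9)
})

test_that("generated studies satisfy the data-layout invariants", {
  for (seed in 1:100) {
    rec <- simulate_study(study_design(n_per_strength = 1L,
                                       trials_per_block = 3L, seed = seed))
    expect_length(rec, 2L)
    for (r in rec) {
      expect_s3_class(r, "participant_record")   # constructor validated
      expect_true(r$guess %in% c("correct", "incorrect"))
      for (s in r$sessions) {
        expect_equal(nrow(s$probes), 32L)
        conf <- s$probes$confidence[s$probes$response != "missing"]
        expect_true(all(conf >= 0 & conf <= 10))
        expect_true(all(s$side_effects >= 1 & s$side_effects <= 5))
        expect_equal(sum(s$rt_trials$block == 1), 100L)
      }
      orders <- sort(vapply(r$sessions, function(s) s$session_order, 0L))
      expect_equal(unname(orders), 1:2)
    }
  }
})

test_that("default study dimensions match the two-study layout", {
  rec <- simulate_study(study_design(seed = 29, trials_per_block = 3L))
  expect_length(rec, 64L)
  expect_equal(sum(vapply(rec, function(r) r$current_mA, 0) == 1), 32L)
  n_sessions <- sum(vapply(rec, function(r) length(r$sessions), 0L))
  expect_equal(n_sessions, 128L)
  n_probe_rows <- sum(unlist(lapply(rec, function(r)
    lapply(r$sessions, function(s) nrow(s$probes)))))
  expect_equal(n_probe_rows, 4096L)
  truth <- attr(rec, "truth")
  expect_equal(nrow(truth), 64L)
  expect_true(all(truth$g_base > 0))
})

test_that("within-participant gains induce an active-sham sensitivity correlation", {
  rec <- simulate_study(study_design(n_per_strength = 16L,
                                     trials_per_block = 3L, seed = 37))
  tab <- sensitivity_table(rec)
  congr <- tab[tab$reference == "congruent", ]
  w <- reshape(congr[, c("participant_id", "condition", "peak_r")],
               idvar = "participant_id", timevar = "condition",
               direction = "wide")
  expect_gt(cor(w$peak_r.active, w$peak_r.sham), 0)
})

test_that("the assessment object assembles every pipeline stage", {
  rec <- simulate_study(tiny_design(43, n = 6L))
  a <- assess_blinding(rec, n_boot = 100, seed = 2)
  expect_s3_class(a, "blinding_assessment")
  expect_equal(nrow(a$sensitivity), 4L * length(rec))
  expect_equal(nrow(a$group_curves), 4L * 32L)  # 2 conditions x 2 strengths
  expect_true(all(c("congruence", "current_strength", "guess_accuracy") %in%
                    a$classifiers$classifier))
  expect_true("anova_congruence" %in% names(a$stats))
  expect_output(print(a), "Sham-blinding assessment")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(a); grDevices::dev.off()
  expect_true(file.size(f) > 0)
  unlink(f)
})
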
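test_that("detrending removes linear trends and centres residuals", {
  expect_equal(detrend(1:5), rep(0, 5), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(detrend(rep(3.7, 8)), rep(0, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
  x <- c(1, 0, 2, 0, 3, 0)
  r <- detrend(x)
  # closed-form least squares: residuals orthogonal to 1 and to time
  t <- seq_along(x)
  beta <- cov(t, x) / var(t)
  alpha <- mean(x) - beta * mean(t)
  expect_equal(r, x - alpha - beta * t, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(r), 0, tolerance = 1e-10)
  expect_equal(sum(r * t), 0, tolerance = 1e-9)
  expect_error(detrend(1), "at least 2")
})

test_that("cross-correlation matches the brute-force double loop", {
  set.seed(1)
  for (i in 1:25) {
    x <- rnorm(32); y <- rnorm(32)
    L <- sample(1:31, 1)
    expect_equal(xcorr_coeff(x, y, max_lag = L), brute_xcorr(x, y, L),
                 tolerance = 1e-12)
  }
})

test_that("cross-correlation has the documented structure", {
  set.seed(2)
  x <- rnorm(20)
  r <- xcorr_coeff(x, x, max_lag = 19)
  expect_equal(unname(r["0"]), 1)            # Cauchy-Schwarz equality
  expect_true(all(abs(r) <= 1 + 1e-12))
  # a delayed copy peaks at the positive delay
  y <- c(rep(0, 3), x[1:17])
  ry <- xcorr_coeff(x, y, max_lag = 19)
  expect_equal(as.integer(names(ry)[which.max(ry)]), 3L)
  # orthogonal series: sine and cosine over full periods
  t <- seq_len(32)
  s <- sin(2 * pi * t / 8); cth <- cos(2 * pi * t / 8)
  expect_equal(unname(xcorr_coeff(s, cth, max_lag = 31)["0"]), 0,
               tolerance = 1e-12)
  expect_error(xcorr_coeff(rep(0, 10), rnorm(10)), "all-zero")
  expect_error(xcorr_coeff(rnorm(5), rnorm(5), max_lag = 5), "at most")
})

test_that("normalization is invariant to positive rescaling of either series", {
  set.seed(3)
  x <- rnorm(32); y <- rnorm(32)
  base <- xcorr_coeff(x, y, 31)
  for (c in c(0.01, 3, 250)) {
    expect_equal(xcorr_coeff(c * x, y, 31), base, tolerance = 1e-12)
    expect_equal(xcorr_coeff(x, c * y, 31), base, tolerance = 1e-12)
  }
  # so +-10 and +-1 ideal-curve scalings give identical coefficients
  ia <- build_ideal_curve(active2())$values
  expect_equal(xcorr_coeff(detrend(ia), y, 31),
               xcorr_coeff(detrend(ia / 10), y, 31), tolerance = 1e-12)
})

test_that("a perfect responder peaks at r = 1, lag 0, for both protocols", {
  for (spec in list(active2(), sham2())) {
    ideal <- build_ideal_curve(spec)
    res <- peak_sensitivity(ideal$values, ideal)
    expect_equal(res$peak_r, 1, tolerance = 1e-12)
    expect_equal(res$peak_lag, 0L)
  }
})

test_that("a one-probe-late responder peaks at lag +1", {
  ideal <- build_ideal_curve(active2())
  late <- c(ideal$values[1], ideal$values[1:31])
  res <- peak_sensitivity(late, ideal)
  expect_equal(res$peak_lag, 1L)
  # and the whole lag profile agrees with the brute-force oracle
  expect_equal(res$r_by_lag,
               brute_xcorr(detrend(ideal$values), detrend(late), 31),
               tolerance = 1e-12)
})

test_that("sign-flipped responses match the brute-force signed maximum", {
  set.seed(4)
  ideal <- build_ideal_curve(sham2())
  v <- sample(c(-1, 1), 32, TRUE) * runif(32, 0, 10)
  flipped <- -v
  res <- peak_sensitivity(flipped, ideal)
  oracle <- brute_xcorr(detrend(ideal$values), detrend(flipped), 31)
  expect_equal(res$peak_r, max(oracle), tolerance = 1e-12)
})

test_that("peak ties break toward the smallest then negative lag", {
  r <- rep(0.2, 7)
  r[c(2, 6)] <- 0.9  # lags -2 and +2
  lags <- -3:3
  expect_equal(lags[shamtrack:::pick_peak(r, lags)], -2L)
  r2 <- rep(0.1, 7); r2[c(3, 6)] <- 0.8  # lags -1 and +2
  expect_equal(lags[shamtrack:::pick_peak(r2, lags)], -1L)
})

test_that("missing probes are interpolated linearly with end fill", {
  x <- c(NA, 2, NA, 4, NA)
  f <- interpolate_missing(x)
  expect_equal(as.numeric(f), c(2, 2, 3, 4, 4))
  expect_equal(attr(f, "n_interpolated"), 3L)
  expect_error(interpolate_missing(rep(NA_real_, 4)), "all-missing")
  # interpolation count propagates into results
  ideal <- build_ideal_curve(active2())
  v <- ideal$values; v[c(5, 20)] <- NA
  expect_equal(peak_sensitivity(v, ideal)$n_interpolated, 2L)
})

test_that("the per-lag Pearson variant is a valid correlation everywhere", {
  set.seed(5)
  x <- rnorm(32); y <- rnorm(32)
  rp <- xcorr_coeff(x, y, 31, pearson = TRUE)
  expect_true(all(abs(rp) <= 1 + 1e-12, na.rm = TRUE))
  # at lag 0 it equals cor(x, y), unlike the global 'coeff' normalization
  expect_equal(unname(rp["0"]), cor(x, y), tolerance = 1e-12)
})

test_that("the sensitivity table has 4 rows per participant, well formed", {
  recs <- list(perfect_record("P1"), perfect_record("P2", guess = "incorrect"))
  tab <- sensitivity_table(recs)
  expect_equal(nrow(tab), 8L)
  expect_equal(sort(unique(tab$reference)), c("congruent", "incongruent"))
  congr <- tab[tab$reference == "congruent", ]
  expect_equal(congr$peak_r, rep(1, 4), tolerance = 1e-12)
  expect_equal(congr$peak_lag, rep(0L, 4))
  rec64 <- simulate_study(tiny_design(9, n = 3L))
  expect_equal(nrow(sensitivity_table(rec64)), 6L * 4L)
})

test_that("higher perceptual gain raises congruent sensitivity", {
  des <- tiny_design(31, n = 12L)
  hi <- simulate_study(des, population_params(g_meanlog_1mA = log(6),
                                              g_meanlog_2mA = log(6),
                                              g_sdlog = 0.2))
  lo <- simulate_study(des, population_params(g_meanlog_1mA = log(0.001),
                                              g_meanlog_2mA = log(0.001),
                                              g_sdlog = 0.2))
  mean_congr <- function(r) {
    t <- sensitivity_table(r)
    mean(t$peak_r[t$reference == "congruent"])
  }
  expect_gt(mean_congr(hi), mean_congr(lo))
})

test_that("random responders sit at the max-selection bias level", {
  # Monte Carlo regression band frozen from a 2,000-series run:
  # mean peak r vs the active ideal 0.30 (SD 0.08)
  set.seed(77)
  ideal <- build_ideal_curve(active2())
  pk <- replicate(300, {
    v <- sample(c(-1, 1), 32, TRUE) * runif(32, 0, 10)
    peak_sensitivity(v, ideal)$peak_r
  })
  expect_gt(mean(pk), 0.2)
  expect_lt(mean(pk), 0.45)
})

test_that("congruent exceeds incongruent on average in a sensitive population", {
  rec <- simulate_study(study_design(n_per_strength = 8L,
                                     trials_per_block = 5L, seed = 12))
  tab <- sensitivity_table(rec)
  expect_gt(mean(tab$peak_r[tab$reference == "congruent"]),
            mean(tab$peak_r[tab$reference == "incongruent"]))
})
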
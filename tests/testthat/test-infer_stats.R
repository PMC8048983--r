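test_that("delta-RT subtracts the baseline median over correct trials", {
  s <- make_session(rt_by_block = c(500, 510, 520, 495))
  expect_equal(delta_rt(s), c(block2 = 10, block3 = 20, block4 = -5))
  flat <- make_session(rt_by_block = c(480, 480, 480, 480))
  expect_equal(unname(delta_rt(flat)), c(0, 0, 0))
})

test_that("block medians follow the midpoint convention and drop errors", {
  probes <- data.frame(probe = 1:32, time_s = 30 * (1:32), response = "yes",
                       confidence = 5)
  trials <- rbind(
    data.frame(block = 1, trial = 1:100, correct = 1L,
               rt_ms = c(401:500)),                    # even count: midpoint
    data.frame(block = 2, trial = 1:5, correct = c(1, 1, 1, 0, 0),
               rt_ms = c(300, 700, 500, 10, 10)),      # errors excluded
    data.frame(block = 3, trial = 1:3, correct = 0L, rt_ms = 1),
    data.frame(block = 4, trial = 1, correct = 1L, rt_ms = 600))
  s <- participant_session("P", 2, "active", 1, probes, trials,
                           setNames(rep(2, 5), shamtrack:::SIDE_EFFECTS))
  med <- rt_block_medians(s)
  expect_equal(med$median_rt_ms[1], (450 + 451) / 2)
  expect_equal(med$median_rt_ms[2], 500)
  expect_true(is.na(med$median_rt_ms[3]))   # no correct trials: flagged
  expect_equal(med$n_correct, c(100L, 3L, 0L, 1L))
  d <- delta_rt(s)
  expect_true(is.na(d[["block3"]]))
})

test_that("paired and Welch t tests match their closed forms", {
  x <- c(5.1, 4.8, 6.0, 5.5, 5.9, 4.7)
  # a mean-zero perturbation leaves t = 0 and p = 1
  expect_equal(paired_t(x, x + 1e-9 * c(1, -1, 1, -1, 1, -1))$p_value, 1,
               tolerance = 1e-6)
  y <- c(4.9, 4.5, 5.0, 5.1, 5.2, 4.4)
  res <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 5)
  expect_equal(res$effect_size, mean(d) / sd(d), tolerance = 1e-10)
  # Welch df by hand (Welch-Satterthwaite, fractional)
  a <- c(10, 12, 9, 14, 11); b <- c(20, 24, 19, 28, 25, 23, 21)
  w <- welch_t(a, b)
  va <- var(a) / 5; vb <- var(b) / 7
  df_hand <- (va + vb)^2 / (va^2 / 4 + vb^2 / 6)
  expect_equal(w$df, df_hand, tolerance = 1e-10)
  expect_equal(w$statistic, (mean(a) - mean(b)) / sqrt(va + vb),
               tolerance = 1e-10)
  # one-tailed direction is x > y
  one <- paired_t(x, y, tails = "one")
  expect_equal(one$p_value, res$p_value / 2, tolerance = 1e-10)
  expect_error(paired_t(x, x), "zero variance")
})

test_that("the mixed ANOVA reproduces a hand-worked sums-of-squares fixture", {
  # 8 subjects (4 per group), 2 within-levels
  d <- expand.grid(id = paste0("S", 1:8), w = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$b <- ifelse(d$id %in% paste0("S", 1:4), "g1", "g2")
  set.seed(21)
  d$y <- 10 + 2 * (d$b == "g2") + 1.5 * (d$w == "w2") +
    1.2 * (d$b == "g2") * (d$w == "w2") + rnorm(16)
  res <- mixed_anova(d, "y", "b", "w", "id")
  # manual split-plot decomposition
  n <- 8; cell <- with(d, tapply(y, list(b, w), mean))
  gm <- mean(d$y)
  subj_m <- with(d, tapply(y, id, mean))
  grp_of <- ifelse(names(subj_m) %in% paste0("S", 1:4), "g1", "g2")
  grp_m <- with(d, tapply(y, b, mean))
  w_m <- with(d, tapply(y, w, mean))
  ss_b <- 8 * sum((grp_m - gm)^2)
  ss_subj <- 2 * sum((subj_m - grp_m[grp_of])^2)
  ss_w <- 8 * sum((w_m - gm)^2)
  ss_cells <- 4 * sum((cell - gm)^2)
  ss_bw <- ss_cells - ss_b - ss_w
  ss_tot <- sum((d$y - gm)^2)
  ss_err_w <- ss_tot - ss_b - ss_subj - ss_w - ss_bw
  expect_equal(res$b$statistic, (ss_b / 1) / (ss_subj / 6), tolerance = 1e-10)
  expect_equal(res$w$statistic, (ss_w / 1) / (ss_err_w / 6), tolerance = 1e-10)
  expect_equal(res$`b:w`$statistic, (ss_bw / 1) / (ss_err_w / 6),
               tolerance = 1e-10)
  expect_equal(res$b$df, c(1, 6))
  expect_equal(res$b$effect_size, ss_b / (ss_b + ss_subj), tolerance = 1e-10)
})

test_that("degenerate ANOVA patterns behave as constructed", {
  d <- expand.grid(id = paste0("S", 1:6), w = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$b <- ifelse(d$id %in% paste0("S", 1:3), "g1", "g2")
  # additive between-group shift only, no noise
  d$y <- ifelse(d$b == "g2", 7, 3)
  res <- mixed_anova(d, "y", "b", "w", "id")
  expect_gt(res$b$statistic, 1e10)   # pure between effect
  expect_equal(res$w$statistic, 0)
  expect_equal(res$`b:w`$statistic, 0)
  # all observations equal: every F is 0
  d$y <- 4
  flat <- mixed_anova(d, "y", "b", "w", "id")
  expect_equal(unname(sapply(flat, function(r) r$statistic)), c(0, 0, 0))
  expect_error(mixed_anova(d[-1, ], "y", "b", "w", "id"), "exactly one")
})

test_that("the fully within 2x2 ANOVA matches aov strata on a fixture", {
  set.seed(22)
  d <- expand.grid(id = paste0("S", 1:6), a = c("a1", "a2"), b = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(24) + 2 * (d$a == "a2")
  res <- repeated_anova_2x2(d, "y", "a", "b", "id")
  # independent oracle: per-effect paired contrast t tests; F = t^2 for df1 = 1
  amat <- with(d, tapply(y, list(id, a), mean))
  t_a <- t.test(amat[, 1], amat[, 2], paired = TRUE)$statistic
  expect_equal(res$a$statistic, unname(t_a^2), tolerance = 1e-10)
  bmat <- with(d, tapply(y, list(id, b), mean))
  t_b <- t.test(bmat[, 1], bmat[, 2], paired = TRUE)$statistic
  expect_equal(res$b$statistic, unname(t_b^2), tolerance = 1e-10)
  inter <- with(d, tapply(y, list(id, interaction(a, b)), mean))
  contrast <- inter[, "a1.b1"] - inter[, "a2.b1"] - inter[, "a1.b2"] +
    inter[, "a2.b2"]
  t_ab <- t.test(contrast)$statistic
  expect_equal(res$`a:b`$statistic, unname(t_ab^2), tolerance = 1e-10)
  expect_equal(res$a$df, c(1, 5))
})

test_that("Wilcoxon signed-rank matches exhaustive enumeration at n = 6", {
  a <- c(12, 9, 14, 11, 10, 16)
  b <- c(10, 11.5, 8, 12, 6, 9)
  res <- wilcoxon_signed_rank(a, b)
  d <- a - b
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  expect_equal(res$statistic, W_obs)
  # full 2^6 enumeration of the null distribution of W+
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  W_null <- signs %*% r
  p_exact <- min(1, 2 * min(mean(W_null <= W_obs), mean(W_null >= W_obs)))
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  # agrees with the standard implementation when there are no ties
  expect_equal(res$p_value, wilcox.test(a, b, paired = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Wilcoxon handles zeros, ties and antisymmetry", {
  a <- c(3, 5, 5, 8, 2, 2)
  b <- c(3, 4, 7, 5, 1, 4)   # one zero difference, tied |d|
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$n_used, 5L)
  swapped <- wilcoxon_signed_rank(b, a)
  expect_equal(swapped$z, -res$z, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  degen <- wilcoxon_signed_rank(1:4, 1:4)
  expect_equal(degen$flag, "all differences zero")
  expect_equal(degen$p_value, 1)
  # large-n branch: normal approximation with continuity correction
  set.seed(23)
  x <- rnorm(40); y <- rnorm(40)
  big <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(big$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("sensitivity-RT correlations cover the four strata and flag degenerates", {
  expect_equal(pearson_cor(1:5, 2 * (1:5) + 3)$statistic, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(1:5, rep(1, 5))$flag,
               "zero variance: correlation undefined")
  rec <- simulate_study(tiny_design(41, n = 6L))
  out <- sensitivity_rt_correlations(sensitivity_table(rec), rec)
  expect_setequal(names(out),
                  c("sensitivity_vs_dRT3_1mA_active",
                    "sensitivity_vs_dRT3_1mA_sham",
                    "sensitivity_vs_dRT3_2mA_active",
                    "sensitivity_vs_dRT3_2mA_sham"))
})

test_that("distraction coupling produces the 2 mA active RT correlation only", {
  des <- study_design(n_per_strength = 24L, trials_per_block = 60L,
                      distraction_coupling = 25, seed = 71)
  rec <- simulate_study(des)
  out <- sensitivity_rt_correlations(sensitivity_table(rec), rec)
  r2a <- out$sensitivity_vs_dRT3_2mA_active$statistic
  expect_gt(r2a, 0.3)
  expect_lt(abs(out$sensitivity_vs_dRT3_1mA_active$statistic), r2a)
  expect_lt(abs(out$sensitivity_vs_dRT3_2mA_sham$statistic), r2a)
})
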
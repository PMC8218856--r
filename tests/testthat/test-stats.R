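test_that("normality gate routes by Shapiro-Wilk deviation", {
  set.seed(12)
  m <- matrix(rnorm(29 * 4), 29, 4)
  g <- normality_gate(m)
  expect_identical(g$route, "anova")
  expect_true(all(g$shapiro_p > 0.05))
  expect_equal(unname(g$shapiro_p[1]), shapiro.test(m[, 1])$p.value)
  m2 <- m
  m2[, 2] <- exp(3 * rnorm(29))
  expect_identical(normality_gate(m2)$route, "friedman")
  m3 <- m
  m3[, 3] <- 5
  expect_identical(normality_gate(m3)$route, "friedman")
})

test_that("repeated-measures ANOVA matches the definitional SS decomposition", {
  set.seed(7)
  m <- matrix(rnorm(29 * 4, mean = rep(c(7.8, 5.1, 4.8, 5.3), each = 29),
                    sd = 2.5), 29, 4)
  a <- rm_anova(m)
  expect_equal(unname(a$df), c(3, 84))
  # definitional sums of squares
  grand <- mean(m)
  ss_s <- 4 * sum((rowMeans(m) - grand)^2)
  ss_c <- 29 * sum((colMeans(m) - grand)^2)
  ss_e <- sum((m - grand)^2) - ss_s - ss_c
  expect_equal(unname(a$ss["condition"]), ss_c)
  expect_equal(unname(a$ss["error"]), ss_e)
  expect_equal(a$statistic, (ss_c / 3) / (ss_e / 84))
  expect_equal(a$eta_sq_partial, ss_c / (ss_c + ss_e))
  # reference values computed independently with a dedicated rm-ANOVA
  # implementation (GG-corrected)
  expect_equal(a$statistic, 20.430135, tolerance = 1e-6)
  expect_equal(a$epsilon, 0.911390, tolerance = 1e-5)
  expect_equal(a$p, 2.476929e-09, tolerance = 1e-5)
  expect_equal(a$eta_sq_partial, 0.421848, tolerance = 1e-5)
  # identical columns: no condition effect
  expect_equal(rm_anova(matrix(rep(rnorm(10), 4), 10))$statistic, 0)
  # invariance to per-subject constants
  a2 <- rm_anova(m + rnorm(29) * 10)
  expect_equal(a2$statistic, a$statistic, tolerance = 1e-9)
  expect_error(rm_anova(cbind(m[, 1], NA)), "missing")
})

test_that("Friedman test uses mid-ranks and k-1 degrees of freedom", {
  set.seed(9)
  m <- matrix(sample(1:5, 15, replace = TRUE), 5, 3)
  f <- friedman_rank_test(m)
  expect_equal(f$df, 2)
  expect_equal(f$statistic, oracle_friedman_stat(m), tolerance = 1e-12)
  m4 <- matrix(rnorm(29 * 4), 29, 4)
  expect_equal(friedman_rank_test(m4)$df, 3)
  expect_equal(friedman_rank_test(matrix(rep(rnorm(8), 3), 8))$statistic, 0)
  # invariant to strictly monotone row-wise transforms
  mt <- t(apply(m4, 1, function(r) exp(r) + 5))
  expect_equal(friedman_rank_test(mt)$statistic,
               friedman_rank_test(m4)$statistic)
})

test_that("Wilcoxon post hocs match exact enumeration and report the Bonferroni rule", {
  # all-positive differences, n = 10: one-sided exact p = 1/1024
  x <- 1:10 + 0.5
  y <- 1:10 - seq(0.1, 1, 0.1)
  d <- x - y
  orc <- oracle_wilcoxon_exact(d)
  expect_equal(orc$p_ge, 1 / 1024)
  ph <- wilcoxon_posthocs(cbind(a = x, b = y), bf = FALSE)
  expect_equal(ph$p, 2 / 1024)
  expect_equal(ph$V, orc$v)
  # random paired data, exact path agrees with enumeration
  set.seed(21)
  for (r in 1:5) {
    x <- rnorm(12); y <- rnorm(12)
    ph <- wilcoxon_posthocs(cbind(a = x, b = y), bf = FALSE)
    expect_equal(ph$p, oracle_wilcoxon_exact(x - y)$p_two, tolerance = 1e-12)
  }
  # antisymmetric differences: Z near zero
  x <- c(1, 2, 3, -1, -2, -3) + 10
  ph <- wilcoxon_posthocs(cbind(a = x, b = rep(10, 6)), bf = FALSE)
  expect_lt(abs(ph$Z), 0.5)
  # six pairwise comparisons at family alpha 0.05
  m <- matrix(rnorm(40), 10, 4)
  ph6 <- wilcoxon_posthocs(m, bf = FALSE)
  expect_identical(nrow(ph6), 6L)
  expect_equal(unique(ph6$bonferroni_threshold), 0.05 / 6)
  expect_warning(wilcoxon_posthocs(cbind(a = 1:5, b = 1:5), bf = FALSE),
                 "zero")
})

test_that("JZS Bayes factors match an independent quadrature of the g-mixture form", {
  for (n in c(10, 29, 50)) for (t in c(0, 0.5, 2, 5)) {
    expect_equal(bf10_from_t(t, n), oracle_bf10_g(t, n),
                 tolerance = 0.01)
  }
  # null-favouring at t = 0, monotone increasing in |t|
  expect_lt(bf10_from_t(0, 29), 1)
  bfs <- vapply(seq(0, 10, by = 1), bf10_from_t, numeric(1), n = 20)
  expect_true(all(diff(bfs) > 0))
  # two-sided: swapping the pair leaves the BF unchanged
  set.seed(2)
  x <- rnorm(15); y <- rnorm(15, 0.8)
  expect_equal(bf10_paired_t(x, y), bf10_paired_t(y, x), tolerance = 1e-9)
  expect_error(bf10_paired_t(1:5, 1:5), "zero variance")
})

test_that("omnibus tests hold their nominal level under a true null", {
  set.seed(33)
  n_rep <- 200
  rej <- 0
  for (r in seq_len(n_rep)) {
    m <- matrix(rnorm(20 * 4), 20, 4)
    rej <- rej + (rm_anova(m)$p < 0.05)
  }
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.05)
  expect_gte(rej, ci[1] - 1)
  expect_lte(rej, ci[2] + 1)
})

test_that("behavioural analysis applies the window, outlier rule and routing", {
  # constant RTs: medians 300, zero omnibus statistic
  rt <- data.frame(subject = rep(1:6, each = 40),
                   trial = rep(1:40, 6),
                   condition = rep(rep(c("self", "fearful", "happy", "neutral"),
                                       each = 10), 6),
                   rt_ms = 300, responded = TRUE)
  res <- suppressWarnings(analyze_rts(rt))
  expect_true(all(res$medians == 300))
  expect_equal(res$omnibus$statistic, 0)
  # planted medians: self fastest; outlier subject excluded
  cfg <- sim_config(rng_seed = 15)
  rts <- list()
  for (s in 1:15) {
    set.seed(s * 101)
    conds <- sample(rep(c("self", "fearful", "happy", "neutral"), each = 72))
    rts[[s]] <- simulate_rts(cfg, s, conds)
  }
  rt <- do.call(rbind, rts)
  res <- analyze_rts(rt)
  expect_length(res$excluded_subjects, 0)
  expect_identical(names(which.min(res$condition_means)), "self")
  rt$rt_ms[rt$subject == 15] <- rt$rt_ms[rt$subject == 15] + 160
  res2 <- analyze_rts(rt)
  expect_equal(res2$excluded_subjects, 15)
  expect_identical(nrow(res2$medians), 14L)
  # out-of-window RTs are discarded
  rt3 <- rt[rt$subject != 15, ]
  rt3$rt_ms[1:10] <- 5000
  expect_silent(analyze_rts(rt3))
})
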
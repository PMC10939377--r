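test_that("threshold-crossing growth rates follow the decadal-log formula", {
  # crossing exactly at a sample: rate = log10(0.5/0.05)/10 = 0.1
  est <- effective_growth_rate(c(0, 10, 20), c(0.05, 0.5, 1.0))
  expect_false(est$censored)
  expect_equal(est$t_threshold, 10)
  expect_equal(est$rate, 0.1)
  # two decades in 20 h
  est2 <- effective_growth_rate(c(0, 20, 30), c(0.005, 0.5, 1.0))
  expect_equal(est2$rate, log10(100) / 20)
  # linear interpolation between bracketing samples
  est3 <- effective_growth_rate(c(0, 1, 2), c(0.1, 0.4, 0.6))
  expect_equal(est3$t_threshold, 1.5)
  expect_equal(est3$rate, log10(0.5 / 0.1) / 1.5)
  # censoring and error contracts
  est4 <- effective_growth_rate(c(0, 1, 2), c(0.1, 0.2, 0.3))
  expect_true(est4$censored)
  expect_true(is.na(est4$rate))
  expect_error(effective_growth_rate(c(0, 1), c(0.6, 0.7)), "threshold")
  expect_error(effective_growth_rate(c(0, 0), c(0.1, 0.2)))
})

test_that("estimated rate tracks a known exponential within 1%", {
  r <- 0.3  # natural-log units per hour
  tt <- seq(0, 24, by = 0.5)
  od <- 0.01 * exp(r * tt)
  est <- effective_growth_rate(tt, od)
  expect_equal(est$rate, r * log10(exp(1)), tolerance = 0.01)
})

test_that("growth rates are invariant to a uniform OD unit rescale", {
  tt <- seq(0, 24, by = 0.5)
  od <- 0.02 * exp(0.25 * tt)
  a <- effective_growth_rate(tt, od, od_threshold = 0.5)
  b <- effective_growth_rate(tt, od * 7, od_threshold = 0.5 * 7)
  expect_equal(a$rate, b$rate)
  expect_equal(a$t_threshold, b$t_threshold)
})

test_that("growth_rate_table estimates one row per well", {
  tt <- seq(0, 24, by = 1)
  df <- rbind(
    data.frame(well = "w1", strain = "s", initial_density = 1e6,
               smx = FALSE, time = tt, od600 = 0.01 * exp(0.3 * tt)),
    data.frame(well = "w2", strain = "s", initial_density = 1e6,
               smx = TRUE, time = tt, od600 = 0.01 * exp(0.01 * tt))
  )
  tab <- growth_rate_table(df)
  expect_equal(nrow(tab), 2L)
  expect_false(tab$censored[tab$well == "w1"])
  expect_true(tab$censored[tab$well == "w2"])
  expect_error(growth_rate_table(df[, -6]), "lacks columns")
})

test_that("plate-count arithmetic is exact, linear and flagged", {
  expect_equal(as.numeric(cfu_per_ml(50, 1e6, 0.01)), 5e9)
  expect_equal(as.numeric(cfu_per_ml(120, 1e5, 0.01)), 1.2e9)
  z <- cfu_per_ml(0, 1e6, 0.01)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "below_detection"))
  big <- cfu_per_ml(500, 1e2, 0.01)
  expect_true(attr(big, "implausible"))
  # linear in colonies and dilution factor
  set.seed(5)
  n0 <- sample(3:300, 20)
  expect_equal(as.numeric(cfu_per_ml(3 * n0, 1e4)),
               3 * as.numeric(cfu_per_ml(n0, 1e4)))
  expect_equal(as.numeric(cfu_per_ml(n0, 1e5)),
               10 * as.numeric(cfu_per_ml(n0, 1e4)))
  expect_error(cfu_per_ml(10, 1e4, 0), "positive")
})

test_that("linear fits reproduce the normal-equations oracle", {
  x <- 1:5
  fit <- fit_linear(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  flat <- fit_linear(x, rep(3, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(fit_linear(rep(1, 5), 1:5), "variance")
  expect_error(fit_linear(1:2, 1:2), ">= 3")
  set.seed(21)
  for (k in 1:20) {
    xs <- rnorm(10); ys <- rnorm(10)
    got <- fit_linear(xs, ys)
    want <- ols_normal_equations(xs, ys)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
  }
})

test_that("noisy slopes are recovered within three standard errors", {
  set.seed(33)
  x <- seq(5, 9, length.out = 30)      # log10 density axis
  y <- -0.012 * x + 0.2 + rnorm(30, 0, 0.01)
  fit <- fit_linear(x, y)
  expect_lt(abs(fit$slope - (-0.012)), 3 * fit$slope_se)
})

test_that("rank-sum p-values match full enumeration for small groups", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p_value,
               wilcoxon_enum_p(c(1, 2, 3), c(10, 11, 12)))
  set.seed(9)
  for (k in 1:40) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    x <- round(rnorm(m), 6); y <- round(rnorm(n, 0.5), 6)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcoxon_enum_p(x, y))
  }
})

test_that("rank-sum edge cases behave as documented", {
  expect_warning(deg <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5)), "identical")
  expect_equal(deg$p_value, 1)
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  sep <- wilcoxon_rank_sum(1:6, 11:16)
  expect_lt(sep$p_value, 0.05)
  big <- wilcoxon_rank_sum(rnorm(15), rnorm(15, 2))
  expect_equal(big$method, "normal approximation")
  expect_error(wilcoxon_rank_sum(1:2, 1:5), ">= 3")
})
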
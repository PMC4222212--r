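test_that("calibration formula reproduces worked values and anchor identities", {
  expect_equal(round(wild_genome_proportion(0.48, 0.93, 0.07), 3), 0.477)
  expect_equal(wild_genome_proportion(0.93, 0.93, 0.07), 1.0)
  expect_equal(wild_genome_proportion(0.07, 0.93, 0.07), 0.0)
  expect_error(wild_genome_proportion(0.5, 0.07, 0.93), "must exceed")
  expect_warning(wild_genome_proportion(0.99, 0.93, 0.07), "outside")
})

test_that("calibration is linear in the admixed mean with slope 1/(wild - farm)", {
  w <- 0.91; f <- 0.05
  x <- seq(0.1, 0.9, by = 0.1)
  y <- wild_genome_proportion(x, w, f)
  slopes <- diff(y) / diff(x)
  expect_equal(slopes, rep(1 / (w - f), length(slopes)))
})

test_that("a contemporary sample identical to its historical one is not rejected", {
  vals <- c(0.95, 0.9, 0.85, 0.92, 0.88, 0.97, 0.9, 0.86)
  hist <- dist_from_values(vals, role = "wild")
  cont <- dist_from_values(vals, role = "admixed")
  panel <- dist_from_values(c(vals, 0.93, 0.89, 0.91, 0.87),
                            pops = rep(c("a", "b"), each = 6))
  t <- test_mean_pwild(cont, historical = hist, wild_panel = list(panel))
  expect_equal(t$p_value, 0.5)
  expect_false(t$reject)
  expect_identical(t$mode, "with_reference")
  expect_gte(t$sigma2_within, 0)
})

test_that("a contemporary sample at the farm mean is rejected decisively", {
  set.seed(41)
  wild_vals <- inv_logit(rnorm(120, 2.6, 1))
  panel <- dist_from_values(wild_vals, pops = rep(paste0("w", 1:4), each = 30))
  cont <- dist_from_values(rep(0.07, 30), role = "admixed")
  t_wo <- test_mean_pwild(cont, wild_panel = list(panel))
  expect_true(t_wo$reject)
  expect_lt(t_wo$p_value, 0.001)
  hist <- dist_from_values(inv_logit(rnorm(33, 2.6, 1)), role = "wild")
  t_w <- test_mean_pwild(cont, historical = hist, wild_panel = list(panel))
  expect_true(t_w$reject)
  expect_lt(t_w$p_value, 0.001)
})

test_that("without-reference mode requires at least two wild populations", {
  panel <- dist_from_values(runif(20, 0.7, 1), pops = "only_one")
  cont <- dist_from_values(runif(10, 0.7, 1), role = "admixed")
  expect_error(test_mean_pwild(cont, wild_panel = list(panel)),
               ">= 2 populations")
})

test_that("rejection is dual to the critical-value curve", {
  set.seed(43)
  panel <- dist_from_values(inv_logit(rnorm(90, 2.4, 0.9)),
                            pops = rep(paste0("w", 1:3), each = 30))
  curve <- critical_value_curve(list(panel), n_range = c(10, 25, 40))
  for (k in seq_len(nrow(curve))) {
    n <- curve$n[k]
    just_below <- inv_logit(curve$critical_value_logit[k] - 1e-6)
    just_above <- inv_logit(curve$critical_value_logit[k] + 1e-6)
    t_lo <- test_mean_pwild(dist_from_values(rep(just_below, n), role = "admixed"),
                            wild_panel = list(panel))
    t_hi <- test_mean_pwild(dist_from_values(rep(just_above, n), role = "admixed"),
                            wild_panel = list(panel))
    expect_true(t_lo$reject)
    expect_false(t_hi$reject)
    expect_equal(t_lo$reject, t_lo$p_value < t_lo$level)
    expect_equal(t_hi$reject, t_hi$p_value < t_hi$level)
  }
})

test_that("critical-value curves are monotone and reach the closed-form limit", {
  set.seed(47)
  panel <- dist_from_values(inv_logit(rnorm(150, 2.5, 1)),
                            pops = rep(paste0("w", 1:5), each = 30))
  ns <- c(2, 5, 10, 30, 100, 1000)
  cv_wo <- critical_value_curve(list(panel), n_range = ns)
  expect_true(all(diff(cv_wo$critical_value) >= 0))

  hist <- dist_from_values(inv_logit(rnorm(33, 2.5, 1)))
  cv_w <- critical_value_curve(list(panel), historical = hist, n_range = ns)
  expect_true(all(diff(cv_w$critical_value) >= 0))

  # large-n limit without reference: grand mean - z_0.95 * sqrt(sigma2_between)
  comp <- split(panel$values$logit_p_wild, panel$values$population)
  pop_means <- vapply(comp, mean, numeric(1))
  s2w <- sum(vapply(comp, function(v) sum((v - mean(v))^2), numeric(1))) /
    sum(lengths(comp) - 1)
  s2b <- max(0, var(pop_means) - s2w * mean(1 / lengths(comp)))
  limit <- mean(pop_means) + qnorm(0.05) * sqrt(s2b)
  big <- critical_value_curve(list(panel), n_range = 1e7)
  expect_equal(big$critical_value_logit, limit, tolerance = 1e-4)
})

test_that("bootstrap intervals behave like percentile intervals", {
  # degenerate sample: zero-width interval at the point estimate
  e0 <- bootstrap_ci(rep(0.5, 20), 0.93, 0.07, n_boot = 200, seed = 3)
  expect_equal(e0$ci_low, e0$wild_genome_left)
  expect_equal(e0$ci_high, e0$wild_genome_left)

  set.seed(51)
  vals <- rbeta(100, 3, 3)
  e100 <- bootstrap_ci(vals, 0.93, 0.07, n_boot = 1000, seed = 4)
  e30 <- bootstrap_ci(vals[1:30], 0.93, 0.07, n_boot = 1000, seed = 5)
  expect_gt(e30$ci_high - e30$ci_low, e100$ci_high - e100$ci_low)
  expect_lte(e100$ci_low, e100$wild_genome_left)
  expect_gte(e100$ci_high, e100$wild_genome_left)
  expect_error(bootstrap_ci(numeric(0), 0.93, 0.07), "no P")

  # determinism
  e_again <- bootstrap_ci(vals, 0.93, 0.07, n_boot = 1000, seed = 4)
  expect_identical(e_again$ci_low, e100$ci_low)
})
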
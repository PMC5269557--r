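test_that("error-free trajectory evaluates the quadratic mixed trend", {
  beta <- c(4.05, -0.14, 0.0021)
  expect_equal(true_trajectory(beta, c(0, 0), 0), 4.05)
  # direct arithmetic: 4.05 - 0.14*26 + 0.0021*676
  expect_equal(true_trajectory(beta, c(0, 0), 26), 1.8296)
  # intercept shift
  expect_equal(true_trajectory(c(1, 2, 3), c(0.7, 0), 0), 1.7)
  expect_error(true_trajectory(beta, c(0, 0), -1), ">= 0")
})

test_that("cumulative hazard has closed forms in degenerate cases", {
  cfg <- generator_config(alpha = 0, gamma = rep(0, 5),
                          knots = c(0, 50), lambda = 0.1)
  w0 <- rep(0, 5)
  expect_equal(cumulative_hazard(cfg, w0, c(0, 0), 10), 1.0,
               tolerance = 1e-10)
  expect_equal(cumulative_hazard(cfg, w0, c(0, 0), 0), 0)
  # constant m = 2 with alpha = 0.5: H(t) = 0.1 * e * t
  cfg2 <- generator_config(alpha = 0.5, gamma = rep(0, 5),
                           beta = c(0, 0, 0), knots = c(0, 50),
                           lambda = 0.1)
  expect_equal(cumulative_hazard(cfg2, w0, c(2, 0), 7), 0.1 * exp(1) * 7,
               tolerance = 1e-10)
  expect_error(cumulative_hazard(cfg, w0, c(0, 0), -2), ">= 0")
})

test_that("cumulative hazard matches dense trapezoid integration", {
  cfg <- generator_config()  # beta2 != 0: no elementary antiderivative
  w <- c(3.2, 1, 0, 1, 0)
  b <- c(0.8, -0.03)
  for (t in c(5, 13.7, 26)) {
    s <- seq(0, t, length.out = 200001)
    h <- exp(sum(cfg$gamma * w) + cfg$alpha *
               true_trajectory(cfg$beta, b, s))
    lam <- cfg$lambda[pmin(findInterval(s, cfg$knots,
                                        all.inside = TRUE),
                           length(cfg$lambda))]
    oracle <- sum((h * lam)[-1] + (h * lam)[-length(s)]) / 2 * diff(s)[1]
    expect_equal(cumulative_hazard(cfg, w, b, t), oracle,
                 tolerance = 1e-8)
  }
})

test_that("cumulative hazard is monotone nondecreasing in t", {
  cfg <- generator_config()
  w <- c(-4, 0, 1, 0, 0)
  b <- c(-0.5, 0.02)
  H <- vapply(seq(0, 30, by = 1.5),
              function(t) cumulative_hazard(cfg, w, b, t), numeric(1))
  expect_true(all(diff(H) >= 0))
})

test_that("sampled event times reduce to exponentials when hazard is flat", {
  cfg <- generator_config(alpha = 0, gamma = rep(0, 5),
                          knots = c(0, 100), lambda = 0.25)
  w0 <- rep(0, 5)
  set.seed(401)
  draws <- replicate(3000, sample_event_time(cfg, w0, c(0, 0)))
  expect_true(all(is.finite(draws)))
  se <- (1 / 0.25) / sqrt(3000)
  expect_lt(abs(mean(draws) - 1 / 0.25), 3 * se)
})

test_that("higher engagement delays dropout stochastically when alpha < 0", {
  cfg <- generator_config()  # alpha = -0.26
  w0 <- rep(0, 5)
  set.seed(402)
  low <- replicate(800, sample_event_time(cfg, w0, c(-1.5, 0)))
  high <- replicate(800, sample_event_time(cfg, w0, c(1.5, 0)))
  ks <- suppressWarnings(stats::ks.test(high, low,
                                        alternative = "greater"))
  # one-sided: the high-engagement subject's times are stochastically
  # larger, so the "greater" direction should NOT reject ...
  expect_gt(ks$p.value, 0.05)
  # ... while the opposite direction rejects decisively
  ks2 <- suppressWarnings(stats::ks.test(low, high,
                                         alternative = "greater"))
  expect_lt(ks2$p.value, 1e-6)
})

test_that("event-time draws follow the analytic survival function", {
  cfg <- generator_config()
  w <- c(0, 1, 0, 0, 0)
  b <- c(0.4, -0.02)
  set.seed(403)
  n <- 2000
  draws <- replicate(n, sample_event_time(cfg, w, b))
  grid <- seq(1, 60, by = 0.5)
  S_hat <- vapply(grid, function(t) mean(draws > t), numeric(1))
  S_true <- vapply(grid, function(t)
    exp(-cumulative_hazard(cfg, w, b, t)), numeric(1))
  # Kolmogorov-Smirnov band at alpha = 0.001
  expect_lt(max(abs(S_hat - S_true)), 1.95 / sqrt(n))
})

test_that("generation is deterministic under a fixed seed and stable in n", {
  cfg <- generator_config(n_subjects = 12, seed = 99)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$longitudinal, g2$cohort$longitudinal)
  expect_identical(g1$truth, g2$truth)
  # adding subjects must not disturb earlier subjects' draws
  g3 <- generate_cohort(generator_config(n_subjects = 20, seed = 99))
  expect_identical(g3$truth[1:12, ], g1$truth)
})

test_that("generated cohorts satisfy the full contract", {
  g <- generate_cohort(generator_config(n_subjects = 100, seed = 17))
  expect_equal(n_subjects(g$cohort), 100)
  expect_silent(validate_cohort(g$cohort))
  expect_equal(nrow(g$truth), 100)
  # observation weeks never extend past the event/censoring time
  last <- tapply(g$cohort$longitudinal$time_weeks,
                 g$cohort$longitudinal$subject_id, max)
  et <- setNames(g$cohort$survival$event_time_weeks,
                 g$cohort$survival$subject_id)
  expect_true(all(last <= et[names(last)]))
  # at least one week of follow-up for everyone
  expect_true(all(et >= 1))
  # likert rounding produces integers
  gl <- generate_cohort(generator_config(n_subjects = 30, seed = 18,
                                         clamp_to_likert = TRUE))
  expect_true(all(gl$cohort$longitudinal$engagement_days %in% 0:7))
})

test_that("the noiseless limit reproduces the true trajectory exactly", {
  cfg <- generator_config(n_subjects = 25, sigma = 0, alpha = 0,
                          lambda = rep(1e-6, 5), staggered_fraction = 0,
                          D = matrix(c(0.15^2, 0, 0, 0.005^2), 2, 2),
                          seed = 21)
  g <- generate_cohort(cfg)
  long <- g$cohort$longitudinal
  b <- g$truth[match(long$subject_id, g$truth$subject_id), c("b0", "b1")]
  m <- cfg$beta[1] + cfg$beta[2] * long$time_weeks +
    cfg$beta[3] * long$time_weeks^2 + b$b0 + b$b1 * long$time_weeks
  expect_equal(long$engagement_days, m, tolerance = 1e-12)
})

test_that("alpha = 0 decouples dropout from the random effects", {
  g <- generate_cohort(generator_config(n_subjects = 600, alpha = 0,
                                        seed = 23))
  rho <- stats::cor(g$truth$b0, g$truth$true_event_time,
                    method = "spearman")
  expect_lt(abs(rho), 3 / sqrt(600))
})

test_that("alpha < 0 links engagement level to follow-up duration", {
  # compare engagement at a common early window (weeks 0-1), since the
  # population trend declines: subjects observed longer would otherwise
  # average over later, lower values
  g <- generate_cohort(generator_config(n_subjects = 400, seed = 29))
  long <- g$cohort$longitudinal
  early <- long[long$time_weeks <= 1, ]
  mean_y <- tapply(early$engagement_days, early$subject_id, mean)
  et <- setNames(g$cohort$survival$event_time_weeks,
                 g$cohort$survival$subject_id)
  expect_gt(stats::cor(mean_y, et[names(mean_y)]), 0.1)
})

test_that("default conditions put the median dropout near 22 weeks", {
  meds <- vapply(1:20, function(s) {
    g <- generate_cohort(generator_config(seed = 600 + s))
    km_estimate(g$cohort)$median
  }, numeric(1))
  expect_true(all(meds >= 18 & meds <= 26))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(D = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive-definite")
  expect_error(generator_config(lambda = rep(-0.1, 5)), "positive")
  expect_error(generator_config(staggered_fraction = 1.4), "\\[0, 1\\]")
  expect_error(generator_config(knots = c(0, 5, 5, 10, 20, 26)),
               "increasing")
})
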
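toy_joint_params <- function(knots = c(0, 30)) {
  joint_params(beta = c(4.0, -0.13, 0.002),
               D = matrix(c(1.4, -0.03, -0.03, 0.0036), 2, 2),
               sigma2 = 1.2,
               gamma = c(-0.02, -0.1, -0.1, 0.15, 0.11), alpha = -0.25,
               log_lambda = log(rep(0.07, length(knots) - 1)),
               knots = knots)
}

test_that("the conditional subject log-likelihood matches an independent
           hand composition", {
  par <- toy_joint_params(knots = c(0, 4, 30))
  subj <- list(time_weeks = c(0, 1), engagement_days = c(5, 3.5),
               w = c(2, 1, 0, 0, 1), event_time = 2.4, event = 1)
  b <- c(0.6, -0.05)
  # independent composition: Gaussian densities + log h(T) - H(T), with
  # the cumulative hazard from stats::integrate
  m <- function(t) par$beta[1] + par$beta[2] * t + par$beta[3] * t^2 +
    b[1] + b[2] * t
  eta <- sum(par$gamma * subj$w)
  haz <- function(t) exp(par$log_lambda[findInterval(t, par$knots,
                                                     all.inside = TRUE)] +
                           eta + par$alpha * m(t))
  H <- stats::integrate(haz, 0, 2.4, rel.tol = 1e-12)$value
  expected <- sum(dnorm(c(5, 3.5), m(c(0, 1)), sqrt(par$sigma2),
                        log = TRUE)) + log(haz(2.4)) - H
  expect_equal(subject_joint_loglik_given_b(par, subj, b), expected,
               tolerance = 1e-10)
})

test_that("with alpha = 0 the subject log-likelihood separates", {
  par <- toy_joint_params()
  par$alpha <- 0
  subj <- list(time_weeks = c(0, 1, 2), engagement_days = c(5, 4.5, 4),
               w = c(1, 0, 1, 0, 0), event_time = 3, event = 1)
  gauss_part <- function(b) {
    m <- true_trajectory(par$beta, b, subj$time_weeks)
    sum(dnorm(subj$engagement_days, m, sqrt(par$sigma2), log = TRUE))
  }
  b1 <- c(1.2, 0.04)
  b2 <- c(-0.7, -0.01)
  # the survival factor no longer depends on b
  expect_equal(
    subject_joint_loglik_given_b(par, subj, b1) - gauss_part(b1),
    subject_joint_loglik_given_b(par, subj, b2) - gauss_part(b2),
    tolerance = 1e-10)
})

test_that("a censored subject with no records contributes only -H(C)", {
  par <- toy_joint_params()
  subj <- list(time_weeks = numeric(0), engagement_days = numeric(0),
               w = c(0, 1, 0, 0, 0), event_time = 9, event = 0)
  b <- c(0.3, 0.01)
  H <- cumulative_hazard(list(beta = par$beta, alpha = par$alpha,
                              gamma = par$gamma, knots = par$knots,
                              lambda = exp(par$log_lambda)),
                         subj$w, b, 9)
  expect_equal(subject_joint_loglik_given_b(par, subj, b), -H,
               tolerance = 1e-12)
})

test_that("adaptive Gauss-Hermite matches brute-force grid integration", {
  chk <- agh_grid_check()
  expect_equal(chk$agh, chk$oracle, tolerance = 1e-6)
})

test_that("quadrature refinement converges monotonically", {
  g <- small_cohort(n = 25, seed = 89)
  par <- toy_joint_params(knots = c(0, 9, 18, 30))
  ll5 <- joint_marginal_loglik(par, g$cohort, quad_order = 5)
  ll9 <- joint_marginal_loglik(par, g$cohort, quad_order = 9)
  ll15 <- joint_marginal_loglik(par, g$cohort, quad_order = 15)
  expect_lt(abs(ll15 - ll9), abs(ll9 - ll5) + 1e-12)
  expect_lt(abs(ll15 - ll9), 1e-6 * abs(ll15))
})

test_that("the D -> 0 limit collapses onto the zero-random-effect
           likelihood", {
  g <- small_cohort(n = 6, seed = 97)
  des <- build_design(g$cohort)
  par <- toy_joint_params()
  par$D <- diag(c(1e-10, 1e-12))
  ll <- joint_marginal_loglik(par, g$cohort, quad_order = 9)
  direct <- 0
  for (i in 1:6) {
    ii <- which(des$subject == i)
    subj <- list(time_weeks = des$Z[ii, 2],
                 engagement_days = des$y[ii], w = des$W[i, ],
                 event_time = des$event_time[i], event = des$event[i])
    direct <- direct + subject_joint_loglik_given_b(par, subj, c(0, 0))
  }
  expect_equal(ll, direct, tolerance = 1e-6)
})

test_that("marginal likelihood is invariant to subject relabeling", {
  g <- small_cohort(n = 15, seed = 101)
  ch <- g$cohort
  relabel <- setNames(sprintf("Z%03d", rev(seq_len(n_subjects(ch)))),
                      ch$survival$subject_id)
  long2 <- ch$longitudinal
  long2$subject_id <- unname(relabel[long2$subject_id])
  surv2 <- ch$survival
  surv2$subject_id <- unname(relabel[surv2$subject_id])
  ch2 <- linked_cohort(long2, surv2)
  par <- toy_joint_params()
  expect_equal(joint_marginal_loglik(par, ch),
               joint_marginal_loglik(par, ch2), tolerance = 1e-10)
})

test_that("with alpha pinned at zero the model factorizes exactly", {
  g <- small_cohort(n = 80, seed = 103, alpha = 0)
  jf <- fit_joint(g$cohort,
                  control = joint_control(quad_order = 7,
                                          compute_se = FALSE,
                                          fix_alpha = 0))
  lf <- fit_lmm(g$cohort)
  # longitudinal block equals the standalone mixed model
  expect_equal(jf$params$beta, lf$params$beta, tolerance = 2e-3)
  expect_equal(jf$params$sigma2, lf$params$sigma2, tolerance = 1e-2)
  # survival block equals an independent piecewise-exponential
  # proportional-hazards fit (Poisson person-period likelihood)
  des <- build_design(g$cohort)
  kn <- jf$params$knots
  np <- length(kn) - 1
  rows <- list()
  for (i in seq_along(des$event_time)) {
    for (j in seq_len(np)) {
      lo <- kn[j]
      hi <- min(kn[j + 1], des$event_time[i])
      if (hi <= lo) next
      rows[[length(rows) + 1]] <- data.frame(
        piece = factor(j, levels = seq_len(np)),
        exposure = hi - lo,
        d = as.numeric(des$event[i] == 1 &
                         des$event_time[i] <= kn[j + 1] &
                         des$event_time[i] > lo),
        age = des$W[i, 1], male = des$W[i, 2],
        r_b = des$W[i, 3], r_h = des$W[i, 4], r_o = des$W[i, 5])
    }
  }
  pp <- do.call(rbind, rows)
  pexp_fit <- stats::glm(
    d ~ 0 + piece + age + male + r_b + r_h + r_o +
      offset(log(exposure)), family = stats::poisson, data = pp)
  co <- coef(pexp_fit)
  expect_equal(unname(jf$params$gamma),
               unname(co[c("age", "male", "r_b", "r_h", "r_o")]),
               tolerance = 2e-3)
  expect_equal(unname(jf$params$log_lambda),
               unname(co[paste0("piece", seq_len(np))]),
               tolerance = 2e-3)
})

test_that("free estimation on decoupled data recovers the factorized
           solution", {
  fits <- decoupling_fits()
  jf <- fits$jf
  lf <- fits$lf
  expect_true(jf$converged)
  # alpha indistinguishable from zero
  expect_lt(abs(jf$params$alpha), 3 * jf$se[["alpha"]])
  # joint and naive longitudinal estimates agree within half a joint SE
  dev <- abs(jf$params$beta - lf$params$beta) /
    jf$se[c("beta0", "beta1", "beta2")]
  expect_true(all(dev < 0.5))
})

test_that("hazard-ratio helpers reproduce the published arithmetic", {
  expect_equal(round(hazard_ratio(-0.26), 2), 0.77)
  expect_equal(round(percent_risk_change(-0.26)), 23)
  expect_identical(hazard_ratio(0), 1)
  expect_error(hazard_ratio(NA_real_))
})

test_that("mean-trajectory predictions reproduce the published six-month
           values", {
  est <- focus_reference_estimates()
  pj <- predict_mean_trajectory(est$joint$beta, 26)
  pn <- predict_mean_trajectory(est$naive$beta, 26)
  expect_equal(round(pj$estimate, 1), 1.8)
  expect_equal(round(pn$estimate, 1), 2.9)
  # intercepts are returned exactly at t = 0
  expect_equal(predict_mean_trajectory(est$joint$beta, 0)$estimate, 4.05)
  expect_error(predict_mean_trajectory(est$joint$beta, -3), ">= 0")
})

test_that("fitted trajectory predictions carry delta-method errors", {
  g <- small_cohort(n = 60, seed = 109)
  jf <- fit_joint(g$cohort, control = joint_control(quad_order = 5))
  pr <- predict_mean_trajectory(jf, c(0, 10, 26))
  expect_true(all(is.finite(pr$se)) && all(pr$se > 0))
  expect_equal(pr$estimate[1], jf$params$beta[1])
  # pointwise uncertainty grows toward the extrapolation end
  expect_gt(pr$se[3], pr$se[1])
})

test_that("estimated association is negative in nearly all informative-
           dropout replicates", {
  reps <- mnar_replicates()
  expect_gte(mean(reps$alpha < 0), 0.95)
  expect_gte(mean(reps$converged), 0.95)
})
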
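# Synthetic cohort generator: draws engagement trajectories and dropout
# times from the exact shared-parameter mechanism, so every estimation
# stage can be tested against known ground truth.
#
# Longitudinal law:  y_i(t) = m_i(t) + eps,  m_i(t) = b0 + b1*t added to a
# quadratic fixed trend.  Dropout hazard:
# h_i(t) = lambda_k * exp(gamma'w_i + alpha * m_i(t)) with a
# piecewise-constant baseline, so low current engagement raises the
# dropout hazard when alpha < 0 — engagement data are missing not at
# random by construction.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of the FOCUS mHealth engagement cohort:
#' 342 subjects followed weekly for up to 26 weeks, engagement starting
#' near 4 days/week and declining curvilinearly, an engagement-dropout
#' association of \eqn{\alpha = -0.26} per day/week, baseline-hazard rates
#' calibrated so the Kaplan-Meier median dropout is about 22 weeks, and a
#' fraction of subjects with shortened follow-up from staggered
#' enrollment.
#'
#' @param n_subjects number of subjects.
#' @param beta fixed effects `(beta0, beta1, beta2)` of the quadratic
#'   engagement trend (days/week, days/week per week, per week^2).
#' @param D 2x2 positive-definite covariance of the random intercept and
#'   slope.
#' @param sigma residual standard deviation (days/week); `0` gives
#'   noiseless trajectories.
#' @param gamma baseline hazard coefficients for
#'   `(age_centered, male, race_black, race_hispanic, race_other)`.
#' @param alpha association: log hazard ratio of dropout per day/week of
#'   current error-free engagement.
#' @param knots baseline-hazard knot grid `0 = s_0 < ... < s_K`; the last
#'   rate extends beyond `s_K`.
#' @param lambda `K` piecewise-constant baseline rates (per week), one per
#'   knot interval.
#' @param admin_censor_max administrative censoring time (weeks).
#' @param staggered_fraction proportion of subjects whose follow-up is
#'   shortened (censoring drawn uniformly on `[4, admin_censor_max]`),
#'   emulating late enrollment.
#' @param covariate_model list with `age_mean`, `age_sd`, `p_male`, and
#'   `race_probs` (named probabilities for white/black/hispanic/other).
#' @param clamp_to_likert if `TRUE`, observed engagement is rounded to
#'   integers 0..7 (the recorded outcome is days-per-week); if `FALSE`
#'   (default) it is only clamped to `[0, 7]`, which keeps the Gaussian
#'   measurement model exact for estimation tests.
#' @param seed integer seed; each subject consumes an independent
#'   substream derived from it, so earlier subjects' draws do not change
#'   when `n_subjects` changes.
#' @return a validated object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 342,
                             beta = c(4.05, -0.14, 0.0021),
                             D = matrix(c(1.5^2, -0.2 * 1.5 * 0.05,
                                          -0.2 * 1.5 * 0.05, 0.05^2), 2, 2),
                             sigma = 0.5,
                             gamma = c(-0.021, -0.10, -0.097, 0.15, 0.11),
                             alpha = -0.26,
                             knots = seq(0, 26, length.out = 6),
                             lambda = rep(0.071, 5),
                             admin_censor_max = 26,
                             staggered_fraction = 0.2,
                             covariate_model = list(
                               age_mean = 35, age_sd = 11, p_male = 0.623,
                               race_probs = c(white = 0.50, black = 0.252,
                                              hispanic = 0.108,
                                              other = 0.14)),
                             clamp_to_likert = FALSE,
                             seed = 1L) {
  cfg <- structure(list(n_subjects = as.integer(n_subjects), beta = beta,
                        D = D, sigma = sigma, gamma = gamma, alpha = alpha,
                        knots = knots, lambda = lambda,
                        admin_censor_max = admin_censor_max,
                        staggered_fraction = staggered_fraction,
                        covariate_model = covariate_model,
                        clamp_to_likert = isTRUE(clamp_to_likert),
                        seed = as.integer(seed)),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (length(cfg$beta) != 3L) stop("beta must have length 3", call. = FALSE)
  check_pd2(cfg$D)
  if (cfg$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (length(cfg$gamma) != 5L) stop("gamma must have length 5",
                                    call. = FALSE)
  k <- cfg$knots
  if (length(k) < 2L || k[1] != 0 || any(diff(k) <= 0))
    stop("knots must be strictly increasing and start at 0", call. = FALSE)
  if (length(cfg$lambda) != length(k) - 1L || any(cfg$lambda <= 0))
    stop("lambda must hold one positive rate per knot interval",
         call. = FALSE)
  if (cfg$admin_censor_max <= 0)
    stop("admin_censor_max must be > 0", call. = FALSE)
  if (cfg$staggered_fraction < 0 || cfg$staggered_fraction > 1)
    stop("staggered_fraction must lie in [0, 1]", call. = FALSE)
  rp <- cfg$covariate_model$race_probs
  if (abs(sum(rp) - 1) > 1e-8 || any(rp < 0))
    stop("race_probs must be nonnegative and sum to 1", call. = FALSE)
  invisible(cfg)
}

#' Error-free engagement trajectory
#'
#' Evaluates \eqn{m_i(t) = \beta_0 + \beta_1 t + \beta_2 t^2 + b_{0i} +
#' b_{1i} t}, the subject's true engagement level with the measurement
#' error removed.  This is the quantity that enters the dropout hazard as
#' a time-varying covariate.
#'
#' @param beta fixed effects `(beta0, beta1, beta2)`.
#' @param b subject random effects `(b0, b1)`.
#' @param t time(s) in weeks, `>= 0`; vectorized.
#' @return `m_i(t)` in days/week (unbounded; the model is linear-Gaussian).
#' @examples
#' true_trajectory(c(4.05, -0.14, 0.0021), c(0, 0), 26)
#' @export
true_trajectory <- function(beta, b, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  beta[1] + beta[2] * t + beta[3] * t^2 + b[1] + b[2] * t
}

# per-piece decomposition of [0, t] over the knot grid, extending the last
# rate beyond the final knot
hazard_pieces <- function(knots, lambda, t) {
  lo <- knots[-length(knots)]
  hi <- knots[-1]
  if (t > knots[length(knots)]) {
    lo <- c(lo, knots[length(knots)])
    hi <- c(hi, t)
    lambda <- c(lambda, lambda[length(lambda)])
  }
  keep <- lo < t
  list(lo = lo[keep], hi = pmin(hi[keep], t), lambda = lambda[keep])
}

#' Cumulative dropout hazard under the generating mechanism
#'
#' Integrates \eqn{h_i(s) = \lambda_k \exp\{\gamma'w_i + \alpha m_i(s)\}}
#' from 0 to `t`.  Because \eqn{\exp\{\alpha m_i(s)\}} is the exponential
#' of a quadratic in `s`, each baseline piece is integrated by adaptive
#' Gauss-Legendre quadrature (absolute tolerance `1e-10`).
#'
#' @param config a `generator_config`.
#' @param w hazard covariate row
#'   `(age_centered, male, race_black, race_hispanic, race_other)`.
#' @param b random effects `(b0, b1)`.
#' @param t time in weeks, `>= 0`.
#' @return \eqn{H_i(t) \ge 0}, nondecreasing in `t`, with `H(0) = 0`.
#' @export
cumulative_hazard <- function(config, w, b, t) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  if (t == 0) return(0)
  pc <- hazard_pieces(config$knots, config$lambda, t)
  a0 <- config$alpha * (config$beta[1] + b[1])
  a1 <- config$alpha * (config$beta[2] + b[2])
  a2 <- config$alpha * config$beta[3]
  base <- exp(sum(config$gamma * w))
  tot <- 0
  for (j in seq_along(pc$lo))
    tot <- tot + pc$lambda[j] *
      exp_quad_integral(a0, a1, a2, pc$lo[j], pc$hi[j])
  base * tot
}

#' Sample a dropout time by inverse-transform sampling
#'
#' Draws `E ~ Exponential(1)` (or uses a supplied value) and solves
#' `H_i(T) = E` for `T` by bracketed root finding on the cumulative
#' hazard.  Subjects whose cumulative hazard never reaches `E` within the
#' numerical horizon never drop out and are returned as `Inf`.
#'
#' @param config a `generator_config`.
#' @param w hazard covariate row (see [cumulative_hazard()]).
#' @param b random effects `(b0, b1)`.
#' @param E optional unit-exponential draw; by default drawn from the
#'   current RNG stream.
#' @param horizon numerical support bound in weeks (default
#'   `max(200, 8 * admin_censor_max)`).
#' @return dropout time in weeks, or `Inf`.
#' @export
sample_event_time <- function(config, w, b, E = NULL, horizon = NULL) {
  if (is.null(E)) E <- stats::rexp(1)
  if (is.null(horizon)) horizon <- max(200, 8 * config$admin_censor_max)
  H <- function(t) cumulative_hazard(config, w, b, t)
  if (H(horizon) < E) return(Inf)
  root <- stats::uniroot(function(t) H(t) - E, lower = 0, upper = horizon,
                         tol = 1e-9, maxiter = 200L)
  if (abs(root$f.root) > 1e-4)
    stop("event-time root finding did not converge (|H(T)-E| = ",
         format(root$f.root), ")", call. = FALSE)
  root$root
}

draw_covariates <- function(cm) {
  age <- stats::rnorm(1, cm$age_mean, cm$age_sd)
  male <- as.numeric(stats::runif(1) < cm$p_male)
  race <- sample(names(cm$race_probs), 1, prob = cm$race_probs)
  list(age = age, male = male, race = race)
}

#' Generate a synthetic linked cohort with known ground truth
#'
#' Per subject: draws baseline covariates and random effects, samples the
#' true dropout time from the engagement-linked hazard, samples an
#' administrative censoring time (`admin_censor_max`, shortened uniformly
#' on `[4, admin_censor_max]` for the staggered fraction), and records
#' weekly engagement `y = m_i(t) + eps` at integer weeks up to the
#' observed event/censoring time, clamped to `[0, 7]`.  Subjects with
#' less than one week of follow-up are redrawn, mirroring a cohort
#' restricted to participants who used the intervention for at least one
#' week.  Each subject consumes a seed substream indexed by subject
#' counter, so cohorts of different sizes share their first subjects.
#'
#' @param config a `generator_config`.
#' @return list with `cohort` (a [linked_cohort()]) and `truth` (a data
#'   frame with per-subject `b0`, `b1`, `true_event_time`, `censor_time`,
#'   and drawn covariates).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  n <- config$n_subjects
  Lc <- t(chol(config$D))
  cm <- config$covariate_model
  ids <- sprintf("S%04d", seq_len(n))
  surv_rows <- vector("list", n)
  long_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((config$seed + 7919L * i) %% 2147483629L)
    for (attempt in 1:100) {
      cov <- draw_covariates(cm)
      w <- c(cov$age - cm$age_mean, cov$male,
             as.numeric(cov$race == "black"),
             as.numeric(cov$race == "hispanic"),
             as.numeric(cov$race == "other"))
      b <- as.numeric(Lc %*% stats::rnorm(2))
      T_true <- sample_event_time(config, w, b)
      C <- if (stats::runif(1) < config$staggered_fraction)
        stats::runif(1, 4, config$admin_censor_max)
      else config$admin_censor_max
      event_time <- min(T_true, C)
      if (event_time >= 1) break
      if (attempt == 100)
        stop("could not generate a subject with >= 1 week of follow-up; ",
             "check hazard configuration", call. = FALSE)
    }
    event <- as.numeric(T_true <= C)
    nw <- floor(event_time) - (event_time == floor(event_time))
    weeks <- 0:nw
    m <- true_trajectory(config$beta, b, weeks)
    y <- m + if (config$sigma > 0) stats::rnorm(length(weeks), 0,
                                                config$sigma) else 0
    if (config$clamp_to_likert) y <- round(y)
    y <- pmin(pmax(y, 0), 7)
    long_rows[[i]] <- data.frame(subject_id = ids[i], time_weeks = weeks,
                                 engagement_days = y,
                                 stringsAsFactors = FALSE)
    surv_rows[[i]] <- data.frame(subject_id = ids[i],
                                 event_time_weeks = event_time,
                                 event = event, age_years = cov$age,
                                 male = cov$male, race = cov$race,
                                 stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(subject_id = ids[i], b0 = b[1], b1 = b[2],
                                  true_event_time = T_true, censor_time = C,
                                  age_years = cov$age, male = cov$male,
                                  race = cov$race, stringsAsFactors = FALSE)
  }
  cohort <- linked_cohort(do.call(rbind, long_rows),
                          do.call(rbind, surv_rows))
  list(cohort = cohort, truth = do.call(rbind, truth_rows))
}
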
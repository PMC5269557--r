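# Fixtures are built in code: small hand-written cohorts plus cached
# simulation results shared across test files.

# two-subject fixture: subject A observed at weeks 0,1,2 with engagement
# 5,4,3 and dropout at week 3; subject B censored at week 2.5
two_subject_cohort <- function() {
  linked_cohort(
    data.frame(subject_id = c("A", "A", "A", "B", "B"),
               time_weeks = c(0, 1, 2, 0, 1),
               engagement_days = c(5, 4, 3, 6, 5.5)),
    data.frame(subject_id = c("A", "B"),
               event_time_weeks = c(3, 2.5), event = c(1, 0),
               age_years = c(30, 42), male = c(1, 0),
               race = c("white", "black")))
}

# small generated cohort for estimation smoke tests
small_cohort <- function(n = 60, seed = 7, ...) {
  generate_cohort(generator_config(n_subjects = n, seed = seed, ...))
}

# session-level cache so expensive simulation studies run once and are
# shared between property and acceptance tests
.sim_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- compute()
  .sim_cache[[key]]
}

# adaptive Gauss-Hermite marginal likelihood versus a brute-force
# 201 x 201 grid integration over +-8 prior SDs, on a tiny cohort
agh_grid_check <- function(seed = 83) {
  cache_get(paste0("agh_grid_", seed), function() {
    g <- small_cohort(n = 2, seed = seed)
    des <- build_design(g$cohort)
    par <- joint_params(beta = c(4.0, -0.13, 0.002),
                        D = matrix(c(1.4, -0.03, -0.03, 0.0036), 2, 2),
                        sigma2 = 1.2,
                        gamma = c(-0.02, -0.1, -0.1, 0.15, 0.11),
                        alpha = -0.25, log_lambda = log(0.07),
                        knots = c(0, 30))
    Di <- solve(par$D)
    ld <- determinant(par$D)$modulus[1]
    sd0 <- sqrt(par$D[1, 1])
    sd1 <- sqrt(par$D[2, 2])
    oracle <- 0
    for (i in 1:2) {
      ii <- which(des$subject == i)
      subj <- list(time_weeks = des$Z[ii, 2],
                   engagement_days = des$y[ii], w = des$W[i, ],
                   event_time = des$event_time[i],
                   event = des$event[i])
      b0g <- seq(-8 * sd0, 8 * sd0, length.out = 201)
      b1g <- seq(-8 * sd1, 8 * sd1, length.out = 201)
      lv <- matrix(0, 201, 201)
      for (a in seq_along(b0g)) {
        for (bb in seq_along(b1g)) {
          bvec <- c(b0g[a], b1g[bb])
          lv[a, bb] <- subject_joint_loglik_given_b(par, subj, bvec) -
            log(2 * pi) - 0.5 * ld - 0.5 * sum(bvec * (Di %*% bvec))
        }
      }
      mx <- max(lv)
      oracle <- oracle + mx + log(sum(exp(lv - mx))) +
        log(b0g[2] - b0g[1]) + log(b1g[2] - b1g[1])
    }
    list(agh = joint_marginal_loglik(par, g$cohort, quad_order = 9),
         oracle = oracle)
  })
}

# joint and naive fits on a cohort generated WITHOUT any
# engagement-dropout association (alpha = 0)
decoupling_fits <- function(seed = 107, n = 150) {
  cache_get(paste0("decouple_", seed, "_", n), function() {
    g <- small_cohort(n = n, seed = seed, alpha = 0)
    list(jf = fit_joint(g$cohort,
                        control = joint_control(quad_order = 7)),
         lf = fit_lmm(g$cohort))
  })
}

# replicated joint-vs-naive study under the default informative-dropout
# conditions (true alpha = -0.26); returns one row per replicate
mnar_replicates <- function(n_reps = 50, n_subjects = 300,
                            seed_base = 5000) {
  key <- paste("mnar", n_reps, n_subjects, seed_base, sep = "_")
  cache_get(key, function() {
    out <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      g <- generate_cohort(generator_config(n_subjects = n_subjects,
                                            seed = seed_base + r))
      jf <- fit_joint(g$cohort, control = joint_control(quad_order = 5))
      lf <- jf$lmm_init
      pj <- predict_mean_trajectory(jf, c(0, 26))$estimate
      pn <- predict_mean_trajectory(lf, c(0, 26))$estimate
      out[[r]] <- data.frame(
        rep = r, alpha = jf$params$alpha, se_alpha = jf$se[["alpha"]],
        converged = jf$converged,
        joint_b0 = jf$params$beta[1], joint_b1 = jf$params$beta[2],
        naive_b0 = lf$params$beta[1], naive_b1 = lf$params$beta[2],
        div_start = pn[1] - pj[1], div_end = pn[2] - pj[2])
    }
    do.call(rbind, out)
  })
}
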
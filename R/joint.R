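# Shared-parameter joint model: the dropout hazard depends on the
# subject's current error-free engagement m_i(t), and the same bivariate
# random effects (b0, b1) drive both the engagement trajectory and the
# hazard.  The marginal likelihood integrates the per-subject joint
# density over b by adaptive Gauss-Hermite quadrature (nodes recentered
# at each subject's posterior mode and rescaled by posterior curvature).
#
# Parameterization for optimization is fully unconstrained: log-Cholesky
# factor of D, log sigma^2, log baseline rates.  The analytic score is
# the posterior-expected complete-data score evaluated with the same
# quadrature nodes as the log-likelihood.

#' Parameters of the joint model
#'
#' @param beta fixed effects `(beta0, beta1, beta2)` of the quadratic
#'   engagement trend.
#' @param D 2x2 positive-definite random-effects covariance.
#' @param sigma2 residual variance, `> 0`.
#' @param gamma hazard coefficients for
#'   `(age_centered, male, race_black, race_hispanic, race_other)`.
#' @param alpha association: log hazard ratio per day/week of current
#'   error-free engagement.
#' @param log_lambda log piecewise-constant baseline hazards, one per
#'   knot interval.
#' @param knots baseline-hazard knot grid `0 = s_0 < ... < s_K`.
#' @return a validated list of class `joint_params`.
#' @export
joint_params <- function(beta, D, sigma2, gamma, alpha, log_lambda, knots) {
  if (length(beta) != 3L) stop("beta must have length 3", call. = FALSE)
  check_pd2(D)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  if (length(gamma) != 5L) stop("gamma must have length 5", call. = FALSE)
  if (length(knots) < 2L || knots[1] != 0 || any(diff(knots) <= 0))
    stop("knots must be strictly increasing and start at 0", call. = FALSE)
  if (length(log_lambda) != length(knots) - 1L)
    stop("log_lambda must hold one value per knot interval", call. = FALSE)
  structure(list(beta = as.numeric(beta), D = D,
                 sigma2 = as.numeric(sigma2), gamma = as.numeric(gamma),
                 alpha = as.numeric(alpha),
                 log_lambda = as.numeric(log_lambda),
                 knots = as.numeric(knots)),
            class = "joint_params")
}

#' Joint log-likelihood of one subject given its random effects
#'
#' Evaluates \eqn{\log[\prod_j N(y_{ij}; m_i(t_{ij}), \sigma^2) \times
#' h_i(T_i)^{\delta_i} \exp\{-H_i(T_i)\}]} where the hazard is
#' \eqn{\lambda_k \exp\{\gamma'w_i + \alpha m_i(t)\}} and the cumulative
#' hazard is computed by adaptive per-piece quadrature (the same integral
#' contract as [cumulative_hazard()]).  A subject with no longitudinal
#' records and `event = 0` contributes only the pure censoring term
#' `-H_i(C_i)`.
#'
#' @param params a [joint_params()].
#' @param subject list with `time_weeks`, `engagement_days` (both may be
#'   empty), `w` (5-vector of hazard covariates), `event_time`, `event`.
#' @param b random effects `(b0, b1)`.
#' @return the conditional joint log-likelihood (finite for valid input).
#' @export
subject_joint_loglik_given_b <- function(params, subject, b) {
  ll <- 0
  if (length(subject$time_weeks)) {
    m <- true_trajectory(params$beta, b, subject$time_weeks)
    ll <- ll + sum(stats::dnorm(subject$engagement_days, m,
                                sqrt(params$sigma2), log = TRUE))
  }
  lambda <- exp(params$log_lambda)
  Tt <- subject$event_time
  H <- cumulative_hazard(list(beta = params$beta, alpha = params$alpha,
                              gamma = params$gamma, knots = params$knots,
                              lambda = lambda),
                         subject$w, b, Tt)
  if (subject$event == 1) {
    kT <- min(findInterval(Tt, params$knots, all.inside = TRUE),
              length(lambda))
    mT <- true_trajectory(params$beta, b, Tt)
    ll <- ll + params$log_lambda[kT] + sum(params$gamma * subject$w) +
      params$alpha * mT
  }
  ll - H
}

#' Control settings for joint-model estimation
#'
#' @param quad_order adaptive Gauss-Hermite points per random-effect
#'   dimension (default 9; the 2-D rule has `quad_order^2` nodes).
#' @param gl_points Gauss-Legendre points per baseline piece for the
#'   within-subject cumulative-hazard integral.
#' @param maxit,reltol BFGS iteration cap and relative-tolerance for the
#'   marginal log-likelihood.
#' @param grad_tol scaled gradient-norm threshold declared as converged.
#' @param inner_maxit,inner_tol Newton settings for the per-subject
#'   posterior modes.
#' @param compute_se if `FALSE`, skip the observed-information standard
#'   errors (useful in simulation loops that only need point estimates).
#' @param fix_alpha optional value at which to pin the association
#'   parameter (e.g. `0` for a profile fit in which the longitudinal and
#'   survival submodels factorize exactly).
#' @return list of class `joint_control`.
#' @export
joint_control <- function(quad_order = 9, gl_points = 7, maxit = 400,
                          reltol = 1e-10, grad_tol = 1e-4,
                          inner_maxit = 50, inner_tol = 1e-9,
                          compute_se = TRUE, fix_alpha = NULL) {
  structure(list(quad_order = as.integer(quad_order),
                 gl_points = as.integer(gl_points),
                 maxit = as.integer(maxit), reltol = reltol,
                 grad_tol = grad_tol, inner_maxit = as.integer(inner_maxit),
                 inner_tol = inner_tol, compute_se = isTRUE(compute_se),
                 fix_alpha = fix_alpha),
            class = "joint_control")
}

# ---- precomputed per-cohort structures ---------------------------------

build_joint_data <- function(design, knots, gl_points) {
  n <- length(design$event_time)
  subj <- design$subject
  tt <- design$Z[, 2]
  y <- design$y
  agg <- function(v) {
    out <- numeric(n)
    rs <- rowsum(v, subj)
    out[as.integer(rownames(rs))] <- rs
    out
  }
  Tn <- design$event_time
  np <- length(knots) - 1L
  glu <- pracma::gaussLegendre(gl_points, 0, 1)
  s_g <- wt_g <- numeric(0)
  piece_g <- subj_g <- integer(0)
  lo <- knots[-length(knots)]
  hi <- knots[-1]
  add_piece <- function(j, l, sel) {
    u <- pmin(hi_ext[j], Tn[sel])
    width <- u - l
    for (q in seq_len(gl_points)) {
      s_g <<- c(s_g, l + width * glu$x[q])
      wt_g <<- c(wt_g, width * glu$w[q])
      piece_g <<- c(piece_g, rep(min(j, np), length(sel)))
      subj_g <<- c(subj_g, sel)
    }
  }
  hi_ext <- c(hi, Inf)
  lo_ext <- c(lo, knots[length(knots)])
  for (j in seq_len(np + 1L)) {
    sel <- which(Tn > lo_ext[j])
    if (!length(sel)) next
    if (j > np && !any(Tn > lo_ext[j])) next
    add_piece(j, lo_ext[j], sel)
  }
  kT <- pmin(findInterval(Tn, knots, all.inside = TRUE), np)
  list(n = n, np = np, knots = knots,
       Sn = agg(rep(1, length(y))), St = agg(tt), St2 = agg(tt^2),
       St3 = agg(tt^3), St4 = agg(tt^4),
       Sy = agg(y), Sty = agg(tt * y), St2y = agg(tt^2 * y),
       Syy = agg(y^2),
       W = design$W, Tn = Tn, delta = design$event, kT = kT,
       s_g = s_g, s2_g = s_g^2, wt_g = wt_g, piece_g = piece_g,
       subj_g = subj_g,
       subject_id = design$subject_id, age_center = design$age_center)
}

rowsum_full <- function(v, group, n) {
  out <- numeric(n)
  rs <- rowsum(v, group)
  out[as.integer(rownames(rs))] <- rs
  out
}

# conditional pieces of the joint log-density at vectors b0, b1 (one pair
# per subject); returns g and, when wanted, hazard summaries
joint_g_eval <- function(b0, b1, comp, jd, want = c("g", "grad", "score")) {
  want <- match.arg(want)
  ub <- comp$cg * exp(comp$alpha_b1s * b1[jd$subj_g])
  P0 <- rowsum_full(ub, jd$subj_g, jd$n)
  P1 <- rowsum_full(ub * jd$s_g, jd$subj_g, jd$n)
  Hfac <- exp(comp$eta + comp$alpha * b0)
  H <- Hfac * P0
  HP1 <- Hfac * P1
  Q <- comp$Srr - 2 * (b0 * comp$Szr0 + b1 * comp$Szr1) +
    b0^2 * jd$Sn + 2 * b0 * b1 * jd$St + b1^2 * jd$St2
  mT <- comp$fT + b0 + b1 * jd$Tn
  g <- -jd$Sn / 2 * log(2 * pi * comp$sigma2) - Q / (2 * comp$sigma2) +
    jd$delta * (comp$loglamT + comp$eta + comp$alpha * mT) - H -
    log(2 * pi) - 0.5 * comp$logdetD -
    0.5 * (comp$Di11 * b0^2 + 2 * comp$Di12 * b0 * b1 +
             comp$Di22 * b1^2)
  out <- list(g = g, H = H, HP1 = HP1, Q = Q, mT = mT)
  if (want == "g") return(out)
  P2 <- rowsum_full(ub * jd$s2_g, jd$subj_g, jd$n)
  HP2 <- Hfac * P2
  out$HP2 <- HP2
  if (want == "grad") {
    out$g0 <- (comp$Szr0 - (jd$Sn * b0 + jd$St * b1)) / comp$sigma2 +
      jd$delta * comp$alpha - comp$alpha * H -
      (comp$Di11 * b0 + comp$Di12 * b1)
    out$g1 <- (comp$Szr1 - (jd$St * b0 + jd$St2 * b1)) / comp$sigma2 +
      jd$delta * comp$alpha * jd$Tn - comp$alpha * HP1 -
      (comp$Di12 * b0 + comp$Di22 * b1)
    out$h00 <- -jd$Sn / comp$sigma2 - comp$alpha^2 * H - comp$Di11
    out$h01 <- -jd$St / comp$sigma2 - comp$alpha^2 * HP1 - comp$Di12
    out$h11 <- -jd$St2 / comp$sigma2 - comp$alpha^2 * HP2 - comp$Di22
    return(out)
  }
  # score pass: per-piece hazard mass and f-weighted mass
  out$HPf <- Hfac * rowsum_full(ub * comp$fg, jd$subj_g, jd$n)
  grp <- jd$subj_g + jd$n * (jd$piece_g - 1L)
  HPp <- matrix(rowsum_full(ub, grp, jd$n * jd$np), jd$n, jd$np)
  out$HPp <- HPp * Hfac
  out
}

# unpack theta and precompute beta/gamma-dependent per-subject quantities
joint_components <- function(theta, jd) {
  np <- jd$np
  beta <- theta[1:3]
  thD <- theta[4:6]
  sigma2 <- exp(theta[7])
  gamma <- theta[8:12]
  alpha <- theta[13]
  loglam <- theta[14:(13 + np)]
  D <- theta_to_D(thD)
  Di <- solve(D)
  XtXb1 <- beta[1] * jd$Sn + beta[2] * jd$St + beta[3] * jd$St2
  XtXb2 <- beta[1] * jd$St + beta[2] * jd$St2 + beta[3] * jd$St3
  XtXb3 <- beta[1] * jd$St2 + beta[2] * jd$St3 + beta[3] * jd$St4
  fg <- beta[1] + beta[2] * jd$s_g + beta[3] * jd$s2_g
  list(beta = beta, thD = thD, D = D, Di11 = Di[1, 1], Di12 = Di[1, 2],
       Di22 = Di[2, 2], logdetD = determinant(D)$modulus[1],
       sigma2 = sigma2, gamma = gamma, alpha = alpha, loglam = loglam,
       Srr = jd$Syy - 2 * (beta[1] * jd$Sy + beta[2] * jd$Sty +
                             beta[3] * jd$St2y) +
         beta[1] * XtXb1 + beta[2] * XtXb2 + beta[3] * XtXb3,
       Szr0 = jd$Sy - XtXb1, Szr1 = jd$Sty - XtXb2,
       Szr2 = jd$St2y - XtXb3,
       XtXb1 = XtXb1, XtXb2 = XtXb2, XtXb3 = XtXb3,
       eta = as.numeric(jd$W %*% gamma),
       fT = beta[1] + beta[2] * jd$Tn + beta[3] * jd$Tn^2,
       fg = fg,
       cg = jd$wt_g * exp(loglam[jd$piece_g]) * exp(alpha * fg),
       alpha_b1s = alpha * jd$s_g,
       loglamT = loglam[jd$kT])
}

# posterior modes of b per subject by damped Newton, vectorized across
# subjects; warm-started from `start`
joint_modes <- function(comp, jd, start, ctrl) {
  b0 <- start[, 1]
  b1 <- start[, 2]
  ev <- joint_g_eval(b0, b1, comp, jd, want = "grad")
  for (it in seq_len(ctrl$inner_maxit)) {
    det <- ev$h00 * ev$h11 - ev$h01^2
    bad <- det <= 1e-12 | ev$h00 >= 0
    det[bad] <- 1
    st0 <- -(ev$h11 * ev$g0 - ev$h01 * ev$g1) / det
    st1 <- -(-ev$h01 * ev$g0 + ev$h00 * ev$g1) / det
    st0[bad] <- ev$g0[bad] * 0.1
    st1[bad] <- ev$g1[bad] * 0.1
    fac <- rep(1, jd$n)
    for (h in 1:12) {
      nb0 <- b0 + fac * st0
      nb1 <- b1 + fac * st1
      nev <- joint_g_eval(nb0, nb1, comp, jd, want = "grad")
      worse <- !is.finite(nev$g) | nev$g < ev$g - 1e-10
      if (!any(worse)) break
      fac[worse] <- fac[worse] / 2
    }
    moved <- max(abs(fac * st0), abs(fac * st1))
    b0 <- nb0
    b1 <- nb1
    ev <- nev
    if (max(abs(ev$g0), abs(ev$g1)) < ctrl$inner_tol || moved < 1e-12)
      break
  }
  list(b0 = b0, b1 = b1, ev = ev)
}

# loglik (+ optional score) of the adaptive-GH marginal likelihood
joint_engine <- function(theta, jd, ctrl, state = NULL,
                         want_score = TRUE) {
  comp <- joint_components(theta, jd)
  n <- jd$n
  start <- if (!is.null(state) && !is.null(state$modes)) state$modes
           else matrix(0, n, 2)
  md <- joint_modes(comp, jd, start, ctrl)
  if (!is.null(state)) state$modes <- cbind(md$b0, md$b1)
  # posterior curvature -> scaling Cholesky
  a <- -md$ev$h00
  c2 <- -md$ev$h01
  d <- -md$ev$h11
  a <- pmax(a, 1e-8)
  d <- pmax(d, 1e-8)
  detA <- pmax(a * d - c2^2, 1e-12)
  C00 <- d / detA
  C01 <- -c2 / detA
  C11 <- a / detA
  l11 <- sqrt(C00)
  l21 <- C01 / l11
  l22 <- sqrt(pmax(C11 - l21^2, 1e-12))

  gh <- pracma::gaussHermite(ctrl$quad_order)
  z1 <- rep(gh$x, times = ctrl$quad_order)
  z2 <- rep(gh$x, each = ctrl$quad_order)
  lw <- log(rep(gh$w, times = ctrl$quad_order)) +
    log(rep(gh$w, each = ctrl$quad_order)) + z1^2 + z2^2
  K <- length(z1)
  s2c <- sqrt(2)

  G <- B0 <- B1 <- H <- HP1 <- Qm <- MT <- matrix(0, n, K)
  HPf <- HP2 <- if (want_score) matrix(0, n, K) else NULL
  HPp <- if (want_score) array(0, c(n, jd$np, K)) else NULL
  for (k in seq_len(K)) {
    b0k <- md$b0 + s2c * l11 * z1[k]
    b1k <- md$b1 + s2c * (l21 * z1[k] + l22 * z2[k])
    ev <- joint_g_eval(b0k, b1k, comp, jd,
                       want = if (want_score) "score" else "g")
    G[, k] <- ev$g
    B0[, k] <- b0k
    B1[, k] <- b1k
    H[, k] <- ev$H
    HP1[, k] <- ev$HP1
    Qm[, k] <- ev$Q
    MT[, k] <- ev$mT
    if (want_score) {
      HPf[, k] <- ev$HPf
      HP2[, k] <- ev$HP2
      HPp[, , k] <- ev$HPp
    }
  }
  M <- sweep(G, 2, lw, `+`)
  rmax <- do.call(pmax, as.data.frame(M))
  li <- rmax + log(rowSums(exp(M - rmax))) + log(2) + log(l11) + log(l22)
  ll <- sum(li)
  out <- list(loglik = ll, loglik_i = li,
              modes = cbind(md$b0, md$b1))
  if (!want_score) return(out)

  om <- exp(M - rmax)
  om <- om / rowSums(om)
  E <- function(X) rowSums(om * X)
  Eb0 <- E(B0); Eb1 <- E(B1)
  EH <- E(H)
  sc <- numeric(length(theta))
  # beta
  sc[1] <- sum((comp$Szr0 - (jd$Sn * Eb0 + jd$St * Eb1)) / comp$sigma2 +
                 comp$alpha * (jd$delta - EH))
  sc[2] <- sum((comp$Szr1 - (jd$St * Eb0 + jd$St2 * Eb1)) / comp$sigma2 +
                 comp$alpha * (jd$delta * jd$Tn - E(HP1)))
  sc[3] <- sum((comp$Szr2 - (jd$St2 * Eb0 + jd$St3 * Eb1)) / comp$sigma2 +
                 comp$alpha * (jd$delta * jd$Tn^2 - E(HP2)))
  # D via log-Cholesky
  Msum <- matrix(c(sum(E(B0^2)), sum(E(B0 * B1)), sum(E(B0 * B1)),
                   sum(E(B1^2))), 2, 2)
  Di <- matrix(c(comp$Di11, comp$Di12, comp$Di12, comp$Di22), 2, 2)
  GD <- 0.5 * (Di %*% Msum %*% Di - n * Di)
  L <- theta_to_chol2(comp$thD)
  dL <- 2 * GD %*% L
  sc[4] <- dL[1, 1] * L[1, 1]
  sc[5] <- dL[2, 1]
  sc[6] <- dL[2, 2] * L[2, 2]
  # log sigma2
  sc[7] <- sum(-jd$Sn / (2 * comp$sigma2) +
                 E(Qm) / (2 * comp$sigma2^2)) * comp$sigma2
  # gamma
  sc[8:12] <- colSums((jd$delta - EH) * jd$W)
  # alpha
  sc[13] <- sum(jd$delta * E(MT) - (E(HPf) + E(H * B0) + E(HP1 * B1)))
  # log lambda
  for (j in seq_len(jd$np))
    sc[13 + j] <- sum(jd$delta * (jd$kT == j)) - sum(E(HPp[, j, ]))
  out$score <- sc
  out
}

#' Marginal log-likelihood of the joint model
#'
#' \eqn{\sum_i \log \int \exp\{\ell_i(b)\}\, dN(b; 0, D)} with
#' \eqn{\ell_i} the conditional joint log-density of
#' [subject_joint_loglik_given_b()] (random-effect terms excluded), the
#' integral computed by adaptive Gauss-Hermite quadrature: nodes centered
#' at each subject's posterior mode and scaled by posterior curvature.
#' Deterministic for a fixed quadrature order.  Underflow is handled in
#' log space.
#'
#' @param params a [joint_params()].
#' @param cohort a `linked_cohort` or [build_design()] list.
#' @param quad_order Gauss-Hermite points per dimension.
#' @param gl_points Gauss-Legendre points per baseline piece.
#' @return the marginal log-likelihood.
#' @export
joint_marginal_loglik <- function(params, cohort, quad_order = 9,
                                  gl_points = 7) {
  design <- if (inherits(cohort, "linked_cohort")) build_design(cohort)
            else cohort
  jd <- build_joint_data(design, params$knots, gl_points)
  theta <- c(params$beta, chol2_to_theta(params$D), log(params$sigma2),
             params$gamma, params$alpha, params$log_lambda)
  ctrl <- joint_control(quad_order = quad_order, gl_points = gl_points)
  res <- joint_engine(theta, jd, ctrl, want_score = FALSE)
  if (!is.finite(res$loglik))
    stop("marginal likelihood overflowed for subject ",
         jd$subject_id[which(!is.finite(res$loglik_i))[1L]], call. = FALSE)
  res$loglik
}

default_knots <- function(event_time, event, K) {
  et <- event_time[event == 1]
  smax <- max(event_time) * (1 + 1e-8)
  kn <- c(0, stats::quantile(et, probs = seq_len(K - 1) / K,
                             names = FALSE), smax)
  if (any(diff(kn) <= 0)) kn <- seq(0, smax, length.out = K + 1)
  kn
}

init_lambda <- function(jd) {
  lam <- numeric(jd$np)
  lo <- jd$knots[-length(jd$knots)]
  hi <- jd$knots[-1]
  for (j in seq_len(jd$np)) {
    expo <- sum(pmax(pmin(jd$Tn, hi[j]) - lo[j], 0))
    dj <- sum(jd$delta[jd$kT == j])
    lam[j] <- max(dj, 0.5) / max(expo, 1e-8)
  }
  lam
}

#' Fit the shared-parameter joint model by maximum likelihood
#'
#' Maximizes the adaptive Gauss-Hermite marginal likelihood over the
#' unconstrained parameter vector (fixed effects, log-Cholesky of `D`,
#' `log sigma2`, hazard coefficients, association, log baseline rates) by
#' BFGS with the analytic posterior-expected score, restarting once on a
#' line-search failure.  Initialization: `beta`, `D`, `sigma2` from
#' [fit_lmm()], `gamma` from [fit_cox()], `alpha = 0`, baseline rates
#' from per-piece event counts over exposure.  Standard errors come from
#' the numerically differentiated observed information of the marginal
#' log-likelihood; empirical-Bayes random effects are the posterior modes
#' at the final parameters.
#'
#' @param cohort a `linked_cohort`.
#' @param init optional [joint_params()] starting values (its knots are
#'   then used).
#' @param control a [joint_control()].
#' @param n_knots number of baseline-hazard pieces (knots at empirical
#'   event-time quantiles).
#' @return object of class `joint_fit`: `params`, `se` (named, for beta,
#'   gamma, alpha), `vcov`, `loglik`, `converged`, `n_iter`, `ranef`,
#'   plus the naive `lmm_init`/`cox_init` fits used for initialization.
#' @export
fit_joint <- function(cohort, init = NULL, control = joint_control(),
                      n_knots = 5) {
  design <- if (inherits(cohort, "linked_cohort")) build_design(cohort)
            else cohort
  if (sum(design$event) < 1)
    stop("at least one observed dropout event is required", call. = FALSE)
  lmm0 <- NULL
  cox0 <- NULL
  if (is.null(init)) {
    lmm0 <- fit_lmm(design)
    cox0 <- fit_cox(data.frame(event_time_weeks = design$event_time,
                               event = design$event),
                    covariates = design$W)
    knots <- default_knots(design$event_time, design$event, n_knots)
    jd <- build_joint_data(design, knots, control$gl_points)
    gamma0 <- ifelse(is.na(cox0$gamma), 0, cox0$gamma)
    theta0 <- c(lmm0$params$beta, chol2_to_theta(lmm0$params$D),
                log(lmm0$params$sigma2), gamma0, 0, log(init_lambda(jd)))
  } else {
    knots <- init$knots
    jd <- build_joint_data(design, knots, control$gl_points)
    theta0 <- c(init$beta, chol2_to_theta(init$D), log(init$sigma2),
                init$gamma, init$alpha, init$log_lambda)
  }
  state <- new.env(parent = emptyenv())
  state$modes <- matrix(0, jd$n, 2)
  cache <- new.env(parent = emptyenv())
  evalfn <- function(th) {
    key <- paste(th, collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    val <- tryCatch(joint_engine(th, jd, control, state = state),
                    error = function(e) NULL)
    if (is.null(val) || !is.finite(val$loglik))
      val <- list(loglik = -1e10, score = rep(0, length(th)))
    cache$key <- key
    cache$val <- val
    val
  }
  free <- rep(TRUE, length(theta0))
  if (!is.null(control$fix_alpha)) {
    theta0[13] <- control$fix_alpha
    free[13] <- FALSE
  }
  expand <- function(thf) { th <- theta0; th[free] <- thf; th }
  negll <- function(thf) -evalfn(expand(thf))$loglik
  neggr <- function(thf) -evalfn(expand(thf))$score[free]
  opt <- stats::optim(theta0[free], negll, neggr, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  n_iter <- opt$counts[["function"]]
  if (opt$convergence != 0) {  # restart once on line-search trouble
    opt <- stats::optim(opt$par, negll, neggr, method = "BFGS",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    n_iter <- n_iter + opt$counts[["function"]]
  }
  theta <- expand(opt$par)
  fin <- joint_engine(theta, jd, control, state = state)
  grad_ok <- max(abs(fin$score[free])) < control$grad_tol *
    max(1, abs(fin$loglik))
  converged <- opt$convergence == 0 && grad_ok
  if (!converged)
    warning("joint model did not meet convergence criteria ",
            "(optim code ", opt$convergence, ", max |score| = ",
            format(max(abs(fin$score)), digits = 3), ")")
  np <- jd$np
  se <- rep(NA_real_, length(theta))
  vcov <- NULL
  if (control$compute_se) {
    Hn <- num_hessian(NULL, theta[free],
                      grad = function(thf)
                        -joint_engine(expand(thf), jd, control,
                                      state = state)$score[free])
    vc <- tryCatch(solve(Hn), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      vcov <- matrix(NA_real_, length(theta), length(theta))
      vcov[free, free] <- vc
      se[free] <- sqrt(diag(vc))
    } else {
      warning("observed information not positive definite; ",
              "standard errors unavailable")
    }
  }
  par_names <- c("beta0", "beta1", "beta2", "chol1", "chol2", "chol3",
                 "log_sigma2", "age", "male", "race_black",
                 "race_hispanic", "race_other", "alpha",
                 paste0("log_lambda", seq_len(np)))
  names(se) <- par_names
  if (!is.null(vcov)) dimnames(vcov) <- list(par_names, par_names)
  params <- joint_params(theta[1:3], theta_to_D(theta[4:6]),
                         exp(theta[7]), theta[8:12], theta[13],
                         theta[14:(13 + np)], knots)
  ranef <- fin$modes
  dimnames(ranef) <- list(jd$subject_id, c("b0", "b1"))
  structure(list(params = params,
                 se = se[c(1:3, 8:13)], se_all = se, vcov = vcov,
                 loglik = fin$loglik, converged = converged,
                 n_iter = as.integer(n_iter), ranef = ranef,
                 lmm_init = lmm0, cox_init = cox0,
                 age_center = jd$age_center),
            class = "joint_fit")
}

#' @export
print.joint_fit <- function(x, ...) {
  cat("Shared-parameter joint model of engagement and time to dropout\n")
  est <- c(x$params$beta, x$params$gamma, x$params$alpha)
  tab <- data.frame(estimate = est,
                    se = x$se,
                    row.names = c("intercept", "week", "week^2",
                                  "age (centered)", "male", "race: black",
                                  "race: hispanic", "race: other",
                                  "engagement association (alpha)"))
  tab$z <- tab$estimate / tab$se
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  print(format(tab, digits = 3))
  cat("hazard ratio per day/week of engagement: exp(alpha) =",
      format(exp(x$params$alpha), digits = 3), "\n")
  cat("log-likelihood =", format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Hazard ratio for a log-hazard coefficient
#'
#' @param coef a finite log hazard-ratio coefficient.
#' @return `exp(coef)`.
#' @seealso [percent_risk_change()]
#' @examples
#' hazard_ratio(-0.26)   # 0.77: risk multiplier per extra day/week
#' @export
hazard_ratio <- function(coef) {
  stopifnot(is.finite(coef))
  exp(coef)
}

#' Percent change in risk for a log-hazard coefficient
#'
#' For a negative coefficient this is the percent *decrease* in risk per
#' unit of the covariate: `100 * (1 - exp(coef))`.
#'
#' @param coef a finite log hazard-ratio coefficient.
#' @return percent change in risk (positive = decreased risk).
#' @examples
#' percent_risk_change(-0.26)  # ~23: a 23% decreased risk of dropout
#' @export
percent_risk_change <- function(coef) {
  stopifnot(is.finite(coef))
  100 * (1 - exp(coef))
}

#' Population-mean engagement trajectory from fitted (or supplied) fixed
#' effects
#'
#' Evaluates \eqn{\hat\beta_0 + \hat\beta_1 t + \hat\beta_2 t^2} (random
#' effects at zero) on a time grid, with delta-method pointwise standard
#' errors from the fixed-effect covariance block when available.
#'
#' @param object a `joint_fit`, an `lmm_fit`, or a numeric vector of
#'   three coefficients `(beta0, beta1, beta2)` for worked examples with
#'   externally supplied estimates.
#' @param times weeks, `>= 0`.
#' @return data frame with `time`, `estimate`, and `se` (`NA` when no
#'   covariance is available).
#' @examples
#' predict_mean_trajectory(c(4.05, -0.14, 0.0021), c(0, 26))
#' @export
predict_mean_trajectory <- function(object, times) {
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (is.numeric(object)) {
    beta <- object
    vb <- NULL
  } else if (inherits(object, "lmm_fit")) {
    beta <- object$params$beta
    vb <- object$vcov_beta
  } else if (inherits(object, "joint_fit")) {
    beta <- object$params$beta
    vb <- if (!is.null(object$vcov)) object$vcov[1:3, 1:3] else NULL
  } else stop("object must be a fit or a coefficient vector",
              call. = FALSE)
  if (length(beta) != 3L) stop("need 3 coefficients", call. = FALSE)
  Xg <- cbind(1, times, times^2)
  est <- as.numeric(Xg %*% beta)
  se <- if (is.null(vb)) rep(NA_real_, length(times))
        else sqrt(rowSums((Xg %*% vb) * Xg))
  data.frame(time = times, estimate = est, se = se)
}
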
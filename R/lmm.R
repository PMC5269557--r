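# Naive longitudinal submodel: linear mixed-effects model with quadratic
# fixed time trend and correlated random intercept + slope, fitted by
# maximum likelihood (not REML) so that the naive-vs-joint comparison is
# an apples-to-apples likelihood contrast.  Dropout is ignored, which is
# exactly the bias the joint model corrects.

#' Parameters of the longitudinal mixed model
#'
#' @param beta fixed effects `(beta0, beta1, beta2)`.
#' @param D 2x2 positive-definite covariance of `(b0, b1)`.
#' @param sigma2 residual variance, `> 0`.
#' @return a validated list of class `lmm_params`.
#' @export
lmm_params <- function(beta, D, sigma2) {
  if (length(beta) != 3L) stop("beta must have length 3", call. = FALSE)
  check_pd2(D)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  structure(list(beta = as.numeric(beta), D = D,
                 sigma2 = as.numeric(sigma2)), class = "lmm_params")
}

# per-subject sufficient pieces shared by the LMM and joint engines
split_design <- function(design) {
  idx <- split(seq_along(design$y), design$subject)
  lapply(idx, function(ii)
    list(X = design$X[ii, , drop = FALSE], Z = design$Z[ii, , drop = FALSE],
         y = design$y[ii]))
}

#' Exact marginal Gaussian log-likelihood of the mixed model
#'
#' Evaluates \eqn{\sum_i \log N(y_i; X_i\beta, Z_i D Z_i' + \sigma^2 I)}
#' with per-subject Cholesky factorizations, ignoring the dropout process.
#'
#' @param params an [lmm_params()] (or list with `beta`, `D`, `sigma2`).
#' @param cohort a `linked_cohort`, or a design list from
#'   [build_design()].
#' @return the marginal log-likelihood (finite for valid parameters).
#' @export
lmm_marginal_loglik <- function(params, cohort) {
  design <- if (inherits(cohort, "linked_cohort")) build_design(cohort)
            else cohort
  subs <- split_design(design)
  ll <- 0
  for (s in subs) {
    V <- s$Z %*% params$D %*% t(s$Z) + diag(params$sigma2, nrow(s$Z))
    R <- tryCatch(chol(V), error = function(e)
      stop("marginal covariance not positive definite", call. = FALSE))
    r <- s$y - as.numeric(s$X %*% params$beta)
    u <- backsolve(R, r, transpose = TRUE)
    ll <- ll - 0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(R))) +
                        sum(u^2))
  }
  ll
}

# per-subject sufficient statistics for the vectorized profile likelihood
lmm_suff <- function(subs) {
  tsum <- function(f) vapply(subs, function(s) sum(f(s$Z[, 2], s$y)),
                             numeric(1))
  list(Sn = tsum(function(t, y) t^0), St = tsum(function(t, y) t),
       St2 = tsum(function(t, y) t^2), St3 = tsum(function(t, y) t^3),
       St4 = tsum(function(t, y) t^4), Sy = tsum(function(t, y) y),
       Sty = tsum(function(t, y) t * y),
       St2y = tsum(function(t, y) t^2 * y),
       Syy = tsum(function(t, y) y^2))
}

# profiled machinery: given variance parameters, beta has a closed GLS
# form; optimization runs over (log-Cholesky D, log sigma2) only.
# Woodbury on the 2x2 random-effects block keeps every quantity a
# vectorized function of per-subject sufficient statistics.
lmm_profile <- function(theta, suff) {
  D <- theta_to_D(theta[1:3])
  sigma2 <- exp(theta[4])
  Di <- solve(D)
  s2 <- sigma2
  a11 <- Di[1, 1] + suff$Sn / s2
  a12 <- Di[1, 2] + suff$St / s2
  a22 <- Di[2, 2] + suff$St2 / s2
  detA <- a11 * a22 - a12^2
  if (any(detA <= 0)) stop("marginal covariance not positive definite")
  # A^{-1} entries
  g11 <- a22 / detA
  g12 <- -a12 / detA
  g22 <- a11 / detA
  # quadratic/bilinear forms u' A^{-1} v for u, v in the Z' columns of
  # X and y:  u1 = (Sn, St), u2 = (St, St2), u3 = (St2, St3),
  # uy = (Sy, Sty)
  bil <- function(p1, p2, q1, q2)
    g11 * p1 * q1 + g12 * (p1 * q2 + p2 * q1) + g22 * p2 * q2
  u <- list(c1 = cbind(suff$Sn, suff$St), c2 = cbind(suff$St, suff$St2),
            c3 = cbind(suff$St2, suff$St3), cy = cbind(suff$Sy, suff$Sty))
  XtX <- matrix(c(sum(suff$Sn), sum(suff$St), sum(suff$St2),
                  sum(suff$St), sum(suff$St2), sum(suff$St3),
                  sum(suff$St2), sum(suff$St3), sum(suff$St4)), 3, 3)
  Xty <- c(sum(suff$Sy), sum(suff$Sty), sum(suff$St2y))
  XtVX <- XtX / s2
  XtVy <- Xty / s2
  for (r in 1:3) {
    for (c in r:3) {
      v <- sum(bil(u[[r]][, 1], u[[r]][, 2], u[[c]][, 1], u[[c]][, 2]))
      XtVX[r, c] <- XtVX[r, c] - v / s2^2
      XtVX[c, r] <- XtVX[r, c]
    }
    XtVy[r] <- XtVy[r] -
      sum(bil(u[[r]][, 1], u[[r]][, 2], u$cy[, 1], u$cy[, 2])) / s2^2
  }
  ytVy <- sum(suff$Syy) / s2 -
    sum(bil(u$cy[, 1], u$cy[, 2], u$cy[, 1], u$cy[, 2])) / s2^2
  beta <- solve(XtVX, XtVy)
  N <- sum(suff$Sn)
  logdet <- sum(suff$Sn * log(s2)) +
    length(suff$Sn) * determinant(D)$modulus[1] + sum(log(detA))
  quad <- ytVy - 2 * sum(beta * XtVy) + sum(beta * (XtVX %*% beta))
  ll <- -0.5 * (logdet + quad + N * log(2 * pi))
  list(loglik = as.numeric(ll), beta = as.numeric(beta), XtVX = XtVX)
}

lmm_init <- function(subs) {
  X <- do.call(rbind, lapply(subs, `[[`, "X"))
  y <- unlist(lapply(subs, `[[`, "y"), use.names = FALSE)
  beta <- stats::lm.fit(X, y)$coefficients
  res <- y - as.numeric(X %*% beta)
  # between-subject spread of per-subject OLS intercept/slope on residuals
  coefs <- t(vapply(subs, function(s) {
    r <- s$y - as.numeric(s$X %*% beta)
    t <- s$Z[, 2]
    if (length(r) >= 2L && stats::var(t) > 0)
      stats::lm.fit(cbind(1, t), r)$coefficients
    else c(mean(r), 0)
  }, numeric(2)))
  D <- stats::cov(coefs)
  if (!all(is.finite(D))) D <- diag(c(1, 0.01))
  # shrink toward a PD diagonal
  D <- D + diag(c(0.05, 0.001))
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) D <- diag(pmax(diag(D), 0.05))
  sigma2 <- max(stats::var(res) / 2, 0.05)
  list(beta = beta, D = D, sigma2 = sigma2)
}

#' Fit the naive linear mixed model by maximum likelihood
#'
#' Maximizes [lmm_marginal_loglik()] over an unconstrained
#' reparameterization (log-Cholesky factor of `D`, `log sigma2`) by
#' quasi-Newton (BFGS), profiling the fixed effects analytically.
#' Initialization is deterministic: pooled OLS for `beta`,
#' between-subject spread of per-subject OLS coefficients for `D`, pooled
#' residual variance for `sigma2`.  Standard errors of the fixed effects
#' come from the observed information \eqn{(\sum_i X_i' V_i^{-1}
#' X_i)^{-1}} at the optimum.
#'
#' @param cohort a `linked_cohort` (or [build_design()] list).
#' @param init optional [lmm_params()] starting values.
#' @return an object of class `lmm_fit`: `params`, `se_beta`, `loglik`,
#'   `converged`, `n_iter`.
#' @export
fit_lmm <- function(cohort, init = NULL) {
  design <- if (inherits(cohort, "linked_cohort")) build_design(cohort)
            else cohort
  subs <- split_design(design)
  if (length(subs) < 2L)
    stop("at least 2 subjects are required", call. = FALSE)
  if (all(vapply(subs, function(s) length(s$y), integer(1)) < 2L))
    stop("random slope not identifiable: every subject has a single ",
         "record", call. = FALSE)
  ini <- if (is.null(init)) lmm_init(subs)
         else list(beta = init$beta, D = init$D, sigma2 = init$sigma2)
  suff <- lmm_suff(subs)
  theta0 <- c(chol2_to_theta(ini$D), log(ini$sigma2))
  # variance parameters are kept on scales compatible with a 0-7
  # days/week outcome; the sigma2 floor keeps the profile numerically
  # sound when noiseless data push the likelihood toward the boundary
  negll <- function(th) {
    if (any(!is.finite(th)) || any(th[c(1, 3)] > log(20)) ||
        any(th[c(1, 3)] < -50) || abs(th[2]) > 20 ||
        th[4] < log(1e-8) || th[4] > log(100)) return(1e10)
    val <- tryCatch(-lmm_profile(th, suff)$loglik,
                    error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }
  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  prof <- lmm_profile(opt$par, suff)
  # recompute the GLS fixed effects by stacked whitened QR: numerically
  # stable even when the fitted variances sit on a degenerate boundary
  D_hat <- theta_to_D(opt$par[1:3])
  s2_hat <- exp(opt$par[4])
  Xw <- vector("list", length(subs))
  yw <- vector("list", length(subs))
  for (k in seq_along(subs)) {
    s <- subs[[k]]
    R <- tryCatch(chol(s$Z %*% D_hat %*% t(s$Z) +
                         diag(s2_hat, nrow(s$Z))),
                  error = function(e) NULL)
    if (is.null(R)) { Xw <- NULL; break }
    Xw[[k]] <- backsolve(R, s$X, transpose = TRUE)
    yw[[k]] <- backsolve(R, s$y, transpose = TRUE)
  }
  if (!is.null(Xw))
    prof$beta <- as.numeric(qr.solve(do.call(rbind, Xw),
                                     unlist(yw, use.names = FALSE)))
  grad <- num_gradient(negll, opt$par)
  converged <- opt$convergence == 0 &&
    max(abs(grad)) < 1e-4 * max(1, abs(prof$loglik))
  vcov_beta <- solve(prof$XtVX)
  se_beta <- sqrt(diag(vcov_beta))
  structure(list(
    params = lmm_params(prof$beta, theta_to_D(opt$par[1:3]),
                        exp(opt$par[4])),
    se_beta = se_beta, vcov_beta = vcov_beta, loglik = prof$loglik,
    converged = converged, n_iter = as.integer(opt$counts[["function"]])),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML), quadratic time trend\n")
  est <- x$params$beta
  tab <- data.frame(estimate = est, se = x$se_beta,
                    row.names = c("intercept", "week", "week^2"))
  print(format(tab, digits = 4))
  cat("sigma^2 =", format(x$params$sigma2, digits = 4),
      "; random-effect SDs =",
      paste(format(sqrt(diag(x$params$D)), digits = 4), collapse = ", "),
      "\nlog-likelihood =", format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}
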
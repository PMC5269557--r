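# Naive time-to-event pieces: Kaplan-Meier product-limit estimation of
# dropout and a Cox proportional-hazards model with baseline covariates
# only.  Breslow tie handling throughout (event times sit on a weekly
# grid, so ties are common); subjects censored at an event time remain at
# risk at that time (left-continuous risk sets).

#' Kaplan-Meier estimate of time to dropout
#'
#' Product-limit estimator \eqn{S(t) = \prod_{t_j \le t} (1 - d_j/r_j)}
#' over distinct observed event times.  The median is the earliest time
#' at which `S` first reaches 0.5 or below (step-function convention, no
#' interpolation); it is `NA` when the curve never reaches 0.5.
#'
#' @param survival a survival data frame (the `survival` component of a
#'   `linked_cohort`: columns `event_time_weeks`, `event`), or a whole
#'   `linked_cohort`.
#' @return an object of class `km_estimate` with `event_times`,
#'   `survival`, `n_risk`, `n_events`, `n_censored`, and `median`.
#' @export
km_estimate <- function(survival) {
  if (inherits(survival, "linked_cohort")) survival <- survival$survival
  time <- survival$event_time_weeks
  status <- survival$event
  if (length(time) < 1L) stop("at least one subject required",
                              call. = FALSE)
  et <- sort(unique(time[status == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_events <- vapply(et, function(t) sum(time == t & status == 1),
                     numeric(1))
  n_censored <- vapply(et, function(t) sum(time == t & status == 0),
                       numeric(1))
  S <- cumprod(1 - n_events / n_risk)
  med <- if (length(S) && any(S <= 0.5)) et[which(S <= 0.5)[1L]] else NA_real_
  structure(list(event_times = et, survival = S, n_risk = n_risk,
                 n_events = n_events, n_censored = n_censored,
                 median = med, n = length(time)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate:", x$n, "subjects,", sum(x$n_events),
      "dropout events\n")
  cat("median time to dropout:",
      if (is.na(x$median)) "not reached"
      else paste(format(x$median, digits = 3), "weeks"), "\n")
  invisible(x)
}

#' Evaluate the Kaplan-Meier curve at arbitrary times
#' @param km a `km_estimate`.
#' @param times times at which to evaluate `S(t)`.
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  vapply(times, function(t) {
    j <- sum(km$event_times <= t)
    if (j == 0L) 1 else km$survival[j]
  }, numeric(1))
}

#' Breslow partial log-likelihood of the Cox model
#'
#' @param gamma coefficient vector.
#' @param survival survival data frame (columns `event_time_weeks`,
#'   `event`) or `linked_cohort`.
#' @param covariates covariate matrix with one row per subject, in the
#'   same order (e.g. `build_design(cohort)$W`).
#' @return the Breslow-approximation partial log-likelihood.
#' @export
cox_partial_loglik <- function(gamma, survival, covariates) {
  if (inherits(survival, "linked_cohort")) survival <- survival$survival
  d <- cox_loglik_engine(gamma, survival$event_time_weeks, survival$event,
                         as.matrix(covariates), derivatives = FALSE)
  d$loglik
}

# loglik (+ optional analytic gradient and information) for Breslow
# partial likelihood
cox_loglik_engine <- function(gamma, time, status, W, derivatives = TRUE) {
  eta <- as.numeric(W %*% gamma)
  ex <- exp(eta)
  et <- sort(unique(time[status == 1]))
  ll <- 0
  p <- length(gamma)
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (t in et) {
    risk <- time >= t
    dead <- time == t & status == 1
    d_j <- sum(dead)
    s0 <- sum(ex[risk])
    ll <- ll + sum(eta[dead]) - d_j * log(s0)
    if (derivatives) {
      Wr <- W[risk, , drop = FALSE]
      s1 <- colSums(Wr * ex[risk])
      xbar <- s1 / s0
      grad <- grad + colSums(W[dead, , drop = FALSE]) - d_j * xbar
      s2 <- crossprod(Wr, Wr * ex[risk])
      info <- info + d_j * (s2 / s0 - tcrossprod(xbar))
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

#' Fit a Cox proportional-hazards model of time to dropout
#'
#' Newton-Raphson on the Breslow partial likelihood with step-halving;
#' convergence when the log-likelihood change falls below `1e-10`.
#' Standard errors come from the inverse observed information; the
#' baseline cumulative hazard is the Breslow estimator at the optimum.
#' Covariate columns with no variation are fixed at coefficient 0 (their
#' standard error is `NA`); collinear columns raise an error.
#'
#' @param survival a `linked_cohort` (covariates built via
#'   [build_design()]), or a survival data frame combined with a
#'   `covariates` matrix.
#' @param covariates optional covariate matrix when `survival` is a data
#'   frame.
#' @return object of class `cox_fit`: `gamma`, `se_gamma`,
#'   `partial_loglik`, `baseline_cumhaz` (data frame `time`, `hazard`),
#'   `converged`, `n_iter`.
#' @export
fit_cox <- function(survival, covariates = NULL) {
  if (inherits(survival, "linked_cohort")) {
    design <- build_design(survival)
    W <- design$W
    time <- design$event_time
    status <- design$event
  } else {
    W <- as.matrix(covariates)
    time <- survival$event_time_weeks
    status <- survival$event
  }
  if (sum(status) < 1) stop("at least one observed event is required",
                            call. = FALSE)
  p <- ncol(W)
  active <- apply(W, 2, function(col) stats::var(col) > 0)
  gamma <- numeric(p)
  converged <- FALSE
  iter <- 0L
  warn_sep <- FALSE
  if (any(active)) {
    Wa <- W[, active, drop = FALSE]
    qrW <- qr(Wa)
    if (qrW$rank < ncol(Wa))
      stop("covariate matrix is rank deficient (collinear columns)",
           call. = FALSE)
    g <- numeric(ncol(Wa))
    cur <- cox_loglik_engine(g, time, status, Wa)
    for (iter in 1:50) {
      step <- tryCatch(solve(cur$info, cur$grad), error = function(e)
        stop("singular information matrix in Cox fit", call. = FALSE))
      h <- 1
      repeat {
        g_new <- g + h * step
        nxt <- cox_loglik_engine(g_new, time, status, Wa)
        if (nxt$loglik >= cur$loglik - 1e-12 || h < 1e-8) break
        h <- h / 2
      }
      delta <- nxt$loglik - cur$loglik
      g <- g_new
      cur <- nxt
      if (abs(delta) < 1e-10) { converged <- TRUE; break }
    }
    if (any(abs(g) > 15)) {
      warning("diverging Cox estimate: possible monotone likelihood ",
              "(perfect separation)")
      converged <- FALSE
      warn_sep <- TRUE
    }
    gamma[active] <- g
  } else {
    cur <- cox_loglik_engine(numeric(0), time, status,
                             W[, FALSE, drop = FALSE])
    converged <- TRUE
  }
  se <- rep(NA_real_, p)
  if (any(active) && !warn_sep) {
    cov_g <- solve(cox_loglik_engine(gamma[active], time, status,
                                     W[, active, drop = FALSE])$info)
    se[active] <- sqrt(diag(cov_g))
  }
  # Breslow baseline cumulative hazard
  ex <- exp(as.numeric(W %*% gamma))
  et <- sort(unique(time[status == 1]))
  dH <- vapply(et, function(t)
    sum(time == t & status == 1) / sum(ex[time >= t]), numeric(1))
  names(gamma) <- names(se) <- colnames(W)
  structure(list(gamma = gamma, se_gamma = se,
                 partial_loglik = cur$loglik,
                 baseline_cumhaz = data.frame(time = et,
                                              hazard = cumsum(dH)),
                 converged = converged, n_iter = iter),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards model (Breslow ties)\n")
  tab <- data.frame(estimate = x$gamma, se = x$se_gamma,
                    hazard_ratio = exp(x$gamma))
  print(format(tab, digits = 4))
  cat("partial log-likelihood =", format(x$partial_loglik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}
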
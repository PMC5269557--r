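# Shared numeric helpers: log-sum-exp, quadrature over baseline-hazard
# pieces, numerical derivatives.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# unit-interval Gauss-Legendre rules, cached at load time
.gl_unit <- new.env(parent = emptyenv())
gl_unit <- function(q) {
  key <- as.character(q)
  if (is.null(.gl_unit[[key]]))
    .gl_unit[[key]] <- pracma::gaussLegendre(q, 0, 1)
  .gl_unit[[key]]
}

# integral of exp(a0 + a1*s + a2*s^2) over [l, u] by adaptive
# Gauss-Legendre: compare orders 7 and 15, bisect until the two agree to
# `tol` (absolute).  The integrand is smooth, so one level almost always
# suffices; recursion guards pathological coefficient scales.
exp_quad_integral <- function(a0, a1, a2, l, u, tol = 1e-10, depth = 0L) {
  if (u <= l) return(0)
  w <- u - l
  g7 <- gl_unit(7)
  g15 <- gl_unit(15)
  f <- function(s) exp(a0 + a1 * s + a2 * s^2)
  i7 <- w * sum(g7$w * f(l + w * g7$x))
  i15 <- w * sum(g15$w * f(l + w * g15$x))
  if (abs(i15 - i7) <= tol || depth >= 25L) return(i15)
  mid <- (l + u) / 2
  exp_quad_integral(a0, a1, a2, l, mid, tol / 2, depth + 1L) +
    exp_quad_integral(a0, a1, a2, mid, u, tol / 2, depth + 1L)
}

# numerical Hessian of f at x by central differences on the gradient when
# `grad` is supplied, else by central second differences of f.
num_hessian <- function(f, x, grad = NULL) {
  p <- length(x)
  h <- pmax(abs(x), 1) * .Machine$double.eps^(1 / 3)
  H <- matrix(0, p, p)
  if (!is.null(grad)) {
    for (j in seq_len(p)) {
      xp <- x; xp[j] <- xp[j] + h[j]
      xm <- x; xm[j] <- xm[j] - h[j]
      H[, j] <- (grad(xp) - grad(xm)) / (2 * h[j])
    }
  } else {
    f0 <- f(x)
    for (j in seq_len(p)) {
      for (k in seq_len(j)) {
        xpp <- x; xpp[j] <- xpp[j] + h[j]; xpp[k] <- xpp[k] + h[k]
        xpm <- x; xpm[j] <- xpm[j] + h[j]; xpm[k] <- xpm[k] - h[k]
        xmp <- x; xmp[j] <- xmp[j] - h[j]; xmp[k] <- xmp[k] + h[k]
        xmm <- x; xmm[j] <- xmm[j] - h[j]; xmm[k] <- xmm[k] - h[k]
        H[j, k] <- H[k, j] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[j] * h[k])
      }
    }
  }
  (H + t(H)) / 2
}

num_gradient <- function(f, x) {
  p <- length(x)
  h <- pmax(abs(x), 1) * .Machine$double.eps^(1 / 3)
  g <- numeric(p)
  for (j in seq_len(p)) {
    xp <- x; xp[j] <- xp[j] + h[j]
    xm <- x; xm[j] <- xm[j] - h[j]
    g[j] <- (f(xp) - f(xm)) / (2 * h[j])
  }
  g
}

# lower-triangular log-Cholesky <-> 2x2 PD matrix
chol2_to_theta <- function(D) {
  L <- t(chol(D))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

theta_to_chol2 <- function(theta) {
  L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  # column-major: [1,1]=exp(t1), [2,1]=t2, [1,2]=0, [2,2]=exp(t3)
  L
}

theta_to_D <- function(theta) {
  L <- theta_to_chol2(theta)
  L %*% t(L)
}

check_pd2 <- function(D, what = "D") {
  if (!isTRUE(all.equal(D, t(D))) || D[1, 1] <= 0 ||
      D[1, 1] * D[2, 2] - D[1, 2]^2 <= 0)
    stop(what, " must be a symmetric positive-definite 2x2 matrix",
         call. = FALSE)
  invisible(D)
}
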
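# Independent numerical oracles used to cross-check closed forms.

# Boundary positions by bisection on the threshold crossing of the thresholded
# gradient, g_prime * |du/dx|(x, t_n) = eta_t, independent of the closed form.
oracle_boundary_bisection <- function(params, rule, clock, tol = 1e-10) {
  n <- 0:clock$n_somites
  t_n <- clock$t0 + n * clock$period
  vapply(t_n, function(t) {
    f <- function(x) rule$g_prime * gradient_magnitude(x, t, params) - rule$eta_t
    upper <- params$lambda
    while (f(upper) > 0) upper <- upper * 2
    stats::uniroot(f, lower = 0, upper = upper, tol = tol)$root
  }, numeric(1))
}

# Brute-force chi-square minimiser for the straight-line fit: direct numeric
# minimisation of the objective, no normal equations.
oracle_wls <- function(x, y, sd = rep(1, length(x))) {
  chi2 <- function(p) sum(((y - p[1] * x - p[2]) / sd)^2)
  # gradient of the objective itself (plain calculus, no normal-equation solve)
  grad <- function(p) {
    r <- y - p[1] * x - p[2]
    c(-2 * sum(r * x / sd^2), -2 * sum(r / sd^2))
  }
  fit <- stats::optim(c(0, mean(y)), chi2, gr = grad, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 5000))
  # Newton polish with finite-difference Hessian: central differences are
  # exact for a quadratic objective, so this lands on the minimum
  p <- fit$par
  h <- 1e-4
  for (i in 1:3) {
    g <- grad(p)
    h11 <- (chi2(p + c(h, 0)) - 2 * chi2(p) + chi2(p - c(h, 0))) / h^2
    h22 <- (chi2(p + c(0, h)) - 2 * chi2(p) + chi2(p - c(0, h))) / h^2
    h12 <- (chi2(p + c(h, h)) - chi2(p + c(h, -h)) -
              chi2(p + c(-h, h)) + chi2(p - c(h, h))) / (4 * h^2)
    H <- matrix(c(h11, h12, h12, h22), 2, 2)
    step <- solve(H, g)
    if (any(!is.finite(step)) || max(abs(step)) < 1e-14) break
    p <- p - step
  }
  list(slope = p[1], intercept = p[2], chi2 = chi2(p))
}

# Random scenario with a positive anchor and no truncation over n somites.
random_scenario <- function(n_somites = 5) {
  lambda <- stats::runif(1, 100, 500)
  tau <- stats::runif(1, 2, 10)
  F0 <- exp(stats::runif(1, -1, 2))
  g_prime <- stats::runif(1, 0.5, 2)
  period <- stats::runif(1, 0.2, 1)
  # place the anchor far enough out that the series stays positive
  x0 <- n_somites * period * lambda / tau + stats::runif(1, 200, 500)
  eta_t <- g_prime * F0 / lambda * exp(-x0 / lambda)
  list(params = morphogen_params(F0, lambda, tau),
       rule = threshold_rule(eta_t, g_prime),
       clock = clock_schedule(period, n_somites))
}
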
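# Numerical oracles and fixture builders shared across the suite.

# central finite-difference gradient of a scalar function
num_grad <- function(f, theta, h = 1e-6) {
  vapply(seq_along(theta), function(j) {
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

# central finite-difference Hessian of a scalar function (symmetrized)
num_hess <- function(f, theta, h = 1e-4) {
  k <- length(theta)
  H <- matrix(0, k, k)
  f0 <- f(theta)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h
    H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h^2
    if (i < k) for (j in seq(i + 1, k)) {
      ej <- numeric(k); ej[j] <- h
      H[i, j] <- H[j, i] <- (f(theta + ei + ej) - f(theta + ei - ej) -
                               f(theta - ei + ej) + f(theta - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

# simulate one dataset from the study's generating model using the current
# RNG state (independent of the package's scenario machinery)
make_aft_data <- function(n, dist = "weibull", beta = c(3, 1.2, 0.7),
                          b = 0.67, lambda = Inf, pi_b = 0.5) {
  d <- aft_dist(dist)
  xc <- rnorm(n)
  xb <- rbinom(n, 1, pi_b)
  logT <- beta[1] + beta[2] * xb + beta[3] * xc + b * d$quantile(runif(n))
  logC <- if (is.finite(lambda)) lambda + b * d$quantile(runif(n)) else Inf
  delta <- as.numeric(logT <= logC)
  surv_data(exp(pmin(logT, logC)), delta, cbind(xb = xb, xc = xc))
}

# a dataset whose binary covariate perfectly splits events from censored
# subjects (one empty cell in the 2x2 table): classic separation
make_separated_data <- function(n = 30, seed = 3) {
  set.seed(seed)
  xb <- rep(c(0, 1), each = n / 2)
  delta <- xb
  t <- exp(3 + 0.5 * xb + 0.67 * rnorm(n))
  surv_data(t, delta, cbind(xb = xb))
}

# random parameter point kept inside the positive-definite region (moderate
# perturbations of the generating values, so chol(I) succeeds)
random_params <- function(p) {
  list(beta = rnorm(p + 1, sd = 0.25) + c(3, rep(0.5, p)),
       b = runif(1, 0.5, 1.0))
}
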
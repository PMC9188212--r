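test_that("log-likelihood matches hand-summed single-subject values", {
  d1 <- surv_data(1, 1)                      # y = 0, event
  expect_equal(aft_loglik(d1, beta = 0, b = 1, "normal"),
               dnorm(0, log = TRUE))
  d2 <- surv_data(1, 0)                      # y = 0, censored
  expect_equal(aft_loglik(d2, beta = 0, b = 1, "extreme_value"), -1)

  # three subjects, logistic errors, hand-summed scalar by scalar
  d3 <- surv_data(exp(c(0, 0.5, -0.5)), c(1, 1, 0))
  b <- 0.67
  z <- c(0, 0.5, -0.5) / b
  by_hand <- -2 * log(b) +
    dlogis(z[1], log = TRUE) + dlogis(z[2], log = TRUE) +
    plogis(z[3], lower.tail = FALSE, log.p = TRUE)
  expect_equal(aft_loglik(d3, beta = 0, b = b, "logistic"), by_hand)

  expect_error(aft_loglik(d1, beta = 0, b = -1, "normal"), "positive")
})

test_that("score matches its hand evaluation and vanishes at the optimum", {
  # single subject, normal, delta = 1: U_0 = z/b = y, U_b = -m/b + z^2/b
  d <- surv_data(exp(0.3), 1)
  u <- aft_score(d, beta = 0, b = 1, "normal")
  expect_equal(unname(u), c(0.3, -1 + 0.09))

  set.seed(201)
  dd <- make_aft_data(70, "weibull", lambda = 4.8)
  fit <- aft_mle(dd, "weibull")
  expect_true(fit$converged)
  expect_lt(max(abs(aft_score(dd, coef(fit), fit$scale, "weibull"))), 1e-5)
})

test_that("score and observed information match finite differences of the log-likelihood", {
  set.seed(77)
  for (nm in c("extreme_value", "normal", "logistic")) {
    for (rep in 1:4) {
      d <- make_aft_data(35, nm, lambda = 4.2)
      pr <- random_params(2)
      f <- function(th) aft_loglik(d, th[1:3], th[4], nm)
      th0 <- c(pr$beta, pr$b)
      expect_equal(unname(aft_score(d, pr$beta, pr$b, nm)),
                   num_grad(f, th0), tolerance = 1e-5)
      expect_equal(unname(aft_information(d, pr$beta, pr$b, nm)),
                   unname(-num_hess(f, th0)), tolerance = 1e-4)
    }
  }
})

test_that("uncensored normal blocks reduce to their closed forms", {
  set.seed(5)
  d <- make_aft_data(40, "normal", beta = c(1, 1.2, 0.7), lambda = Inf)
  b <- 0.8
  info <- aft_information(d, c(1, 1.2, 0.7), b, "normal")
  # A_i = -1 for every uncensored subject: beta block is X'X / b^2
  expect_equal(info[1:3, 1:3], crossprod(d$X) / b^2, ignore_attr = TRUE)

  # extreme value, single censored subject at z = 0: I_00 = e^0 = 1
  dc <- surv_data(1, 0)
  expect_equal(aft_information(dc, 0, 1, "extreme_value")[1, 1], 1)
})

test_that("uncensored log-normal MLE equals least squares with b^2 = RSS/n", {
  set.seed(11)
  d <- make_aft_data(80, "normal", beta = c(1, 1.2, 0.7), lambda = Inf)
  fit <- aft_mle(d, "lognormal")
  ols <- lm.fit(d$X, d$y)
  expect_equal(unname(coef(fit)), unname(ols$coefficients), tolerance = 1e-6)
  expect_equal(fit$scale^2, sum(ols$residuals^2) / d$n, tolerance = 1e-6)
})

test_that("Weibull MLE agrees with the survreg oracle on censored data", {
  set.seed(13)
  d <- make_aft_data(90, "weibull", lambda = 4.8)
  fit <- aft_mle(d, "weibull")
  df <- data.frame(time = d$time, status = d$delta,
                   xb = d$X[, 2], xc = d$X[, 3])
  sr <- survival::survreg(survival::Surv(time, status) ~ xb + xc, df,
                          dist = "weibull")
  expect_equal(unname(coef(fit)), unname(coef(sr)), tolerance = 1e-6)
  expect_equal(fit$scale, sr$scale, tolerance = 1e-6)
  expect_equal(unname(fit$se[1:3]),
               unname(sqrt(diag(vcov(sr)))[1:3]), tolerance = 1e-4)
})

test_that("fits are equivariant under location shifts and covariate scaling", {
  set.seed(17)
  d <- make_aft_data(60, "logistic", lambda = 4.5)
  fit <- aft_mle(d, "logistic")

  dshift <- surv_data(d$time * exp(2), d$delta, d$X[, -1],
                      covariate_names = d$covariate_names)
  fshift <- aft_mle(dshift, "logistic")
  expect_equal(coef(fshift)[1], coef(fit)[1] + 2, tolerance = 1e-6)
  expect_equal(coef(fshift)[-1], coef(fit)[-1], tolerance = 1e-6)
  expect_equal(fshift$scale, fit$scale, tolerance = 1e-6)

  xs <- d$X[, -1]; xs[, "xc"] <- 3 * xs[, "xc"]
  fsc <- aft_mle(surv_data(d$time, d$delta, xs,
                           covariate_names = d$covariate_names), "logistic")
  expect_equal(coef(fsc)[["xc"]], coef(fit)[["xc"]] / 3, tolerance = 1e-6)
  expect_equal(fsc$objective, fit$objective, tolerance = 1e-6)
})

test_that("degenerate inputs are refused with informative errors", {
  set.seed(23)
  d_all_cens <- surv_data(rexp(10) + 1, rep(0, 10))
  expect_error(aft_mle(d_all_cens, "weibull"), "no events")

  x <- rnorm(20)
  d_rank <- surv_data(rexp(20) + 1, rep(1, 20),
                      cbind(a = x, b = 2 * x))
  expect_error(aft_mle(d_rank, "weibull"), "rank deficient.*b")
})
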
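test_that("the penalty is half the log-determinant of the observed information", {
  set.seed(41)
  d <- make_aft_data(50, "weibull", lambda = 4.8)
  pr <- random_params(2)
  info <- aft_information(d, pr$beta, pr$b, "weibull")
  expect_equal(firth_penalty(d, pr$beta, pr$b, "weibull"),
               0.5 * determinant(info, logarithm = TRUE)$modulus[[1]],
               tolerance = 1e-10)
  expect_equal(aft_penalized_loglik(d, pr$beta, pr$b, "weibull") -
                 aft_loglik(d, pr$beta, pr$b, "weibull"),
               firth_penalty(d, pr$beta, pr$b, "weibull"))
})

test_that("scaling a covariate shifts the penalty by an additive constant", {
  set.seed(43)
  d <- make_aft_data(50, "weibull", lambda = 4.8)
  xs <- d$X[, -1]
  xs[, "xc"] <- 2 * xs[, "xc"]
  d2 <- surv_data(d$time, d$delta, xs, covariate_names = d$covariate_names)
  pr <- random_params(2)
  beta2 <- pr$beta; beta2[3] <- beta2[3] / 2
  # identical model: the information transforms by diag(1,1,2,1) on both
  # sides, so det picks up a factor 2^2 and the penalty shifts by +log 2
  expect_equal(firth_penalty(d2, beta2, pr$b, "weibull"),
               firth_penalty(d, pr$beta, pr$b, "weibull") + log(2),
               tolerance = 1e-8)
})

test_that("the penalized score matches finite differences and its trace form", {
  set.seed(47)
  for (nm in c("extreme_value", "normal", "logistic")) {
    d <- make_aft_data(40, nm, lambda = 4.2)
    pr <- random_params(2)
    th0 <- c(pr$beta, pr$b)
    f <- function(th) aft_penalized_loglik(d, th[1:3], th[4], nm)
    ps <- aft_penalized_score(d, pr$beta, pr$b, nm)
    expect_equal(unname(ps), num_grad(f, th0, h = 1e-5), tolerance = 1e-4)
    expect_equal(unname(ps),
                 unname(aft_penalized_score(d, pr$beta, pr$b, nm,
                                            route = "trace")),
                 tolerance = 1e-6)
  }
})

test_that("the penalized score vanishes at the Firth estimate", {
  set.seed(53)
  d <- make_aft_data(60, "weibull", lambda = 4.8)
  ff <- aft_firth(d, "weibull")
  expect_true(ff$converged)
  expect_lt(max(abs(aft_penalized_score(d, coef(ff), ff$scale, "weibull"))),
            1e-3)
})

test_that("Firth fitting stays finite under separation where the MLE diverges", {
  d <- make_separated_data(30)
  ml <- aft_mle(d, "weibull")
  expect_true(!ml$converged || max(abs(coef(ml))) > 10)
  ff <- aft_firth(d, "weibull")
  expect_true(ff$converged)
  expect_true(all(is.finite(coef(ff))))
  expect_true(all(is.finite(ff$se)))
  expect_lt(max(abs(coef(ff))), 10)
})

test_that("the penalty is asymptotically negligible and Firth approaches the MLE", {
  set.seed(59)
  per_n <- sapply(c(100, 1000, 10000), function(n) {
    d <- make_aft_data(n, "weibull", lambda = 4.8)
    (aft_penalized_loglik(d, c(3, 1.2, 0.7), 0.67, "weibull") -
        aft_loglik(d, c(3, 1.2, 0.7), 0.67, "weibull")) / n
  })
  # the per-observation penalty shrinks like log(n)/n
  expect_true(all(diff(abs(per_n)) < 0))
  expect_lt(abs(per_n[3]), abs(per_n[1]) / 20)

  d <- make_aft_data(10000, "weibull", lambda = 4.8)
  ml <- aft_mle(d, "weibull")
  ff <- aft_firth(d, "weibull")
  expect_lt(max(abs(c(coef(ff) - coef(ml), ff$scale - ml$scale))), 0.01)
})

test_that("Firth estimates are equivariant under covariate rescaling", {
  set.seed(61)
  d <- make_aft_data(40, "weibull", lambda = 4.5)
  ff <- aft_firth(d, "weibull")
  xs <- d$X[, -1]; xs[, "xc"] <- 5 * xs[, "xc"]
  ff2 <- aft_firth(surv_data(d$time, d$delta, xs,
                             covariate_names = d$covariate_names), "weibull")
  expect_equal(coef(ff2)[["xc"]], coef(ff)[["xc"]] / 5, tolerance = 1e-5)
  expect_equal(coef(ff2)[["xb"]], coef(ff)[["xb"]], tolerance = 1e-5)
  expect_equal(ff2$scale, ff$scale, tolerance = 1e-5)
})

test_that("intercept-only Firth fits converge with a positive scale", {
  set.seed(67)
  for (nm in c("weibull", "lognormal", "loglogistic")) {
    d <- surv_data(rexp(25) + 0.5, rbinom(25, 1, 0.8))
    ff <- aft_firth(d, nm)
    expect_true(ff$converged)
    expect_gt(ff$scale, 0)
  }
})

test_that("the returned optimum improves on the starting point", {
  set.seed(71)
  d <- make_aft_data(50, "weibull", lambda = 4.8)
  ml <- aft_mle(d, "weibull")
  ff <- aft_firth(d, "weibull")
  expect_gte(ff$objective + 1e-8,
             aft_penalized_loglik(d, coef(ml), ml$scale, "weibull"))
})

test_that("Firth shrinks the binary coefficient toward the truth more than the MLE", {
  # small samples with 40% censoring: the MLE of beta_b overshoots on
  # average, the penalized estimate is closer to the generating value
  set.seed(73)
  sc <- aft_scenario("weibull", n = 30, target_censoring = 0.4,
                     n_reps = 200, seed = 73)
  lam <- calibrate_lambda(sc)
  err_ml <- err_fi <- c()
  for (r in seq_len(sc$n_reps)) {
    set.seed(sc$seed + r)
    d <- simulate_aft_data(sc, lam)
    ml <- tryCatch(aft_mle(d, "weibull"), error = function(e) NULL)
    fi <- tryCatch(aft_firth(d, "weibull"), error = function(e) NULL)
    if (!is.null(ml) && !is.null(fi) && ml$converged && fi$converged &&
        max(abs(coef(ml))) < 50) {
      err_ml <- c(err_ml, abs(coef(ml)[["xb"]] - 1.2))
      err_fi <- c(err_fi, abs(coef(fi)[["xb"]] - 1.2))
    }
  }
  expect_gt(length(err_ml), 150)
  expect_lt(mean(err_fi), mean(err_ml))
})
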
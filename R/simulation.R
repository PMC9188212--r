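# Monte Carlo study engine: data generation under the log-location-scale AFT
# model, iterative calibration of the censoring-distribution parameter, and
# the replicated study producing bias / MSE / SE / CI-width summaries for the
# maximum-likelihood, Firth, and Firth-plus-correction estimators.
#
# Survival times:  T = exp(beta_0 + beta_b X_b + beta_c X_c + b Z)
# Censoring times: C = exp(lambda + b Z'), Z' an independent draw from the
# same standard distribution; lambda tunes the censoring proportion.
# Observed: t = min(T, C), delta = 1{T <= C}; X_c ~ N(0,1),
# X_b ~ Bernoulli(pi_b).

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards, so calibration draws do not disturb replicate streams.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Define a simulation scenario
#'
#' @param dist Survival distribution: `"weibull"`, `"lognormal"` or
#'   `"loglogistic"` (or the corresponding error-law names).
#' @param n Sample size per replicate.
#' @param beta True coefficients `(intercept, binary, continuous)`.  Defaults
#'   to `(3, 1.2, 0.7)` — the Weibull / log-logistic study values; the
#'   log-normal series uses intercept 1.
#' @param b True scale parameter (default 0.67).
#' @param pi_b Bernoulli success probability of the binary covariate
#'   (default 0.5, a balanced covariate).
#' @param target_censoring Desired censoring proportion in \[0, 1).
#' @param n_reps Number of Monte Carlo replicates.
#' @param seed Master seed; each replicate uses its own derived substream.
#' @param separation_mode `"off"`, or `"screen_separation"` /
#'   `"screen_near"` to keep regenerating each replicate's dataset until the
#'   separation diagnostic on the binary covariate returns the corresponding
#'   status.
#' @return An object of class `aft_scenario`.
#' @export
aft_scenario <- function(dist = "weibull", n,
                         beta = c(intercept = 3, binary = 1.2, continuous = 0.7),
                         b = 0.67, pi_b = 0.5, target_censoring = 0.2,
                         n_reps = 1000L, seed = 1L,
                         separation_mode = c("off", "screen_separation",
                                             "screen_near")) {
  separation_mode <- match.arg(separation_mode)
  stopifnot(length(beta) == 3, b > 0, pi_b > 0, pi_b < 1,
            target_censoring >= 0, target_censoring < 1,
            n_reps >= 1, n >= 5)
  structure(
    list(dist = aft_dist(dist)$name, n = as.integer(n),
         beta = stats::setNames(as.numeric(beta),
                                c("intercept", "binary", "continuous")),
         b = b, pi_b = pi_b, target_censoring = target_censoring,
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         separation_mode = separation_mode),
    class = "aft_scenario")
}

#' @export
print.aft_scenario <- function(x, ...) {
  cat("AFT simulation scenario:", x$dist, "errors, n =", x$n, "\n")
  cat("true beta = (", paste(format(x$beta), collapse = ", "),
      "), b =", x$b, ", pi_b =", x$pi_b, "\n")
  cat("target censoring:", x$target_censoring, "; replicates:", x$n_reps,
      "; seed:", x$seed, "; separation mode:", x$separation_mode, "\n")
  invisible(x)
}

#' Calibrate the censoring-distribution parameter
#'
#' Finds lambda such that censoring times `C = exp(lambda + b Z')` yield the
#' scenario's target censoring proportion.  The censoring proportion
#' `P(T > C)` is non-increasing in lambda, so a monotone bisection over a
#' large fixed auxiliary sample (its own seed stream, independent of the
#' replicate streams) converges to the target within `tol`.
#'
#' @param scenario An [aft_scenario()].
#' @param n_calib Auxiliary Monte Carlo sample size (default 200000).
#' @param tol Tolerance on the censoring proportion (default 0.005).
#' @return The calibrated lambda.  A target of 0 returns the no-censoring
#'   surrogate `beta_0 + 50 b`.
#' @export
calibrate_lambda <- function(scenario, n_calib = 2e5, tol = 0.005) {
  stopifnot(inherits(scenario, "aft_scenario"))
  if (scenario$target_censoring == 0)
    return(scenario$beta[["intercept"]] + 50 * scenario$b)
  d <- aft_dist(scenario$dist)
  W <- .with_seed(scenario$seed + 104729L, {
    xc <- stats::rnorm(n_calib)
    xb <- stats::rbinom(n_calib, 1, scenario$pi_b)
    z <- d$quantile(stats::runif(n_calib))
    zc <- d$quantile(stats::runif(n_calib))
    # censored iff log T - b Z' = lp + b(Z - Z') > lambda
    scenario$beta[["intercept"]] + scenario$beta[["binary"]] * xb +
      scenario$beta[["continuous"]] * xc + scenario$b * (z - zc)
  })
  lo <- min(W) - 1; hi <- max(W) + 1
  cens <- function(lam) mean(W > lam)
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    cm <- cens(mid)
    if (abs(cm - scenario$target_censoring) <= tol || (hi - lo) < 1e-10) break
    if (cm > scenario$target_censoring) lo <- mid else hi <- mid
  }
  mid
}

#' Generate one dataset under a scenario
#'
#' Draws covariates, survival and censoring times from the scenario's model
#' using the current RNG state (callers seed per replicate).
#'
#' @param scenario An [aft_scenario()].
#' @param lambda Censoring parameter, usually from [calibrate_lambda()].
#' @return An [surv_data()] object with covariate columns `xb`, `xc` and an
#'   attribute `achieved_censoring` (the realized censored fraction).
#' @export
simulate_aft_data <- function(scenario, lambda) {
  stopifnot(inherits(scenario, "aft_scenario"), is.finite(lambda))
  d <- aft_dist(scenario$dist)
  n <- scenario$n
  xc <- stats::rnorm(n)
  xb <- stats::rbinom(n, 1, scenario$pi_b)
  z <- d$quantile(stats::runif(n))
  zc <- d$quantile(stats::runif(n))
  logT <- scenario$beta[["intercept"]] + scenario$beta[["binary"]] * xb +
    scenario$beta[["continuous"]] * xc + scenario$b * z
  logC <- lambda + scenario$b * zc
  delta <- as.numeric(logT <= logC)
  out <- surv_data(exp(pmin(logT, logC)), delta, cbind(xb = xb, xc = xc))
  attr(out, "achieved_censoring") <- 1 - mean(delta)
  out
}

# One replicate's dataset, honouring the separation screen.
.draw_replicate <- function(scenario, lambda, screen_cap = 10000L) {
  if (scenario$separation_mode == "off")
    return(simulate_aft_data(scenario, lambda))
  want <- switch(scenario$separation_mode,
                 screen_separation = "separation", screen_near = "near")
  for (i in seq_len(screen_cap)) {
    ds <- simulate_aft_data(scenario, lambda)
    st <- tryCatch(classify_separation(ds, "xb")$status,
                   error = function(e) NA_character_)
    if (identical(st, want)) return(ds)
  }
  stop("separation screen not met within ", screen_cap, " attempts",
       call. = FALSE)
}

# A replicate is valid for a method if the fit converged, every coefficient
# is moderate (|coef| <= coef_cap), and every SE is finite.
.replicate_valid <- function(fit, coef_cap) {
  !is.null(fit) && isTRUE(fit$converged) &&
    all(is.finite(fit$coefficients)) &&
    max(abs(fit$coefficients)) <= coef_cap &&
    all(is.finite(fit$se))
}

#' Run a Monte Carlo study
#'
#' For each replicate: generate a dataset (optionally screened for
#' separation), fit by maximum likelihood, Firth penalization, and Firth with
#' the intercept/scale correction, and record estimates, analytic standard
#' errors and Wald 95% CI widths.  Aggregates per parameter and method over
#' the replicates that pass the validity rule.
#'
#' @param scenario An [aft_scenario()].
#' @param lambda Optional pre-calibrated censoring parameter; calibrated from
#'   the scenario when `NULL`.
#' @param methods Subset of `c("mle", "firth", "firth_corrected")`.
#' @param coef_cap Validity rule: a replicate is discarded for a method when
#'   the fit fails to converge, any |coefficient| exceeds `coef_cap`
#'   (default 50), or any standard error is non-finite.
#' @return An object of class `aft_study`: `summary` (a data frame with one
#'   row per method x parameter: mean estimate, bias, MSE, mean analytic SE,
#'   simulation SE, mean Wald 95% CI width), `n_valid` and `n_failed` per
#'   method, `achieved_censoring` (mean over all replicates), `lambda`, and
#'   the scenario.  Identical scenarios (including seed) reproduce bit-
#'   identical results.
#' @export
run_study <- function(scenario, lambda = NULL,
                      methods = c("mle", "firth", "firth_corrected"),
                      coef_cap = 50) {
  stopifnot(inherits(scenario, "aft_scenario"))
  methods <- match.arg(methods, c("mle", "firth", "firth_corrected"),
                       several.ok = TRUE)
  if (is.null(lambda)) lambda <- calibrate_lambda(scenario)
  d <- scenario$dist
  par_names <- c("intercept", "binary", "continuous", "scale")
  true <- c(scenario$beta, scale = scenario$b)
  R <- scenario$n_reps
  est <- se <- array(NA_real_,
                     dim = c(R, 4L, length(methods)),
                     dimnames = list(NULL, par_names, methods))
  valid <- matrix(FALSE, R, length(methods), dimnames = list(NULL, methods))
  cens <- numeric(R)

  need_firth <- any(c("firth", "firth_corrected") %in% methods)
  for (r in seq_len(R)) {
    set.seed(scenario$seed + r)
    ds <- .draw_replicate(scenario, lambda)
    cens[r] <- attr(ds, "achieved_censoring")

    fits <- list()
    if ("mle" %in% methods)
      fits$mle <- tryCatch(aft_mle(ds, d), error = function(e) NULL)
    if (need_firth) {
      ff <- tryCatch(aft_firth(ds, d), error = function(e) NULL)
      if ("firth" %in% methods) fits$firth <- ff
      if ("firth_corrected" %in% methods)
        fits$firth_corrected <- if (!is.null(ff) && ff$converged)
          tryCatch(correct_intercept_scale(ds, d, ff),
                   error = function(e) NULL)
        else NULL
    }
    for (mth in methods) {
      f <- fits[[mth]]
      if (!is.null(f)) {
        est[r, , mth] <- c(f$coefficients, f$scale)
        se[r, , mth] <- f$se
      }
      valid[r, mth] <- .replicate_valid(f, coef_cap)
    }
  }

  rows <- list()
  for (mth in methods) {
    ok <- valid[, mth]
    for (pn in par_names) {
      e <- est[ok, pn, mth]; s <- se[ok, pn, mth]
      rows[[length(rows) + 1L]] <- if (length(e) == 0)
        data.frame(method = mth, parameter = pn, true = unname(true[pn]),
                   estimate = NA_real_, bias = NA_real_, mse = NA_real_,
                   se = NA_real_, sim_se = NA_real_, ci_width = NA_real_)
      else data.frame(
        method = mth, parameter = pn, true = unname(true[pn]),
        estimate = mean(e), bias = mean(e) - true[[pn]],
        mse = mean((e - true[[pn]])^2),
        se = mean(s),
        sim_se = if (length(e) > 1) stats::sd(e) else 0,
        ci_width = mean(2 * 1.96 * s))
    }
  }
  n_valid <- colSums(valid)
  if (all(n_valid == 0)) stop("no valid replicates", call. = FALSE)

  structure(
    list(scenario = scenario, lambda = lambda,
         summary = do.call(rbind, rows),
         n_valid = n_valid, n_failed = R - n_valid,
         achieved_censoring = mean(cens)),
    class = "aft_study")
}

#' @export
print.aft_study <- function(x, digits = 4, ...) {
  print(x$scenario)
  cat("calibrated lambda:", format(x$lambda, digits = 5),
      "; mean achieved censoring:",
      format(x$achieved_censoring, digits = 3), "\n")
  cat("valid replicates:",
      paste(names(x$n_valid), x$n_valid, sep = "=", collapse = ", "), "\n\n")
  out <- x$summary
  out[-(1:2)] <- lapply(out[-(1:2)], round, digits = digits)
  print(out, row.names = FALSE)
  invisible(x)
}
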
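# Survival prediction from a fitted AFT model:
#   S(t | x) = S0( (log t - beta'x) / b )
# and its inverse, the survival-time quantile
#   t_q = exp( beta'x + b * Q0(q) ),   S(t_q | x) = 1 - q,
# where Q0 is the standard quantile under the convention F0 = 1 - S0.

.pred_params <- function(fit) {
  if (inherits(fit, "aft_fit"))
    list(beta = fit$coefficients, b = fit$scale,
         dist = fit$dist)
  else if (is.list(fit) && !is.null(fit$beta) && !is.null(fit$b))
    list(beta = fit$beta, b = fit$b, dist = fit$dist)
  else stop("'fit' must be an aft_fit or a list(beta=, b=)", call. = FALSE)
}

#' Predict survival probability
#'
#' @param fit An `aft_fit`, or a list with elements `beta` and `b` (true or
#'   external parameter values).
#' @param dist Distribution name or object; defaults to the one stored in
#'   `fit`.
#' @param x Covariate vector including the intercept slot (length p+1).
#' @param time Positive time(s) at which to evaluate the survivor function.
#' @return Survival probabilities in \[0, 1\], one per element of `time`.
#' @examples
#' pars <- list(beta = c(3, 1.2, 0.7), b = 0.67)
#' predict_survival(pars, "weibull", x = c(1, 1, 0), time = exp(4.2))
#' @export
predict_survival <- function(fit, dist = NULL, x, time) {
  p <- .pred_params(fit)
  d <- aft_dist(if (is.null(dist)) p$dist else dist)
  stopifnot(length(x) == length(p$beta))
  if (any(!is.finite(time)) || any(time <= 0))
    stop("'time' must be positive and finite", call. = FALSE)
  lp <- sum(p$beta * x)
  exp(d$logS0((log(time) - lp) / p$b))
}

#' Predict a survival-time quantile
#'
#' Returns the time `t` at which the predicted survivor function falls to
#' `1 - q`, i.e. the q-th quantile of the survival-time distribution at
#' covariate pattern `x`.
#'
#' @inheritParams predict_survival
#' @param q Probability level(s) in (0, 1); `q = 0.25` gives the first
#'   quartile of survival time.
#' @return Positive time(s).
#' @export
predict_time_quantile <- function(fit, dist = NULL, x, q) {
  p <- .pred_params(fit)
  d <- aft_dist(if (is.null(dist)) p$dist else dist)
  stopifnot(length(x) == length(p$beta))
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("'q' must lie strictly in (0, 1)", call. = FALSE)
  lp <- sum(p$beta * x)
  exp(lp + p$b * d$quantile(q))
}
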
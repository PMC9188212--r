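# Log-likelihood, analytic score, observed information, and maximum-likelihood
# fitting for the AFT model y = beta'x + offset + b*Z.
#
# With z_i = (y_i - u_i)/b, u_i = x_i'beta + offset_i, and m = sum(delta):
#
#   l(beta, b) = -m log b + sum_i [ delta_i log f0(z_i)
#                                   + (1 - delta_i) log S0(z_i) ]
#
# Writing B_i = delta_i d/dz log f0(z_i) + (1-delta_i) d/dz log S0(z_i) and
# A_i the same combination of second derivatives, the score is
#   U_r = -(1/b) sum_i B_i x_ir,        r = 0..p
#   U_b = -m/b  - (1/b) sum_i B_i z_i
# and the observed information (negative Hessian) has blocks
#   I_bb' = -(1/b^2) sum_i A_i x_i x_i'
#   I_bs  = -(1/b^2) sum_i (A_i z_i + B_i) x_i
#   I_ss  = -(1/b^2) [ m + sum_i (A_i z_i^2 + 2 B_i z_i) ].
#
# The optimizer works on (beta, log b) so the b > 0 constraint never binds;
# reported covariance comes from inverting the observed information on the
# original (beta, b) scale at the optimum.

.check_params <- function(beta, b) {
  if (anyNA(beta) || any(!is.finite(beta)))
    stop("'beta' must be finite", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("scale 'b' must be a finite positive scalar", call. = FALSE)
}

.resid_AB <- function(data, beta, b, dist, offset) {
  z <- (data$y - drop(data$X %*% beta) - offset) / b
  list(z = z,
       A = data$delta * dist$logf0_d2(z) + (1 - data$delta) * dist$logS0_d2(z),
       B = data$delta * dist$logf0_d1(z) + (1 - data$delta) * dist$logS0_d1(z))
}

.offset_or_zero <- function(data, offset) {
  if (is.null(offset)) rep(0, data$n)
  else { stopifnot(length(offset) == data$n); as.numeric(offset) }
}

#' AFT log-likelihood
#'
#' @param data An [surv_data()] object.
#' @param beta Coefficient vector, intercept first (length p+1).
#' @param b Positive scale parameter.
#' @param dist Distribution name or [aft_dist()] object.
#' @param offset Optional fixed additive term in the location (length n).
#' @return The log-likelihood value.
#' @export
aft_loglik <- function(data, beta, b, dist, offset = NULL) {
  dist <- aft_dist(dist)
  .check_params(beta, b)
  offset <- .offset_or_zero(data, offset)
  z <- (data$y - drop(data$X %*% beta) - offset) / b
  m <- sum(data$delta)
  -m * log(b) + sum(data$delta * dist$logf0(z) +
                      (1 - data$delta) * dist$logS0(z))
}

#' AFT score vector
#'
#' Gradient of [aft_loglik()] with respect to (beta, b); the scale component
#' uses the event count m from the -m log b likelihood term.
#'
#' @inheritParams aft_loglik
#' @return Numeric vector of length p+2, ordered (beta_0, ..., beta_p, b).
#' @export
aft_score <- function(data, beta, b, dist, offset = NULL) {
  dist <- aft_dist(dist)
  .check_params(beta, b)
  offset <- .offset_or_zero(data, offset)
  r <- .resid_AB(data, beta, b, dist, offset)
  m <- sum(data$delta)
  u_beta <- -drop(crossprod(data$X, r$B)) / b
  u_b <- -m / b - sum(r$B * r$z) / b
  stats::setNames(c(u_beta, u_b), c(colnames(data$X), "scale"))
}

#' AFT observed information matrix
#'
#' Negative Hessian of [aft_loglik()] with respect to (beta, b), the
#' (p+2) x (p+2) matrix whose half log-determinant is the Firth penalty.
#'
#' @inheritParams aft_loglik
#' @return Symmetric (p+2) x (p+2) matrix.
#' @export
aft_information <- function(data, beta, b, dist, offset = NULL) {
  dist <- aft_dist(dist)
  .check_params(beta, b)
  offset <- .offset_or_zero(data, offset)
  r <- .resid_AB(data, beta, b, dist, offset)
  m <- sum(data$delta)
  k <- ncol(data$X)
  I_bb <- -crossprod(data$X, r$A * data$X) / b^2
  I_bs <- -drop(crossprod(data$X, r$A * r$z + r$B)) / b^2
  I_ss <- -(m + sum(r$A * r$z^2 + 2 * r$B * r$z)) / b^2
  info <- rbind(cbind(I_bb, I_bs), c(I_bs, I_ss))
  nm <- c(colnames(data$X), "scale")
  dimnames(info) <- list(nm, nm)
  (info + t(info)) / 2
}

# OLS-based starting values: beta from least squares of (y - offset) on X
# over all rows (censored included), b from the residual SD floored at 1e-3.
.start_values <- function(data, offset) {
  fit <- stats::lm.fit(data$X, data$y - offset)
  b0 <- stats::sd(fit$residuals)
  if (!is.finite(b0)) b0 <- 1
  list(beta = fit$coefficients, b = max(b0, 1e-3))
}

.check_fit_data <- function(data) {
  stopifnot(inherits(data, "aft_data"))
  if (sum(data$delta) < 1)
    stop("cannot fit: no events in the data (all observations censored)",
         call. = FALSE)
  qrX <- qr(data$X)
  if (qrX$rank < ncol(data$X)) {
    dep <- colnames(data$X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
}

# Score and negative Hessian on the working (beta, s = log b) scale.
.score_tilde <- function(data, beta, b, dist, offset) {
  u <- aft_score(data, beta, b, dist, offset)
  u[length(u)] <- b * u[length(u)]
  u
}

.info_tilde <- function(data, beta, b, dist, offset) {
  info <- aft_information(data, beta, b, dist, offset)
  k <- nrow(info)
  u_b <- aft_score(data, beta, b, dist, offset)[k]
  info[k, ] <- b * info[k, ]
  info[, k] <- b * info[, k]
  info[k, k] <- info[k, k] - b * u_b   # d^2 l/ds^2 = b^2 l_bb + b l_b
  info
}

.make_fit <- function(data, beta, b, dist, objective, converged, n_iter,
                      method, gradient_norm, offset = NULL) {
  k <- length(beta) + 1L
  nm <- c(colnames(data$X), "scale")
  info <- aft_information(data, beta, b, dist, offset)
  cov <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  se <- rep(NA_real_, k)
  se_available <- FALSE
  ch <- tryCatch(chol(info), error = function(e) NULL)
  if (!is.null(ch)) {
    cov <- chol2inv(ch)
    dimnames(cov) <- list(nm, nm)
    if (all(diag(cov) >= 0)) {
      se <- sqrt(diag(cov))
      se_available <- TRUE
    }
  }
  structure(
    list(coefficients = stats::setNames(beta, colnames(data$X)),
         scale = b,
         se = stats::setNames(se, nm),
         cov = cov,
         se_available = se_available,
         objective = objective,
         loglik = aft_loglik(data, beta, b, dist, offset),
         converged = converged,
         n_iter = n_iter,
         method = method,
         gradient_norm = gradient_norm,
         dist = aft_dist(dist)$name,
         n = data$n, p = data$p,
         n_events = sum(data$delta)),
    class = "aft_fit")
}

#' Fit an AFT model by maximum likelihood
#'
#' Maximizes the log-likelihood over (beta, log b) by BFGS with the analytic
#' score, followed by Newton polishing steps on the working scale.  The
#' covariance is the inverse observed information at the optimum.
#'
#' @inheritParams aft_loglik
#' @param init Optional list with starting values `beta` and `b`; defaults to
#'   ordinary least squares of the log-times on the design matrix, with the
#'   residual standard deviation (floored at 1e-3) as the scale start.
#' @param control List of control values: `maxit` (iteration cap, 500),
#'   `grad_tol` (convergence gradient max-norm, 1e-6), `reltol` (relative
#'   objective change, 1e-10).
#' @return An object of class `aft_fit`: coefficients, scale, standard errors
#'   (order beta_0..beta_p, scale), covariance matrix, log-likelihood,
#'   convergence status, iteration count, gradient norm and method tag.
#'   `converged = FALSE` marks a fit whose gradient never fell below the
#'   tolerance (as happens under separation, where the likelihood is
#'   monotone); `se_available = FALSE` marks a singular or non-positive
#'   observed information at the returned point.
#' @examples
#' set.seed(1)
#' x <- rnorm(80)
#' t <- exp(1 + 0.5 * x + 0.6 * log(-log(1 - runif(80))))
#' d <- surv_data(t, rep(1, 80), cbind(x = x))
#' fit <- aft_mle(d, "weibull")
#' coef(fit)
#' @export
aft_mle <- function(data, dist, init = NULL, offset = NULL,
                    control = list()) {
  dist <- aft_dist(dist)
  .check_fit_data(data)
  offset <- .offset_or_zero(data, offset)
  ctl <- utils::modifyList(
    list(maxit = 500L, grad_tol = 1e-6, reltol = 1e-10), control)

  if (is.null(init)) init <- .start_values(data, offset)
  theta0 <- unname(c(init$beta, log(init$b)))
  k <- length(theta0)

  negll <- function(th) {
    b <- exp(th[k])
    if (!is.finite(b) || b <= 0 || any(!is.finite(th))) return(1e10)
    v <- tryCatch(-aft_loglik(data, th[-k], b, dist, offset),
                  error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  neggr <- function(th) {
    b <- exp(th[k])
    if (!is.finite(b) || b <= 0 || any(!is.finite(th))) return(rep(0, k))
    g <- tryCatch(-.score_tilde(data, th[-k], b, dist, offset),
                  error = function(e) rep(0, k))
    g[!is.finite(g)] <- 0
    g
  }
  opt <- stats::optim(theta0, negll, neggr, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  th <- opt$par
  n_iter <- opt$counts[["function"]]

  # Newton polish on (beta, log b): drives the gradient to machine precision
  # when the information is positive definite near the optimum.
  for (it in seq_len(25L)) {
    if (!is.finite(exp(th[k]))) break
    g <- .score_tilde(data, th[-k], exp(th[k]), dist, offset)
    if (max(abs(g)) <= ctl$grad_tol) break
    H <- .info_tilde(data, th[-k], exp(th[k]), dist, offset)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    th_new <- th + step
    # backtrack if the step does not improve the objective
    f_old <- -negll(th); shrink <- 0L
    while (-negll(th_new) < f_old && shrink < 30L) {
      step <- step / 2; th_new <- th + step; shrink <- shrink + 1L
    }
    if (-negll(th_new) < f_old) break
    th <- th_new
  }

  beta <- unname(th[-k]); b <- unname(exp(th[k]))
  g <- .score_tilde(data, beta, b, dist, offset)
  gnorm <- max(abs(g))
  .make_fit(data, beta, b, dist,
            objective = aft_loglik(data, beta, b, dist, offset),
            converged = is.finite(gnorm) && gnorm <= max(ctl$grad_tol, 1e-6),
            n_iter = n_iter, method = "mle",
            gradient_norm = gnorm, offset = offset)
}

#' @export
print.aft_fit <- function(x, ...) {
  cat("AFT model (", x$dist, " errors), method = ", x$method, "\n", sep = "")
  cat("n =", x$n, " events =", x$n_events, "\n")
  est <- c(x$coefficients, scale = x$scale)
  tab <- data.frame(Estimate = est, SE = x$se,
                    `Lower 95` = est - 1.96 * x$se,
                    `Upper 95` = est + 1.96 * x$se,
                    check.names = FALSE)
  print(round(tab, 4))
  lab <- if (x$method == "mle") "Log-likelihood:" else "Penalized log-likelihood:"
  cat(lab, format(x$objective, digits = 6), "\n")
  if (!x$converged) cat("WARNING: fit did not converge (gradient norm ",
                        format(x$gradient_norm, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.aft_fit <- function(object, ...) object$coefficients

#' @export
vcov.aft_fit <- function(object, ...) object$cov

#' @export
logLik.aft_fit <- function(object, ...) {
  structure(object$loglik, df = object$p + 2, class = "logLik")
}
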
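# Standardized error distributions of the log-location-scale family.
#
# An AFT model writes log survival time as y = beta'x + b*Z where Z follows a
# standard location-scale law: Gumbel (smallest extreme value) for Weibull
# survival times, normal for log-normal, logistic for log-logistic.  The score
# and observed-information formulas need the first two derivatives of both
# log f0 and log S0, so each registry entry bundles all of them together with
# the standard quantile (inverse CDF, convention F0 = 1 - S0).

.aft_dist_registry <- new.env(parent = emptyenv())

.check_z <- function(z) {
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z)))
    stop("'z' must be finite numeric", call. = FALSE)
  invisible(z)
}

.check_u <- function(u) {
  if (!is.numeric(u) || anyNA(u) || any(u <= 0) || any(u >= 1))
    stop("probability must lie strictly in (0, 1)", call. = FALSE)
  invisible(u)
}

#' Register a standardized error distribution
#'
#' Adds (or replaces) an entry in the distribution registry used by
#' [aft_dist()].  All functions take a numeric vector of standardized
#' residuals `z` and must be vectorized.  The three members required for the
#' Weibull, log-normal and log-logistic AFT models are pre-registered; this
#' hook exists so further log-location-scale members can be added without
#' touching the fitting code.
#'
#' @param name Canonical name of the standardized distribution.
#' @param logf0 Function: log density of Z.
#' @param logS0 Function: log survivor of Z (must stay finite far into the
#'   upper tail; use a tail-stable form).
#' @param logf0_d1,logf0_d2 First and second derivative of `logf0`.
#' @param logS0_d1,logS0_d2 First and second derivative of `logS0`.
#' @param quantile Function of `u` in (0,1) returning `z` with
#'   `S0(z) = 1 - u`.
#' @param aliases Character vector of alternative names (e.g. the name of the
#'   survival-time distribution the error law induces).
#' @return The registered bundle, invisibly.
#' @export
register_aft_dist <- function(name, logf0, logS0, logf0_d1, logf0_d2,
                              logS0_d1, logS0_d2, quantile,
                              aliases = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  bundle <- structure(
    list(name = name,
         logf0 = function(z) { .check_z(z); logf0(z) },
         logS0 = function(z) { .check_z(z); logS0(z) },
         logf0_d1 = function(z) { .check_z(z); logf0_d1(z) },
         logf0_d2 = function(z) { .check_z(z); logf0_d2(z) },
         logS0_d1 = function(z) { .check_z(z); logS0_d1(z) },
         logS0_d2 = function(z) { .check_z(z); logS0_d2(z) },
         quantile = function(u) { .check_u(u); quantile(u) }),
    class = "aft_dist")
  for (key in c(name, aliases))
    assign(key, bundle, envir = .aft_dist_registry)
  invisible(bundle)
}

#' Look up a standardized error distribution
#'
#' @param name One of `"extreme_value"` (alias `"weibull"`, `"gumbel"`),
#'   `"normal"` (alias `"lognormal"`), `"logistic"` (alias `"loglogistic"`),
#'   or any name added through [register_aft_dist()].  An `aft_dist` object
#'   passes through unchanged.
#' @return An object of class `aft_dist`: a list of vectorized functions
#'   `logf0`, `logS0`, their first and second derivatives `logf0_d1`,
#'   `logf0_d2`, `logS0_d1`, `logS0_d2`, and `quantile`.
#' @examples
#' d <- aft_dist("weibull")
#' d$logf0(0)       # z - exp(z) at 0: -1
#' d$quantile(1 - exp(-1))  # 0
#' @export
aft_dist <- function(name) {
  if (inherits(name, "aft_dist")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(name)
  if (!exists(key, envir = .aft_dist_registry, inherits = FALSE))
    stop("unknown distribution '", name, "'; known: ",
         paste(sort(ls(.aft_dist_registry)), collapse = ", "), call. = FALSE)
  get(key, envir = .aft_dist_registry, inherits = FALSE)
}

#' @export
print.aft_dist <- function(x, ...) {
  cat("Standardized AFT error distribution:", x$name, "\n")
  invisible(x)
}

# Normal hazard phi(z)/(1 - Phi(z)), computed on the log scale so the upper
# tail (heavily censored observations push z far right) does not underflow.
.norm_hazard <- function(z) {
  exp(stats::dnorm(z, log = TRUE) -
        stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
}

.register_builtin_dists <- function() {
  # Gumbel (smallest extreme value): S0(z) = exp(-e^z), log f0(z) = z - e^z
  register_aft_dist(
    "extreme_value",
    logf0    = function(z) z - exp(z),
    logS0    = function(z) -exp(z),
    logf0_d1 = function(z) 1 - exp(z),
    logf0_d2 = function(z) -exp(z),
    logS0_d1 = function(z) -exp(z),
    logS0_d2 = function(z) -exp(z),
    quantile = function(u) log(-log1p(-u)),
    aliases  = c("weibull", "gumbel"))

  # Standard normal; log S0 and its derivatives via the tail-stable log
  # survivor and the Mills-ratio hazard.
  register_aft_dist(
    "normal",
    logf0    = function(z) stats::dnorm(z, log = TRUE),
    logS0    = function(z) stats::pnorm(z, lower.tail = FALSE, log.p = TRUE),
    logf0_d1 = function(z) -z,
    logf0_d2 = function(z) rep(-1, length(z)),
    logS0_d1 = function(z) -.norm_hazard(z),
    logS0_d2 = function(z) { h <- .norm_hazard(z); h * (z - h) },
    quantile = function(u) stats::qnorm(u),
    aliases  = c("lognormal", "log_normal"))

  # Standard logistic, F(z) = e^z/(1+e^z)
  register_aft_dist(
    "logistic",
    logf0    = function(z) stats::dlogis(z, log = TRUE),
    logS0    = function(z) stats::plogis(z, lower.tail = FALSE, log.p = TRUE),
    logf0_d1 = function(z) 1 - 2 * stats::plogis(z),
    logf0_d2 = function(z) { F <- stats::plogis(z); -2 * F * (1 - F) },
    logS0_d1 = function(z) -stats::plogis(z),
    logS0_d2 = function(z) { F <- stats::plogis(z); -F * (1 - F) },
    quantile = function(u) stats::qlogis(u),
    aliases  = c("loglogistic", "log_logistic"))
}

.register_builtin_dists()
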
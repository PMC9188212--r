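# User-facing fitting surface: a one-call dispatcher over the three
# estimation methods, a formula interface in the style of the field's
# survival-regression functions, and the report builder behind the `fit`
# command of the shipped CLI script.

#' Fit an AFT model by a chosen method
#'
#' Thin dispatcher over [aft_mle()], [aft_firth()] and
#' [correct_intercept_scale()].
#'
#' @inheritParams aft_mle
#' @param method `"mle"`, `"firth"`, or `"firth_corrected"` (Firth fit
#'   followed by the post-hoc intercept/scale correction).
#' @return An `aft_fit`.
#' @export
aft_fit <- function(data, dist, method = c("mle", "firth", "firth_corrected"),
                    init = NULL, control = list()) {
  method <- match.arg(method)
  switch(method,
         mle = aft_mle(data, dist, init = init, control = control),
         firth = aft_firth(data, dist, init = init, control = control),
         firth_corrected = correct_intercept_scale(
           data, dist, aft_firth(data, dist, init = init, control = control)))
}

#' Formula interface for AFT fitting
#'
#' @param formula A formula with a [survival::Surv()] response on the natural
#'   time scale, e.g. `Surv(time, status) ~ age + treatment`.
#' @param data A data frame holding the variables.
#' @param dist Distribution name (see [aft_dist()]).
#' @param method Estimation method, as in [aft_fit()].
#' @return An `aft_fit`.
#' @examples
#' df <- data.frame(time = rexp(40) + 0.1, status = rbinom(40, 1, 0.8),
#'                  x = rnorm(40))
#' aftreg(survival::Surv(time, status) ~ x, df, dist = "weibull",
#'        method = "firth")
#' @export
aftreg <- function(formula, data, dist = "weibull",
                   method = c("mle", "firth", "firth_corrected")) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv"))
    stop("the response must be a survival::Surv(time, event) object",
         call. = FALSE)
  if (attr(y, "type") != "right")
    stop("only right-censored responses are supported", call. = FALSE)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (colnames(X)[1] != "(Intercept)")
    stop("the model must include an intercept", call. = FALSE)
  xm <- X[, -1, drop = FALSE]
  sd <- surv_data(y[, "time"], y[, "status"],
                  x = if (ncol(xm)) xm else NULL)
  aft_fit(sd, dist, method)
}

#' Fit a model from a CSV file and build a coefficient report
#'
#' The work-horse behind the CLI `fit` subcommand: reads the data, runs the
#' requested fit, assembles a coefficient table with Wald 95% confidence
#' intervals, and attaches a separation diagnostic for every binary covariate.
#'
#' @inheritParams read_surv_csv
#' @param dist Distribution name.
#' @param method Estimation method, as in [aft_fit()].
#' @param output Optional path; when given, the coefficient table is written
#'   there as CSV.
#' @return A list of class `aft_fit_report`: `fit` (the `aft_fit`), `table`
#'   (data frame: term, estimate, se, lower, upper), and
#'   `separation_warnings` (list of `separation_report`s with status other
#'   than `"none"`).
#' @export
fit_command <- function(path, time_col, event_col,
                        covariate_cols = character(),
                        dist = "weibull",
                        method = c("mle", "firth", "firth_corrected"),
                        output = NULL) {
  method <- match.arg(method)
  data <- read_surv_csv(path, time_col, event_col, covariate_cols)
  fit <- aft_fit(data, dist, method)
  est <- c(fit$coefficients, scale = fit$scale)
  tab <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(fit$se),
                    lower = unname(est - 1.96 * fit$se),
                    upper = unname(est + 1.96 * fit$se))

  warns <- list()
  for (j in seq_len(data$p)) {
    xj <- data$X[, j + 1L]
    if (all(xj %in% c(0, 1)) && length(unique(xj)) > 1L) {
      rep_j <- classify_separation(data, j)
      if (rep_j$status != "none") warns[[data$covariate_names[j]]] <- rep_j
    }
  }
  if (!is.null(output)) utils::write.csv(tab, output, row.names = FALSE)
  structure(list(fit = fit, table = tab, separation_warnings = warns),
            class = "aft_fit_report")
}

#' @export
print.aft_fit_report <- function(x, ...) {
  print(x$fit)
  for (nm in names(x$separation_warnings)) {
    w <- x$separation_warnings[[nm]]
    cat("\nWARNING: covariate '", nm, "' shows ", w$status,
        if (w$status == "near") "-to-separation" else "",
        " (min cell = ", w$min_cell, ", log-rank p = ",
        format(w$group_test_p, digits = 3), ")\n", sep = "")
  }
  invisible(x)
}
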
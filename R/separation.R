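# Separation / near-to-separation diagnostic for a binary covariate.
#
# Separation (monotone likelihood) in censored data shows up as a binary
# covariate that (fully or partly) splits events from censored subjects: the
# 2x2 table of covariate level by event status has an empty cell, and/or the
# two covariate groups have strongly different survival.  Classification
# rules, applied in order:
#   separation: any cell of the 2x2 table is 0, or the two-group survival
#               difference has p < 0.01;
#   near:       any cell <= 5, or 0.01 <= p < 0.05;
#   none:       otherwise.
# The two-group comparison is the log-rank test.

#' Classify separation with respect to a binary covariate
#'
#' @param data An [surv_data()] object.
#' @param covariate Covariate name or index (into the covariate columns,
#'   intercept excluded).  The column must be coded 0/1.
#' @return An object of class `separation_report`: `table` (2 x 2 counts,
#'   covariate level by event status), `min_cell`, `group_test_p` (log-rank
#'   p-value, `NA` when the test is undefined, e.g. one group empty), and
#'   `status` in `{"none", "near", "separation"}`.
#' @examples
#' set.seed(7)
#' xb <- rbinom(30, 1, 0.5)
#' t <- exp(3 + 1.9 * xb + 0.67 * log(-log(1 - runif(30))))
#' cens <- exp(3.8 + 0.67 * log(-log(1 - runif(30))))
#' d <- surv_data(pmin(t, cens), as.numeric(t <= cens), cbind(xb = xb))
#' classify_separation(d, "xb")
#' @export
classify_separation <- function(data, covariate) {
  stopifnot(inherits(data, "aft_data"))
  if (is.character(covariate)) {
    j <- match(covariate, data$covariate_names)
    if (is.na(j)) stop("no covariate named '", covariate, "'", call. = FALSE)
  } else {
    j <- as.integer(covariate)
    if (j < 1L || j > data$p) stop("covariate index out of range", call. = FALSE)
  }
  xb <- data$X[, j + 1L]
  if (!all(xb %in% c(0, 1)))
    stop("covariate '", data$covariate_names[j], "' is not coded 0/1",
         call. = FALSE)

  tab <- table(factor(xb, levels = c(0, 1)),
               factor(data$delta, levels = c(0, 1)),
               dnn = c("covariate", "event"))
  min_cell <- min(tab)

  p_val <- NA_real_
  if (length(unique(xb)) == 2L && sum(data$delta) >= 1) {
    sd <- tryCatch(
      survival::survdiff(survival::Surv(data$time, data$delta) ~ xb),
      error = function(e) NULL)
    if (!is.null(sd))
      p_val <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }

  status <- if (min_cell == 0 || (is.finite(p_val) && p_val < 0.01))
    "separation"
  else if (min_cell <= 5 || (is.finite(p_val) && p_val < 0.05))
    "near"
  else "none"

  structure(
    list(table = tab, min_cell = min_cell, group_test_p = p_val,
         covariate = data$covariate_names[j], status = status),
    class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("Separation diagnostic for binary covariate '", x$covariate, "'\n",
      sep = "")
  print(x$table)
  cat("minimum cell count:", x$min_cell, "\n")
  cat("log-rank p-value:",
      if (is.finite(x$group_test_p)) format(x$group_test_p, digits = 4)
      else "undefined", "\n")
  cat("status:", x$status, "\n")
  invisible(x)
}
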
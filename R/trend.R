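#' Fit a polynomial trend to yearly median log-concentrations
#'
#' Ordinary least squares of `log(median)` on a centered-year polynomial.
#' Skewed concentration data make the raw medians unsuitable for direct
#' regression, so the fit is on the log scale (base 10 by default). The
#' default quadratic is the minimal model able to produce a single
#' rise-then-fall turning point; its vertex is `-b/(2a)` in calendar years.
#' Years are centered internally to keep the normal equations
#' well-conditioned; reported coefficients are de-centered back to calendar
#' years.
#'
#' @param medians Output of [yearly_medians()] (data frame with `year` and
#'   `median`), or a numeric vector of medians named by year.
#' @param degree Polynomial degree, 2 (quadratic, default) or 3 (cubic).
#' @param log_base `"log10"` (default) or `"ln"`.
#' @return Object of class `cr_trend`: coefficients in calendar years
#'   (`c0 + c1*year + ... `), `vertex_year` (quadratic only; `NA` when the
#'   curvature is numerically zero), `r_squared`, `n_years`, `log_base`,
#'   and the underlying `lm` fit.
#' @export
fit_trend <- function(medians, degree = 2, log_base = c("log10", "ln")) {
  log_base <- match.arg(log_base)
  if (is.numeric(medians) && !is.null(names(medians))) {
    medians <- data.frame(year = as.numeric(names(medians)),
                          median = as.numeric(medians))
  }
  if (!is.data.frame(medians) || !all(c("year", "median") %in% names(medians))) {
    stop_input("medians must be a data frame with columns year and median")
  }
  if (!degree %in% c(2, 3)) stop_config("degree must be 2 or 3")
  medians <- medians[is.finite(medians$median) & medians$median > 0, ]
  n_years <- length(unique(medians$year))
  if (n_years < degree + 1) {
    stop_input("need at least %d distinct years for a degree-%d fit",
               degree + 1, degree)
  }
  logf <- if (log_base == "log10") log10 else log
  y <- logf(medians$median)
  center <- mean(medians$year)
  t <- medians$year - center
  fit <- stats::lm(y ~ stats::poly(t, degree, raw = TRUE))

  # de-center: coefficients of the calendar-year polynomial
  b_cent <- stats::coef(fit)                       # intercept, t, t^2, ...
  coefs <- numeric(degree + 1)                     # calendar powers 0..degree
  for (k in 0:degree) {
    bk <- b_cent[k + 1]
    for (j in 0:k) {
      coefs[j + 1] <- coefs[j + 1] +
        bk * choose(k, j) * (-center)^(k - j)
    }
  }
  names(coefs) <- paste0("year^", 0:degree)

  a <- coefs[degree + 1]
  vertex <- NA_real_
  if (degree == 2) {
    if (abs(a) > 1e-12) vertex <- -coefs[2] / (2 * a)
  }
  structure(list(
    coefficients = coefs,
    vertex_year = unname(vertex),
    r_squared = {
      tss <- sum((y - mean(y))^2)
      if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
    },
    n_years = n_years,
    degree = degree,
    log_base = log_base,
    center = center,
    fit = fit,
    data = medians
  ), class = "cr_trend")
}

#' @export
print.cr_trend <- function(x, digits = 4, ...) {
  base_lab <- if (x$log_base == "log10") "log10" else "ln"
  cat(sprintf("Temporal trend: %s(median Cr) ~ degree-%d polynomial in year (%d years)\n",
              base_lab, x$degree, x$n_years))
  cat("  coefficients (calendar years):\n")
  print(signif(x$coefficients, digits))
  if (x$degree == 2) {
    if (is.na(x$vertex_year)) {
      cat("  vertex: undefined (no curvature)\n")
    } else {
      kind <- if (x$coefficients[3] < 0) "maximum" else "minimum"
      cat(sprintf("  vertex (%s) at year %.1f\n", kind, x$vertex_year))
    }
  }
  cat(sprintf("  R-squared %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
summary.cr_trend <- function(object, ...) {
  print(object)
  cat("\nUnderlying least-squares fit (centered years):\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
coef.cr_trend <- function(object, ...) object$coefficients

#' Predict yearly median concentrations from a fitted trend
#'
#' @param object A [fit_trend()] result.
#' @param years Calendar years to predict at (default: the fitted years).
#' @param scale `"response"` for medians in mg/kg, `"log"` for the log-scale
#'   linear predictor.
#' @param ... Unused.
#' @return Numeric vector named by year.
#' @export
predict.cr_trend <- function(object, years = object$data$year,
                             scale = c("response", "log"), ...) {
  scale <- match.arg(scale)
  powers <- outer(years, 0:object$degree, `^`)
  eta <- drop(powers %*% object$coefficients)
  out <- if (scale == "log") eta
  else if (object$log_base == "log10") 10^eta else exp(eta)
  stats::setNames(out, years)
}

#' @export
residuals.cr_trend <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.cr_trend <- function(object, ...) stats::fitted(object$fit)

#' Plot a fitted temporal trend
#'
#' Yearly median points with the fitted curve, on the log scale.
#'
#' @param x A `cr_trend` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cr_trend <- function(x, ...) {
  logf <- if (x$log_base == "log10") log10 else log
  ylab <- if (x$log_base == "log10") "log10(median Cr, mg/kg)" else "ln(median Cr, mg/kg)"
  graphics::plot(x$data$year, logf(x$data$median),
                 xlab = "sampling year", ylab = ylab, pch = 19, ...)
  yy <- seq(min(x$data$year), max(x$data$year), length.out = 200)
  graphics::lines(yy, predict(x, yy, scale = "log"), col = "firebrick", lwd = 2)
  if (!is.na(x$vertex_year) &&
      x$vertex_year >= min(x$data$year) && x$vertex_year <= max(x$data$year)) {
    graphics::abline(v = x$vertex_year, lty = 2, col = "grey40")
  }
  invisible(x)
}
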
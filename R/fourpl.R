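#' Four-parameter logistic comparator fit
#'
#' Least-squares fit of the 4PL sigmoid
#' `y = D + (A - D) / (1 + (x/C)^B)`
#' to an overlap curve on the original count scale. The lower asymptote D is
#' an independent, model-free-ish comparator for the driver count: it is what
#' the curve "stabilizes at" as isolates accumulate. It is informational only
#' and never feeds back into [soflr_fit()].
#'
#' Fitting uses Levenberg-Marquardt least squares with starting values
#' `A = y_1`, `D = y_n`, `C = median(k)`, `B = 1`, and the box constraint
#' `D >= 0`.
#'
#' @param curve An [overlap_curve()] with at least 4 points.
#' @return An object of class `fourpl_fit` wrapping the converged model, with
#'   a `tidy()` method returning the parameters `lower_asymptote` (D),
#'   `upper_asymptote` (A), `inflection` (C) and `slope` (B).
#' @examples
#' cd <- overlap_curve(c(1673, 850, 574, 433, 346, 285))
#' tidy(fit_4pl(cd))
#' @export
fit_4pl <- function(curve) {
  y <- curve$y
  x <- curve$k
  if (length(y) < 4) stop("4PL needs at least 4 points", call. = FALSE)
  if (max(y) - min(y) < sqrt(.Machine$double.eps) * max(abs(y), 1)) {
    # degenerate flat curve: both asymptotes are the constant, shape
    # parameters are unidentifiable
    return(structure(
      list(
        coef = c(lower_asymptote = y[1], upper_asymptote = y[1],
                 inflection = NA_real_, slope = NA_real_),
        model = NULL, curve = curve, rss = 0
      ),
      class = "fourpl_fit"
    ))
  }
  start <- list(A = y[1], D = y[length(y)], C = stats::median(x), B = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ D + (A - D) / (1 + (x / C)^B),
      data = data.frame(x = x, y = y),
      start = start,
      lower = c(A = -Inf, D = 0, C = .Machine$double.eps, B = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) {
      stop(sprintf(
        "4PL fit failed to converge (start A=%.3g D=%.3g C=%.3g B=%.3g): %s",
        start$A, start$D, start$C, start$B, conditionMessage(e)
      ), call. = FALSE)
    }
  )
  cf <- stats::coef(fit)
  structure(
    list(
      coef = c(lower_asymptote = unname(cf["D"]),
               upper_asymptote = unname(cf["A"]),
               inflection = unname(cf["C"]),
               slope = unname(cf["B"])),
      model = fit, curve = curve,
      rss = sum(stats::resid(fit)^2)
    ),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("4-parameter logistic fit\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fourpl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
predict.fourpl_fit <- function(object, x, ...) {
  cf <- object$coef
  if (is.null(object$model)) return(rep(cf[["lower_asymptote"]], length(x)))
  cf[["lower_asymptote"]] +
    (cf[["upper_asymptote"]] - cf[["lower_asymptote"]]) /
      (1 + (x / cf[["inflection"]])^cf[["slope"]])
}
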
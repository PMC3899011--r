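# Closed-form simple linear regression of log(y - d) on x, vectorized over a
# grid of candidate d. Returns one row per d. Used by both the single-d fit
# and the grid search so the two cannot disagree.
ols_profile <- function(y, x, ds) {
  n <- length(y)
  xbar <- mean(x)
  cx <- x - xbar
  sxx <- sum(cx^2)
  z <- log(outer(ds, y, function(d, yy) yy - d)) # length(ds) x n
  zbar <- rowMeans(z)
  beta <- as.vector(z %*% cx) / sxx
  alpha <- zbar - beta * xbar
  fitted <- outer(beta, cx) + zbar
  ss_res <- rowSums((z - fitted)^2)
  ss_tot <- rowSums((z - zbar)^2)
  r2 <- 1 - ss_res / ss_tot
  tibble::tibble(
    d = ds,
    alpha = alpha,
    beta = beta,
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
    residual_sd = sqrt(ss_res / (n - 2)),
    n_points = n
  )
}

#' Log-linear regression of an overlap curve at a fixed driver count
#'
#' Fits `log(y_k - d) = alpha + beta * k` by ordinary least squares for a
#' given candidate driver count d. Under the driver/passenger model the
#' passenger component of the overlap decays geometrically, so on the log
#' scale the d-corrected curve is linear with intercept `log(T)` and slope
#' `log(p)`.
#'
#' @param curve An [overlap_curve()] (any data frame with columns `k`, `y`).
#' @param d Candidate driver count; every `y_k` must exceed `d` so the log is
#'   defined.
#' @return A one-row tibble with columns `d`, `alpha`, `beta`, `r2`,
#'   `adj_r2` (`1 - (1 - r2) * (n - 1) / (n - 2)`), `residual_sd`, and
#'   `n_points`.
#' @examples
#' cd <- overlap_curve(c(1673, 850, 574, 433, 346, 285))
#' fit_linear_given_d(cd, d = 233)
#' @export
fit_linear_given_d <- function(curve, d) {
  y <- curve$y
  x <- curve$k
  if (length(y) < 3) {
    stop("at least 3 curve points are needed to fit the regression",
         call. = FALSE)
  }
  if (!is.numeric(d) || length(d) != 1 || d < 0 || d != floor(d)) {
    stop("`d` must be a single nonnegative integer", call. = FALSE)
  }
  if (any(y <= d)) {
    stop(sprintf("log(y - d) undefined: some y_k <= d = %d", as.integer(d)),
         call. = FALSE)
  }
  ols_profile(y, x, as.numeric(d))
}

#' Estimate the driver-set size by sequential log-linear fitting (SOFLR)
#'
#' Under the driver/passenger model the mean k-isolate overlap is
#' `y_k = d + T * p^k`: d genes are activated in every isolate (drivers) while
#' each of T passenger genes is activated independently with probability p per
#' isolate, so the passenger overlap decays geometrically. SOFLR estimates d
#' by trying every integer candidate in `[d_min, d_max]`, fitting
#' `log(y_k - d)` on k by least squares, and keeping the d with the highest
#' adjusted R-squared. The regression coefficients at the optimum recover the
#' passenger parameters as `T = exp(alpha)` and `p = exp(beta)`.
#'
#' Adjusted R-squared values within `tie_tol` of the maximum are treated as
#' ties and resolved to the smallest d (the conservative reading: fewer
#' drivers).
#'
#' @param curve An [overlap_curve()] with at least 3 points and strictly
#'   positive y.
#' @param d_min,d_max Integer candidate range; the default upper limit
#'   `ceiling(min(y)) - 1` is the largest integer strictly below every `y_k`,
#'   so the log stays defined (for integer curves this is `min(y) - 1`).
#' @param tie_tol Absolute adjusted-R-squared tolerance within which candidate
#'   d values are considered tied.
#' @return An object of class `soflr_fit`: a list with the selected `d_hat`,
#'   regression coefficients (`alpha`, `beta`) and their transforms (`T_hat`,
#'   `p_hat`), fit statistics (`r2`, `adj_r2`, `residual_sd`), the full
#'   adjusted-R-squared `profile` (a tibble over d), and the input `curve`.
#'   Supports [generics::tidy()], [generics::glance()], `predict()`, and
#'   [ggplot2::autoplot()].
#' @examples
#' cd <- overlap_curve(c(1673, 850, 574, 433, 346, 285))
#' fit <- soflr_fit(cd)
#' glance(fit)
#' @export
soflr_fit <- function(curve, d_min = 0, d_max = NULL, tie_tol = 1e-12) {
  y <- curve$y
  x <- curve$k
  if (length(y) < 3) {
    stop("at least 3 curve points are needed", call. = FALSE)
  }
  if (any(y <= 0)) stop("overlap counts must be strictly positive", call. = FALSE)
  if (min(y) < 1) {
    stop("empty candidate range: the smallest overlap count is below 1",
         call. = FALSE)
  }
  d_max <- d_max %||% (ceiling(min(y)) - 1)
  d_min <- as.integer(d_min)
  d_max <- as.integer(d_max)
  if (d_max < d_min) {
    stop("empty candidate range: need d_max >= d_min", call. = FALSE)
  }
  if (d_max >= min(y)) {
    stop("d_max must lie strictly below min(y)", call. = FALSE)
  }
  profile <- ols_profile(y, x, as.numeric(d_min:d_max))
  ok <- is.finite(profile$adj_r2)
  if (!any(ok)) stop("no candidate d gave a finite fit", call. = FALSE)
  best <- max(profile$adj_r2[ok])
  d_hat <- min(profile$d[ok & profile$adj_r2 >= best - tie_tol])
  at <- profile[profile$d == d_hat, ]
  if (at$beta >= 0) {
    warning("fitted slope is nonnegative: the curve does not decay",
            call. = FALSE)
  }
  structure(
    list(
      d_hat = as.integer(d_hat),
      alpha = at$alpha, beta = at$beta,
      T_hat = exp(at$alpha), p_hat = exp(at$beta),
      r2 = at$r2, adj_r2 = at$adj_r2, residual_sd = at$residual_sd,
      n = length(y), x_mean = mean(x), x_ss = sum((x - mean(x))^2),
      profile = profile[, c("d", "adj_r2")],
      curve = curve
    ),
    class = "soflr_fit"
  )
}

#' @export
print.soflr_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "SOFLR fit over %d isolates\n",
      "  d_hat (driver count) : %d\n",
      "  T_hat (passengers)   : %.1f\n",
      "  p_hat (per-isolate)  : %.4f\n",
      "  adjusted R-squared   : %.4f\n"
    ),
    x$n, x$d_hat, x$T_hat, x$p_hat, x$adj_r2
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.soflr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("d_hat", "alpha", "beta", "T_hat", "p_hat"),
    estimate = c(x$d_hat, x$alpha, x$beta, x$T_hat, x$p_hat)
  )
}

#' @exportS3Method generics::glance
glance.soflr_fit <- function(x, ...) {
  tibble::tibble(
    d_hat = x$d_hat, T_hat = x$T_hat, p_hat = x$p_hat,
    r2 = x$r2, adj_r2 = x$adj_r2, residual_sd = x$residual_sd,
    n_isolates = x$n
  )
}

#' Predicted common-gene count at a hypothetical isolate number
#'
#' Evaluates the fitted decay `d_hat + T_hat * p_hat^x`. The prediction is
#' strictly decreasing in x when `0 < p_hat < 1` and tends to `d_hat` as x
#' grows.
#'
#' @param fit A [soflr_fit()] object.
#' @param x Positive integer isolate count(s); vectorized.
#' @return Numeric vector of predicted mean overlap counts.
#' @export
predict_common_genes <- function(fit, x) {
  stopifnot(inherits(fit, "soflr_fit"), all(x >= 1))
  if (fit$p_hat >= 1) {
    warning("p_hat >= 1: fitted curve does not decay", call. = FALSE)
  }
  fit$d_hat + fit$T_hat * fit$p_hat^x
}

#' @export
predict.soflr_fit <- function(object, x, ...) predict_common_genes(object, x)

#' Smallest isolate count at which the passenger overlap is resolved away
#'
#' Scans increasing isolate counts x and, at each, forms the two-sided
#' confidence interval for the mean response of the log-scale regression
#' (Student-t quantile on n - 2 degrees of freedom), mapped back to the count
#' scale as `d_hat + exp(bound)`. Reports the smallest x at which the upper
#' bound exceeds `d_hat` by less than `tol` — the point where the expected
#' common-gene count has collapsed onto the driver count, so further isolates
#' no longer change the common set.
#'
#' The interval convention (mean-response CI on the log scale, t quantile) and
#' the stopping tolerance are package choices; both are exposed as arguments
#' because conventions differ across tools.
#'
#' @param fit A [soflr_fit()] with negative slope.
#' @param confidence Two-sided confidence level, default 0.95.
#' @param tol Count-scale tolerance, default 0.5 (the predicted overlap rounds
#'   to `d_hat`).
#' @param x_max Largest isolate count to scan.
#' @return A one-row tibble with `n_required`, the interval bounds
#'   `ci_lower`/`ci_upper` for the predicted common-gene count at that x, and
#'   the `confidence` and `tol` used. `n_required` is NA (with a warning) if
#'   no x up to `x_max` meets the tolerance.
#' @export
required_isolates <- function(fit, confidence = 0.95, tol = 0.5,
                              x_max = 1000) {
  stopifnot(inherits(fit, "soflr_fit"))
  if (fit$beta >= 0) {
    stop("required_isolates needs a decaying fit (beta < 0)", call. = FALSE)
  }
  stopifnot(confidence > 0, confidence < 1, tol > 0, x_max >= 1)
  xs <- seq_len(x_max)
  tcrit <- stats::qt(1 - (1 - confidence) / 2, df = fit$n - 2)
  se <- fit$residual_sd * sqrt(1 / fit$n + (xs - fit$x_mean)^2 / fit$x_ss)
  mid <- fit$alpha + fit$beta * xs
  upper <- fit$d_hat + exp(mid + tcrit * se)
  lower <- fit$d_hat + exp(mid - tcrit * se)
  hit <- which(upper - fit$d_hat < tol)
  if (length(hit) == 0) {
    warning(sprintf("tolerance not reached within x_max = %d isolates", x_max),
            call. = FALSE)
    return(tibble::tibble(
      n_required = NA_integer_, ci_lower = NA_real_, ci_upper = NA_real_,
      confidence = confidence, tol = tol
    ))
  }
  n_req <- hit[1]
  tibble::tibble(
    n_required = as.integer(n_req),
    ci_lower = lower[n_req], ci_upper = upper[n_req],
    confidence = confidence, tol = tol
  )
}

#' Adjusted R-squared profile plot for a SOFLR grid search
#'
#' @param fit A [soflr_fit()] object.
#' @return A ggplot of adjusted R-squared against candidate d, with the
#'   selected `d_hat` marked.
#' @export
plot_d_profile <- function(fit) {
  stopifnot(inherits(fit, "soflr_fit"))
  ggplot2::ggplot(fit$profile, ggplot2::aes(x = .data$d, y = .data$adj_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = fit$d_hat, linetype = "dashed") +
    ggplot2::labs(
      x = "candidate driver count d",
      y = "adjusted R-squared",
      title = sprintf("SOFLR profile: d_hat = %d", fit$d_hat)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.soflr_fit <- function(object, ...) {
  obs <- tibble::tibble(k = object$curve$k, y = object$curve$y)
  xs <- seq(1, max(obs$k) + 4, by = 0.1)
  pred <- tibble::tibble(k = xs, y = object$d_hat + object$T_hat * object$p_hat^xs)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$k, y = .data$y)) +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$d_hat, linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "number of isolates",
      y = "mean overlapping activated probes",
      title = sprintf("Fitted overlap decay: y = %d + %.0f * %.3f^x",
                      object$d_hat, object$T_hat, object$p_hat)
    ) +
    ggplot2::theme_minimal()
}
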
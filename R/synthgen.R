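#' Simulate an activation matrix under the driver/passenger model
#'
#' Generates binary activation calls for a probe universe partitioned into
#' three disjoint classes: `d` driver probes active in every isolate, `T`
#' passenger probes each active in each isolate independently with
#' probability `p`, and `n_nonresponsive` probes never active. The expected
#' mean k-way overlap of such a matrix is `d + T * p^k`.
#'
#' @param d Driver count (active in all isolates).
#' @param T_genes Passenger count.
#' @param p Per-isolate passenger activation probability in `[0, 1]`; the
#'   boundaries are handled deterministically (0 = never, 1 = always).
#' @param n_isolates Number of isolates (columns), at least 1.
#' @param n_nonresponsive Count of never-active filler probes.
#' @param direction Direction label to attach to the calls.
#' @param seed Optional integer seed.
#' @return A list with elements `activation` (an [activation_matrix()]) and
#'   `truth` (class `synthetic_truth`: the disjoint `driver_ids`,
#'   `passenger_ids`, `nonresponsive_ids`, and the generating `config`).
#' @examples
#' sim <- simulate_activation(d = 20, T_genes = 100, p = 0.3,
#'                            n_isolates = 5, seed = 1)
#' mean_overlap_curve(sim$activation)
#' @export
simulate_activation <- function(d, T_genes, p, n_isolates,
                                n_nonresponsive = 0,
                                direction = c("induced", "repressed"),
                                seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(d >= 0, T_genes >= 0, n_nonresponsive >= 0, n_isolates >= 1,
            p >= 0, p <= 1)
  d <- as.integer(d); T_genes <- as.integer(T_genes)
  n_nonresponsive <- as.integer(n_nonresponsive)
  n_isolates <- as.integer(n_isolates)
  total <- d + T_genes + n_nonresponsive
  if (total == 0) stop("no probes to simulate", call. = FALSE)
  driver_ids <- if (d > 0) sprintf("driver_%05d", seq_len(d)) else character(0)
  passenger_ids <- if (T_genes > 0) {
    sprintf("passenger_%05d", seq_len(T_genes))
  } else {
    character(0)
  }
  nonresp_ids <- if (n_nonresponsive > 0) {
    sprintf("nonresponsive_%05d", seq_len(n_nonresponsive))
  } else {
    character(0)
  }
  calls <- matrix(FALSE, nrow = total, ncol = n_isolates)
  if (d > 0) calls[seq_len(d), ] <- TRUE
  if (T_genes > 0) {
    calls[d + seq_len(T_genes), ] <- with_optional_seed(seed, {
      matrix(stats::runif(T_genes * n_isolates) < p,
             nrow = T_genes, ncol = n_isolates)
    })
  }
  act <- activation_matrix(
    calls, direction = direction,
    probe_ids = c(driver_ids, passenger_ids, nonresp_ids),
    isolate_ids = sprintf("isolate_%d", seq_len(n_isolates))
  )
  truth <- structure(
    list(
      driver_ids = driver_ids,
      passenger_ids = passenger_ids,
      nonresponsive_ids = nonresp_ids,
      config = list(d = d, T_genes = T_genes, p = p,
                    n_isolates = n_isolates,
                    n_nonresponsive = n_nonresponsive, seed = seed)
    ),
    class = "synthetic_truth"
  )
  list(activation = act, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> d = %d drivers, T = %d passengers (p = %g), %d non-responsive\n",
    length(x$driver_ids), length(x$passenger_ids), x$config$p,
    length(x$nonresponsive_ids)
  ))
  invisible(x)
}

#' Lift activation calls to a synthetic expression table
#'
#' Builds a positive-intensity expression table whose fold changes reproduce
#' the supplied activation calls exactly: control samples are drawn from a
#' log-normal baseline per probe; each transformed sample's value is the
#' realised control mean times a fold factor drawn at least `margin` beyond
#' the calling threshold when the call is TRUE, and strictly inside the
#' no-call band `(1/threshold, threshold)` when FALSE. By construction,
#' `call_activation()` on the result recovers the input matrix for any
#' `margin > 0`.
#'
#' @param act An [activation_matrix()] to reproduce.
#' @param n_controls Number of control replicate columns (default 3).
#' @param control_meanlog,control_sdlog Log-scale location and spread of the
#'   per-probe baseline intensity.
#' @param margin Fold-change safety margin beyond the threshold for TRUE
#'   calls (and inside the band for FALSE calls); must be in (0, 1).
#' @param threshold Calling threshold the table is built against (default 2).
#' @param seed Optional integer seed.
#' @return A tibble with `probe_id`, `control_*` columns and one column per
#'   isolate, carrying the control column names in attribute `"controls"`.
#' @examples
#' sim <- simulate_activation(d = 5, T_genes = 20, p = 0.4, n_isolates = 3,
#'                            seed = 1)
#' expr <- simulate_expression(sim$activation, seed = 2)
#' act2 <- call_activation(expr, attr(expr, "controls"))
#' identical(act2$calls, sim$activation$calls)
#' @export
simulate_expression <- function(act, n_controls = 3,
                                control_meanlog = log(500),
                                control_sdlog = 0.25,
                                margin = 0.2, threshold = 2, seed = NULL) {
  stopifnot(inherits(act, "activation_matrix"), n_controls >= 1,
            threshold > 1)
  if (!is.numeric(margin) || margin <= 0) {
    stop("`margin` must be positive", call. = FALSE)
  }
  if (margin >= 1) stop("`margin` must be below 1", call. = FALSE)
  n_probes <- nrow(act$calls)
  n_iso <- ncol(act$calls)
  with_optional_seed(seed, {
    base <- stats::rlnorm(n_probes, control_meanlog, control_sdlog)
    ctrl <- matrix(
      base * stats::rlnorm(n_probes * n_controls, 0, control_sdlog / 4),
      nrow = n_probes, ncol = n_controls
    )
    ctrl_mean <- rowMeans(ctrl)
    # fold factors: active induced in [thr + margin, 2 thr]; active repressed
    # mirrored below 1/(thr + margin); inactive strictly inside the band
    u <- matrix(stats::runif(n_probes * n_iso), nrow = n_probes)
    fc <- matrix(NA_real_, n_probes, n_iso)
    on <- act$calls
    if (act$direction == "induced") {
      fc[on] <- (threshold + margin) + u[on] * threshold
    } else {
      fc[on] <- 1 / ((threshold + margin) + u[on] * threshold)
    }
    lo <- 1 / (threshold * (1 - margin / 2))
    hi <- threshold * (1 - margin / 2)
    fc[!on] <- lo + u[!on] * (hi - lo)
    vals <- fc * ctrl_mean
    out <- tibble::as_tibble(as.data.frame(cbind(ctrl, vals)))
    names(out) <- c(sprintf("control_%d", seq_len(n_controls)),
                    colnames(act$calls))
    out <- tibble::add_column(out, probe_id = rownames(act$calls),
                              .before = 1)
    attr(out, "controls") <- sprintf("control_%d", seq_len(n_controls))
    out
  })
}

#' End-to-end parameter recovery on synthetic data
#'
#' The package's headline self-validation: simulate an activation matrix with
#' known (d, T, p), reduce it to its exact mean overlap curve, fit SOFLR, and
#' compare estimates with the generating truth.
#'
#' @inheritParams simulate_activation
#' @return A list with the fitted `soflr_fit` object (`fit`), the simulated
#'   `curve`, and `summary`, a one-row tibble holding truth, estimates and
#'   errors (`d_error = d_hat - d`, etc.).
#' @examples
#' end_to_end_recovery(d = 200, T_genes = 5000, p = 0.3, n_isolates = 10,
#'                     seed = 1)$summary
#' @export
end_to_end_recovery <- function(d, T_genes, p, n_isolates,
                                n_nonresponsive = 0, seed = NULL) {
  stopifnot(n_isolates >= 4)
  sim <- simulate_activation(d, T_genes, p, n_isolates,
                             n_nonresponsive, seed = seed)
  curve <- mean_overlap_curve(sim$activation)
  fit <- soflr_fit(curve)
  list(
    fit = fit,
    curve = curve,
    summary = tibble::tibble(
      d = as.integer(d), d_hat = fit$d_hat, d_error = fit$d_hat - d,
      T_genes = as.integer(T_genes), T_hat = fit$T_hat,
      p = p, p_hat = fit$p_hat,
      adj_r2 = fit$adj_r2, n_isolates = as.integer(n_isolates),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
  )
}
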
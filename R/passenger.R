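#' Minimum isolates until the passenger overlap is empty (single run)
#'
#' Simulates the pure passenger null: each of `T` passenger genes is active
#' in each isolate independently with probability `p`. Isolates are added one
#' at a time and the running intersection of active sets is tracked; the run
#' ends at the first isolate count (starting at 1, the first isolate's own
#' active set) at which the intersection is empty.
#'
#' The default implementation thins gene counts: the first isolate's active
#' set has Binomial(T, p) genes, and each gene in the running intersection
#' survives the next isolate independently with probability p, so the
#' intersection size is thinned binomially. This is distributionally
#' identical to materialising full T-gene activation vectors
#' (`method = "naive"`, kept for verification) but uses O(1) memory.
#'
#' @param T_genes Number of passenger genes (T), a nonnegative integer.
#' @param p Per-isolate activation probability in `[0, 1]`.
#' @param max_isolates Cap on the isolate count; reaching it before the
#'   intersection empties (possible only for p near 1) is an error that
#'   reports the cap.
#' @param method `"thin"` (default) or `"naive"`.
#' @return The minimum isolate count (integer >= 1).
#' @examples
#' set.seed(1)
#' min_isolates_single_run(50, 0.5)
#' @export
min_isolates_single_run <- function(T_genes, p, max_isolates = 10000,
                                    method = c("thin", "naive")) {
  method <- match.arg(method)
  stopifnot(T_genes >= 0, T_genes == floor(T_genes), p >= 0, p <= 1,
            max_isolates >= 1)
  if (method == "thin") {
    size <- stats::rbinom(1L, as.integer(T_genes), p)
    n <- 1L
    while (size > 0L) {
      if (n >= max_isolates) {
        stop(sprintf(
          "running intersection still nonempty at max_isolates = %d",
          as.integer(max_isolates)
        ), call. = FALSE)
      }
      n <- n + 1L
      size <- stats::rbinom(1L, size, p)
    }
    n
  } else {
    inter <- which(stats::runif(T_genes) < p)
    n <- 1L
    while (length(inter) > 0L) {
      if (n >= max_isolates) {
        stop(sprintf(
          "running intersection still nonempty at max_isolates = %d",
          as.integer(max_isolates)
        ), call. = FALSE)
      }
      n <- n + 1L
      active <- which(stats::runif(T_genes) < p)
      inter <- intersect(inter, active)
    }
    n
  }
}

#' Mean minimum isolate count over replicate passenger simulations
#'
#' Repeats [min_isolates_single_run()] and summarises the replicate values
#' with their mean and standard error (SD / sqrt(replicates)).
#'
#' @inheritParams min_isolates_single_run
#' @param replicates Number of independent replicate runs (default 10).
#' @param seed Optional integer seed for reproducibility.
#' @return A one-row tibble with columns `T_genes`, `p`, `replicates`,
#'   `mean_min_isolates`, `se`, and a list-column `replicate_values` holding
#'   the raw integer vector.
#' @examples
#' mean_min_isolates(5000, 0.3, seed = 1)
#' @export
mean_min_isolates <- function(T_genes, p, replicates = 10,
                              max_isolates = 10000, seed = NULL,
                              method = c("thin", "naive")) {
  method <- match.arg(method)
  stopifnot(replicates >= 1)
  vals <- with_optional_seed(seed, {
    vapply(seq_len(replicates), function(i) {
      min_isolates_single_run(T_genes, p, max_isolates, method)
    }, integer(1))
  })
  tibble::tibble(
    T_genes = as.integer(T_genes), p = p, replicates = as.integer(replicates),
    mean_min_isolates = mean(vals),
    se = if (replicates > 1) stats::sd(vals) / sqrt(replicates) else 0,
    replicate_values = list(vals)
  )
}

#' Grid sweep of the passenger minimum-isolate simulation
#'
#' Full factorial sweep of [mean_min_isolates()] over passenger-set sizes and
#' activation probabilities, with an independent reproducible RNG substream
#' per grid cell derived from the master seed.
#'
#' @param T_values,p_values Nonempty numeric vectors defining the grid.
#' @inheritParams mean_min_isolates
#' @return A tidy tibble with one row per (T, p) cell: `T_genes`, `p`,
#'   `replicates`, `mean_min_isolates`, `se`, `replicate_values`.
#' @examples
#' sweep_passenger_grid(c(1000, 5000), c(0.1, 0.3), seed = 1)
#' @export
sweep_passenger_grid <- function(T_values, p_values, replicates = 10,
                                 max_isolates = 10000, seed = NULL) {
  stopifnot(length(T_values) >= 1, length(p_values) >= 1)
  grid <- tidyr::expand_grid(T_genes = T_values, p = p_values)
  seeds <- derive_seeds(seed, nrow(grid))
  purrr::pmap_dfr(
    list(grid$T_genes, grid$p, seeds),
    function(tt, pp, s) {
      mean_min_isolates(tt, pp, replicates = replicates,
                        max_isolates = max_isolates, seed = s)
    }
  )
}

#' Error-bar plot of a passenger sweep
#'
#' @param sweep Output of [sweep_passenger_grid()].
#' @return A ggplot: mean minimum isolate count against T, one line per p,
#'   with standard-error bars.
#' @export
plot_passenger_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(
    x = .data$T_genes, y = .data$mean_min_isolates,
    colour = factor(.data$p), group = factor(.data$p)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_min_isolates - .data$se,
      ymax = .data$mean_min_isolates + .data$se
    ), width = 0.02 * diff(range(sweep$T_genes, 1))) +
    ggplot2::labs(
      x = "passenger-set size T",
      y = "isolates required for empty passenger overlap",
      colour = "p"
    ) +
    ggplot2::theme_minimal()
}

#' Closed-form distribution of the passenger minimum isolate count
#'
#' Each gene independently stays in the running intersection through k
#' isolates with probability `p^k`, so
#' `P(min_isolates <= k) = (1 - p^k)^T`. Provided as an analytic reference
#' for the simulator.
#'
#' @inheritParams min_isolates_single_run
#' @param k Integer isolate count(s); vectorized.
#' @return `P(min_isolates <= k)`.
#' @export
pmin_isolates <- function(k, T_genes, p) {
  stopifnot(all(k >= 0), T_genes >= 0, p >= 0, p <= 1)
  (1 - p^k)^T_genes
}
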
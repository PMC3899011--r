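#' Draw k-way overlap sizes under the random-subset null
#'
#' Simulates the size of the common intersection of uniformly random probe
#' subsets of fixed sizes drawn from a shared universe. The default sampler
#' never materialises the subsets: conditioning on the running intersection
#' having size m after the first i subsets, the next subset of size s covers
#' those m probes hypergeometrically, so the chain
#' `m_{i+1} ~ Hypergeometric(universe_size, m_i, s_{i+1})` is distributionally
#' identical to explicit set sampling and costs O(k) per draw. The explicit
#' sampler (`method = "sets"`) is retained for verification.
#'
#' @param universe_size Total number of probes on the array.
#' @param subset_sizes Integer vector of per-isolate activated-probe counts,
#'   each between 0 and `universe_size`.
#' @param reps Number of independent draws.
#' @param method `"chain"` (default, vectorized hypergeometric chain) or
#'   `"sets"` (naive explicit subset sampling, slow; for cross-checks).
#' @return Integer vector of `reps` simulated intersection sizes.
#' @examples
#' set.seed(1)
#' sample_null_overlap(10, c(5, 5), reps = 5)
#' @export
sample_null_overlap <- function(universe_size, subset_sizes, reps = 1,
                                method = c("chain", "sets")) {
  method <- match.arg(method)
  check_null_config(universe_size, subset_sizes)
  stopifnot(reps >= 1)
  if (method == "chain") {
    cur <- rep.int(as.integer(subset_sizes[1]), reps)
    for (s in subset_sizes[-1]) {
      # rhyper draws the number of the current intersection's probes that the
      # next random subset of size s happens to cover
      cur <- stats::rhyper(reps, m = cur, n = universe_size - cur, k = s)
    }
    as.integer(cur)
  } else {
    vapply(seq_len(reps), function(i) {
      sets <- lapply(subset_sizes, function(s) {
        sample.int(universe_size, s)
      })
      length(Reduce(intersect, sets))
    }, integer(1))
  }
}

check_null_config <- function(universe_size, subset_sizes) {
  if (!is.numeric(universe_size) || length(universe_size) != 1 ||
      universe_size < 1 || universe_size != floor(universe_size)) {
    stop("`universe_size` must be a positive integer", call. = FALSE)
  }
  if (length(subset_sizes) < 1 || any(subset_sizes < 0) ||
      any(subset_sizes > universe_size) ||
      any(subset_sizes != floor(subset_sizes))) {
    stop("`subset_sizes` must be integers in [0, universe_size]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Expected overlap under the random-subset null
#'
#' Each probe lies in the random subset of size `s_i` with probability
#' `s_i / N` independently across subsets, so the expected intersection size
#' is `N * prod(s_i / N)`. Used as an analytic anchor for the Monte Carlo
#' sampler.
#'
#' @inheritParams sample_null_overlap
#' @return Expected intersection size (a real number).
#' @export
expected_null_overlap <- function(universe_size, subset_sizes) {
  check_null_config(universe_size, subset_sizes)
  universe_size * prod(subset_sizes / universe_size)
}

#' Monte Carlo significance of an observed multi-set overlap
#'
#' Tests whether an observed all-isolate overlap could plausibly arise from
#' independent random probe subsets of the observed per-isolate sizes.
#' Exceedance is counted as simulated >= observed (the conservative Monte
#' Carlo convention) and the p-value uses the add-one estimator
#' `(b + 1) / (reps + 1)`; when no draw reaches the observed overlap the
#' paper-style bound `1 / reps` is also reported.
#'
#' @inheritParams sample_null_overlap
#' @param observed Observed intersection size (nonnegative integer).
#' @param seed Integer seed; the draw stream is consumed in subset order
#'   within each vectorized pass, so results are reproducible per
#'   (seed, reps, method).
#' @return An object of class `overlap_null` with fields `observed`,
#'   `exceed_count`, `max_simulated`, `mean_simulated`, `p_estimate`,
#'   `p_upper_bound`, `expected`, `reps`, and `seed`. Has `tidy()` and
#'   `glance()` methods.
#' @examples
#' overlap_significance(100, c(30, 30, 30), observed = 10, reps = 1e4, seed = 1)
#' @export
overlap_significance <- function(universe_size, subset_sizes, observed,
                                 reps = 1e6, seed = NULL,
                                 method = c("chain", "sets")) {
  method <- match.arg(method)
  stopifnot(observed >= 0, observed == floor(observed))
  reps <- as.integer(reps)
  draws <- with_optional_seed(seed, {
    sample_null_overlap(universe_size, subset_sizes, reps, method)
  })
  b <- sum(draws >= observed)
  structure(
    list(
      observed = as.integer(observed),
      exceed_count = as.integer(b),
      max_simulated = max(draws),
      mean_simulated = mean(draws),
      p_estimate = (b + 1) / (reps + 1),
      p_upper_bound = if (b == 0) 1 / reps else (b + 1) / (reps + 1),
      expected = expected_null_overlap(universe_size, subset_sizes),
      universe_size = as.integer(universe_size),
      subset_sizes = as.integer(subset_sizes),
      reps = reps,
      seed = seed
    ),
    class = "overlap_null"
  )
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Random-subset overlap null (%d reps, universe %d)\n",
      "  observed overlap   : %d\n",
      "  max simulated      : %d\n",
      "  mean simulated     : %.4g (expected %.4g)\n",
      "  exceedances (>=)   : %d\n",
      "  p (add-one)        : %.3g\n"
    ),
    x$reps, x$universe_size, x$observed, x$max_simulated,
    x$mean_simulated, x$expected, x$exceed_count, x$p_estimate
  ))
  if (x$exceed_count == 0) {
    cat(sprintf("  p bound            : < %.1g\n", x$p_upper_bound))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.overlap_null <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, exceed_count = x$exceed_count,
    max_simulated = x$max_simulated, mean_simulated = x$mean_simulated,
    expected = x$expected, p_estimate = x$p_estimate,
    p_upper_bound = x$p_upper_bound, reps = x$reps
  )
}

#' @exportS3Method generics::tidy
tidy.overlap_null <- function(x, ...) glance.overlap_null(x, ...)
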
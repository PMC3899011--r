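# Independent oracles used across tests. These deliberately use the naive,
# obviously-correct route (loops, enumeration, lm, explicit sets) so they
# stay independent of the package implementation they check.

cd_curve <- function() overlap_curve(c(1673, 850, 574, 433, 346, 285))

random_activation <- function(n_probes, n_isolates, prob = 0.5,
                              direction = "induced") {
  calls <- matrix(stats::runif(n_probes * n_isolates) < prob,
                  nrow = n_probes)
  activation_matrix(calls, direction = direction)
}

# Mean k-way overlap by explicit enumeration of all C(n, k) isolate subsets
enum_overlap_curve <- function(act) {
  calls <- act$calls
  n <- ncol(calls)
  vapply(seq_len(n), function(k) {
    subsets <- utils::combn(n, k, simplify = FALSE)
    mean(vapply(subsets, function(s) {
      sum(rowSums(calls[, s, drop = FALSE]) == k)
    }, numeric(1)))
  }, numeric(1))
}

# Reference OLS of log(y - d, base `base`) on x via stats::lm
lm_log_fit <- function(y, x, d, base = exp(1)) {
  z <- log(y - d, base = base)
  fit <- stats::lm(z ~ x)
  s <- summary(fit)
  list(
    alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
    r2 = s$r.squared, adj_r2 = s$adj.r.squared, residual_sd = s$sigma
  )
}

# Exact pmf of the k-way random-subset intersection size via the
# hypergeometric chain convolved step by step
exact_null_pmf <- function(universe_size, subset_sizes) {
  pmf <- rep(0, universe_size + 1)
  pmf[subset_sizes[1] + 1] <- 1
  for (s in subset_sizes[-1]) {
    new <- rep(0, universe_size + 1)
    for (m in which(pmf > 0) - 1) {
      j <- 0:m
      new[j + 1] <- new[j + 1] +
        pmf[m + 1] * stats::dhyper(j, m, universe_size - m, s)
    }
    pmf <- new
  }
  pmf # indexed by size 0..universe_size
}
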
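#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Evaluate `code` under a fixed seed when one is given, without touching the
# caller's RNG state; with seed = NULL the global stream is used as-is.
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Deterministic per-cell child seeds (< 2^31) for grid sweeps
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(withr::with_seed(as.integer(seed),
                           sample.int(.Machine$integer.max - 1L, n)))
}
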
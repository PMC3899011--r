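#' Construct an overlap-decay curve
#'
#' An overlap curve records the mean size `y_k` of the k-way intersection of
#' activated-gene sets over all subsets of k isolates, for k = 1..n. It is the
#' input that [soflr_fit()] models as `y = d + T * p^k`.
#'
#' @param y Numeric vector of mean overlap counts, ordered by k = 1..n. All
#'   values must be finite and nonnegative; a curve that increases anywhere
#'   raises a warning, since intersections can only shrink as isolates are
#'   added.
#' @param direction Which activation direction the curve summarises,
#'   `"induced"` or `"repressed"`.
#'
#' @return A tibble of class `overlap_curve` with integer column `k` and
#'   numeric column `y`, carrying the direction as an attribute.
#' @examples
#' overlap_curve(c(1673, 850, 574, 433, 346, 285))
#' @export
overlap_curve <- function(y, direction = c("induced", "repressed")) {
  direction <- match.arg(direction)
  y <- as.numeric(y)
  if (length(y) < 1L) {
    stop("an overlap curve needs at least one point", call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y))) {
    stop("overlap counts must be finite", call. = FALSE)
  }
  if (any(y < 0)) {
    stop("overlap counts must be nonnegative", call. = FALSE)
  }
  if (length(y) > 1L && any(diff(y) > 0)) {
    warning("overlap curve is not nonincreasing in k", call. = FALSE)
  }
  out <- tibble::tibble(k = seq_along(y), y = y)
  attr(out, "direction") <- direction
  class(out) <- c("overlap_curve", class(out))
  out
}

#' @export
print.overlap_curve <- function(x, ...) {
  cat(sprintf(
    "<overlap_curve> %s, n = %d isolates\n",
    attr(x, "direction"), nrow(x)
  ))
  NextMethod()
}

#' Read or write an overlap curve as CSV
#'
#' The on-disk format is a two-column CSV with header `k,y`, rows ordered or
#' orderable by k = 1..n.
#'
#' @param path File path.
#' @param direction Activation direction to attach on read.
#' @return `read_overlap_curve()` returns an [overlap_curve()];
#'   `write_overlap_curve()` returns `path` invisibly.
#' @export
read_overlap_curve <- function(path, direction = c("induced", "repressed")) {
  direction <- match.arg(direction)
  df <- readr::read_csv(path, col_types = readr::cols(
    k = readr::col_integer(), y = readr::col_double()
  ))
  if (!all(c("k", "y") %in% names(df))) {
    stop("curve file must have columns 'k' and 'y'", call. = FALSE)
  }
  df <- df[order(df$k), ]
  if (!identical(as.integer(df$k), seq_len(nrow(df)))) {
    stop("curve file must cover k = 1..n without gaps", call. = FALSE)
  }
  overlap_curve(df$y, direction = direction)
}

#' @rdname read_overlap_curve
#' @param curve An [overlap_curve()] (or any data frame with columns k, y).
#' @export
write_overlap_curve <- function(curve, path) {
  readr::write_csv(tibble::tibble(k = curve$k, y = curve$y), path)
  invisible(path)
}
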
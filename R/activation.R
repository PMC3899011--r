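#' Construct an activation matrix
#'
#' Binary activation calls (one direction at a time) for probes across
#' independently transformed isolates: the working representation for overlap
#' counting and for the synthetic generator.
#'
#' @param calls Logical matrix, probes in rows and isolates in columns.
#' @param direction `"induced"` or `"repressed"`; a single object never mixes
#'   the two.
#' @param probe_ids,isolate_ids Optional identifier vectors; default to the
#'   dimnames of `calls`, or generated `probe_*` / `isolate_*` labels.
#'
#' @return An object of class `activation_matrix`.
#' @export
activation_matrix <- function(calls, direction = c("induced", "repressed"),
                              probe_ids = NULL, isolate_ids = NULL) {
  direction <- match.arg(direction)
  if (!is.matrix(calls) || !is.logical(calls)) {
    stop("`calls` must be a logical matrix (probes x isolates)", call. = FALSE)
  }
  if (anyNA(calls)) stop("`calls` must not contain NA", call. = FALSE)
  probe_ids <- probe_ids %||% rownames(calls) %||%
    sprintf("probe_%04d", seq_len(nrow(calls)))
  isolate_ids <- isolate_ids %||% colnames(calls) %||%
    sprintf("isolate_%d", seq_len(ncol(calls)))
  if (length(probe_ids) != nrow(calls) || anyDuplicated(probe_ids)) {
    stop("probe_ids must be unique and match nrow(calls)", call. = FALSE)
  }
  if (length(isolate_ids) != ncol(calls) || anyDuplicated(isolate_ids)) {
    stop("isolate_ids must be unique and match ncol(calls)", call. = FALSE)
  }
  dimnames(calls) <- list(probe_ids, isolate_ids)
  structure(
    list(calls = calls, direction = direction),
    class = "activation_matrix"
  )
}

#' @export
print.activation_matrix <- function(x, ...) {
  cat(sprintf(
    "<activation_matrix> %d probes x %d isolates (%s), %d calls active\n",
    nrow(x$calls), ncol(x$calls), x$direction, sum(x$calls)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.activation_matrix <- function(x, ...) {
  tibble::tibble(
    probe_id = rep(rownames(x$calls), times = ncol(x$calls)),
    isolate_id = rep(colnames(x$calls), each = nrow(x$calls)),
    active = as.vector(x$calls)
  )
}

#' Call activation from an expression table by fold change over controls
#'
#' A probe is called active in a transformed sample when its intensity is at
#' least `threshold`-fold its mean intensity across the control samples
#' (induced), or at most `1/threshold`-fold (repressed). The boundary is
#' inclusive. Probes whose control mean is nonpositive or non-finite are
#' dropped before calling, with a message reporting how many.
#'
#' @param expr A data frame whose first column holds unique probe identifiers
#'   and whose remaining columns are per-sample intensities (positive,
#'   arbitrary units), one column per array.
#' @param controls Character vector of column names designating the control
#'   (parental line) samples; every other sample column is treated as one
#'   transformed isolate.
#' @param direction Call direction, `"induced"` or `"repressed"`.
#' @param threshold Fold-change cutoff, default 2 (two-fold).
#'
#' @return An [activation_matrix()] with one column per transformed sample.
#' @examples
#' expr <- tibble::tibble(
#'   probe_id = c("a", "b"),
#'   ctrl1 = c(100, 100), ctrl2 = c(100, 100),
#'   iso1 = c(200, 50)
#' )
#' call_activation(expr, controls = c("ctrl1", "ctrl2"))
#' @export
call_activation <- function(expr, controls,
                            direction = c("induced", "repressed"),
                            threshold = 2) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(expr), ncol(expr) >= 3)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  probe_ids <- as.character(expr[[1]])
  if (anyDuplicated(probe_ids)) {
    stop("probe identifiers (first column) must be unique", call. = FALSE)
  }
  sample_ids <- names(expr)[-1]
  if (length(controls) == 0 || !all(controls %in% sample_ids)) {
    stop("`controls` must name at least one sample column", call. = FALSE)
  }
  transformed <- setdiff(sample_ids, controls)
  if (length(transformed) == 0) {
    stop("no transformed sample columns remain after removing controls",
         call. = FALSE)
  }
  vals <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  ctrl_mean <- rowMeans(vals[, controls, drop = FALSE])
  keep <- is.finite(ctrl_mean) & ctrl_mean > 0 &
    apply(is.finite(vals[, transformed, drop = FALSE]), 1L, all)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf(
      "dropping %d probe(s) with nonpositive or non-finite control mean",
      n_drop
    ))
  }
  fc <- vals[keep, transformed, drop = FALSE] / ctrl_mean[keep]
  calls <- if (direction == "induced") fc >= threshold else fc <= 1 / threshold
  activation_matrix(calls, direction = direction,
                    probe_ids = probe_ids[keep], isolate_ids = transformed)
}

#' Per-isolate activated-probe counts
#'
#' @param act An [activation_matrix()].
#' @return A tibble with columns `isolate_id` and `n_active` (column sums of
#'   the call matrix, in isolate order).
#' @export
per_isolate_counts <- function(act) {
  stopifnot(inherits(act, "activation_matrix"))
  tibble::tibble(
    isolate_id = colnames(act$calls),
    n_active = as.integer(colSums(act$calls))
  )
}

#' Probes active in every isolate
#'
#' @param act An [activation_matrix()].
#' @return Integer count of probes whose call is TRUE in all isolates.
#' @export
full_intersection_count <- function(act) {
  stopifnot(inherits(act, "activation_matrix"))
  as.integer(sum(rowSums(act$calls) == ncol(act$calls)))
}

#' Exact mean overlap-decay curve
#'
#' Computes, for each k = 1..n, the mean size of the k-way intersection of the
#' per-isolate active sets over all `choose(n, k)` isolate subsets. The mean
#' is exact, via the identity
#' `y_k = sum_g choose(m_g, k) / choose(n, k)`,
#' where `m_g` counts the isolates in which probe g is active: a probe
#' contributes to a k-subset's intersection exactly when all k chosen isolates
#' lie among its `m_g` active ones. No subsets are sampled or enumerated.
#'
#' `y_1` equals the mean of [per_isolate_counts()] and `y_n` equals
#' [full_intersection_count()].
#'
#' @param act An [activation_matrix()].
#' @return An [overlap_curve()] of length `n = ncol(act$calls)`.
#' @export
mean_overlap_curve <- function(act) {
  stopifnot(inherits(act, "activation_matrix"))
  n <- ncol(act$calls)
  m <- rowSums(act$calls) # per-probe activity multiplicity
  # tab[j] = number of probes active in exactly j isolates, j = 1..n
  tab <- tabulate(m[m > 0], nbins = n)
  y <- vapply(seq_len(n), function(k) {
    sum(tab * choose(seq_len(n), k)) / choose(n, k)
  }, numeric(1))
  overlap_curve(y, direction = act$direction)
}

#' Read or write an activation matrix as TSV
#'
#' The on-disk format is a tab-separated table of 0/1 values with the probe
#' identifier in the first column and one header column per isolate.
#'
#' @param path File path.
#' @param direction Activation direction to attach on read.
#' @return `read_activation_tsv()` returns an [activation_matrix()];
#'   `write_activation_tsv()` returns `path` invisibly.
#' @export
read_activation_tsv <- function(path, direction = c("induced", "repressed")) {
  direction <- match.arg(direction)
  df <- readr::read_tsv(path, col_types = readr::cols())
  calls <- as.matrix(df[, -1, drop = FALSE]) == 1
  activation_matrix(calls, direction = direction,
                    probe_ids = as.character(df[[1]]),
                    isolate_ids = names(df)[-1])
}

#' @rdname read_activation_tsv
#' @param act An [activation_matrix()].
#' @export
write_activation_tsv <- function(act, path) {
  df <- tibble::as_tibble(as.data.frame(act$calls * 1L))
  df <- tibble::add_column(df, probe_id = rownames(act$calls), .before = 1)
  readr::write_tsv(df, path)
  invisible(path)
}
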
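#' Median-of-ratios size factors
#'
#' Computes one positive scaling factor per sample by the median-of-ratios
#' ("geometric") procedure: each gene's counts are divided by that gene's
#' geometric mean across samples, and the sample's factor is the median of
#' those ratios over the reference genes.  Reference genes are those with a
#' strictly positive count in every sample (a single zero makes the geometric
#' mean zero and the log undefined, so such genes are excluded).  The median
#' of an even-length ratio vector is the midpoint of the two central order
#' statistics, and the factors are reported as-is — they are not rescaled to
#' unit geometric mean.
#'
#' @param counts a [count_matrix()] of raw counts.
#' @return an object of class `size_factors`: a named numeric vector, one
#'   factor per sample in column order.
#' @export
compute_size_factors <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  v <- counts$values
  log_geomean <- rowMeans(log(v))          # -Inf for any gene with a zero
  ref <- is.finite(log_geomean)
  if (!any(ref))
    stop("no reference gene has positive counts in every sample; ",
         "prefilter low/zero-expression genes first", call. = FALSE)
  sf <- apply(v[ref, , drop = FALSE], 2L, function(col)
    stats::median(exp(log(col) - log_geomean[ref])))
  structure(sf, class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat("size_factors:\n")
  print(unclass(signif(x, 4L)))
  invisible(x)
}

#' Divide counts by per-sample size factors
#'
#' Returns the matrix with every column divided by its sample's factor;
#' gene and sample order are preserved and zeros stay zero.
#'
#' @param counts a [count_matrix()].
#' @param factors a [compute_size_factors()] result (or any named positive
#'   vector covering every sample in `counts`).
#' @return a `count_matrix` of normalized (real-valued) expression.
#' @export
normalize_counts <- function(counts, factors) {
  stopifnot(inherits(counts, "count_matrix"))
  sid <- sample_ids(counts)
  missing <- setdiff(sid, names(factors))
  if (length(missing))
    stop("no size factor for sample: ", paste(missing, collapse = ", "),
         call. = FALSE)
  f <- unclass(factors)[sid]
  if (any(!is.finite(f)) || any(f <= 0))
    stop("size factors must be positive and finite", call. = FALSE)
  out <- sweep(counts$values, 2L, f, `/`)
  count_matrix(out, counts$groups)
}
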
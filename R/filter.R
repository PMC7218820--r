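#' Filter genes by mean normalized expression
#'
#' Retains exactly the genes whose mean expression across all samples (both
#' groups pooled) is at or above `threshold`; the boundary is inclusive, so
#' after filtering at 50 the minimum per-gene mean is exactly 50.  Genes on a
#' caller-supplied keep-list survive regardless of their mean — this is how a
#' lowly expressed analysis target (e.g. a provirus feature) is protected
#' from its own prefilter.  Gene order is preserved; an empty result is
#' returned with a warning, not an error.
#'
#' @param counts a [count_matrix()] (normally of normalized values).
#' @param threshold non-negative mean-expression cutoff (default 50).
#' @param keep gene identifiers exempt from the filter.
#' @return the filtered `count_matrix`.
#' @export
filter_by_mean_expression <- function(counts, threshold = 50, keep = character()) {
  stopifnot(inherits(counts, "count_matrix"), threshold >= 0)
  m <- rowMeans(counts$values)
  sel <- m >= threshold | gene_ids(counts) %in% keep
  if (!any(sel))
    warning("mean-expression filter removed every gene", call. = FALSE)
  count_matrix(counts$values[sel, , drop = FALSE], counts$groups)
}

#' Filter genes by gene-set annotation
#'
#' Retains the genes that belong to at least one set of the collection
#' (mirroring removal of genes with no known functional annotation), plus any
#' keep-listed genes.  Order preserved; empty result warns.
#'
#' @param counts a [count_matrix()].
#' @param sets a [gene_sets()] collection.
#' @param keep gene identifiers exempt from the filter.
#' @return the filtered `count_matrix`.
#' @export
filter_by_annotation <- function(counts, sets, keep = character()) {
  stopifnot(inherits(counts, "count_matrix"), inherits(sets, "gene_sets"))
  annotated <- unique(unlist(sets$genes, use.names = FALSE))
  sel <- gene_ids(counts) %in% c(annotated, keep)
  if (!any(sel))
    warning("annotation filter removed every gene", call. = FALSE)
  count_matrix(counts$values[sel, , drop = FALSE], counts$groups)
}

#' Quantiles of per-gene mean expression
#'
#' The five quantiles (min, quartiles, max) of the per-gene means, using the
#' linear-interpolation quantile definition (R type 7).  Used to report how
#' the expression distribution changes across filtering stages.
#'
#' @param counts a non-empty [count_matrix()].
#' @return named numeric vector of length 5 at probabilities 0, .25, .5,
#'   .75, 1.
#' @export
summarize_quantiles <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  if (nrow(counts$values) == 0L)
    stop("cannot summarize an empty matrix", call. = FALSE)
  stats::quantile(rowMeans(counts$values), probs = c(0, .25, .5, .75, 1),
                  type = 7)
}

#' Apply both prefilters and report intermediate gene counts
#'
#' Convenience wrapper running the mean-expression filter then the annotation
#' filter, recording the gene count after each stage and the mean-expression
#' quantiles before and after.  Both intermediate counts are exposed because
#' the two filters are often reported as one combined reduction.
#'
#' @inheritParams filter_by_mean_expression
#' @inheritParams filter_by_annotation
#' @return list with elements `counts` (the filtered matrix) and `report`, an
#'   object of class `filter_report` with fields `n_before`,
#'   `n_after_expression`, `n_after_annotation`, `quantiles_before`,
#'   `quantiles_after`.
#' @export
filter_counts <- function(counts, sets, threshold = 50, keep = character()) {
  q_before <- summarize_quantiles(counts)
  s1 <- filter_by_mean_expression(counts, threshold, keep)
  s2 <- filter_by_annotation(s1, sets, keep)
  report <- structure(list(
    n_before = nrow(counts$values),
    n_after_expression = nrow(s1$values),
    n_after_annotation = nrow(s2$values),
    quantiles_before = q_before,
    quantiles_after = if (nrow(s2$values)) summarize_quantiles(s2) else
      stats::setNames(rep(NA_real_, 5L), names(q_before))
  ), class = "filter_report")
  list(counts = s2, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("genes: %d -> %d (mean filter) -> %d (annotation filter)\n",
              x$n_before, x$n_after_expression, x$n_after_annotation))
  cat("mean-expression quantiles before:\n")
  print(signif(x$quantiles_before, 6L))
  cat("after:\n")
  print(signif(x$quantiles_after, 6L))
  invisible(x)
}
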
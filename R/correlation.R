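#' Pearson product-moment correlation of two vectors
#'
#' Thin validating wrapper around [stats::cor()]: requires equal lengths of
#' at least 3 and a nonzero variance in both arguments (a zero-variance
#' vector gives an undefined correlation, which is an error here rather than
#' a silently propagated NaN).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the sample correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact t transform: t = r sqrt(n-2) / sqrt(1-r^2) referred to a t
#' distribution with n-2 degrees of freedom.  Vectorized over `r`.  A
#' correlation of exactly +/-1 returns p = 0.
#'
#' @param r correlation coefficient(s) in \[-1, 1\].
#' @param n number of paired observations (>= 3).
#' @return two-sided p-value(s) in \[0, 1\].
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3L)) stop("need n >= 3", call. = FALSE)
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must be <= 1", call. = FALSE)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p[abs(r) == 1] <- 0
  p
}

#' Correlate every gene with a target feature within one sample group
#'
#' Restricts the matrix to the group's sample columns and computes, for every
#' non-target gene, the Pearson correlation with the target feature together
#' with its t statistic and two-sided p-value.  Genes with zero variance
#' within the group have an undefined correlation: they are kept in the table
#' with `r = NA` (and flagged) so they can never silently occupy a rank, and
#' are excluded when the table is turned into a ranked list.
#'
#' @param counts a [count_matrix()] (normally normalized and filtered).
#' @param target_id gene identifier of the target feature row.
#' @param group one of the matrix's group labels, with >= 3 samples.
#' @return an object of class `correlation_table`: a data frame with columns
#'   `gene_id`, `r`, `t`, `p`, `n` and attributes `group`, `target_id`.
#' @export
correlate_matrix <- function(counts, target_id, group) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!target_id %in% gene_ids(counts))
    stop("unknown target feature: ", target_id, call. = FALSE)
  sel <- counts$groups == group
  if (!any(sel)) stop("unknown group: ", group, call. = FALSE)
  n <- sum(sel)
  if (n < 3L) stop("group '", group, "' has fewer than 3 samples", call. = FALSE)
  sub <- counts$values[, sel, drop = FALSE]
  tgt <- sub[target_id, ]
  if (stats::sd(tgt) == 0)
    stop("target feature has zero variance in group '", group, "'", call. = FALSE)
  others <- setdiff(rownames(sub), target_id)
  mat <- sub[others, , drop = FALSE]
  sds <- apply(mat, 1L, stats::sd)
  r <- rep(NA_real_, length(others))
  ok <- sds > 0
  if (any(ok))
    r[ok] <- as.vector(stats::cor(t(mat[ok, , drop = FALSE]), tgt))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- ifelse(is.na(r), NA_real_, correlation_pvalue(ifelse(is.na(r), 0, r), n))
  out <- data.frame(gene_id = others, r = r, t = t, p = p, n = n,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("correlation_table", "data.frame"),
            group = group, target_id = target_id)
}

#' Genes correlating strongly with the target
#'
#' Extracts the identifiers whose correlation magnitude reaches `threshold`.
#' The default reads "strong" as absolute correlation (both signs count); a
#' signed mode keeping only r >= threshold is available.  Undefined (NA)
#' correlations never qualify.
#'
#' @param table a [correlate_matrix()] result.
#' @param threshold correlation cutoff in (0, 1\] (default 0.7).
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return character vector of gene identifiers.
#' @export
strong_gene_sets <- function(table, threshold = 0.7,
                             mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold <= 1)
  r <- table$r
  sel <- if (mode == "absolute") !is.na(r) & abs(r) >= threshold
         else !is.na(r) & r >= threshold
  table$gene_id[sel]
}

#' Overlap of two strong-correlator sets
#'
#' @param a,b character vectors of gene identifiers.
#' @return list with `n_a`, `n_b`, `n_both` and the sorted intersection
#'   `genes`.
#' @export
overlap_strong_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  both <- sort(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_both = length(both), genes = both)
}

#' Normal quantile-quantile points for a sample
#'
#' Standardizes the sample to mean 0 and unit standard deviation, sorts it,
#' and pairs the order statistics with standard-normal quantiles at plotting
#' positions (i - 0.5)/n.  A diagnostic for the normality assumption behind
#' the correlation t test — it is never used as a gate.
#'
#' @param values numeric vector of length >= 3 with nonzero variance.
#' @return data frame with columns `theoretical` and `sample`, both
#'   non-decreasing.
#' @export
qq_normal_points <- function(values) {
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance", call. = FALSE)
  n <- length(values)
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             sample = sort((values - mean(values)) / s))
}
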
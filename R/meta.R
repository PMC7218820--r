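#' Exact hypergeometric tail probability
#'
#' Probability of observing more than (strict) or at least (inclusive) `x`
#' category members when `k_window` items are drawn without replacement from
#' a universe of `n_universe` items of which `n_category` belong to the
#' category.  Computed exactly via [stats::phyper()] (which works in
#' log-space internally); no normal approximation is ever used.  The two
#' conventions differ by exactly the point mass P(X = x); upper-tail software
#' defaults commonly report the strict tail, while the statistically standard
#' report is the inclusive one — both are first-class here.
#'
#' @param n_universe total number of items (e.g. all ontology terms).
#' @param n_category number of items in the designated category.
#' @param k_window number of items drawn (the top-k window).
#' @param x observed number of category items among the drawn.
#' @param strict if `TRUE` return P(X > x); otherwise (default) P(X >= x).
#' @return the exact tail probability.
#' @export
hypergeometric_tail <- function(n_universe, n_category, k_window, x,
                                strict = FALSE) {
  if (n_category > n_universe || k_window > n_universe ||
      x > min(n_category, k_window) || x < 0 ||
      n_universe < 0 || n_category < 0 || k_window < 0)
    stop("impossible hypergeometric parameters", call. = FALSE)
  q <- if (strict) x else x - 1
  stats::phyper(q, m = n_category, n = n_universe - n_category,
                k = k_window, lower.tail = FALSE)
}

#' Over-representation of a term category among the top-k enriched terms
#'
#' Counts how many of the `k` most significantly enriched terms (the table
#' is already ordered by ascending p-value) belong to a designated category,
#' and evaluates both hypergeometric tails at that count.  The universe size
#' is a required explicit input: the natural choice is the size of the full
#' term vocabulary the category was defined against, not merely the number
#' of sets that happened to be tested, and the two differ by orders of
#' magnitude in the resulting p-value — so the choice must be auditable,
#' never implicit.
#'
#' @param table a [run_gsea()] result (ordered by ascending p-value).
#' @param category_ids term identifiers forming the category.
#' @param k size of the top window (default 20).
#' @param n_universe total number of terms in the vocabulary; must be at
#'   least the number of tested terms.
#' @return an object of class `meta_test`: list with `n_universe`,
#'   `n_category`, `k_window`, `x_observed`, `category_hits` (the
#'   intersecting term ids), `p_strict` = P(X > x), `p_inclusive` = P(X >= x).
#' @export
top_k_category_test <- function(table, category_ids, k = 20,
                                n_universe) {
  stopifnot(k >= 1)
  if (k > nrow(table))
    stop("k exceeds the number of tested terms (", nrow(table), ")",
         call. = FALSE)
  if (n_universe < nrow(table))
    stop("n_universe smaller than the number of tested terms", call. = FALSE)
  category_ids <- unique(category_ids)
  top <- table$term_id[seq_len(k)]
  hits <- intersect(top, category_ids)
  x <- length(hits)
  structure(list(n_universe = n_universe,
                 n_category = length(category_ids),
                 k_window = k, x_observed = x, category_hits = sort(hits),
                 p_strict = hypergeometric_tail(n_universe,
                                                length(category_ids), k, x,
                                                strict = TRUE),
                 p_inclusive = hypergeometric_tail(n_universe,
                                                   length(category_ids), k, x,
                                                   strict = FALSE)),
            class = "meta_test")
}

#' @export
print.meta_test <- function(x, ...) {
  cat(sprintf(
    "category over-representation: %d of top %d terms (category %d of %d)\n",
    x$x_observed, x$k_window, x$n_category, x$n_universe))
  cat(sprintf("  P(X >= %d) = %.3g   P(X > %d) = %.3g\n",
              x$x_observed, x$p_inclusive, x$x_observed, x$p_strict))
  invisible(x)
}
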
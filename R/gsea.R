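#' GSEA configuration
#'
#' Bundles the tunable parameters of the preranked enrichment analysis.  The
#' defaults are a minimum restricted set size of 25, a maximum of 500,
#' 100,000 permutations, the classic weighted running-sum statistic
#' (exponent 1), and a 0.05 adjusted-p significance level.
#'
#' @param n_perm number of gene-label permutations per set size (>= 1).
#' @param min_size,max_size bounds on the set size after restriction to the
#'   analyzed gene universe.
#' @param weight_exponent exponent applied to |score| in the hit increment;
#'   0 gives the unweighted Kolmogorov-Smirnov statistic.
#' @param seed integer seed for the permutation RNG.
#' @param alpha adjusted-p threshold for the `significant` flag.
#' @return an object of class `gsea_config`.
#' @export
gsea_config <- function(n_perm = 100000L, min_size = 25L, max_size = 500L,
                        weight_exponent = 1, seed = 1L, alpha = 0.05) {
  stopifnot(n_perm >= 1, min_size >= 1, min_size <= max_size,
            weight_exponent >= 0, alpha > 0, alpha < 1)
  structure(list(n_perm = as.integer(n_perm), min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 weight_exponent = weight_exponent,
                 seed = as.integer(seed), alpha = alpha),
            class = "gsea_config")
}

#' Rank genes by signed correlation with the target
#'
#' Orders a correlation table by descending signed r; ties are broken by
#' ascending gene identifier so the order is bit-reproducible.  Genes whose
#' correlation is undefined (zero within-group variance) are dropped — an
#' undefined statistic must not occupy a rank.  The target feature itself is
#' never present (the correlation table excludes it).
#'
#' @param table a [correlate_matrix()] result.
#' @return an object of class `ranked_gene_list`: a data frame with columns
#'   `gene_id` and `score`, in ranking order.
#' @export
build_ranked_list <- function(table) {
  if (nrow(table) == 0L) stop("empty correlation table", call. = FALSE)
  if (anyDuplicated(table$gene_id))
    stop("duplicate gene id in correlation table", call. = FALSE)
  tab <- table[!is.na(table$r), , drop = FALSE]
  ord <- order(-tab$r, tab$gene_id)
  out <- data.frame(gene_id = tab$gene_id[ord], score = tab$r[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("ranked_gene_list", "data.frame"))
}

#' Construct a ranked gene list from scores
#'
#' @param scores named numeric vector (names are gene identifiers); sorted
#'   internally by descending score, ties by ascending gene id.
#' @return a `ranked_gene_list`.
#' @export
ranked_gene_list <- function(scores) {
  ids <- names(scores)
  if (is.null(ids) || anyDuplicated(ids))
    stop("scores must be named with unique gene ids", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  ord <- order(-scores, ids)
  structure(data.frame(gene_id = ids[ord], score = unname(scores[ord]),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ranked_gene_list", "data.frame"))
}

# Enrichment score from member positions in the ranked list.
# Closed over the precomputed |score|^w vector; evaluates only at the 2k
# candidate extremes (just before / just after each member), which is where
# the piecewise-linear running sum attains its extrema.  Used unchanged for
# the observed statistic and for every permutation draw.
es_from_positions <- function(aw, pos, N) {
  k <- length(pos)
  pos <- sort.int(pos)
  w <- aw[pos]
  NR <- sum(w)
  if (NR == 0) { w <- rep.int(1, k); NR <- k }   # all-zero scores: flat weights
  miss <- 1 / (N - k)
  cw <- cumsum(w) / NR
  drop_ <- (pos - seq_len(k)) * miss
  top <- cw - drop_                 # running sum just after each member
  bot <- c(0, cw[-k]) - drop_       # running sum just before each member
  max_v <- max(top, 0)
  min_v <- min(bot, 0)
  if (max_v >= -min_v) {            # ties resolve to the positive extreme
    j <- which.max(top)
    list(es = max_v, peak = pos[j], leading = pos[seq_len(j)])
  } else {
    j <- which.min(bot)
    list(es = min_v, peak = pos[j] - 1L, leading = pos[j:k])
  }
}

#' Running-sum enrichment score of a gene set
#'
#' Walks the ranked list from top to bottom, incrementing by
#' |score|^w / N_R at member genes (N_R = sum of members' |score|^w) and
#' decrementing by 1/(N - N_hits) at non-members.  The enrichment score is
#' the running-sum value of maximal absolute deviation from zero (ties
#' between an equal positive peak and negative trough resolve to the
#' positive one).  The leading edge contains the member genes at or before
#' the peak for a positive score, and at or after the trough for a negative
#' one.
#'
#' @param ranked a [ranked_gene_list()].
#' @param members character vector of member gene identifiers; at least one
#'   must be in the list and they must not cover the whole list.
#' @param weight_exponent exponent on |score| (default 1).
#' @return list with `es`, `running_sum` (length = list length),
#'   `peak_index`, and `leading_edge` (gene identifiers in rank order).
#' @export
enrichment_score <- function(ranked, members, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  N <- nrow(ranked)
  pos <- which(ranked$gene_id %in% members)
  k <- length(pos)
  if (k == 0L) stop("no member gene in the ranked list", call. = FALSE)
  if (k == N) stop("gene set covers the whole ranked list", call. = FALSE)
  aw <- abs(ranked$score)^weight_exponent
  st <- es_from_positions(aw, pos, N)
  w <- aw[pos]
  NR <- sum(w)
  if (NR == 0) { w <- rep.int(1, k); NR <- k }
  incr <- rep.int(-1 / (N - k), N)
  incr[pos] <- w / NR
  list(es = st$es, running_sum = cumsum(incr), peak_index = st$peak,
       leading_edge = ranked$gene_id[st$leading])
}

#' Gene-permutation p-values for enrichment scores
#'
#' For every set, draws `n_perm` uniformly random same-size gene subsets of
#' the ranked list (the gene-label permutation null of preranked GSEA) and
#' computes their enrichment scores.  Because the null depends only on the
#' set size, draws are shared across sets of equal restricted size, which
#' also makes identical sets receive bit-identical p-values.  The one-sided
#' p-value uses add-one smoothing: p = (1 + #\{null ES >= observed\}) /
#' (1 + n_perm) for a non-negative observed score, mirrored for a negative
#' one, so p is never zero and never below 1/(n_perm + 1).  The mean
#' positive and mean |negative| null scores are retained for normalization.
#'
#' @param ranked a [ranked_gene_list()].
#' @param sets a [gene_sets()] collection, already restricted to the size
#'   bounds (as done by [run_gsea()]).
#' @param config a [gsea_config()]; `config$seed` seeds the draws.
#' @return data frame with one row per set: `term_id`, `es`, `pvalue`,
#'   `null_mean_pos`, `null_mean_neg` (NA when the null produced no draw of
#'   that sign).
#' @export
permutation_pvalues <- function(ranked, sets, config = gsea_config()) {
  stopifnot(inherits(ranked, "ranked_gene_list"), inherits(sets, "gene_sets"))
  if (config$n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  N <- nrow(ranked)
  aw <- abs(ranked$score)^config$weight_exponent
  pos_list <- lapply(sets$genes, function(g) which(ranked$gene_id %in% g))
  sizes <- lengths(pos_list)
  if (any(sizes == 0L) || any(sizes == N))
    stop("degenerate set: no member in list, or set covers the list",
         call. = FALSE)
  set.seed(config$seed)
  null_by_size <- list()
  for (s in sort(unique(sizes))) {        # ascending size: deterministic order
    null_by_size[[as.character(s)]] <- vapply(
      seq_len(config$n_perm),
      function(b) es_from_positions(aw, sample.int(N, s), N)$es,
      numeric(1L))
  }
  es <- vapply(pos_list, function(p) es_from_positions(aw, p, N)$es, numeric(1L))
  out <- data.frame(term_id = sets$term_id, es = es,
                    pvalue = NA_real_, null_mean_pos = NA_real_,
                    null_mean_neg = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(es)) {
    null <- null_by_size[[as.character(sizes[i])]]
    out$pvalue[i] <- if (es[i] >= 0)
      (1 + sum(null >= es[i])) / (1 + config$n_perm)
    else
      (1 + sum(null <= es[i])) / (1 + config$n_perm)
    if (any(null > 0)) out$null_mean_pos[i] <- mean(null[null > 0])
    if (any(null < 0)) out$null_mean_neg[i] <- mean(abs(null[null < 0]))
  }
  out
}

#' Normalized enrichment score
#'
#' Scales an enrichment score by the mean absolute null score of the same
#' sign: nes = es / mean(null es of matching sign, in absolute value).  A
#' zero score maps to zero; if the null produced no draw of the matching
#' sign the NES is undefined (NA) and flagged with a warning.
#'
#' @param es observed enrichment score.
#' @param null_mean_pos mean of the positive null scores.
#' @param null_mean_neg mean absolute value of the negative null scores.
#' @return the normalized score (same sign as `es`).
#' @export
normalize_es <- function(es, null_mean_pos, null_mean_neg) {
  if (es == 0) return(0)
  denom <- if (es > 0) null_mean_pos else null_mean_neg
  if (is.na(denom) || denom == 0) {
    warning("no same-sign null draw: NES undefined", call. = FALSE)
    return(NA_real_)
  }
  es / denom
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone-enforced, capped at 1),
#' delegated to [stats::p.adjust()] after validating the input range.
#'
#' @param pvalues numeric vector with all values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' q-values with a fixed-lambda null-proportion estimate
#'
#' A deliberately simple q-value estimator: pi0 is estimated at lambda = 0.5
#' as #\{p > 0.5\} / (0.5 m), clamped to \[1/m, 1\] (the lower clamp keeps a
#' degenerate all-small-p input from zeroing every q), and each q-value is
#' pi0 times the BH-adjusted p.  When the pi0 estimate reaches 1 the q-values
#' equal the BH values exactly; they are never larger.
#'
#' @param pvalues numeric vector with all values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
storey_qvalues <- function(pvalues) {
  bh <- adjust_bh(pvalues)
  m <- length(pvalues)
  pi0 <- sum(pvalues > 0.5) / (0.5 * m)
  pi0 <- min(1, max(1 / m, pi0))
  pi0 * bh
}

#' Preranked gene set enrichment analysis
#'
#' The full preranked GSEA: every set is restricted to the genes present in
#' the ranked list; sets whose restricted size falls within
#' `[min_size, max_size]` are tested.  For each tested set the running-sum
#' enrichment score, gene-permutation p-value, normalized score, leading
#' edge and gene ratio (leading-edge size over restricted set size) are
#' computed; p-values are Benjamini-Hochberg adjusted across all tested sets
#' and accompanied by fixed-lambda q-values.  Rows are ordered by ascending
#' p-value, ties broken by term identifier.
#'
#' @param ranked a [ranked_gene_list()].
#' @param sets a [gene_sets()] collection.
#' @param config a [gsea_config()].
#' @return an object of class `gsea_table`: a data frame with columns
#'   `term_id`, `description`, `set_size`, `es`, `nes`, `pvalue`, `p_adjust`,
#'   `qvalue`, `gene_ratio` (with an integer-percent rendering in
#'   `gene_ratio_pct`), `leading_edge` (comma-joined identifiers),
#'   `significant`.  Empty (with a warning) when no set meets the size
#'   bounds.
#' @export
run_gsea <- function(ranked, sets, config = gsea_config()) {
  stopifnot(inherits(ranked, "ranked_gene_list"), inherits(sets, "gene_sets"))
  restricted <- lapply(sets$genes, function(g)
    g[g %in% ranked$gene_id])
  size <- lengths(restricted)
  keep <- size >= config$min_size & size <= config$max_size & size < nrow(ranked)
  empty <- data.frame(term_id = character(), description = character(),
                      set_size = integer(), es = numeric(), nes = numeric(),
                      pvalue = numeric(), p_adjust = numeric(),
                      qvalue = numeric(), gene_ratio = numeric(),
                      gene_ratio_pct = integer(),
                      leading_edge = character(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("no gene set within the size bounds after restriction",
            call. = FALSE)
    return(structure(empty, class = c("gsea_table", "data.frame"),
                     config = config))
  }
  tested <- gene_sets(sets$term_id[keep], sets$description[keep],
                      restricted[keep])
  perm <- permutation_pvalues(ranked, tested, config)
  nes <- numeric(nrow(perm))
  le <- character(nrow(perm))
  ratio <- numeric(nrow(perm))
  for (i in seq_len(nrow(perm))) {
    st <- enrichment_score(ranked, tested$genes[[i]], config$weight_exponent)
    nes[i] <- normalize_es(perm$es[i], perm$null_mean_pos[i],
                           perm$null_mean_neg[i])
    le[i] <- paste(st$leading_edge, collapse = ",")
    ratio[i] <- length(st$leading_edge) / length(tested$genes[[i]])
  }
  out <- data.frame(term_id = tested$term_id,
                    description = tested$description,
                    set_size = lengths(tested$genes),
                    es = perm$es, nes = nes, pvalue = perm$pvalue,
                    p_adjust = adjust_bh(perm$pvalue),
                    qvalue = storey_qvalues(perm$pvalue),
                    gene_ratio = ratio,
                    gene_ratio_pct = as.integer(round(100 * ratio)),
                    leading_edge = le,
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adjust < config$alpha
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gsea_table", "data.frame"), config = config)
}
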
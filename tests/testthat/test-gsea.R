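test_that("ranking is by signed score descending with lexicographic ties", {
  tab <- structure(data.frame(gene_id = c("a", "b", "c"),
                              r = c(0.5, 0.9, -0.2)),
                   class = c("correlation_table", "data.frame"))
  expect_equal(build_ranked_list(tab)$gene_id, c("b", "a", "c"))

  tie <- structure(data.frame(gene_id = c("zz", "aa"), r = c(0.4, 0.4)),
                   class = c("correlation_table", "data.frame"))
  expect_equal(build_ranked_list(tie)$gene_id, c("aa", "zz"))

  set.seed(23)
  big <- structure(data.frame(gene_id = sprintf("g%03d", 1:100),
                              r = round(runif(100, -1, 1), 2)),
                   class = c("correlation_table", "data.frame"))
  rl <- build_ranked_list(big)
  ord <- order(-big$r, big$gene_id)
  expect_equal(rl$gene_id, big$gene_id[ord])

  expect_error(build_ranked_list(rbind(tab, tab)), "duplicate")
})

test_that("enrichment score reproduces the hand-walked worked examples", {
  rl <- toy_ranked()
  top <- enrichment_score(rl, c("a", "b"))
  expect_equal(top$es, 1)
  expect_equal(top$running_sum[1:2], c(0.6, 1.0))
  expect_equal(top$leading_edge, c("a", "b"))

  bottom <- enrichment_score(rl, c("d", "e"))
  expect_equal(bottom$es, -1)
  expect_equal(bottom$leading_edge, c("d", "e"))

  mid <- enrichment_score(rl, c("a", "c"))
  expect_equal(mid$running_sum,
               c(0.75, 0.75 - 1 / 3, 0.75 - 1 / 3 + 0.25,
                 0.75 - 1 / 3 + 0.25 - 1 / 3, 0),
               tolerance = 1e-12)
  expect_equal(mid$es, 0.75)
  expect_equal(mid$peak_index, 1L)
  expect_equal(mid$leading_edge, "a")

  expect_error(enrichment_score(rl, "nothere"), "no member")
  expect_error(enrichment_score(rl, c("a", "b", "c", "d", "e")), "whole")
})

test_that("ES stays in [-1,1]; +/-1 iff members form a pure prefix/suffix", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(6:15, 1)
    scores <- sort(round(rnorm(n), 2), decreasing = TRUE)
    names(scores) <- sprintf("g%02d", seq_len(n))
    rl <- ranked_gene_list(scores)
    k <- sample(2:(n - 2), 1)
    members <- sample(rl$gene_id, k)
    es <- enrichment_score(rl, members)$es
    expect_gte(es, -1); expect_lte(es, 1)
  }
  rl <- toy_ranked()
  expect_lt(enrichment_score(rl, c("a", "c"))$es, 1)
})

test_that("reversing the list and negating scores flips every ES", {
  set.seed(52)
  scores <- round(rnorm(9), 2)
  names(scores) <- sprintf("g%02d", 1:9)
  rl <- ranked_gene_list(scores)
  rl_rev <- ranked_gene_list(-scores)
  for (k in c(2, 4)) {
    for (rep in 1:5) {
      members <- sample(names(scores), k)
      expect_equal(enrichment_score(rl_rev, members)$es,
                   -enrichment_score(rl, members)$es,
                   tolerance = 1e-12)
    }
  }
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration", {
  rl <- toy_ranked()
  null <- enumerate_null_es(rl, 2)         # all C(5,2) = 10 placements
  expect_equal(sum(null >= 1), 1L)         # exactly one attains ES >= 1
  exact_p <- mean(null >= 1)
  expect_equal(exact_p, 0.1)

  cfg <- gsea_config(n_perm = 10000, min_size = 2, max_size = 2, seed = 19)
  pp <- permutation_pvalues(rl, gene_sets("S", "", list(c("a", "b"))), cfg)
  se3 <- 3 * sqrt(exact_p * (1 - exact_p) / cfg$n_perm)
  expect_lt(abs(pp$pvalue - exact_p), se3)

  # a larger list, still enumerable: C(8,3) = 56 placements
  set.seed(77)
  scores <- sort(round(rnorm(8), 2), decreasing = TRUE)
  names(scores) <- sprintf("h%02d", 1:8)
  rl8 <- ranked_gene_list(scores)
  members <- c("h01", "h03", "h04")
  obs <- enrichment_score(rl8, members)$es
  null8 <- enumerate_null_es(rl8, 3)
  exact8 <- if (obs >= 0) mean(null8 >= obs) else mean(null8 <= obs)
  pp8 <- permutation_pvalues(rl8, gene_sets("T", "", list(members)),
                             gsea_config(n_perm = 10000, min_size = 2,
                                         max_size = 4, seed = 4))
  expect_lt(abs(pp8$pvalue - exact8),
            3 * sqrt(exact8 * (1 - exact8) / 10000) + 2e-4)
})

test_that("permutation p-values are add-one smoothed and deterministic", {
  rl <- toy_ranked()
  sets <- gene_sets(c("S1", "S2"), c("", ""),
                    list(c("a", "b"), c("a", "b")))
  cfg <- gsea_config(n_perm = 500, min_size = 2, max_size = 2, seed = 8)
  pp1 <- permutation_pvalues(rl, sets, cfg)
  pp2 <- permutation_pvalues(rl, sets, cfg)
  expect_identical(pp1, pp2)                       # same seed, bit-identical
  expect_identical(pp1$pvalue[1], pp1$pvalue[2])   # identical sets agree
  expect_gte(min(pp1$pvalue), 1 / (cfg$n_perm + 1))  # smoothing floor
})

test_that("NES scales by the same-sign null mean", {
  expect_equal(normalize_es(0.5, 0.5, NA), 1)
  expect_equal(normalize_es(0, NA, NA), 0)
  expect_equal(normalize_es(-0.6, 0.4, 0.3), -2)
  expect_warning(out <- normalize_es(0.5, NA, 0.3), "undefined")
  expect_true(is.na(out))

  # enumerable null: NES of the toy set equals the hand-computed ratio
  rl <- toy_ranked()
  null <- enumerate_null_es(rl, 2)
  expect_equal(normalize_es(1, mean(null[null > 0]), mean(abs(null[null < 0]))),
               1 / mean(null[null > 0]))
})

test_that("BH adjustment and q-values satisfy their defining relations", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(33)
  p <- runif(20)
  bh <- adjust_bh(p)
  expect_true(all(diff(bh[order(p)]) >= 0))            # monotone
  perm <- sample(20)
  expect_equal(adjust_bh(p[perm]), bh[perm])           # permutation-stable

  q <- storey_qvalues(p)
  expect_true(all(q <= bh + 1e-15))
  m <- length(p)
  pi0 <- min(1, max(1 / m, sum(p > 0.5) / (0.5 * m)))
  expect_equal(q, pi0 * bh)

  expect_equal(storey_qvalues(c(0.1, 0.6, 0.9)),       # pi0 capped at 1
               adjust_bh(c(0.1, 0.6, 0.9)))
  p_small <- c(0.01, 0.02, 0.04, 0.05)                 # pi0 floor 1/m
  expect_equal(storey_qvalues(p_small), adjust_bh(p_small) / 4)
})

test_that("run_gsea applies size bounds after restriction and orders output", {
  rl <- toy_ranked()
  sets <- gene_sets(c("BIG", "OK", "TINY"), c("", "", ""),
                    list(c("a", "b", "c", "d", "zzz"),   # restricted size 4
                         c("a", "b", "qqq"),             # restricted size 2
                         "e"))
  cfg <- gsea_config(n_perm = 200, min_size = 2, max_size = 3, seed = 2)
  tab <- run_gsea(rl, sets, cfg)
  expect_equal(tab$term_id, "OK")
  expect_equal(tab$set_size, 2L)

  expect_warning(empty <- run_gsea(rl, gene_sets("T", "", list("a")),
                                   gsea_config(n_perm = 10, min_size = 3)),
                 "size bounds")
  expect_equal(nrow(empty), 0L)
})

test_that("gsea table invariants hold on a synthetic study", {
  st <- generate_study(synthetic_config(seed = 5, n_genes = 400, n_sets = 6,
                                        set_size_range = c(25, 30),
                                        coexpr_strength = 1.5,
                                        dispersion = 0.05))
  ct <- correlate_matrix(normalize_counts(st$counts,
                                          compute_size_factors(st$counts)),
                         "ERVK-7", "old")
  tab <- run_gsea(build_ranked_list(ct), st$sets,
                  gsea_config(n_perm = 1000, min_size = 20, seed = 6))
  expect_true(all(abs(tab$es) <= 1))
  expect_true(all(sign(tab$nes) == sign(tab$es) | tab$es == 0))
  expect_true(all(tab$p_adjust >= tab$pvalue - 1e-15))
  expect_true(all(tab$qvalue <= tab$p_adjust + 1e-15))
  le_sizes <- lengths(strsplit(tab$leading_edge, ",", fixed = TRUE))
  expect_equal(tab$gene_ratio, le_sizes / tab$set_size)
  expect_false(is.unsorted(tab$pvalue))
})

test_that("enrichment scores agree with the independent preranked reference", {
  skip_if_not_installed("fgsea")
  set.seed(61)
  scores <- sort(round(rnorm(60), 3), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:60)
  rl <- ranked_gene_list(scores)
  for (rep in 1:10) {
    members <- sample(rl$gene_id, sample(5:15, 1))
    ours <- enrichment_score(rl, members)$es
    ref <- fgsea::calcGseaStat(rl$score,
                               selectedStats = which(rl$gene_id %in% members),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})
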
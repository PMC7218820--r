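# Shared fixture builders.  Everything is generated in code; no data files.

make_counts <- function(values, genes = NULL, samples = NULL,
                        groups = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  if (is.null(groups))
    groups <- stats::setNames(rep(c("old", "young"),
                                  length.out = ncol(values)), samples)
  count_matrix(values, groups)
}

random_counts <- function(n_genes, n_samples, seed = 42, max = 1000) {
  set.seed(seed)
  make_counts(matrix(sample.int(max, n_genes * n_samples, replace = TRUE),
                     nrow = n_genes))
}

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# five-gene worked list used throughout the GSEA tests
toy_ranked <- function()
  ranked_gene_list(c(a = 3, b = 2, c = 1, d = -1, e = -2))

# exhaustive gene-permutation null for small lists: ES of every size-k subset
enumerate_null_es <- function(ranked, k, weight_exponent = 1) {
  N <- nrow(ranked)
  combos <- utils::combn(N, k)
  apply(combos, 2L, function(pos)
    enrichment_score(ranked, ranked$gene_id[pos], weight_exponent)$es)
}
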
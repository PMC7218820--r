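test_that("the generator is deterministic and honours its configuration", {
  cfg <- synthetic_config(seed = 9, n_genes = 300, n_sets = 5,
                          set_size_range = c(25, 30))
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$sets, b$sets)
  expect_identical(a$truth$planted_genes, b$truth$planted_genes)

  expect_equal(dim(a$counts), c(301L, 14L))          # target + background
  expect_true("ERVK-7" %in% gene_ids(a$counts))
  expect_equal(unname(table(a$counts$groups)), array(c(7L, 7L)))
  expect_equal(length(a$sets), 5L)
  expect_true(all(lengths(a$sets$genes) >= 25 & lengths(a$sets$genes) <= 30))
  expect_true(all(unlist(a$truth$planted_genes) %in% gene_ids(a$counts)))
  expect_true(all(a$counts$values >= 0))
  expect_true(all(a$counts$values == round(a$counts$values)))
})

test_that("the target's group-mean ratio tracks the configured fold", {
  set.seed(0)
  folds <- vapply(1:40, function(s) {
    st <- generate_study(synthetic_config(seed = 300 + s, n_genes = 2,
                                          n_sets = 0, n_planted_sets = 0))
    v <- st$counts$values["ERVK-7", ]
    mean(v[st$counts$groups == "old"]) / mean(v[st$counts$groups == "young"])
  }, numeric(1))
  expect_equal(mean(folds), 1.3, tolerance = 0.1)
})

test_that("infeasible planted sizes are a hard error", {
  expect_error(generate_study(synthetic_config(seed = 1, n_genes = 30,
                                               n_sets = 2, n_planted_sets = 2,
                                               set_size_range = c(25, 25))),
               "planted")
})

test_that("unknown YAML keys are rejected; valid YAML round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 4", "n_genes: 120", "n_sets: 3",
               "set_size_range: [25, 30]"), path)
  cfg <- read_synthetic_config(path)
  expect_equal(cfg$seed, 4L)
  expect_equal(cfg$n_genes, 120L)

  writeLines(c("seed: 4", "not_a_key: 1"), path)
  expect_error(read_synthetic_config(path), "not_a_key")
})

test_that("recovery scoring handles perfect and empty screens", {
  st <- generate_study(synthetic_config(seed = 2, n_genes = 200, n_sets = 3,
                                        set_size_range = c(25, 30),
                                        n_planted_sets = 1))
  planted <- st$truth$planted_genes[[1]]
  fake <- function(selected_r) {
    gid <- st$truth$gene_table$gene_id
    structure(data.frame(gene_id = gid,
                         r = ifelse(gid %in% selected_r, 0.99, 0),
                         stringsAsFactors = FALSE),
              class = c("correlation_table", "data.frame"),
              group = "old", target_id = "ERVK-7")
  }
  perfect <- evaluate_recovery(st$truth, fake(planted))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  none <- evaluate_recovery(st$truth, fake(character()))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)

  alien <- fake(planted)
  alien$gene_id[1] <- "not-in-study"
  expect_error(evaluate_recovery(st$truth, alien), "outside")
})

test_that("planted-set GSEA rank improves monotonically with coupling strength", {
  median_rank <- function(beta) {
    ranks <- vapply(1:3, function(s) {
      st <- generate_study(synthetic_config(seed = 600 + s,
                                            coexpr_strength = beta,
                                            n_genes = 600, n_sets = 8,
                                            set_size_range = c(25, 30),
                                            dispersion = 0.05))
      ct <- correlate_matrix(normalize_counts(st$counts,
                                              compute_size_factors(st$counts)),
                             "ERVK-7", "old")
      tab <- run_gsea(build_ranked_list(ct), st$sets,
                      gsea_config(n_perm = 500, min_size = 20, seed = s))
      mean(match(st$truth$planted_set_ids, tab$term_id))
    }, numeric(1))
    stats::median(ranks)
  }
  ranks <- vapply(c(0, 1, 2), median_rank, numeric(1))
  expect_true(ranks[3] <= ranks[1])
  expect_lte(ranks[3], 2)                 # strong coupling: planted on top
})

test_that("planting in one group only yields asymmetric strong-set counts", {
  hits <- vapply(1:10, function(s) {
    st <- generate_study(synthetic_config(seed = 900 + s, coexpr_strength = 1.5,
                                          n_genes = 500, n_sets = 6,
                                          set_size_range = c(25, 30),
                                          dispersion = 0.05))
    norm <- normalize_counts(st$counts, compute_size_factors(st$counts))
    n_old <- length(strong_gene_sets(correlate_matrix(norm, "ERVK-7", "old")))
    n_young <- length(strong_gene_sets(correlate_matrix(norm, "ERVK-7",
                                                        "young")))
    n_old > n_young
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
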
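#' Run the full co-expression analysis in memory
#'
#' The package's central fitting-style entry point.  Starting from a raw
#' count matrix, it (1) computes median-of-ratios size factors and
#' normalizes, (2) applies the mean-expression and annotation prefilters
#' with the target feature on the keep-list, (3) screens every gene against
#' the target by Pearson correlation within each analyzed group, (4) ranks
#' genes by signed correlation and runs preranked GSEA per group, (5)
#' optionally tests a designated term category for over-representation among
#' each group's top-k enriched terms, and (6) reports the overlap of the two
#' groups' strong-correlator sets.  Both groups share one filtered gene
#' universe (the filters pool all samples), and each group's screen reads
#' only that group's sample columns.
#'
#' @param counts a [count_matrix()] of raw counts.
#' @param sets a [gene_sets()] collection.
#' @param target_id identifier of the target feature row.
#' @param config a [gsea_config()].
#' @param cor_threshold strong-correlation cutoff (default 0.7).
#' @param mean_threshold mean normalized-expression prefilter (default 50).
#' @param groups group labels to analyze (default: every label present).
#' @param category_ids optional term-category identifiers for the meta-test.
#' @param k top-window size of the meta-test (default 20).
#' @param n_universe term-vocabulary size for the meta-test (required when
#'   `category_ids` is given).
#' @return an object of class `coex_analysis` with components
#'   `size_factors`, `filter_report`, `filtered` (the analyzed matrix),
#'   `correlations`, `ranked`, `gsea`, `strong` (per-group lists keyed by
#'   group label), `overlap`, `meta` (per-group [top_k_category_test()]
#'   results or `NULL`), `target_id` and `params`.
#' @seealso [run_pipeline()] for the file-based front end.
#' @export
analyze_coexpression <- function(counts, sets, target_id,
                                 config = gsea_config(),
                                 cor_threshold = 0.7, mean_threshold = 50,
                                 groups = NULL, category_ids = NULL, k = 20,
                                 n_universe = NULL) {
  stopifnot(inherits(counts, "count_matrix"), inherits(sets, "gene_sets"))
  if (!target_id %in% gene_ids(counts))
    stop("target feature '", target_id, "' not in the count matrix",
         call. = FALSE)
  if (is.null(groups)) groups <- unique(unname(counts$groups))
  sf <- compute_size_factors(counts)
  norm <- normalize_counts(counts, sf)
  flt <- filter_counts(norm, sets, threshold = mean_threshold,
                       keep = target_id)
  res <- list(size_factors = sf, filter_report = flt$report,
              filtered = flt$counts, sets = sets, correlations = list(),
              ranked = list(), gsea = list(), strong = list(), meta = NULL,
              target_id = target_id,
              params = list(cor_threshold = cor_threshold,
                            mean_threshold = mean_threshold,
                            groups = groups, k = k,
                            n_universe = n_universe, config = config))
  for (g in groups) {
    ct <- correlate_matrix(flt$counts, target_id, g)
    res$correlations[[g]] <- ct
    res$strong[[g]] <- strong_gene_sets(ct, cor_threshold)
    res$ranked[[g]] <- build_ranked_list(ct)
    res$gsea[[g]] <- run_gsea(res$ranked[[g]], sets, config)
  }
  if (length(groups) == 2L)
    res$overlap <- overlap_strong_sets(res$strong[[groups[1L]]],
                                       res$strong[[groups[2L]]])
  if (!is.null(category_ids)) {
    if (is.null(n_universe))
      stop("`n_universe` is required for the category meta-test", call. = FALSE)
    res$meta <- lapply(res$gsea, function(tab) {
      kk <- min(k, nrow(tab))
      if (kk < 1L) return(NULL)
      top_k_category_test(tab, category_ids, k = kk, n_universe = n_universe)
    })
  }
  structure(res, class = "coex_analysis")
}

#' @export
print.coex_analysis <- function(x, ...) {
  cat("Co-expression analysis of target feature:", x$target_id, "\n")
  cat(sprintf("gene universe after filtering: %d genes\n",
              x$filter_report$n_after_annotation))
  for (g in names(x$correlations))
    cat(sprintf("  group %-8s strong correlators (|r| >= %.2f): %d; tested sets: %d\n",
                g, x$params$cor_threshold, length(x$strong[[g]]),
                nrow(x$gsea[[g]])))
  if (!is.null(x$overlap))
    cat(sprintf("  strong in both groups: %d\n", x$overlap$n_both))
  invisible(x)
}

#' @export
summary.coex_analysis <- function(object, n_top = 5L, ...) {
  x <- object
  print(x)
  for (g in names(x$gsea)) {
    tab <- x$gsea[[g]]
    cat(sprintf("\ntop enriched terms, group %s:\n", g))
    if (nrow(tab))
      print(utils::head(tab[, c("term_id", "description", "set_size", "es",
                                "nes", "pvalue", "p_adjust")], n_top),
            row.names = FALSE)
    else cat("  (no set within size bounds)\n")
    if (!is.null(x$meta) && !is.null(x$meta[[g]])) {
      cat(sprintf("category meta-test, group %s: ", g)); print(x$meta[[g]])
    }
  }
  invisible(x)
}

#' Diagnostic plots for a co-expression analysis
#'
#' `type = "enrichment"` draws the GSEA running sum of one term in one
#' group, with member positions ticked along the axis; `type = "qq"` draws
#' the normal quantile-quantile plot of the target feature's expression in
#' one group (the normality diagnostic behind the correlation t test).
#'
#' @param x a `coex_analysis`.
#' @param type `"enrichment"` or `"qq"`.
#' @param group group label (default: the first analyzed group).
#' @param term_id term to draw (default: the group's top term).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.coex_analysis <- function(x, type = c("enrichment", "qq"), group = NULL,
                               term_id = NULL, ...) {
  type <- match.arg(type)
  if (is.null(group)) group <- names(x$correlations)[1L]
  if (type == "qq") {
    sel <- x$filtered$groups == group
    qq <- qq_normal_points(x$filtered$values[x$target_id, sel])
    graphics::plot(qq$theoretical, qq$sample,
                   xlab = "theoretical normal quantile",
                   ylab = "standardized expression",
                   main = sprintf("%s, group %s", x$target_id, group))
    graphics::abline(0, 1, lty = 2)
  } else {
    tab <- x$gsea[[group]]
    if (is.null(tab) || !nrow(tab)) stop("no GSEA result to plot", call. = FALSE)
    if (is.null(term_id)) term_id <- tab$term_id[1L]
    row <- match(term_id, tab$term_id)
    if (is.na(row)) stop("term not in GSEA table: ", term_id, call. = FALSE)
    full <- x$ranked[[group]]
    members <- x$sets$genes[[match(term_id, x$sets$term_id)]]
    es <- enrichment_score(full, members, x$params$config$weight_exponent)
    graphics::plot(seq_along(es$running_sum), es$running_sum, type = "l",
                   xlab = "rank in correlation-ordered list",
                   ylab = "running enrichment", main = term_id)
    graphics::abline(h = 0, lty = 3)
    graphics::rug(which(full$gene_id %in% members))
  }
  invisible(x)
}

pipeline_defaults <- function() {
  list(counts = NULL, groups = NULL, gmt = NULL, category = NULL,
       out_dir = "coex_out", target_id = NULL, cor_threshold = 0.7,
       mean_threshold = 50, k = 20, n_universe = NULL,
       analyze_groups = NULL,
       gsea = list(n_perm = 100000L, min_size = 25L, max_size = 500L,
                   weight_exponent = 1, seed = 1L, alpha = 0.05))
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `counts`, `groups`, `gmt` (input paths), optional
#' `category` (one term id per line), `out_dir`, `target_id`,
#' `cor_threshold`, `mean_threshold`, `k`, `n_universe`, `analyze_groups`,
#' and a nested `gsea` block matching [gsea_config()].  Unknown keys are a
#' hard error.
#'
#' @param path path to the YAML file.
#' @return a validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) cfg_stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown))
    cfg_stop("unknown config key: ", paste(unknown, collapse = ", "))
  if (!is.null(vals$gsea)) {
    unknown <- setdiff(names(vals$gsea), names(defaults$gsea))
    if (length(unknown))
      cfg_stop("unknown gsea config key: ", paste(unknown, collapse = ", "))
    defaults$gsea[names(vals$gsea)] <- vals$gsea
    vals$gsea <- NULL
  }
  defaults[names(vals)] <- vals
  validate_pipeline_config(defaults)
}

cfg_stop <- function(...) {
  stop(errorCondition(paste0(...), class = c("hervcoex_config_error", "error")))
}

data_stop <- function(stage, e) {
  stop(errorCondition(sprintf("stage '%s' failed: %s", stage,
                              conditionMessage(e)),
                      class = c("hervcoex_data_error", "error")))
}

validate_pipeline_config <- function(cfg) {
  for (field in c("counts", "groups", "gmt", "target_id"))
    if (is.null(cfg[[field]])) cfg_stop("missing required config field: ", field)
  for (field in c("counts", "groups", "gmt", "category")) {
    p <- cfg[[field]]
    if (!is.null(p) && !file.exists(p))
      cfg_stop("config path does not exist: ", field, " = ", p)
  }
  if (cfg$cor_threshold <= 0 || cfg$cor_threshold > 1)
    cfg_stop("cor_threshold must lie in (0, 1]")
  if (cfg$mean_threshold < 0) cfg_stop("mean_threshold must be >= 0")
  cfg$gsea <- do.call(gsea_config, cfg$gsea)
  structure(cfg, class = "pipeline_config")
}

#' Run the file-based analysis pipeline
#'
#' Front end over [analyze_coexpression()] that reads the inputs named in a
#' [read_pipeline_config()] configuration, executes every stage, and writes
#' all intermediate and final tables plus a YAML run manifest and a
#' human-readable summary into the output directory.  A stage failure
#' aborts with an error naming the stage; files written before the failure
#' are retained and the manifest records the run as incomplete.  Identical
#' configuration and seed reproduce identical result tables.
#'
#' Output files: `size_factors.tsv`, `normalized.tsv`, `filtered.tsv`,
#' `filter_report.tsv`, and per analyzed group `corr_<group>.tsv`,
#' `ranked_<group>.tsv`, `gsea_<group>.tsv`, `metatest_<group>.tsv` (when a
#' category is configured), plus `overlap.tsv`, `summary.txt` and
#' `MANIFEST.yaml`.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @return the [analyze_coexpression()] result, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out_dir, "MANIFEST.yaml")
  manifest <- list(package = "hervcoex",
                   version = as.character(utils::packageVersion("hervcoex")),
                   started = format(t0, "%Y-%m-%d %H:%M:%S"),
                   seed = config$gsea$seed,
                   config = lapply(unclass(config), function(x)
                     if (inherits(x, "gsea_config")) unclass(x) else x),
                   complete = FALSE)
  yaml::write_yaml(manifest, manifest_path)
  log_stage <- function(stage) message(sprintf("[%s] %s",
                                               format(Sys.time(), "%H:%M:%S"),
                                               stage))
  stage <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e) data_stop(name, e))
  }

  counts <- stage("read inputs", read_count_matrix(config$counts, config$groups))
  sets <- stage("read gene sets", read_gmt(config$gmt))
  category <- if (!is.null(config$category))
    readLines(config$category, warn = FALSE) else NULL
  res <- stage("analysis", analyze_coexpression(
    counts, sets, config$target_id, config = config$gsea,
    cor_threshold = config$cor_threshold,
    mean_threshold = config$mean_threshold,
    groups = config$analyze_groups, category_ids = category, k = config$k,
    n_universe = config$n_universe))

  stage("write outputs", {
    out <- function(f) file.path(config$out_dir, f)
    write_tsv_checked(data.frame(sample_id = names(res$size_factors),
                                 factor = signif(unclass(res$size_factors), 6L)),
                      out("size_factors.tsv"))
    write_count_matrix(normalize_counts(counts, res$size_factors),
                       out("normalized.tsv"))
    write_count_matrix(res$filtered, out("filtered.tsv"))
    fr <- res$filter_report
    write_tsv_checked(data.frame(
      stage = c("before", "after_expression", "after_annotation"),
      n_genes = c(fr$n_before, fr$n_after_expression, fr$n_after_annotation)),
      out("filter_report.tsv"))
    for (g in names(res$correlations)) {
      write_result_table(res$correlations[[g]], out(sprintf("corr_%s.tsv", g)))
      write_tsv_checked(res$ranked[[g]], out(sprintf("ranked_%s.tsv", g)))
      write_result_table(res$gsea[[g]], out(sprintf("gsea_%s.tsv", g)))
      if (!is.null(res$meta) && !is.null(res$meta[[g]])) {
        m <- res$meta[[g]]
        write_tsv_checked(data.frame(
          group = g, n_universe = m$n_universe, n_category = m$n_category,
          k_window = m$k_window, x_observed = m$x_observed,
          p_inclusive = m$p_inclusive, p_strict = m$p_strict),
          out(sprintf("metatest_%s.tsv", g)))
      }
    }
    if (!is.null(res$overlap))
      write_tsv_checked(data.frame(
        n_a = res$overlap$n_a, n_b = res$overlap$n_b,
        n_both = res$overlap$n_both,
        genes = paste(res$overlap$genes, collapse = ",")),
        out("overlap.tsv"))
    con <- file(out("summary.txt"), open = "wt")
    sink(con); on.exit({ sink(); close(con) }, add = TRUE)
    summary(res)
  })
  manifest$complete <- TRUE
  manifest$wall_clock_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  yaml::write_yaml(manifest, manifest_path)
  invisible(res)
}
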
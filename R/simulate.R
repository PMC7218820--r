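#' Configuration for the synthetic two-group study generator
#'
#' Describes a simulated bulk RNA-seq co-expression study: two sample groups,
#' one designated target feature whose group means differ by `target_fold`,
#' and a configurable number of "planted" gene sets whose member genes
#' co-vary with the target in one group only.  The defaults mirror a small
#' aging-cohort design: 7 samples per group and a 1.3-fold mean elevation of
#' the target in the first ("old") group.
#'
#' Counts are negative binomial around log-uniform gene baselines.  Planted
#' co-expression enters through a shared latent variable: within the planted
#' group, each planted gene's log-mean is shifted by `coexpr_strength` times
#' the standardized realized target count of that sample, which directly
#' induces the Pearson structure the downstream screen measures.  In the
#' other group, and for all non-planted genes, expression is independent of
#' the target.
#'
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param n_per_group samples per group (default 7).
#' @param n_genes number of background genes, excluding the target
#'   (default 2000).
#' @param n_sets number of gene sets emitted (default 15).
#' @param set_size_range inclusive (low, high) bounds on set sizes
#'   (default c(25, 60)).
#' @param n_planted_sets how many sets carry planted co-expression
#'   (default 2; must not exceed `n_sets`).
#' @param coexpr_strength beta >= 0, the log-scale slope of planted genes on
#'   the standardized target (default 1; 0 plants nothing).
#' @param planted_group group receiving the planted signal (default the
#'   first group label).
#' @param target_fold ratio of target group means, planted group over other
#'   (default 1.3).
#' @param baseline_log_mean_range range of the log-uniform gene baseline
#'   means, in log counts (default log(c(30, 3000))).
#' @param dispersion negative-binomial dispersion (1/size); 0 gives Poisson
#'   counts (default 0.1).
#' @param target_location mean target count in the non-planted group
#'   (default 100; chosen large enough that the target is quantifiable on
#'   the count scale).
#' @param target_id identifier given to the target feature row
#'   (default "ERVK-7").
#' @param group_labels the two group labels (default c("old", "young")).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_per_group = 7L, n_genes = 2000L,
                             n_sets = 15L, set_size_range = c(25L, 60L),
                             n_planted_sets = 2L, coexpr_strength = 1,
                             planted_group = NULL, target_fold = 1.3,
                             baseline_log_mean_range = log(c(30, 3000)),
                             dispersion = 0.1, target_location = 100,
                             target_id = "ERVK-7",
                             group_labels = c("old", "young")) {
  if (is.null(planted_group)) planted_group <- group_labels[1L]
  stopifnot(length(group_labels) == 2L, planted_group %in% group_labels,
            n_per_group >= 3L, n_genes >= 1L, n_sets >= 0L,
            n_planted_sets >= 0L, n_planted_sets <= n_sets,
            length(set_size_range) == 2L,
            set_size_range[1L] >= 1L,
            set_size_range[1L] <= set_size_range[2L],
            coexpr_strength >= 0, target_fold > 0, dispersion >= 0,
            target_location > 0,
            baseline_log_mean_range[1L] <= baseline_log_mean_range[2L])
  structure(list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
                 n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 n_planted_sets = as.integer(n_planted_sets),
                 coexpr_strength = coexpr_strength,
                 planted_group = planted_group, target_fold = target_fold,
                 baseline_log_mean_range = baseline_log_mean_range,
                 dispersion = dispersion, target_location = target_location,
                 target_id = target_id, group_labels = group_labels),
            class = "synthetic_config")
}

#' Read a synthetic-study configuration from YAML
#'
#' Keys map one-to-one onto the arguments of [synthetic_config()]; an
#' unknown key is a hard error rather than a silent ignore.
#'
#' @param path path to the YAML file.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(synthetic_config, vals)
}

rnb <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate a synthetic two-group study with planted co-expression
#'
#' Draws the study described by a [synthetic_config()]: a raw count matrix
#' (the target feature first, then the background genes), a gene-set
#' collection in which the planted sets' members carry the co-expression
#' signal, and the ground truth needed to score recovery.  Randomness is
#' consumed in three fixed phases with sub-seeds derived from `config$seed`
#' (design, target counts, gene counts), so identical configurations give
#' byte-identical output and individual phases can be regenerated.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `counts` (a [count_matrix()]), `sets` (a
#'   [gene_sets()] collection; planted sets are named `PLANTED###`,
#'   background sets `BG###`), and `truth`, an object of class
#'   `synthetic_truth` with fields `planted_set_ids`, `planted_genes` (list
#'   per planted set), `gene_table` (per-gene planted flag), `planted_group`
#'   and `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_per_group
  labels <- config$group_labels
  samples <- c(paste0(labels[1L], "_", seq_len(n)),
               paste0(labels[2L], "_", seq_len(n)))
  groups <- stats::setNames(rep(labels, each = n), samples)
  planted_mask <- groups == config$planted_group

  sizes_all <- if (config$n_sets > 0L)
    seq.int(config$set_size_range[1L], config$set_size_range[2L]) else integer()

  # phase 1: design (baselines, set sizes, memberships)
  set.seed(config$seed)
  base_log <- stats::runif(config$n_genes, config$baseline_log_mean_range[1L],
                           config$baseline_log_mean_range[2L])
  gid <- sprintf("gene%04d", seq_len(config$n_genes))
  set_sizes <- if (config$n_sets > 0L)
    sample(sizes_all, config$n_sets, replace = TRUE) else integer()
  n_planted_genes <- sum(set_sizes[seq_len(config$n_planted_sets)])
  if (n_planted_genes > config$n_genes)
    stop("planted sets need more genes than n_genes provides", call. = FALSE)
  planted_idx <- if (n_planted_genes)
    sample.int(config$n_genes, n_planted_genes) else integer()
  planted_genes <- split(gid[planted_idx],
                         rep(seq_len(config$n_planted_sets),
                             times = set_sizes[seq_len(config$n_planted_sets)]))
  bg_pool <- setdiff(gid, gid[planted_idx])
  bg_genes <- lapply(seq_len(config$n_sets - config$n_planted_sets),
                     function(i) sample(bg_pool,
                                        set_sizes[config$n_planted_sets + i]))

  # phase 2: target counts with the configured group-mean fold
  set.seed(config$seed + 1L)
  mu_target <- ifelse(planted_mask, config$target_location * config$target_fold,
                      config$target_location)
  target <- rnb(length(samples), mu_target, config$dispersion)

  # standardized realized target within the planted group (the shared latent)
  z <- numeric(length(samples))
  tg <- target[planted_mask]
  if (stats::sd(tg) > 0) z[planted_mask] <- (tg - mean(tg)) / stats::sd(tg)

  # phase 3: gene counts; planted genes tilt with the latent in one group only
  set.seed(config$seed + 2L)
  logmu <- matrix(base_log, nrow = config$n_genes, ncol = length(samples))
  is_planted_gene <- gid %in% gid[planted_idx]
  if (any(is_planted_gene) && config$coexpr_strength > 0)
    logmu[is_planted_gene, ] <- sweep(
      logmu[is_planted_gene, , drop = FALSE], 2L,
      config$coexpr_strength * z, `+`)
  counts <- matrix(rnb(length(logmu), exp(logmu), config$dispersion),
                   nrow = config$n_genes,
                   dimnames = list(gid, samples))
  values <- rbind(matrix(target, nrow = 1L,
                         dimnames = list(config$target_id, samples)),
                  counts)

  set_ids <- c(sprintf("PLANTED%03d", seq_len(config$n_planted_sets)),
               sprintf("BG%03d",
                       seq_len(config$n_sets - config$n_planted_sets)))
  descs <- c(rep("planted co-expression set", config$n_planted_sets),
             rep("background set", config$n_sets - config$n_planted_sets))
  sets <- if (config$n_sets > 0L)
    gene_sets(set_ids, descs, c(unname(planted_genes), bg_genes))
  else gene_sets(character(), character(), list())
  truth <- structure(list(
    planted_set_ids = set_ids[seq_len(config$n_planted_sets)],
    planted_genes = stats::setNames(unname(planted_genes),
                                    set_ids[seq_len(config$n_planted_sets)]),
    gene_table = data.frame(gene_id = gid, planted = is_planted_gene,
                            stringsAsFactors = FALSE),
    planted_group = config$planted_group,
    config = config), class = "synthetic_truth")
  list(counts = count_matrix(values, groups), sets = sets, truth = truth)
}

#' Score recovery of the planted signal
#'
#' Compares a correlation screen and a GSEA table, both computed on a
#' generated study, against that study's ground truth.  The strong-gene
#' screen is scored as sensitivity and specificity against the per-gene
#' planted flag (which is all-FALSE when the screened group is not the
#' planted group); the planted sets are located in the GSEA table by rank
#' and significance.
#'
#' @param truth the `synthetic_truth` from [generate_study()].
#' @param corr a [correlate_matrix()] result on the same study.
#' @param gsea a [run_gsea()] result on the same study (optional, `NULL` to
#'   score only the screen).
#' @param threshold strong-correlation cutoff (default 0.7).
#' @param alpha significance level applied to the GSEA adjusted p (default
#'   0.05).
#' @return an object of class `recovery_report`: list with `group`,
#'   `sensitivity`, `specificity`, `n_selected`, and (when `gsea` is given)
#'   a data frame `set_recovery` of planted-set ranks and significance.
#' @export
evaluate_recovery <- function(truth, corr, gsea = NULL, threshold = 0.7,
                              alpha = 0.05) {
  stopifnot(inherits(truth, "synthetic_truth"))
  known <- c(truth$gene_table$gene_id, truth$config$target_id)
  if (!all(corr$gene_id %in% known))
    stop("correlation table contains genes outside the generated study",
         call. = FALSE)
  group <- attr(corr, "group")
  flag <- stats::setNames(truth$gene_table$planted &
                            group == truth$planted_group,
                          truth$gene_table$gene_id)
  flag <- flag[names(flag) %in% corr$gene_id]
  selected <- strong_gene_sets(corr, threshold)
  tp <- sum(names(flag)[flag] %in% selected)
  fp <- sum(selected %in% names(flag)[!flag])
  pos <- sum(flag); neg <- sum(!flag)
  rec <- list(group = group,
              sensitivity = if (pos) tp / pos else NA_real_,
              specificity = if (neg) 1 - fp / neg else NA_real_,
              n_selected = length(selected))
  if (!is.null(gsea)) {
    rank <- match(truth$planted_set_ids, gsea$term_id)
    rec$set_recovery <- data.frame(
      term_id = truth$planted_set_ids, rank = rank,
      p_adjust = gsea$p_adjust[rank],
      significant = gsea$p_adjust[rank] < alpha,
      stringsAsFactors = FALSE)
  }
  structure(rec, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("screen recovery in group '%s': sensitivity %.3f, specificity %.3f (%d selected)\n",
              x$group, x$sensitivity, x$specificity, x$n_selected))
  if (!is.null(x$set_recovery)) {
    cat("planted-set recovery in GSEA:\n")
    print(x$set_recovery)
  }
  invisible(x)
}
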
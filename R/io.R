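#' Construct a count matrix with sample-group labels
#'
#' The basic container used throughout the pipeline: a numeric genes-by-samples
#' matrix with unique row (gene) and column (sample) identifiers, plus a group
#' label for every sample.  Raw counts are integer-valued; normalized matrices
#' hold reals.  All values must be non-negative and finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must carry names.
#' @param groups named character vector mapping every sample identifier to a
#'   group label.
#' @return an object of class `count_matrix`: a list with elements `values`
#'   (the matrix) and `groups` (the label vector, in column order).
#' @export
count_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L && is.null(rownames(values)))
    dimnames(values) <- list(character(), colnames(values))  # 0-row subsets
  gid <- if (nrow(values) == 0L) character() else rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must have row (gene) and column (sample) names", call. = FALSE)
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("duplicate gene id: ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop("duplicate sample id: ", paste(dup, collapse = ", "), call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("count matrix contains non-finite values", call. = FALSE)
  if (any(values < 0))
    stop("count matrix contains negative values", call. = FALSE)
  missing <- setdiff(sid, names(groups))
  if (length(missing))
    stop("sample absent from group map: ", paste(missing, collapse = ", "),
         call. = FALSE)
  groups <- as.character(groups[sid])
  names(groups) <- sid
  structure(list(values = values, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Gene identifiers and sample identifiers of a count matrix
#' @param x a `count_matrix`.
#' @return character vector of identifiers, in stored order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a gene-by-sample count matrix from TSV
#'
#' The expected layout is one header line `gene_id<TAB>sample1<TAB>...` and a
#' numeric body, genes in rows.  Row and column order are preserved.  Group
#' membership is supplied explicitly, never inferred from sample names: either
#' a named character vector (names = sample ids) or the path to a two-column
#' sidecar TSV (`sample_id<TAB>group`, with header).
#'
#' @param path path to the matrix TSV.
#' @param group_map named character vector or path to a sidecar group TSV.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, group_map) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("count matrix needs a gene_id column and at least one sample", call. = FALSE)
  gid <- df[[1L]]
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("duplicate gene id: ", paste(dup, collapse = ", "), call. = FALSE)
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  vals <- matrix(vals, nrow = nrow(body),
                 dimnames = list(gid, colnames(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 gid[bad[1L]], colnames(vals)[bad[2L]]), call. = FALSE)
  }
  count_matrix(vals, as_group_map(group_map))
}

as_group_map <- function(group_map) {
  if (is.character(group_map) && is.null(names(group_map)) &&
      length(group_map) == 1L) {
    df <- utils::read.delim(group_map, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (ncol(df) < 2L)
      stop("group file needs columns sample_id and group", call. = FALSE)
    stats::setNames(df[[2L]], df[[1L]])
  } else if (!is.null(names(group_map))) {
    stats::setNames(as.character(group_map), names(group_map))
  } else {
    stop("`group_map` must be a named vector or a file path", call. = FALSE)
  }
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()]: first column `gene_id`, one column per
#' sample.  Values are written at full precision for integers and at 6
#' significant digits otherwise.
#'
#' @param x a `count_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  v <- x$values
  fmt <- if (all(v == round(v))) format(v, trim = TRUE, scientific = FALSE)
         else format(signif(v, 6L), trim = TRUE)
  df <- data.frame(gene_id = rownames(v), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(v))
  write_tsv_checked(df, path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: `term_id<TAB>description<TAB>gene1<TAB>gene2...`.  A line
#' with fewer than three fields is a hard error (a set must have at least one
#' member), as is a repeated term identifier.  Duplicate genes within one set
#' are dropped with a warning naming the set.
#'
#' @param path path to the GMT file.
#' @return an object of class `gene_sets`: list with character vectors
#'   `term_id` and `description` and a list `genes` of member-id vectors,
#'   parallel to each other.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields", call. = FALSE)
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate term id: ", paste(dup, collapse = ", "), call. = FALSE)
  desc <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(seq_along(fields), function(i) {
    g <- fields[[i]][-(1:2)]
    if (anyDuplicated(g)) {
      warning("dropping duplicate gene(s) within set ", ids[i], call. = FALSE)
      g <- unique(g)
    }
    g
  })
  gene_sets(ids, desc, genes)
}

#' Construct a gene-set collection
#'
#' @param term_id unique term identifiers.
#' @param description one description per term.
#' @param genes list of non-empty, duplicate-free member-id vectors.
#' @return an object of class `gene_sets`.
#' @export
gene_sets <- function(term_id, description, genes) {
  stopifnot(length(term_id) == length(description),
            length(term_id) == length(genes))
  if (anyDuplicated(term_id))
    stop("duplicate term id", call. = FALSE)
  if (any(lengths(genes) == 0L))
    stop("empty gene set", call. = FALSE)
  structure(list(term_id = as.character(term_id),
                 description = as.character(description),
                 genes = lapply(genes, as.character)),
            class = "gene_sets")
}

#' @export
length.gene_sets <- function(x) length(x$term_id)

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, member sizes %s\n", length(x),
              paste(range(lengths(x$genes)), collapse = "-")))
  invisible(x)
}

#' Write a gene-set collection to GMT
#' @param x a `gene_sets` collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  lines <- vapply(seq_along(x$term_id), function(i)
    paste(c(x$term_id[i], x$description[i], x$genes[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table to TSV
#'
#' Writes any of the pipeline's result tables (correlation tables, GSEA
#' tables) with a fixed header, floats at 6 significant digits, and a
#' deterministic row order: ascending p-value, ties broken by the identifier
#' column (`term_id` or `gene_id`).  An empty table produces a header-only
#' file.
#'
#' @param records a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(records, path) {
  if (is.null(records)) stop("`records` must not be NULL", call. = FALSE)
  df <- as.data.frame(records)
  idcol <- intersect(c("term_id", "gene_id"), colnames(df))[1L]
  if (nrow(df) && "pvalue" %in% colnames(df) && !is.na(idcol))
    df <- df[order(df$pvalue, df[[idcol]]), , drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v)
    ifelse(v == round(v) & abs(v) < 1e15,
           format(v, trim = TRUE, scientific = FALSE),
           format(signif(v, 6L), trim = TRUE)))
  write_tsv_checked(df, path)
  invisible(path)
}

write_tsv_checked <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write to '", path, "': ", conditionMessage(ok), call. = FALSE)
}
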
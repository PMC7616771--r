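# Per-cell gene-set expression-fraction scores on UMI counts: the score of a
# cell is the total UMIs over the expressed members of a gene set divided by
# the cell's total UMIs over all genes. "Expressed" set genes are those with
# at least `min_total_umis` UMIs summed over all cells of the compartment
# (default 50); the denominator is always all genes, unfiltered.

#' Construct a UMI count container
#'
#' @param counts Sparse (or dense) genes x cells matrix of non-negative
#'   integer UMI counts with unique row (gene) and column (cell) names.
#' @param cell_groups Optional group label per cell (e.g. Control / MPL).
#' @param compartment Compartment label, e.g. `"hematopoietic"` or
#'   `"stromal"`; the expressed-gene filter is computed per compartment.
#' @return Object of class `umi_counts`.
#' @export
umi_counts <- function(counts, cell_groups = NULL,
                       compartment = "unspecified") {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must have gene (row) and cell (column) names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique",
                                            call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("cell ids must be unique",
                                            call. = FALSE)
  if (min(counts) < 0) stop("counts must be non-negative", call. = FALSE)
  if (any(counts@x != round(counts@x))) {
    stop("counts must be integers", call. = FALSE)
  }
  if (!is.null(cell_groups)) {
    if (length(cell_groups) != ncol(counts)) {
      stop("'cell_groups' must have one label per cell", call. = FALSE)
    }
    cell_groups <- as.factor(cell_groups)
  }
  structure(list(counts = counts, cell_groups = cell_groups,
                 compartment = as.character(compartment)),
            class = "umi_counts")
}

#' @export
print.umi_counts <- function(x, ...) {
  cat(sprintf("umi_counts: %d genes x %d cells (%s compartment)\n",
              nrow(x$counts), ncol(x$counts), x$compartment))
  if (!is.null(x$cell_groups)) {
    cat("groups:", paste(sprintf("%s=%d", levels(x$cell_groups),
                                 table(x$cell_groups)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a gene set
#'
#' @param name Set name (e.g. `"ECM"`, `"chemokine"`, `"NSF"`).
#' @param gene_ids Unique gene identifiers.
#' @param categories Optional category per gene (e.g. collagen /
#'   glycoprotein / proteoglycan), recycled checks applied.
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, gene_ids, categories = NULL) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) stop("gene set is empty", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique", call. = FALSE)
  if (!is.null(categories)) {
    if (length(categories) != length(gene_ids)) {
      stop("'categories' must match gene_ids in length", call. = FALSE)
    }
    categories <- as.character(categories)
  }
  structure(list(name = as.character(name), gene_ids = gene_ids,
                 categories = categories), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes", x$name, length(x$gene_ids)))
  if (!is.null(x$categories)) {
    tb <- table(x$categories)
    cat(" (", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Expressed-gene filter for a gene set
#'
#' A set gene counts as expressed when its total UMIs summed over all cells
#' of the compartment reach `min_total_umis` (default 50). Set genes absent
#' from the matrix are dropped with a warning.
#'
#' @param counts A [umi_counts()] restricted to one compartment.
#' @param geneset A [gene_set()].
#' @param min_total_umis Expressed-gene threshold, >= 0; default 50.
#' @return Character vector of expressed set gene ids.
#' @export
filter_expressed_genes <- function(counts, geneset, min_total_umis = 50) {
  if (!inherits(counts, "umi_counts")) stop("'counts' must be umi_counts",
                                            call. = FALSE)
  if (!inherits(geneset, "gene_set")) stop("'geneset' must be a gene_set",
                                           call. = FALSE)
  stopifnot_scalar_number(min_total_umis, "min_total_umis", min = 0)
  present <- geneset$gene_ids %in% rownames(counts$counts)
  if (any(!present)) {
    warning(sprintf("%d gene(s) of set '%s' absent from the count matrix: %s",
                    sum(!present), geneset$name,
                    paste(utils::head(geneset$gene_ids[!present], 5),
                          collapse = ", ")), call. = FALSE)
  }
  ids <- geneset$gene_ids[present]
  totals <- Matrix::rowSums(counts$counts[ids, , drop = FALSE])
  ids[totals >= min_total_umis]
}

#' Per-cell gene-set expression-fraction score
#'
#' For each cell, the score is the total UMIs over `expressed_set` divided by
#' the cell's total UMIs over all genes (the denominator is never filtered).
#' Cells with zero total counts get `NA` — 0/0 is undefined and such cells
#' are upstream QC failures.
#'
#' @param counts A [umi_counts()].
#' @param expressed_set Character vector of expressed set gene ids (subset of
#'   the matrix's genes), e.g. from [filter_expressed_genes()].
#' @param name Score name recorded in the result.
#' @return Object of class `score_vector`: named numeric per-cell scores in
#'   `[0, 1]` plus attributes `geneset` (name) and `expressed_set`.
#' @export
score_cells <- function(counts, expressed_set, name = "score") {
  if (!inherits(counts, "umi_counts")) stop("'counts' must be umi_counts",
                                            call. = FALSE)
  expressed_set <- as.character(expressed_set)
  if (!all(expressed_set %in% rownames(counts$counts))) {
    stop("'expressed_set' must be a subset of the matrix's gene ids",
         call. = FALSE)
  }
  total <- Matrix::colSums(counts$counts)
  num <- if (length(expressed_set)) {
    Matrix::colSums(counts$counts[expressed_set, , drop = FALSE])
  } else rep(0, ncol(counts$counts))
  score <- ifelse(total > 0, num / total, NA_real_)
  names(score) <- colnames(counts$counts)
  structure(score, class = c("score_vector", "numeric"),
            geneset = name, expressed_set = expressed_set)
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector '%s': %d cells, %d expressed set genes\n",
              attr(x, "geneset"), length(x), length(attr(x, "expressed_set"))))
  print(summary(unclass(x)))
  invisible(x)
}

#' Gene-set score in one step
#'
#' Applies [filter_expressed_genes()] then [score_cells()].
#'
#' @inheritParams filter_expressed_genes
#' @return A `score_vector`.
#' @export
geneset_score <- function(counts, geneset, min_total_umis = 50) {
  expressed <- filter_expressed_genes(counts, geneset, min_total_umis)
  score_cells(counts, expressed, name = geneset$name)
}

#' Count expressed set genes per category for a compartment
#'
#' Applies the expressed-gene filter and tabulates how many set genes pass,
#' overall and per category (e.g. collagens / glycoproteins / proteoglycans).
#'
#' @inheritParams filter_expressed_genes
#' @return List with `total` (integer) and `per_category` (named integer
#'   vector; `NULL` when the set has no categories) and `compartment`.
#' @export
count_expressed_set_genes <- function(counts, geneset, min_total_umis = 50) {
  expressed <- filter_expressed_genes(counts, geneset, min_total_umis)
  per_cat <- NULL
  if (!is.null(geneset$categories)) {
    cat_of <- stats::setNames(geneset$categories, geneset$gene_ids)
    per_cat <- table(factor(cat_of[expressed],
                            levels = sort(unique(geneset$categories))))
    per_cat <- stats::setNames(as.integer(per_cat), names(per_cat))
  }
  list(total = length(expressed), per_category = per_cat,
       compartment = counts$compartment)
}

#' Compare gene-set scores between cell groups
#'
#' Two-sided Wilcoxon rank-sum test (see [wilcoxon_rank_sum()]) for every
#' pair of groups, on non-missing scores.
#'
#' @param scores A `score_vector` from [score_cells()].
#' @param cell_groups Group label per cell (defaults to the `umi_counts`
#'   groups if `scores` was built from one — must be supplied otherwise).
#' @return Data frame with one row per group pair: groups, n per group,
#'   medians, rank-sum statistic, p, BH-adjusted p and method tag.
#' @export
compare_score_groups <- function(scores, cell_groups) {
  g <- as.factor(cell_groups)
  if (length(g) != length(scores)) {
    stop("'cell_groups' must have one label per score", call. = FALSE)
  }
  keep <- !is.na(scores)
  lv <- levels(g)
  for (l in lv) {
    if (sum(keep & g == l) < 2) {
      stop(sprintf("group '%s' has fewer than 2 non-missing scores", l),
           call. = FALSE)
    }
  }
  pairs <- utils::combn(lv, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    x <- as.numeric(scores[keep & g == a])
    y <- as.numeric(scores[keep & g == b])
    t <- wilcoxon_rank_sum(x, y)
    data.frame(group1 = a, group2 = b, n1 = length(x), n2 = length(y),
               median1 = stats::median(x), median2 = stats::median(y),
               statistic = t$statistic, p = t$p, method = t$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p)
  out
}
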
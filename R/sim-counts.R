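# Multinomial UMI count simulator with designed per-cell-type gene-set
# expression fractions. Each cell's counts are one multinomial draw of the
# stated depth, with probability mass p_set spread uniformly over the set
# genes, so the expected gene-set score of a cell equals p_set exactly and
# column sums equal the depth exactly.

#' Specification for a synthetic UMI count matrix
#'
#' @param cell_types Data frame with columns `label` (character), `n_cells`
#'   (positive integer) and `p_set` (designed gene-set expression fraction in
#'   `[0, 1]`), one row per cell type.
#' @param n_set_genes,n_other_genes Numbers of gene-set and non-set genes.
#' @param depth_per_cell Total UMIs per cell (fixed by default).
#' @param depth_lognormal_sd If > 0, per-cell depths are drawn log-normally
#'   with this SD on the log scale around `depth_per_cell` (optional
#'   variable-depth mode; default 0 = fixed depth).
#' @param seed Integer seed.
#' @return Object of class `counts_sim_spec`.
#' @export
counts_sim_spec <- function(cell_types, n_set_genes = 50,
                            n_other_genes = 500, depth_per_cell = 5000,
                            depth_lognormal_sd = 0, seed = 1L) {
  if (!is.data.frame(cell_types) ||
      !all(c("label", "n_cells", "p_set") %in% names(cell_types)) ||
      nrow(cell_types) < 1L) {
    stop("'cell_types' must be a data frame with columns label, n_cells, p_set",
         call. = FALSE)
  }
  if (any(cell_types$n_cells < 1) ||
      any(cell_types$n_cells != round(cell_types$n_cells))) {
    stop("'n_cells' must be positive integers", call. = FALSE)
  }
  if (any(cell_types$p_set < 0 | cell_types$p_set > 1)) {
    stop("'p_set' must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(cell_types$label)) {
    stop("cell type labels must be unique", call. = FALSE)
  }
  stopifnot_scalar_number(n_set_genes, "n_set_genes", min = 1, integer = TRUE)
  stopifnot_scalar_number(n_other_genes, "n_other_genes", min = 1,
                          integer = TRUE)
  stopifnot_scalar_number(depth_per_cell, "depth_per_cell", min = 1,
                          integer = TRUE)
  stopifnot_scalar_number(depth_lognormal_sd, "depth_lognormal_sd", min = 0)
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  structure(list(cell_types = cell_types,
                 n_set_genes = as.integer(n_set_genes),
                 n_other_genes = as.integer(n_other_genes),
                 depth_per_cell = as.integer(depth_per_cell),
                 depth_lognormal_sd = depth_lognormal_sd,
                 seed = as.integer(seed)),
            class = "counts_sim_spec")
}

#' Generate a synthetic UMI count matrix with designed set fractions
#'
#' Set genes are named `SET1..SETk`, other genes `OTH1..OTHm`. Within a cell
#' of type with fraction `p_set`, each set gene has probability
#' `p_set / n_set_genes` and each other gene `(1 - p_set) / n_other_genes`;
#' counts are multinomial at the cell's depth.
#'
#' @param spec A [counts_sim_spec()].
#' @param compartment Compartment label attached to the result, default
#'   `"stromal"`.
#' @return List with `counts` (a [umi_counts()] whose `cell_groups` are the
#'   type labels), `p_set` (named designed fractions) and `set_genes`
#'   (character vector of set gene ids).
#' @export
gen_counts <- function(spec, compartment = "stromal") {
  if (!inherits(spec, "counts_sim_spec")) {
    stop("'spec' must be a counts_sim_spec", call. = FALSE)
  }
  k <- spec$n_set_genes; m <- spec$n_other_genes
  gene_ids <- c(sprintf("SET%d", seq_len(k)), sprintf("OTH%d", seq_len(m)))
  with_rng_seed(stream_seed(spec$seed, "counts"), {
    mats <- vector("list", nrow(spec$cell_types))
    groups <- character(0)
    for (i in seq_len(nrow(spec$cell_types))) {
      ct <- spec$cell_types[i, ]
      p <- c(rep(ct$p_set / k, k), rep((1 - ct$p_set) / m, m))
      depths <- if (spec$depth_lognormal_sd > 0) {
        pmax(1L, as.integer(round(stats::rlnorm(
          ct$n_cells, log(spec$depth_per_cell), spec$depth_lognormal_sd))))
      } else rep(spec$depth_per_cell, ct$n_cells)
      cols <- vapply(depths, function(d) stats::rmultinom(1L, d, p)[, 1L],
                     numeric(k + m))
      mats[[i]] <- cols
      groups <- c(groups, rep(ct$label, ct$n_cells))
    }
    mat <- do.call(cbind, mats)
    cell_ids <- sprintf("cell%05d", seq_len(ncol(mat)))
    dimnames(mat) <- list(gene_ids, cell_ids)
    counts <- umi_counts(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                     "CsparseMatrix"),
                         cell_groups = groups, compartment = compartment)
    p_set <- stats::setNames(spec$cell_types$p_set, spec$cell_types$label)
    list(counts = counts, p_set = p_set,
         set_genes = sprintf("SET%d", seq_len(k)))
  })
}

#' Generate a synthetic protein abundance table with known differentials
#'
#' Log-normal abundances for `n_proteins` features over two groups of
#' `n_per_group` samples; a designated subset of `n_diff` proteins is shifted
#' by `effect_log2fc` (log2 units) in group `"B"`.
#'
#' @param n_per_group Samples per group, >= 2.
#' @param n_proteins Number of proteins.
#' @param effect_log2fc Designed log2 fold change of the shifted subset.
#' @param seed Integer seed.
#' @param n_diff Size of the shifted subset (default 10% of proteins, min 1).
#' @param base_log2_mean,base_log2_sd Log2-scale mean and SD of the null
#'   abundance distribution.
#' @return List with `table` (proteins x samples matrix of linear
#'   abundances), `groups` (factor of `"A"`/`"B"` per sample) and `diff_ids`
#'   (character vector of shifted protein ids; empty when `effect_log2fc`
#'   is 0).
#' @export
gen_proteomics <- function(n_per_group, n_proteins = 100, effect_log2fc = 0,
                           seed = 1L, n_diff = max(1L, round(n_proteins / 10)),
                           base_log2_mean = 10, base_log2_sd = 1) {
  stopifnot_scalar_number(n_per_group, "n_per_group", min = 2, integer = TRUE)
  stopifnot_scalar_number(n_proteins, "n_proteins", min = 1, integer = TRUE)
  stopifnot_scalar_number(n_diff, "n_diff", min = 1, max = n_proteins,
                          integer = TRUE)
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  ids <- sprintf("prot%04d", seq_len(n_proteins))
  with_rng_seed(stream_seed(seed, "proteomics"), {
    n_s <- 2L * n_per_group
    log2ab <- matrix(stats::rnorm(n_proteins * n_s, base_log2_mean,
                                  base_log2_sd),
                     n_proteins, n_s, dimnames = list(ids, NULL))
    groups <- factor(rep(c("A", "B"), each = n_per_group))
    diff_ids <- character(0)
    if (effect_log2fc != 0) {
      diff_idx <- sample.int(n_proteins, n_diff)
      log2ab[diff_idx, groups == "B"] <-
        log2ab[diff_idx, groups == "B"] + effect_log2fc
      diff_ids <- ids[sort(diff_idx)]
    }
    tab <- 2^log2ab
    colnames(tab) <- sprintf("sample%02d", seq_len(n_s))
    list(table = tab, groups = groups, diff_ids = diff_ids)
  })
}
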
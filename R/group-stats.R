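# Shared nonparametric statistics and normalization for the proteomics
# comparison and the score/field group contrasts.

#' Log-normalize an abundance table
#'
#' `x -> log2(x + 1)` elementwise (base and pseudocount configurable);
#' missing values are preserved. Downstream tests are rank-based, so the
#' base does not affect inference.
#'
#' @param x Numeric matrix (features x samples) or vector, values >= 0.
#' @param base Logarithm base, default 2.
#' @param pseudocount Added before the log, default 1.
#' @return Transformed object of the same shape.
#' @export
log_normalize <- function(x, base = 2, pseudocount = 1) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("log normalization requires non-negative values", call. = FALSE)
  }
  log(x + pseudocount, base = base)
}

#' Per-feature min-max scaling to [0, 1]
#'
#' Each feature (row) is mapped by `(x - min) / (max - min)` across samples.
#' A constant feature maps to all zeros with a warning; a feature with no
#' observed values is an error naming the feature.
#'
#' @param x Numeric matrix, features in rows; missing values allowed.
#' @return Matrix of the same shape with every observed value in `[0, 1]`.
#' @export
min_max_scale <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  all_na <- apply(x, 1, function(r) all(is.na(r)))
  if (any(all_na)) {
    nm <- rownames(x)[all_na] %||% paste("row", which(all_na))
    stop(sprintf("feature(s) with no observed values: %s",
                 paste(utils::head(nm, 5), collapse = ", ")), call. = FALSE)
  }
  rng_min <- apply(x, 1, min, na.rm = TRUE)
  rng_max <- apply(x, 1, max, na.rm = TRUE)
  const <- rng_max == rng_min
  if (any(const)) {
    warning(sprintf("%d constant feature(s) mapped to 0", sum(const)),
            call. = FALSE)
  }
  denom <- ifelse(const, 1, rng_max - rng_min)
  out <- (x - rng_min) / denom
  out[const, ] <- ifelse(is.na(x[const, , drop = FALSE]), NA_real_, 0)
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with midranks for ties. The exact
#' permutation distribution is used when the combined sample size is at most
#' 14 and there are no ties (enumeration over all assignments); otherwise
#' the normal approximation with tie and continuity correction. The path
#' taken is recorded in the method tag.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return List of class `rank_sum_test`: `statistic` (Mann-Whitney U of
#'   `x`), `p`, `method` (`"exact"` or `"normal-approx"`), group sizes and
#'   medians.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L || anyNA(c(x, y))) {
    stop("both groups must be non-empty with no missing values",
         call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 14L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  structure(list(statistic = unname(wt$statistic), p = unname(wt$p.value),
                 method = if (exact) "exact" else "normal-approx",
                 n1 = length(x), n2 = length(y),
                 median1 = stats::median(x), median2 = stats::median(y)),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): U = %g, p = %.4g (n = %d vs %d)\n",
              x$method, x$statistic, x$p, x$n1, x$n2))
  invisible(x)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up adjustment (default) or Bonferroni, preserving
#' input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` (default) or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  stats::p.adjust(pvalues,
                  method = if (method == "bh") "BH" else "bonferroni")
}

#' Proteomics group comparison
#'
#' The normalization-and-test pipeline for protein abundance tables: log
#' normalization, per-feature min-max scaling to [0, 1], then a two-sided
#' Wilcoxon rank-sum test per feature between two groups, with
#' multiple-testing adjustment.
#'
#' @param table Numeric matrix, proteins x samples, linear abundances >= 0.
#' @param groups Factor/vector with exactly two levels, one per sample.
#' @param adjust Adjustment method passed to [bh_adjust()].
#' @return Data frame: feature_id, statistic, p, p_adjusted, method tag and
#'   group medians (of the normalized values).
#' @export
compare_protein_groups <- function(table, groups, adjust = "bh") {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L || length(groups) != ncol(table)) {
    stop("'groups' must assign each sample to one of exactly two groups",
         call. = FALSE)
  }
  norm <- min_max_scale(log_normalize(table))
  lv <- levels(groups)
  res <- lapply(seq_len(nrow(norm)), function(i) {
    x <- norm[i, groups == lv[1]]
    y <- norm[i, groups == lv[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 1L || length(y) < 1L) {
      return(data.frame(feature_id = rownames(norm)[i], statistic = NA_real_,
                        p = NA_real_, method = NA_character_,
                        median1 = NA_real_, median2 = NA_real_,
                        stringsAsFactors = FALSE))
    }
    t <- wilcoxon_rank_sum(x, y)
    data.frame(feature_id = rownames(norm)[i] %||% paste0("feature", i),
               statistic = t$statistic, p = t$p, method = t$method,
               median1 = t$median1, median2 = t$median2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$p)
  out$p_adjusted <- NA_real_
  out$p_adjusted[ok] <- bh_adjust(out$p[ok], method = adjust)
  out
}
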
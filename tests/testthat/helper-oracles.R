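# Independent oracles and small fixture builders shared across tests.

# Exhaustive Otsu: evaluate the between-class variance at every candidate bin
# edge directly from the histogram and return the first maximizing edge.
otsu_brute_force <- function(values, n_bins, range = NULL) {
  lo <- if (is.null(range)) min(values) else range[1]
  hi <- if (is.null(range)) max(values) else range[2]
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best_bcv <- -Inf
  best_edge <- NA_real_
  for (k in 1:(n_bins - 1)) {
    in0 <- bin <= k
    n0 <- sum(in0); n1 <- sum(!in0)
    if (n0 == 0 || n1 == 0) next
    mu0 <- mean(mids[bin[in0]])
    mu1 <- mean(mids[bin[!in0]])
    bcv <- as.numeric(n0) * as.numeric(n1) * (mu0 - mu1)^2
    if (bcv > best_bcv) {
      best_bcv <- bcv
      best_edge <- edges[k + 1]
    }
  }
  best_edge
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n1+n2, n1) group assignments (no ties assumed).
wilcoxon_enumerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Benjamini-Hochberg by the literal step-up definition:
# adj_i = min over j >= i (rank order) of p_(j) * m / j, capped at 1.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Orthonormal stain model: deconvolution is exact (inverse = transpose), so
# toy concentration algebra has no conditioning error.
ortho_stain_model <- function() {
  stain_model(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
}

# Toy count matrix used in worked examples: gene A passes the 50-UMI filter,
# gene B does not, C is outside the set; cell1's score is 6/20 = 0.3.
toy_counts <- function() {
  m <- matrix(c(6, 4, 10,
                50, 0, 50,
                6, 4, 10,
                10, 0, 10), nrow = 3,
              dimnames = list(c("A", "B", "C"),
                              c("cell1", "cell2", "cell3", "cell4")))
  umi_counts(m, cell_groups = c("Control", "MPL", "Control", "MPL"),
             compartment = "stromal")
}

toy_gene_set <- function() {
  gene_set("ECM", c("A", "B"),
           categories = c("collagen", "glycoprotein"))
}
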
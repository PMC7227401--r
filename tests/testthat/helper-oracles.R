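# Independent oracles and small fixture builders used across the suite.

# Build an ExpressionMatrix from a plain matrix, auto-naming dims.
make_em <- function(values, layer = "raw", cell_meta = NULL,
                    genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, cells)
  if (!is.null(cell_meta) && !"cell_id" %in% names(cell_meta))
    rownames(cell_meta) <- cells
  expression_matrix(values, layer, cell_meta)
}

# Quadratic-time brute-force mutual-nearest-neighbour oracle: for every
# (r, q) pair check both kNN memberships directly, ties toward the smaller
# index. Independent of the package's vectorised implementation.
brute_mnn <- function(ref_vals, query_vals, k) {
  nr <- ncol(ref_vals); nq <- ncol(query_vals)
  d <- matrix(0, nr, nq)
  for (i in seq_len(nr))
    for (j in seq_len(nq))
      d[i, j] <- sum((ref_vals[, i] - query_vals[, j])^2)
  out <- NULL
  for (i in seq_len(nr)) {
    knn_q <- order(d[i, ], seq_len(nq))[seq_len(k)]
    for (j in knn_q) {
      knn_r <- order(d[, j], seq_len(nr))[seq_len(k)]
      if (i %in% knn_r) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) return(data.frame(ref = integer(0), query = integer(0)))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  data.frame(ref = out[, 1], query = out[, 2])
}

pairs_sorted <- function(p) {
  p <- p[order(p$ref, p$query), c("ref", "query")]
  rownames(p) <- NULL
  p
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# choose(n1+n2, n1) group assignments (no ties assumed).
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Arbitrary numeric data tagged as the lognorm layer, for unit tests of
# operations that only require that layer.
lognorm_em <- function(vals, ...) make_em(vals, layer = "lognorm", ...)

# Drop zero-total cells (if any) and log-normalise; keeps simulation-based
# tests independent of the QC thresholds under test elsewhere.
lognormalize_safe <- function(m, scale = 1e4) {
  tot <- colSums(m$values)
  if (any(tot == 0)) m <- subset_cells(m, tot > 0)
  lognormalize(m, scale)
}

# A cell column with an exact mitochondrial fraction and detected-gene
# count, on a gene list of one "MT-1" gene plus `n_nonmito` others.
# detected = number of genes with count > 0 (mito gene included when
# mito_counts > 0); extra counts are piled on the last detected gene.
qc_cell <- function(mito_counts, nonmito_total, n_detected_nonmito,
                    n_nonmito) {
  stopifnot(nonmito_total >= n_detected_nonmito)
  col <- numeric(n_nonmito + 1)
  col[1] <- mito_counts
  if (n_detected_nonmito > 0) {
    col[1 + seq_len(n_detected_nonmito)] <- 1
    col[1 + n_detected_nonmito] <-
      1 + nonmito_total - n_detected_nonmito
  }
  col
}
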
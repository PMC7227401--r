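#' Parameters for mutual-nearest-neighbour batch correction
#'
#' @param k nearest neighbours per direction when pairing cells across
#'   datasets.
#' @param sigma Gaussian kernel bandwidth used to smooth pair difference
#'   vectors over the query cells (weights `exp(-d^2 / sigma^2)`);
#'   interpreted on the cosine-normalised (unit-sphere) scale when
#'   `cosine_normalize` is `TRUE`. The default squared bandwidth of ~0.1
#'   matches the smoothing scale of the published MNN algorithm; much
#'   smaller values make the correction so local that query cells collapse
#'   onto their individual pairs.
#' @param cosine_normalize whether [project_all()] cosine-normalises the
#'   inputs before pairing and correction.
#' @return an object of class `AlignmentParams`.
#' @export
alignment_params <- function(k = 20, sigma = 0.3, cosine_normalize = TRUE) {
  if (k < 1) stop("k must be >= 1")
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(k = as.integer(k), sigma = sigma,
                 cosine_normalize = isTRUE(cosine_normalize)),
            class = "AlignmentParams")
}

#' Scale every cell to unit Euclidean norm
#'
#' Standard preprocessing for mutual-nearest-neighbour correction: after
#' cosine normalisation, Euclidean distances between cells are a monotone
#' function of the angle between their expression vectors, removing
#' residual per-cell scale differences.
#'
#' @param m lognorm-layer `ExpressionMatrix`.
#' @return a cosine-layer `ExpressionMatrix`.
#' @export
cosine_normalize <- function(m) {
  stopifnot_layer(m, "lognorm", "cosine_normalize")
  norms <- sqrt(colSums(m$values^2))
  if (any(norms == 0))
    stop("all-zero cells cannot be cosine-normalised: ",
         paste(utils::head(colnames(m$values)[norms == 0], 5),
               collapse = ", "))
  out <- m
  out$values <- sweep(m$values, 2, norms, "/")
  out$layer <- "cosine"
  out
}

# Squared Euclidean distances between columns of a (genes x n) and
# b (genes x m): n x m matrix. Clipped at 0 for numerical safety.
cross_dist2 <- function(a, b) {
  d2 <- outer(colSums(a^2), colSums(b^2), "+") - 2 * crossprod(a, b)
  pmax(d2, 0)
}

# Indices of the k nearest columns of `pool_d2` per row of an n x m
# distance matrix; ties broken by smaller column index.
knn_index <- function(d2, k) {
  t(apply(d2, 1, function(row) order(row, seq_along(row))[seq_len(k)]))
}

# Mutual pairs between ref (genes x nr) and query (genes x nq) columns.
mutual_pairs <- function(ref_vals, query_vals, k) {
  d2 <- cross_dist2(ref_vals, query_vals)        # nr x nq
  nr <- nrow(d2); nq <- ncol(d2)
  nn_q_of_r <- knn_index(d2, k)                  # nr x k query indices
  nn_r_of_q <- knn_index(t(d2), k)               # nq x k ref indices
  in_knn_of_r <- matrix(FALSE, nr, nq)
  in_knn_of_r[cbind(rep(seq_len(nr), k), as.vector(nn_q_of_r))] <- TRUE
  in_knn_of_q <- matrix(FALSE, nr, nq)
  in_knn_of_q[cbind(as.vector(nn_r_of_q), rep(seq_len(nq), k))] <- TRUE
  hits <- which(in_knn_of_r & in_knn_of_q, arr.ind = TRUE)
  data.frame(ref = hits[, 1], query = hits[, 2])
}

#' Find mutual nearest-neighbour pairs across two datasets
#'
#' A pair (r, q) is reported iff reference cell r is among the `k`
#' nearest reference cells of query cell q AND q is among the `k` nearest
#' query cells of r, under Euclidean distance on the shared gene space.
#' Ties are broken toward the smaller cell index, so the result is
#' deterministic.
#'
#' @param ref,query `ExpressionMatrix` objects on an identical gene list
#'   (the selected alignment genes), typically cosine layer.
#' @param params an [alignment_params()] object.
#' @return an object of class `MNNPairSet`: list with a `pairs`
#'   data.frame (`ref`, `query` column indices) and the `k` used.
#' @export
find_mnn_pairs <- function(ref, query, params = alignment_params()) {
  if (!identical(rownames(ref$values), rownames(query$values)))
    stop("ref and query must share an identical gene list")
  k <- params$k
  if (k >= min(ncol(ref$values), ncol(query$values)))
    stop("k = ", k, " must be smaller than both dataset sizes (",
         ncol(ref$values), ", ", ncol(query$values), ")")
  pairs <- mutual_pairs(ref$values, query$values, k)
  structure(list(pairs = pairs, k = k), class = "MNNPairSet")
}

#' @export
print.MNNPairSet <- function(x, ...) {
  cat(sprintf("MNNPairSet: %d mutual pairs (k = %d)\n", nrow(x$pairs), x$k))
  invisible(x)
}

#' Correct a query dataset toward the reference using MNN pairs
#'
#' Each pair contributes a difference vector `ref_cell - query_cell` in
#' gene space. Every query cell receives a correction equal to the
#' Gaussian-kernel-weighted average of all pair difference vectors, with
#' weights `exp(-||cell - paired query cell||^2 / sigma^2)`; cells far
#' from every pair fall back to their nearest pair. The reference is
#' never altered.
#'
#' @param ref,query matrices on an identical gene list; `query` is the
#'   dataset to be moved onto `ref`.
#' @param pairs an `MNNPairSet` from [find_mnn_pairs()].
#' @param params an [alignment_params()] (supplies `sigma`).
#' @return the corrected query `ExpressionMatrix` (layer preserved).
#' @export
correct_query <- function(ref, query, pairs, params = alignment_params()) {
  if (!inherits(pairs, "MNNPairSet") || nrow(pairs$pairs) == 0)
    stop("empty MNN pair set; increase k or check that the datasets share ",
         "populations")
  p <- pairs$pairs
  diffs <- ref$values[, p$ref, drop = FALSE] -
    query$values[, p$query, drop = FALSE]          # genes x P
  d2 <- cross_dist2(query$values,
                    query$values[, p$query, drop = FALSE])  # n x P
  w <- exp(-d2 / params$sigma^2)
  rs <- rowSums(w)
  dead <- rs == 0 | !is.finite(rs)
  if (any(dead)) {           # kernel underflow: snap to the nearest pair
    w[dead, ] <- 0
    w[cbind(which(dead), apply(d2[dead, , drop = FALSE], 1, which.min))] <- 1
    rs <- rowSums(w)
  }
  correction <- diffs %*% t(w / rs)                # genes x n
  out <- query
  out$values <- query$values + correction
  out
}

#' Project query datasets independently onto a fixed reference
#'
#' Orchestrates per-dataset correction: optionally cosine-normalises the
#' reference and each query, finds mutual nearest-neighbour pairs against
#' the reference, and corrects each query. Queries are corrected
#' independently against the same fixed reference (never chained through
#' one another), so the result is invariant to their order. Bulk profiles
#' pass through the identical path, one column per sample.
#'
#' @param ref lognorm-layer (or cosine-layer) reference on the selected
#'   gene list.
#' @param queries list of query `ExpressionMatrix` objects.
#' @param params an [alignment_params()] object.
#' @return list with `ref` (the, possibly cosine-normalised, reference
#'   actually used) and `corrected` (list of corrected queries in input
#'   order).
#' @export
project_all <- function(ref, queries, params = alignment_params()) {
  if (!length(queries)) stop("no query datasets supplied")
  for (q in queries) {
    missing <- setdiff(rownames(ref$values), rownames(q$values))
    if (length(missing))
      stop("query lacks alignment genes: ",
           paste(utils::head(missing, 10), collapse = ", "))
  }
  queries <- lapply(queries, subset_genes, genes = rownames(ref$values))
  if (params$cosine_normalize) {
    ref <- cosine_normalize(ref)
    queries <- lapply(queries, cosine_normalize)
  }
  corrected <- lapply(queries, function(q) {
    p <- params
    # small queries (e.g. a handful of bulk profiles) cannot support the
    # default k; clamp per query rather than refusing the projection
    p$k <- min(p$k, ncol(ref$values) - 1L, ncol(q$values) - 1L)
    pr <- find_mnn_pairs(ref, q, p)
    correct_query(ref, q, pr, p)
  })
  list(ref = ref, corrected = corrected)
}
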
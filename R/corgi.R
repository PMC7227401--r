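#' Parameters for CORGI-style randomized gene-subset selection
#'
#' The selector repeatedly samples gene subsets, scores each subset by how
#' much shared low-dimensional structure it induces across a reference and
#' a query dataset, and multiplicatively rewards (or penalises) the
#' sampled genes' weights when the score beats (or falls below) the
#' running median of past scores. Genes that lead to more structured data
#' are thereby encouraged and vice versa.
#'
#' @param n_iterations number of sampling rounds (>= 10, so the running
#'   median is meaningful).
#' @param subset_size genes drawn per round.
#' @param n_selected genes returned at the end (highest final weight).
#' @param alpha weight step in (0, 1): sampled genes' weights are
#'   multiplied by `1 + alpha` or `1 - alpha`.
#' @param w_variance,w_mixing weights of the two structure-score terms
#'   (top-2-PC variance explained; cross-dataset MNN mixing).
#' @param k neighbours used for the mixing term.
#' @param seed integer seed; selection is deterministic given it.
#' @return an object of class `CorgiParams`.
#' @export
corgi_params <- function(n_iterations = 2000, subset_size = 200,
                         n_selected = 1000, alpha = 0.05,
                         w_variance = 0.5, w_mixing = 0.5, k = 10,
                         seed = 1L) {
  if (n_iterations < 10)
    stop("n_iterations must be >= 10 for a meaningful running median")
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (subset_size < 2) stop("subset_size must be >= 2")
  structure(list(n_iterations = as.integer(n_iterations),
                 subset_size = as.integer(subset_size),
                 n_selected = as.integer(n_selected),
                 alpha = alpha, w_variance = w_variance,
                 w_mixing = w_mixing, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "CorgiParams")
}

# Fraction of total variance captured by the top 2 PCs of cells x genes
# data (columns = the gene subset). Degenerate zero-variance data scores 0.
top2_variance_explained <- function(x) {
  x <- sweep(x, 2, colMeans(x), "-")
  d2 <- svd(x, nu = 0, nv = 0)$d^2
  tot <- sum(d2)
  if (tot <= 0) return(0)
  sum(d2[seq_len(min(2, length(d2)))]) / tot
}

#' Score the shared structure a gene subset induces across two datasets
#'
#' `score = w_variance * mean(top-2-PC variance explained in each dataset)
#'        + w_mixing * (fraction of cells in a cross-dataset mutual
#'          nearest-neighbour pair)`, both computed on the subset-restricted
#' log-normalised data. Higher scores mean the subset induces a low-
#' dimensional geometry in which the two datasets interleave. Deterministic
#' given its inputs.
#'
#' @param ref,query lognorm-layer `ExpressionMatrix` objects whose gene
#'   lists contain all subset genes.
#' @param subset a `GeneSet` (or character vector) of genes to score.
#' @param k neighbours per direction for the mutual-nearest-neighbour
#'   mixing term.
#' @param w_variance,w_mixing term weights.
#' @return a single numeric score.
#' @export
structure_score <- function(ref, query, subset, k = 10,
                            w_variance = 0.5, w_mixing = 0.5) {
  genes <- if (inherits(subset, "GeneSet")) subset$genes else
    as.character(subset)
  missing <- c(setdiff(genes, rownames(ref$values)),
               setdiff(genes, rownames(query$values)))
  if (length(missing))
    stop("subset genes absent from input: ",
         paste(unique(missing), collapse = ", "))
  genes <- sort(genes)   # invariant to subset ordering
  xr <- t(ref$values[genes, , drop = FALSE])
  xq <- t(query$values[genes, , drop = FALSE])
  ve <- (top2_variance_explained(xr) + top2_variance_explained(xq)) / 2
  mix <- 0
  if (w_mixing != 0) {
    kk <- min(k, nrow(xr) - 1, nrow(xq) - 1)
    pairs <- mutual_pairs(t(xr), t(xq), kk)
    mix <- (length(unique(pairs$ref)) + length(unique(pairs$query))) /
      (nrow(xr) + nrow(xq))
  }
  w_variance * ve + w_mixing * mix
}

#' CORGI-style selection of genes inducing shared structure
#'
#' Iteratively samples `subset_size` genes with probability proportional
#' to their current weights, scores the subset with [structure_score()],
#' and multiplies the sampled genes' weights by `1 + alpha` when the score
#' exceeds the running median of all previous scores (by `1 - alpha`
#' otherwise). After `n_iterations` rounds the `n_selected` genes of
#' highest weight are returned (ties broken lexicographically). With
#' `alpha = 0` the weights never change and the lexicographically first
#' genes are returned.
#'
#' @inheritParams structure_score
#' @param params a [corgi_params()] object.
#' @return a `GeneSet` named `"corgi"`, plus attributes `weights` and
#'   `score_history` for inspection.
#' @export
corgi_select <- function(ref, query, params = corgi_params()) {
  shared <- intersect(rownames(ref$values), rownames(query$values))
  if (length(shared) < params$subset_size)
    stop("only ", length(shared), " shared genes but subset_size = ",
         params$subset_size)
  ref <- subset_genes(ref, shared)
  query <- subset_genes(query, shared)
  w <- stats::setNames(rep(1, length(shared)), shared)
  history <- numeric(params$n_iterations)
  withr::with_seed(params$seed, {
    for (i in seq_len(params$n_iterations)) {
      pick <- sample(shared, params$subset_size, prob = w)
      s <- structure_score(ref, query, pick, k = params$k,
                           w_variance = params$w_variance,
                           w_mixing = params$w_mixing)
      history[i] <- s
      if (i > 1 && params$alpha > 0) {
        med <- stats::median(history[seq_len(i - 1)])
        w[pick] <- w[pick] * (if (s > med) 1 + params$alpha else
                                1 - params$alpha)
      }
    }
  })
  ord <- order(-w, names(w))
  sel <- names(w)[ord][seq_len(min(params$n_selected, length(w)))]
  out <- gene_set("corgi", sel)
  attr(out, "weights") <- w
  attr(out, "score_history") <- history
  out
}
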
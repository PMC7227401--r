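#' Fit the 2-D reference PCA embedding
#'
#' The top two principal components are fit on the reference cells only
#' (centred by reference gene means); queries are later projected
#' passively through [embed_cells()], so query composition never warps
#' the atlas. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making the embedding
#' deterministic.
#'
#' @param ref corrected reference `ExpressionMatrix` (lognorm or cosine
#'   layer) on the alignment genes; needs >= 3 cells and >= 2 genes.
#' @param stage_key `cell_meta` column holding the developmental-stage
#'   label of each reference cell.
#' @return an object of class `ReferenceEmbedding`: `loadings`
#'   (gene x 2, orthonormal columns), `center` (per-gene reference mean),
#'   `ref_coords` (cell x 2), `stages` (per reference cell).
#' @export
fit_reference_pca <- function(ref, stage_key = "stage") {
  if (ncol(ref$values) < 3) stop("reference PCA needs >= 3 cells")
  if (nrow(ref$values) < 2) stop("reference PCA needs >= 2 genes")
  center <- rowMeans(ref$values)
  x <- t(ref$values - center)                 # cells x genes
  sv <- svd(x, nu = 0, nv = 2)
  loadings <- sv$v[, 1:2, drop = FALSE]
  for (j in 1:2) {                            # deterministic sign
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  dimnames(loadings) <- list(rownames(ref$values), c("PC1", "PC2"))
  coords <- x %*% loadings
  rownames(coords) <- colnames(ref$values)
  stages <- if (stage_key %in% names(ref$cell_meta))
    as.character(ref$cell_meta[[stage_key]]) else
      rep(NA_character_, ncol(ref$values))
  structure(list(loadings = loadings, center = center,
                 ref_coords = coords, stages = stages),
            class = "ReferenceEmbedding")
}

#' Project cells into the reference PCA plane
#'
#' Applies the frozen reference centring and loadings; the reference
#' embedding is never refit on queries.
#'
#' @param emb a [fit_reference_pca()] embedding.
#' @param m an `ExpressionMatrix` on the same genes (any order).
#' @return a cell x 2 coordinate matrix.
#' @export
embed_cells <- function(emb, m) {
  genes <- rownames(emb$loadings)
  missing <- setdiff(genes, rownames(m$values))
  if (length(missing))
    stop("matrix lacks embedding genes: ",
         paste(utils::head(missing, 10), collapse = ", "))
  if (ncol(m$values) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("PC1", "PC2"))))
  x <- t(m$values[genes, , drop = FALSE] - emb$center)
  coords <- x %*% emb$loadings
  rownames(coords) <- colnames(m$values)
  coords
}

#' Fit the arrow-of-time vector
#'
#' The arrow of time is the unit 2-vector from the embryonic-stage
#' centroid to the adult-stage centroid of the reference embedding; its
#' origin is the centroid of all reference cells, so a pseudotime of 0
#' sits at the middle of the atlas and embryonic cells are negative.
#'
#' @param emb a `ReferenceEmbedding`.
#' @param embryonic_stages,adult_stages stage labels defining the two
#'   anchor populations.
#' @return an object of class `ArrowOfTime`: unit `direction` and
#'   `origin`, both 2-vectors.
#' @export
fit_arrow <- function(emb, embryonic_stages, adult_stages) {
  emb_idx <- emb$stages %in% embryonic_stages
  adu_idx <- emb$stages %in% adult_stages
  if (!any(emb_idx))
    stop("no reference cells in embryonic stages: ",
         paste(embryonic_stages, collapse = ", "))
  if (!any(adu_idx))
    stop("no reference cells in adult stages: ",
         paste(adult_stages, collapse = ", "))
  d <- colMeans(emb$ref_coords[adu_idx, , drop = FALSE]) -
    colMeans(emb$ref_coords[emb_idx, , drop = FALSE])
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("embryonic and adult centroids coincide")
  structure(list(direction = d / nd, origin = colMeans(emb$ref_coords)),
            class = "ArrowOfTime")
}

#' Arrow-of-time pseudotime
#'
#' Pseudotime of a cell is the dot product of its (origin-centred) 2-D
#' PCA coordinates with the arrow-of-time direction: the more negative
#' the estimate, the more embryonic-like the cell.
#'
#' @param arrow an [fit_arrow()] object.
#' @param coords cell x 2 coordinates from [embed_cells()].
#' @param group optional per-cell group label stored alongside.
#' @return a data.frame (`cell_id`, `pseudotime`, `group`).
#' @export
pseudotime <- function(arrow, coords, group = NULL) {
  pt <- as.vector(sweep(coords, 2, arrow$origin, "-") %*% arrow$direction)
  data.frame(cell_id = rownames(coords), pseudotime = pt,
             group = if (is.null(group)) NA_character_ else
               as.character(group),
             stringsAsFactors = FALSE)
}

#' Compare group pseudotime means with a Gaussian linear model
#'
#' Fits `pseudotime ~ group` with the reference group as baseline and
#' reports, for every other group, the mean difference, its standard
#' error and the Wald p-value. With exactly two groups this reproduces
#' the pooled-variance two-sample t-test.
#'
#' @param pt a [pseudotime()] table, or any data.frame with a
#'   `pseudotime` column.
#' @param groups per-cell group labels (defaults to `pt$group`).
#' @param ref_group baseline group label.
#' @return data.frame (`group`, `mean_diff`, `se`, `p_value`).
#' @export
compare_groups <- function(pt, groups = pt$group, ref_group) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2))
    stop("singleton group(s): ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (!ref_group %in% groups) stop("ref_group '", ref_group, "' not present")
  g <- stats::relevel(factor(groups), ref = ref_group)
  fit <- stats::lm(pt$pseudotime ~ g)
  cf <- summary(fit)$coefficients[-1, , drop = FALSE]
  data.frame(group = sub("^g", "", rownames(cf)),
             mean_diff = cf[, "Estimate"], se = cf[, "Std. Error"],
             p_value = cf[, "Pr(>|t|)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-gene correlation with pseudotime, ranked ascending
#'
#' Pearson correlation of each gene's log-normalised expression with
#' pseudotime, sorted ascending so the genes most negatively correlated
#' with developmental time (embryonic-associated genes) lead the table.
#' Constant genes are assigned correlation 0 and flagged, keeping the
#' ranking total.
#'
#' @param m `ExpressionMatrix` over the same cells as `pt`.
#' @param pt a [pseudotime()] table for those cells.
#' @return data.frame (`gene`, `correlation`, `constant`), ascending.
#' @export
gene_pseudotime_correlation <- function(m, pt) {
  if (ncol(m$values) < 3) stop("need >= 3 cells")
  if (!identical(colnames(m$values), pt$cell_id))
    pt <- pt[match(colnames(m$values), pt$cell_id), ]
  if (any(is.na(pt$cell_id)))
    stop("pseudotime table does not cover all cells")
  r <- suppressWarnings(as.vector(stats::cor(t(m$values), pt$pseudotime)))
  constant <- !is.finite(r)
  r[constant] <- 0
  out <- data.frame(gene = rownames(m$values), correlation = r,
                    constant = constant, stringsAsFactors = FALSE)
  out[order(out$correlation, out$gene), , drop = FALSE]
}
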
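#' Quality-control thresholds for UMI count matrices
#'
#' Defaults follow the conventional droplet scRNA-seq gate: cells with more
#' than 5\% mitochondrial counts or fewer than 200 detected genes are
#' discarded. Both bounds are strict in the removal direction, so a cell at
#' exactly 5\% mitochondrial fraction or exactly 200 detected genes is kept.
#'
#' @param max_mito_frac maximum tolerated mitochondrial count fraction.
#' @param min_genes minimum number of detected genes (count > 0).
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes.
#' @param mouse_prefix gene-symbol prefix marking mouse-genome genes
#'   (feeder-cell transcripts in a mixed-species reference).
#' @param max_mouse_frac mouse-count fraction above which a cell is flagged
#'   as a feeder cell.
#' @return an object of class `QCThresholds`.
#' @export
qc_thresholds <- function(max_mito_frac = 0.05, min_genes = 200,
                          mito_prefix = "MT-", mouse_prefix = "mm10-",
                          max_mouse_frac = 0.5) {
  if (!is.numeric(max_mito_frac) || max_mito_frac < 0 || max_mito_frac > 1)
    stop("max_mito_frac must lie in [0, 1]")
  if (!is.numeric(min_genes) || min_genes < 1)
    stop("min_genes must be >= 1")
  if (max_mouse_frac < 0 || max_mouse_frac > 1)
    stop("max_mouse_frac must lie in [0, 1]")
  structure(list(max_mito_frac = max_mito_frac,
                 min_genes = as.integer(min_genes),
                 mito_prefix = mito_prefix,
                 mouse_prefix = mouse_prefix,
                 max_mouse_frac = max_mouse_frac),
            class = "QCThresholds")
}

#' Filter cells on mitochondrial fraction and detected genes
#'
#' Retains exactly the cells whose mitochondrial count fraction is at most
#' `max_mito_frac` and whose detected-gene count (genes with count > 0) is
#' at least `min_genes`. The gene list is unchanged; the operation is
#' idempotent. The retained-cell count is attached as the `"qc_log"`
#' attribute.
#'
#' @param m raw-layer `ExpressionMatrix`.
#' @param thresholds a [qc_thresholds()] object.
#' @return the filtered `ExpressionMatrix`.
#' @export
qc_filter <- function(m, thresholds = qc_thresholds()) {
  stopifnot_layer(m, "raw", "qc_filter")
  mito <- startsWith(rownames(m$values), thresholds$mito_prefix)
  totals <- colSums(m$values)
  mito_frac <- if (any(mito)) colSums(m$values[mito, , drop = FALSE]) else
    rep(0, ncol(m$values))
  frac <- ifelse(totals > 0, mito_frac / pmax(totals, 1), 0)
  detected <- colSums(m$values > 0)
  keep <- frac <= thresholds$max_mito_frac & detected >= thresholds$min_genes
  if (!any(keep)) warning("qc_filter removed every cell")
  out <- subset_cells(m, keep)
  attr(out, "qc_log") <- list(n_in = ncol(m$values), n_out = sum(keep),
                              max_mito_frac = thresholds$max_mito_frac,
                              min_genes = thresholds$min_genes)
  out
}

#' Remove mouse feeder cells and mouse genes
#'
#' Cells whose fraction of counts on mouse-prefixed genes exceeds
#' `max_mouse_frac` are removed (feeder fibroblasts from conditional
#' reprogramming cultures); the mouse-prefixed genes are then dropped from
#' the gene list so downstream analyses see a single-species matrix. With
#' no mouse-prefixed genes present the input is returned unchanged.
#'
#' @inheritParams qc_filter
#' @return an `ExpressionMatrix` without feeder cells or mouse genes.
#' @export
remove_feeder_cells <- function(m, thresholds = qc_thresholds()) {
  mouse <- startsWith(rownames(m$values), thresholds$mouse_prefix)
  if (!any(mouse)) return(m)
  totals <- colSums(m$values)
  frac <- ifelse(totals > 0,
                 colSums(m$values[mouse, , drop = FALSE]) / pmax(totals, 1), 0)
  out <- subset_cells(m, frac <= thresholds$max_mouse_frac)
  subset_genes(out, !mouse)
}

#' Global log-normalisation
#'
#' Each cell is scaled to a common total (`scale`) and log-transformed:
#' `log(1 + count / cell_total * scale)`. Zero counts map to zero, so the
#' sparsity pattern is preserved, and the result is invariant to the
#' sequencing depth of each cell.
#'
#' @param m raw-layer `ExpressionMatrix`; every cell must have total
#'   count > 0.
#' @param scale target per-cell total; `1e4` is the de facto standard.
#' @return a lognorm-layer `ExpressionMatrix`.
#' @export
lognormalize <- function(m, scale = 1e4) {
  stopifnot_layer(m, "raw", "lognormalize")
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  totals <- colSums(m$values)
  if (any(totals == 0))
    stop("cells with zero total counts present; run qc_filter first: ",
         paste(utils::head(colnames(m$values)[totals == 0], 5),
               collapse = ", "))
  out <- m
  out$values <- log1p(sweep(m$values, 2, totals, "/") * scale)
  out$layer <- "lognorm"
  out
}

#' Depth-matched normalisation across batches
#'
#' Log-normalises several raw batches with a single shared scale factor,
#' chosen as the smallest per-batch median library size. This rescales
#' every batch to the sequencing depth of the shallowest one before the
#' log transform, so systematic depth differences between batches do not
#' masquerade as expression differences.
#'
#' @param batches named list of raw-layer `ExpressionMatrix` objects.
#' @return a list of lognorm-layer matrices in the same order.
#' @export
normalize_batches <- function(batches) {
  if (!length(batches)) stop("no batches supplied")
  medians <- vapply(batches, function(b) stats::median(colSums(b$values)),
                    numeric(1))
  target <- min(medians)
  lapply(batches, lognormalize, scale = target)
}

#' Downsample cells, optionally stratified
#'
#' Two modes. `"proportional"` draws `n` cells overall while preserving
#' the stratum proportions of the input via largest-remainder rounding, so
#' the sampled composition mirrors the original dataset. `"equal_per_stratum"`
#' draws `n / n_strata` cells from each stratum (e.g. 250 cells from each
#' of four stages for `n = 1000`). Sampling is without replacement and
#' reproducible for a fixed seed.
#'
#' @param m an `ExpressionMatrix` (any layer).
#' @param n total number of cells to retain.
#' @param stratify_by name of a `cell_meta` column defining strata;
#'   required for `"equal_per_stratum"`.
#' @param mode `"proportional"` or `"equal_per_stratum"`.
#' @param seed integer seed controlling the draw.
#' @return the downsampled `ExpressionMatrix` (cells in original order).
#' @export
downsample <- function(m, n, stratify_by = NULL,
                       mode = c("proportional", "equal_per_stratum"),
                       seed = 1L) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (n < 1) stop("n must be positive")
  n_cells <- ncol(m$values)
  strata <- if (is.null(stratify_by)) rep("all", n_cells) else {
    if (!stratify_by %in% names(m$cell_meta))
      stop("cell_meta has no column '", stratify_by, "'")
    as.character(m$cell_meta[[stratify_by]])
  }
  levels <- unique(strata)
  if (mode == "proportional") {
    if (n >= n_cells) {
      warning("requested ", n, " cells but only ", n_cells,
              " available; returning input unchanged")
      return(m)
    }
    quota <- largest_remainder(n * table(factor(strata, levels))[levels] /
                                 n_cells, n)
  } else {
    if (is.null(stratify_by))
      stop("equal_per_stratum mode requires stratify_by")
    if (n %% length(levels) != 0)
      stop("n = ", n, " is not divisible by the ", length(levels), " strata")
    per <- n %/% length(levels)
    sizes <- table(factor(strata, levels))
    short <- levels[sizes < per]
    if (length(short))
      stop("stratum too small for ", per, " cells: ",
           paste(short, collapse = ", "))
    quota <- stats::setNames(rep(per, length(levels)), levels)
  }
  idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(levels, function(s) {
      pool <- which(strata == s)
      if (quota[[s]] >= length(pool)) pool else
        sample(pool, quota[[s]], replace = FALSE)
    }), use.names = FALSE)
  })
  subset_cells(m, sort(idx))
}

# Largest-remainder rounding of non-negative real quotas to integers summing
# to `total`; ties broken by position.
largest_remainder <- function(quota, total) {
  q <- as.numeric(quota)
  base <- floor(q)
  rem <- q - base
  extra <- total - sum(base)
  if (extra > 0) {
    up <- order(-rem, seq_along(q))[seq_len(extra)]
    base[up] <- base[up] + 1
  }
  stats::setNames(as.integer(base), names(quota))
}
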
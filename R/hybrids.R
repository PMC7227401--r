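#' Parameters for marker-percentile hybrid classification
#'
#' Hybrid cell states are called from four markers: luminal keratin
#' (KRT18), basal keratin (KRT14), epithelial (EPCAM) and mesenchymal
#' (VIM). A cell is a "high expressor" of a marker when its
#' log-normalised expression is at or above the configured percentile of
#' that marker over all analysed cells. Because sparse markers can have a
#' median of zero — in which case every cell would trivially be "high" —
#' the default additionally requires nonzero expression.
#'
#' @param luminal,basal,epithelial,mesenchymal marker gene symbols; the
#'   four must be distinct. CDH1 may be substituted for EPCAM via
#'   `epithelial`.
#' @param percentile threshold percentile in (0, 100].
#' @param require_nonzero require expression > 0 in addition to the
#'   percentile criterion.
#' @return an object of class `HybridParams`.
#' @export
hybrid_params <- function(luminal = "KRT18", basal = "KRT14",
                          epithelial = "EPCAM", mesenchymal = "VIM",
                          percentile = 50, require_nonzero = TRUE) {
  markers <- c(luminal = luminal, basal = basal, epithelial = epithelial,
               mesenchymal = mesenchymal)
  if (anyDuplicated(markers))
    stop("the four marker genes must be distinct")
  if (percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]")
  structure(list(markers = markers, percentile = percentile,
                 require_nonzero = isTRUE(require_nonzero)),
            class = "HybridParams")
}

#' Marker thresholds at the configured percentile
#'
#' The threshold of each marker is the linearly interpolated percentile
#' of its expression across all cells of the analysed matrix (zeros
#' included).
#'
#' @param m lognorm-layer `ExpressionMatrix`.
#' @param params a [hybrid_params()] object.
#' @return named numeric vector of per-marker thresholds.
#' @export
marker_thresholds <- function(m, params = hybrid_params()) {
  stopifnot_layer(m, "lognorm", "marker_thresholds")
  for (mk in params$markers)
    if (!mk %in% rownames(m$values))
      stop("marker gene absent from matrix: ", mk)
  vapply(params$markers, function(mk)
    unname(stats::quantile(m$values[mk, ], params$percentile / 100,
                           type = 7)),
    numeric(1))
}

#' Classify hybrid luminal/basal and epithelial/mesenchymal cells
#'
#' A cell high for both keratins (KRT14 and KRT18) is a luminal/basal
#' (`LB`) double positive; high for both EPCAM and VIM an
#' epithelial/mesenchymal (`EM`) double positive; high for all four a
#' quadruple positive (`quad`), which by construction belongs to both
#' double-positive sets. Labels give `quad` precedence; the `lb` and
#' `em` logical columns count quads inclusively.
#'
#' @inheritParams marker_thresholds
#' @return data.frame (`cell_id`, `luminal_high`, `basal_high`,
#'   `epithelial_high`, `mesenchymal_high`, `lb`, `em`, `quad`, `label`)
#'   with the thresholds used attached as attribute `"thresholds"`.
#' @export
classify_hybrids <- function(m, params = hybrid_params()) {
  thr <- marker_thresholds(m, params)
  high <- sapply(names(params$markers), function(role) {
    v <- m$values[params$markers[[role]], ]
    h <- v >= thr[[role]]
    if (params$require_nonzero) h <- h & v > 0
    h
  })
  lb <- high[, "luminal"] & high[, "basal"]
  em <- high[, "epithelial"] & high[, "mesenchymal"]
  quad <- lb & em
  label <- ifelse(quad, "quad", ifelse(lb, "LB", ifelse(em, "EM", "none")))
  out <- data.frame(cell_id = colnames(m$values),
                    luminal_high = high[, "luminal"],
                    basal_high = high[, "basal"],
                    epithelial_high = high[, "epithelial"],
                    mesenchymal_high = high[, "mesenchymal"],
                    lb = lb, em = em, quad = quad, label = label,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thr
  out
}

#' Hybrid proportions per group
#'
#' Percentages of luminal/basal, epithelial/mesenchymal and quadruple
#' positive cells per group (e.g. developmental stage). Double-positive
#' percentages count every cell meeting the pair criteria, quadruple
#' positives included.
#'
#' @param calls a [classify_hybrids()] table.
#' @param groups per-cell group labels, aligned with `calls`.
#' @return data.frame (`group`, `n_cells`, `pct_lb`, `pct_em`,
#'   `pct_quad`).
#' @export
hybrid_proportions <- function(calls, groups) {
  groups <- as.character(groups)
  if (length(groups) != nrow(calls))
    stop("groups must have one label per cell")
  split_idx <- split(seq_len(nrow(calls)), groups)
  rows <- lapply(names(split_idx), function(g) {
    i <- split_idx[[g]]
    data.frame(group = g, n_cells = length(i),
               pct_lb = 100 * mean(calls$lb[i]),
               pct_em = 100 * mean(calls$em[i]),
               pct_quad = 100 * mean(calls$quad[i]))
  })
  do.call(rbind, rows)
}

#' Per-cell embryonic-stem-cell score
#'
#' The ESC score of a cell is the proportion of its total raw counts that
#' fall on genes of the embryonic-stem-cell gene set: a higher score
#' means a greater share of the cell's reads derive from embryonic-stem-
#' cell-associated genes. Computed on raw counts, not normalised values.
#'
#' @param m_raw raw-layer `ExpressionMatrix` with positive cell totals.
#' @param esc a `GeneSet`; members absent from the matrix are ignored
#'   (with a warning if none are present).
#' @return named numeric vector of per-cell scores in [0, 1].
#' @export
esc_score <- function(m_raw, esc) {
  stopifnot_layer(m_raw, "raw", "esc_score")
  totals <- colSums(m_raw$values)
  if (any(totals == 0))
    stop("cells with zero totals present; run qc_filter first")
  present <- intersect(esc$genes, rownames(m_raw$values))
  if (!length(present)) {
    warning("gene set '", esc$name, "' shares no genes with the matrix; ",
            "all scores are 0")
    return(stats::setNames(rep(0, ncol(m_raw$values)),
                           colnames(m_raw$values)))
  }
  colSums(m_raw$values[present, , drop = FALSE]) / totals
}

#' Rank-sum differential expression between two cell groups
#'
#' Desk-scale plumbing DE: per-gene Wilcoxon rank-sum p-values between
#' two disjoint cell groups on the log-normalised layer, a log2 fold
#' change of group means (with a tiny pseudocount), and Benjamini-
#' Hochberg FDR.
#'
#' @param m lognorm-layer `ExpressionMatrix`.
#' @param group1,group2 disjoint cell-id vectors (or indices), each of
#'   size >= 3.
#' @return data.frame (`gene`, `log2fc`, `p_value`, `fdr`), genes in
#'   matrix order.
#' @export
simple_de <- function(m, group1, group2) {
  stopifnot_layer(m, "lognorm", "simple_de")
  ids <- colnames(m$values)
  g1 <- if (is.character(group1)) group1 else ids[group1]
  g2 <- if (is.character(group2)) group2 else ids[group2]
  if (length(intersect(g1, g2)))
    stop("groups overlap: ",
         paste(utils::head(intersect(g1, g2), 5), collapse = ", "))
  if (length(g1) < 3 || length(g2) < 3)
    stop("both groups need >= 3 cells")
  x1 <- m$values[, g1, drop = FALSE]
  x2 <- m$values[, g2, drop = FALSE]
  eps <- 1e-9
  lfc <- log2((rowMeans(x1) + eps) / (rowMeans(x2) + eps))
  p <- vapply(seq_len(nrow(m$values)), function(i) {
    a <- x1[i, ]; b <- x2[i, ]
    if (all(a == a[1]) && all(b == a[1])) return(1)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }, numeric(1))
  data.frame(gene = rownames(m$values), log2fc = lfc, p_value = p,
             fdr = stats::p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Overlap of significant DE genes with a gene signature
#'
#' Intersects the genes significant at `fdr_cut` with a signature (e.g.
#' the 200-gene EMT hallmark set) and splits the overlap by fold-change
#' direction; `n_up + n_down = n_overlap` always (a zero fold change
#' counts as up).
#'
#' @param de a [simple_de()] result.
#' @param sig a `GeneSet`.
#' @param fdr_cut significance cutoff in (0, 1].
#' @return list (`n_overlap`, `n_up_in_group1`, `n_down_in_group1`).
#' @export
signature_overlap <- function(de, sig, fdr_cut = 0.05) {
  if (!inherits(sig, "GeneSet")) sig <- gene_set("signature", sig)
  if (fdr_cut <= 0 || fdr_cut > 1) stop("fdr_cut must lie in (0, 1]")
  hit <- de[de$fdr < fdr_cut & de$gene %in% sig$genes, , drop = FALSE]
  list(n_overlap = nrow(hit),
       n_up_in_group1 = sum(hit$log2fc >= 0),
       n_down_in_group1 = sum(hit$log2fc < 0))
}
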
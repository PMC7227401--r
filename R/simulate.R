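#' Configuration for the synthetic mammary-atlas simulator
#'
#' The simulator emulates a branching mammary developmental trajectory:
#' cells carry a latent time in [0, 1] (0 = embryonic, 1 = adult), develop
#' along a common path until `branch_time` and then commit to a luminal or
#' basal lineage. Gene programs (epithelial, mesenchymal, luminal keratin,
#' basal keratin, embryonic-stem-cell, housekeeping, pure noise) are
#' activated as smooth functions of latent time and lineage; embryonic
#' cells co-express both keratin programs at an intermediate level and
#' activate the stem-cell program. Counts are negative-binomial with
#' log-normal library sizes. Hybrid cells (luminal/basal, epithelial/
#' mesenchymal, or quadruple positive), stem-like cells and mouse feeder
#' cells can be planted with known labels.
#'
#' The default stage table is the four-stage reference atlas actually used
#' for alignment (embryonic day 16, embryonic day 18, postnatal day 4,
#' adult) with 1000 cells weighted toward the adult gland.
#'
#' @param stages data.frame with columns `name`, `n_cells`, `t_min`,
#'   `t_max`, `hybrid_frac`, `stem_frac`: one row per developmental stage;
#'   latent times are drawn uniformly on [`t_min`, `t_max`].
#' @param branch_time latent time of the luminal/basal fork.
#' @param n_genes named integer vector: genes per program.
#' @param loadings named numeric vector: natural-log fold activation of
#'   each structured program (full activation multiplies a gene's relative
#'   expression by `exp(loading)`).
#' @param hybrid_activation program activation given to planted hybrid
#'   cells; slightly above the lineage maximum of 1 so that co-expression,
#'   not single-marker extremity, defines the hybrid state.
#' @param dispersion negative-binomial dispersion (1/size); typical UMI
#'   data sit near 0.1-0.3.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param batch_lfc_sd sd of gene-wise Gaussian log-fold batch offsets
#'   applied by [generate_query()].
#' @param feeder_frac fraction of query cells that are mouse feeder cells.
#' @param n_mouse_genes number of mouse-prefixed genes carried by feeder
#'   cells (includes `mm10-Gapdh`).
#' @param mouse_prefix prefix for the mouse gene block.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return an object of class `SimulationConfig`.
#' @export
sim_config <- function(stages = default_stages(),
                       branch_time = 0.6,
                       n_genes = c(epithelial = 40, mesenchymal = 40,
                                   luminal_keratin = 40, basal_keratin = 40,
                                   esc_program = 100, housekeeping = 80,
                                   noise = 120),
                       loadings = c(epithelial = 3.0, mesenchymal = 2.5,
                                    luminal_keratin = 2.5,
                                    basal_keratin = 2.5,
                                    esc_program = 2.8),
                       hybrid_activation = 1.4,
                       dispersion = 0.1,
                       libsize_meanlog = log(3500), libsize_sdlog = 0.35,
                       batch_lfc_sd = 0.5,
                       feeder_frac = 0,
                       n_mouse_genes = 25,
                       mouse_prefix = "mm10-",
                       seed = 1L) {
  stages <- as.data.frame(stages)
  req <- c("name", "n_cells", "t_min", "t_max", "hybrid_frac", "stem_frac")
  miss <- setdiff(req, names(stages))
  if (length(miss))
    stop("stages table lacks columns: ", paste(miss, collapse = ", "))
  bad <- function(cond, what) if (cond) stop("invalid config field: ", what)
  bad(any(stages$n_cells < 1), "stages$n_cells must be positive")
  bad(any(stages$t_min < 0 | stages$t_max > 1 | stages$t_min > stages$t_max),
      "stage latent-time ranges must satisfy 0 <= t_min <= t_max <= 1")
  bad(any(stages$hybrid_frac < 0 | stages$hybrid_frac > 1),
      "stages$hybrid_frac must lie in [0, 1]")
  bad(any(stages$stem_frac < 0 | stages$stem_frac > 1),
      "stages$stem_frac must lie in [0, 1]")
  bad(branch_time <= 0 || branch_time >= 1, "branch_time must lie in (0, 1)")
  bad(dispersion <= 0, "dispersion must be > 0")
  bad(feeder_frac < 0 || feeder_frac > 1, "feeder_frac must lie in [0, 1]")
  bad(batch_lfc_sd < 0, "batch_lfc_sd must be >= 0")
  programs <- c("epithelial", "mesenchymal", "luminal_keratin",
                "basal_keratin", "esc_program", "housekeeping", "noise")
  miss <- setdiff(programs, names(n_genes))
  if (length(miss))
    stop("n_genes lacks programs: ", paste(miss, collapse = ", "))
  structure(list(stages = stages, branch_time = branch_time,
                 n_genes = n_genes, loadings = loadings,
                 hybrid_activation = hybrid_activation,
                 dispersion = dispersion,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog,
                 batch_lfc_sd = batch_lfc_sd,
                 feeder_frac = feeder_frac,
                 n_mouse_genes = n_mouse_genes,
                 mouse_prefix = mouse_prefix,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Default stage tables for the simulator
#'
#' `default_stages()` is the four-stage reference atlas (E16, E18, P4,
#' Adult; 1000 cells, adult-weighted, small natural hybrid fractions).
#' `adult_series_stages()` is a four-stage adult pregnancy series
#' (nulliparous, gestation, lactation, post-involution): the gestation
#' stage revisits more embryonic-like latent times and is enriched for
#' hybrid cells, the lactation stage partially recovers, and the
#' post-involution stage returns to the nulliparous state with few
#' hybrids.
#'
#' @param n_cells total cells, split across the four stages.
#' @return a stages `data.frame` for [sim_config()].
#' @export
default_stages <- function(n_cells = 1000) {
  w <- c(0.15, 0.20, 0.25, 0.40)
  data.frame(name = c("E16", "E18", "P4", "Adult"),
             n_cells = largest_remainder(n_cells * w, n_cells),
             t_min = c(0.00, 0.25, 0.60, 0.85),
             t_max = c(0.20, 0.50, 0.85, 1.00),
             hybrid_frac = c(0.06, 0.06, 0.06, 0.06),
             stem_frac = 0)
}

#' @rdname default_stages
#' @export
adult_series_stages <- function(n_cells = 1000) {
  data.frame(name = c("NP", "G", "L", "PI"),
             n_cells = largest_remainder(rep(n_cells / 4, 4), n_cells),
             t_min = c(0.85, 0.45, 0.65, 0.85),
             t_max = c(1.00, 0.70, 0.90, 1.00),
             hybrid_frac = c(0.02, 0.20, 0.12, 0.02),
             stem_frac = 0)
}

# Gene program table: symbol, program, baseline log-mean, loading.
# Marker analogs KRT18 / KRT14 / EPCAM / VIM head their programs so that
# downstream defaults work unchanged.
make_gene_table <- function(cfg) {
  heads <- c(epithelial = "EPCAM", mesenchymal = "VIM",
             luminal_keratin = "KRT18", basal_keratin = "KRT14")
  withr::with_seed(cfg$seed, {
    rows <- lapply(names(cfg$n_genes), function(p) {
      k <- cfg$n_genes[[p]]
      if (k == 0) return(NULL)
      sym <- sprintf("%s%03d", toupper(substr(p, 1, 3)), seq_len(k))
      base <- switch(p,
                     housekeeping = stats::rnorm(k, 1.5, 0.5),
                     noise = stats::rnorm(k, 0.5, 1.0),
                     stats::rnorm(k, 0, 0.3))
      if (p %in% names(heads)) {
        sym[1] <- heads[[p]]
        base[1] <- 1.2   # canonical markers are abundantly expressed
      }
      data.frame(gene = sym, program = p, base = base,
                 loading = if (p %in% names(cfg$loadings))
                   cfg$loadings[[p]] else 0)
    })
    do.call(rbind, rows)
  })
}

# Program activations for one cell state. Pre-branch cells co-express both
# keratin programs at 0.5 and are epithelial-dominant; committed lineages
# ramp their own keratin up and the other down. Planted hybrids override
# the relevant programs with cfg$hybrid_activation.
cell_activations <- function(t, lineage, hybrid, stem, branch_time,
                             hybrid_activation) {
  if (lineage == "pre_branch") {
    a <- c(epithelial = 0.7, mesenchymal = 0.4,
           luminal_keratin = 0.5, basal_keratin = 0.5)
  } else {
    s <- (t - branch_time) / (1 - branch_time)
    if (lineage == "luminal") {
      a <- c(epithelial = 0.8, mesenchymal = 0.1,
             luminal_keratin = 0.5 + 0.5 * s,
             basal_keratin = 0.5 * (1 - s))
    } else {
      a <- c(epithelial = 0.25, mesenchymal = 0.8,
             luminal_keratin = 0.5 * (1 - s),
             basal_keratin = 0.5 + 0.5 * s)
    }
  }
  esc <- max(0, 1 - t)   # embryonic program decays across the life course
  if (stem) esc <- 1
  if (hybrid == "LB" || hybrid == "quad")
    a[c("luminal_keratin", "basal_keratin")] <- hybrid_activation
  if (hybrid == "EM" || hybrid == "quad")
    a[c("epithelial", "mesenchymal")] <- hybrid_activation
  c(a, esc_program = esc, housekeeping = 1, noise = 1)
}

# Draw the latent cell table for one batch from a config.
draw_cell_states <- function(cfg, batch_id) {
  stages <- cfg$stages
  n_total <- sum(stages$n_cells)
  rows <- lapply(seq_len(nrow(stages)), function(i) {
    n <- stages$n_cells[i]
    t <- stats::runif(n, stages$t_min[i], stages$t_max[i])
    lineage <- ifelse(t < cfg$branch_time, "pre_branch",
                      sample(c("luminal", "basal"), n, replace = TRUE))
    hybrid <- rep("none", n)
    n_hyb <- round(stages$hybrid_frac[i] * n)
    if (n_hyb > 0) {
      pick <- sample.int(n, n_hyb)
      hybrid[pick] <- sample(c("LB", "EM", "quad"), n_hyb, replace = TRUE)
    }
    stem <- stats::runif(n) < stages$stem_frac[i]
    data.frame(latent_time = t, lineage = lineage,
               stage = stages$name[i], hybrid_label = hybrid,
               stem_flag = stem)
  })
  cells <- do.call(rbind, rows)
  cells$batch <- batch_id
  cells$is_feeder <- stats::runif(n_total) < cfg$feeder_frac
  cells$cell_id <- sprintf("%s_c%04d", batch_id, seq_len(n_total))
  rownames(cells) <- cells$cell_id
  cells
}

# Sample NB counts for the given cell table against a gene table; optional
# per-gene log offsets (batch effect), optional mouse feeder gene block.
sample_counts <- function(cells, genes, cfg, gene_offset = NULL) {
  n_cells <- nrow(cells)
  n_genes <- nrow(genes)
  act <- vapply(seq_len(n_cells), function(i)
    cell_activations(cells$latent_time[i], cells$lineage[i],
                     cells$hybrid_label[i], cells$stem_flag[i],
                     cfg$branch_time, cfg$hybrid_activation),
    numeric(7))
  prog_idx <- match(genes$program, rownames(act))
  log_rel <- matrix(genes$base, n_genes, n_cells) +
    genes$loading * act[prog_idx, , drop = FALSE]
  if (!is.null(gene_offset)) log_rel <- log_rel + gene_offset
  rel <- exp(log_rel)
  any_feeder <- any(cells$is_feeder)
  mouse_block <- NULL
  if (any_feeder && cfg$n_mouse_genes > 0) {
    mouse_sym <- c(paste0(cfg$mouse_prefix, "Gapdh"),
                   sprintf("%sGene%03d", cfg$mouse_prefix,
                           seq_len(cfg$n_mouse_genes - 1)))
    mouse_rel <- matrix(exp(stats::rnorm(cfg$n_mouse_genes, 1, 0.5)),
                        cfg$n_mouse_genes, n_cells)
    mouse_rel[, !cells$is_feeder] <- 0
    rel[, cells$is_feeder] <- 0
    rel <- rbind(rel, mouse_rel)
    mouse_block <- mouse_sym
  }
  prop <- sweep(rel, 2, colSums(rel), "/")
  libsize <- stats::rlnorm(n_cells, cfg$libsize_meanlog, cfg$libsize_sdlog)
  mu <- sweep(prop, 2, libsize, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / cfg$dispersion),
                   nrow(mu), n_cells)
  rownames(counts) <- c(genes$gene, mouse_block)
  colnames(counts) <- cells$cell_id
  counts
}

#' Generate the synthetic reference atlas
#'
#' Draws a reference dataset from the configured branching trajectory and
#' returns the count matrix together with a `SyntheticTruth` object: the
#' planted per-cell latent state (latent time, lineage, stage, hybrid and
#' stem labels) and the per-gene program table, which downstream query and
#' bulk generators reuse so that all synthetic datasets share one latent
#' manifold.
#'
#' @param cfg a [sim_config()].
#' @param batch_id name recorded as the batch / dataset of these cells.
#' @return a list with elements `matrix` (raw-layer `ExpressionMatrix`
#'   with `dataset`, `stage`, `individual` metadata) and `truth`
#'   (class `SyntheticTruth`: `cells`, `genes`, `config`).
#' @export
generate_reference <- function(cfg = sim_config(), batch_id = "reference") {
  genes <- make_gene_table(cfg)
  withr::with_seed(cfg$seed + 1L, {
    cells <- draw_cell_states(cfg, batch_id)
    counts <- sample_counts(cells, genes, cfg)
  })
  meta <- data.frame(dataset = batch_id, stage = cells$stage,
                     individual = paste0(batch_id, "1"),
                     row.names = cells$cell_id)
  truth <- structure(list(cells = cells, genes = genes, config = cfg),
                     class = "SyntheticTruth")
  list(matrix = expression_matrix(counts, "raw", meta), truth = truth)
}

#' Generate a query dataset sharing the reference's latent manifold
#'
#' Query cells are drawn from the same gene programs as the reference
#' (carried in `truth`) under a possibly different stage composition
#' (`cfg`), then perturbed by a gene-wise Gaussian log-fold batch offset
#' with sd `cfg$batch_lfc_sd`. A fraction `cfg$feeder_frac` of cells are
#' mouse feeder cells expressing only mouse-prefixed genes (including
#' `mm10-Gapdh`). Raising `stem_frac`/`hybrid_frac` in `cfg$stages` yields
#' a conditional-reprogramming-like query enriched for stem and hybrid
#' states.
#'
#' @param truth the `SyntheticTruth` from [generate_reference()].
#' @param cfg a [sim_config()] describing the query batch (stage table,
#'   fractions, batch sd, its own seed).
#' @param batch_id name of the query batch.
#' @return a list `matrix` + `truth` as in [generate_reference()]; the
#'   truth additionally records the per-gene batch offset.
#' @export
generate_query <- function(truth, cfg, batch_id) {
  if (!inherits(truth, "SyntheticTruth"))
    stop("truth must come from generate_reference()")
  genes <- truth$genes
  qcfg <- cfg
  qcfg$branch_time <- truth$config$branch_time   # shared manifold geometry
  withr::with_seed(qcfg$seed + 2L, {
    cells <- draw_cell_states(qcfg, batch_id)
    offset <- if (qcfg$batch_lfc_sd > 0)
      stats::rnorm(nrow(genes), 0, qcfg$batch_lfc_sd) else NULL
    counts <- sample_counts(cells, genes, qcfg, gene_offset = offset)
  })
  meta <- data.frame(dataset = batch_id, stage = cells$stage,
                     individual = paste0(batch_id, "1"),
                     row.names = cells$cell_id)
  out_truth <- structure(list(cells = cells, genes = genes, config = qcfg,
                              batch_offset = offset),
                         class = "SyntheticTruth")
  list(matrix = expression_matrix(counts, "raw", meta), truth = out_truth)
}

#' Generate bulk profiles as mixtures of developmental states
#'
#' Each bulk sample is a library-size-scaled weighted combination of the
#' expected expression profiles of the reference stages, plus
#' negative-binomial noise; a tumour-like sample is emulated by weighting
#' toward embryonic or adult states. Stage profiles are computed by
#' averaging the generative mean over a fixed grid of latent times within
#' each stage (lineages mixed equally past the branch), so the operation
#' is deterministic given the truth.
#'
#' @param truth `SyntheticTruth` from [generate_reference()].
#' @param mixtures list of `list(weights = <named vector over stages,
#'   summing to 1>, n_samples = <int>)`.
#' @param libsize_meanlog log library size of a bulk sample.
#' @param dispersion NB dispersion; `0` disables noise (deterministic
#'   rounded means).
#' @param seed integer seed.
#' @return a raw-layer `ExpressionMatrix`, one column per bulk sample,
#'   with `dataset = "bulk"` and a `mixture` metadata column.
#' @export
generate_bulk <- function(truth, mixtures, libsize_meanlog = log(5e5),
                          dispersion = 0.05, seed = 1L) {
  if (!inherits(truth, "SyntheticTruth"))
    stop("truth must come from generate_reference()")
  cfg <- truth$config
  genes <- truth$genes
  stage_names <- cfg$stages$name
  profiles <- vapply(seq_len(nrow(cfg$stages)), function(i) {
    ts <- seq(cfg$stages$t_min[i], cfg$stages$t_max[i], length.out = 25)
    rel <- rowMeans(vapply(ts, function(t) {
      lins <- if (t < cfg$branch_time) "pre_branch" else
        c("luminal", "basal")
      rowMeans(vapply(lins, function(l) {
        a <- cell_activations(t, l, "none", FALSE, cfg$branch_time,
                              cfg$hybrid_activation)
        exp(genes$base + genes$loading * a[genes$program])
      }, numeric(nrow(genes))))
    }, numeric(nrow(genes))))
    rel / sum(rel)
  }, numeric(nrow(genes)))
  colnames(profiles) <- stage_names
  cols <- list(); labels <- character(0)
  withr::with_seed(as.integer(seed), {
    for (j in seq_along(mixtures)) {
      mix <- mixtures[[j]]
      w <- mix$weights
      if (any(w < 0)) stop("mixture weights must be non-negative")
      if (abs(sum(w) - 1) > 1e-9)
        stop("mixture ", j, " weights sum to ", sum(w), ", not 1")
      miss <- setdiff(names(w), stage_names)
      if (length(miss))
        stop("unknown states in mixture ", j, ": ",
             paste(miss, collapse = ", "))
      prop <- as.vector(profiles[, names(w), drop = FALSE] %*% w)
      prop <- prop / sum(prop)
      for (s in seq_len(mix$n_samples)) {
        mu <- prop * exp(libsize_meanlog)
        cnt <- if (dispersion > 0)
          stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
        else round(mu)
        cols[[length(cols) + 1L]] <- cnt
        labels <- c(labels, sprintf("mix%d", j))
      }
    }
  })
  counts <- do.call(cbind, cols)
  rownames(counts) <- genes$gene
  colnames(counts) <- sprintf("bulk_%s_s%03d", labels, seq_along(labels))
  meta <- data.frame(dataset = "bulk", mixture = labels,
                     row.names = colnames(counts))
  expression_matrix(counts, "raw", meta)
}

#' Write a SyntheticTruth cell table as TSV
#' @param truth a `SyntheticTruth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  cols <- c("cell_id", "latent_time", "lineage", "stage", "hybrid_label",
            "stem_flag", "batch", "is_feeder")
  utils::write.table(truth$cells[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
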
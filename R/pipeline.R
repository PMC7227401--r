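#' Derive a stage-specific seed from the global seed
#'
#' Each stochastic pipeline stage is seeded by hashing the global seed
#' with the stage name, so adding or reordering stages never perturbs the
#' randomness of other stages.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return a deterministic integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- as.double(seed) %% 2147483647
  for (u in utf8ToInt(stage)) h <- (h * 131 + u) %% 2147483647
  as.integer(h)
}

# Deterministic md5 of an R object (timestamp-free serialisation).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Assemble a pipeline configuration
#'
#' @param datasets named list; each entry is a list with fields `data`
#'   (an `ExpressionMatrix`, or a path readable by [read_counts()]),
#'   `role` (`"reference"`, `"query_sc"` or `"query_bulk"`), optional
#'   `format` and `meta_path` for path input, optional `downsample`
#'   (list with `n`, optional `mode`, `stratify_by`). Exactly one entry
#'   must have the reference role.
#' @param qc a [qc_thresholds()] object.
#' @param corgi a [corgi_params()] object (used when `gene_set` is NULL).
#' @param alignment an [alignment_params()] object.
#' @param hybrid a [hybrid_params()] object.
#' @param embryonic_stages,adult_stages stage labels anchoring the
#'   arrow of time on the reference.
#' @param stage_key `cell_meta` column holding stage labels.
#' @param gene_set optional `GeneSet` of alignment genes; when NULL the
#'   pipeline runs [corgi_select()] on the reference and the first
#'   single-cell query.
#' @param esc_set optional `GeneSet` for per-cell ESC scores.
#' @param signature optional `GeneSet` overlapped with the quad-hybrid
#'   differential expression result.
#' @param seed global seed; every stochastic stage derives its own seed
#'   from it via [derive_seed()].
#' @param outdir optional directory; when set, all result tables are
#'   written there as TSV with a config-hash header comment.
#' @return a `PipelineConfig` (validate with [validate_config()]).
#' @export
pipeline_config <- function(datasets,
                            qc = qc_thresholds(),
                            corgi = corgi_params(),
                            alignment = alignment_params(),
                            hybrid = hybrid_params(),
                            embryonic_stages = c("E16", "E18"),
                            adult_stages = "Adult",
                            stage_key = "stage",
                            gene_set = NULL,
                            esc_set = NULL,
                            signature = NULL,
                            seed = 1L,
                            outdir = NULL) {
  structure(list(datasets = datasets, qc = qc, corgi = corgi,
                 alignment = alignment, hybrid = hybrid,
                 embryonic_stages = embryonic_stages,
                 adult_stages = adult_stages, stage_key = stage_key,
                 gene_set = gene_set, esc_set = esc_set,
                 signature = signature, seed = as.integer(seed),
                 outdir = outdir),
            class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Checks all config invariants (exactly one reference dataset, known
#' roles and keys, resolvable paths, parameter-object classes), injects
#' defaults for omitted dataset fields, and returns the effective config;
#' a validated config re-validates to itself.
#'
#' @param cfg a [pipeline_config()] object.
#' @return the validated config (attribute `"validated"` set).
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "PipelineConfig"))
    stop("cfg must be built with pipeline_config()")
  allowed <- c("datasets", "qc", "corgi", "alignment", "hybrid",
               "embryonic_stages", "adult_stages", "stage_key", "gene_set",
               "esc_set", "signature", "seed", "outdir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!length(cfg$datasets) || is.null(names(cfg$datasets)) ||
      any(!nzchar(names(cfg$datasets))))
    stop("datasets must be a non-empty named list")
  ds_allowed <- c("data", "role", "format", "meta_path", "downsample")
  roles <- character(0)
  for (nm in names(cfg$datasets)) {
    d <- cfg$datasets[[nm]]
    unknown <- setdiff(names(d), ds_allowed)
    if (length(unknown))
      stop("dataset '", nm, "': unknown keys: ",
           paste(unknown, collapse = ", "))
    if (is.null(d$role) ||
        !d$role %in% c("reference", "query_sc", "query_bulk"))
      stop("dataset '", nm, "': role must be reference, query_sc or ",
           "query_bulk")
    if (is.character(d$data) && !file.exists(d$data))
      stop("dataset '", nm, "': path not found: ", d$data)
    if (!is.character(d$data) && !inherits(d$data, "ExpressionMatrix"))
      stop("dataset '", nm, "': data must be an ExpressionMatrix or a path")
    roles <- c(roles, d$role)
  }
  nref <- sum(roles == "reference")
  if (nref != 1)
    stop("exactly one reference dataset required, found ", nref, ": ",
         paste(names(cfg$datasets)[roles == "reference"], collapse = ", "))
  for (check in list(c("qc", "QCThresholds"), c("corgi", "CorgiParams"),
                     c("alignment", "AlignmentParams"),
                     c("hybrid", "HybridParams"))) {
    if (!inherits(cfg[[check[1]]], check[2]))
      stop("config field '", check[1], "' must be a ", check[2])
  }
  attr(cfg, "validated") <- TRUE
  cfg
}

write_pipeline_table <- function(tab, name, outdir, hash) {
  path <- file.path(outdir, paste0(name, ".tsv"))
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the full atlas-alignment analysis
#'
#' Executes, in order: QC filtering and feeder-cell removal (single-cell
#' datasets; bulk enters at normalisation, since mitochondrial and
#' detected-gene gates are meaningless for bulk profiles), depth-matched
#' log-normalisation across all datasets, downsampling, alignment-gene
#' selection (CORGI-style unless a gene set is supplied), cosine
#' normalisation, MNN correction of every query against the fixed
#' reference, reference PCA and embedding, arrow-of-time pseudotime,
#' dataset contrasts, hybrid classification and proportions, ESC scores,
#' and (when >= 3 quadruple hybrids exist and a signature is configured)
#' quad-vs-rest differential expression with signature overlap.
#'
#' @param cfg a validated [pipeline_config()].
#' @return list of result tables (`pseudotime`, `contrasts`,
#'   `hybrid_calls`, `hybrid_proportions`, `esc_scores`, `corgi_genes`,
#'   `signature_overlap` when computed) plus a `manifest` recording the
#'   config hash, per-table checksums, seeds and software version.
#' @export
run_pipeline <- function(cfg) {
  if (!isTRUE(attr(cfg, "validated"))) cfg <- validate_config(cfg)
  hash <- object_hash(cfg[setdiff(names(cfg), "outdir")])
  stage_key <- cfg$stage_key
  seeds <- list()

  # -- load ------------------------------------------------------------
  raw <- list()
  for (nm in names(cfg$datasets)) {
    d <- cfg$datasets[[nm]]
    m <- if (is.character(d$data))
      read_counts(d$data, format = if (is.null(d$format)) "mtx" else
        d$format, meta_path = d$meta_path) else d$data
    if (!"dataset" %in% names(m$cell_meta)) m$cell_meta$dataset <- nm
    raw[[nm]] <- m
  }
  roles <- vapply(cfg$datasets, `[[`, "", "role")
  ref_name <- names(roles)[roles == "reference"]

  # -- QC + feeder removal (single-cell only) --------------------------
  for (nm in names(raw)) {
    if (roles[[nm]] == "query_bulk") next
    raw[[nm]] <- remove_feeder_cells(qc_filter(raw[[nm]], cfg$qc), cfg$qc)
  }

  # -- depth-matched log-normalisation ---------------------------------
  norm <- normalize_batches(raw)

  # -- downsample ------------------------------------------------------
  for (nm in names(norm)) {
    plan <- cfg$datasets[[nm]]$downsample
    if (is.null(plan)) next
    s <- derive_seed(cfg$seed, paste0("downsample_", nm))
    seeds[[paste0("downsample_", nm)]] <- s
    norm[[nm]] <- downsample(norm[[nm]], plan$n,
                             stratify_by = plan$stratify_by,
                             mode = if (is.null(plan$mode)) "proportional"
                             else plan$mode, seed = s)
    raw[[nm]] <- subset_cells(raw[[nm]], cell_ids(norm[[nm]]))
  }

  # -- alignment genes -------------------------------------------------
  genes_used <- cfg$gene_set
  if (is.null(genes_used)) {
    first_q <- names(roles)[roles == "query_sc"][1]
    if (is.na(first_q))
      stop("no single-cell query available for gene selection; supply ",
           "gene_set")
    cp <- cfg$corgi
    cp$seed <- derive_seed(cfg$seed, "corgi")
    seeds$corgi <- cp$seed
    genes_used <- corgi_select(norm[[ref_name]], norm[[first_q]], cp)
  }
  shared <- Reduce(intersect, lapply(norm, function(m) rownames(m$values)))
  sel <- intersect(genes_used$genes, shared)
  if (!length(sel)) stop("no selected genes shared by all datasets")
  sub <- lapply(norm, subset_genes, genes = sel)

  # -- MNN projection onto the reference -------------------------------
  queries <- sub[setdiff(names(sub), ref_name)]
  proj <- project_all(sub[[ref_name]], queries, cfg$alignment)
  corrected <- c(stats::setNames(list(proj$ref), ref_name), proj$corrected)
  names(corrected) <- c(ref_name, names(queries))

  # -- embedding + pseudotime ------------------------------------------
  emb <- fit_reference_pca(corrected[[ref_name]], stage_key = stage_key)
  arrow <- fit_arrow(emb, cfg$embryonic_stages, cfg$adult_stages)
  pt_tabs <- lapply(names(corrected), function(nm) {
    m <- corrected[[nm]]
    grp <- if (stage_key %in% names(m$cell_meta))
      paste(nm, m$cell_meta[[stage_key]], sep = ":") else nm
    tab <- pseudotime(arrow, embed_cells(emb, m), group = grp)
    tab$dataset <- nm
    tab
  })
  pt <- do.call(rbind, pt_tabs)

  contrasts <- if (length(unique(pt$dataset)) >= 2 &&
                   all(table(pt$dataset) >= 2))
    compare_groups(pt, groups = pt$dataset, ref_group = ref_name) else NULL

  # -- hybrid classification (single-cell datasets) --------------------
  calls <- list(); props <- list()
  for (nm in names(norm)) {
    if (roles[[nm]] == "query_bulk") next
    if (!all(cfg$hybrid$markers %in% rownames(norm[[nm]]$values))) next
    cl <- classify_hybrids(norm[[nm]], cfg$hybrid)
    cl$dataset <- nm
    grp <- if (stage_key %in% names(norm[[nm]]$cell_meta))
      norm[[nm]]$cell_meta[[stage_key]] else rep(nm, nrow(cl))
    pr <- hybrid_proportions(cl, grp)
    pr$dataset <- nm
    calls[[nm]] <- cl; props[[nm]] <- pr
  }
  calls <- if (length(calls)) do.call(rbind, calls) else NULL
  props <- if (length(props)) do.call(rbind, props) else NULL

  # -- ESC scores (raw counts) -----------------------------------------
  esc <- NULL
  if (!is.null(cfg$esc_set)) {
    esc <- do.call(rbind, lapply(names(raw), function(nm) {
      if (roles[[nm]] == "query_bulk") return(NULL)
      s <- esc_score(raw[[nm]], cfg$esc_set)
      data.frame(cell_id = names(s), dataset = nm, esc_score = unname(s),
                 stringsAsFactors = FALSE)
    }))
  }

  # -- quad-hybrid DE + signature overlap ------------------------------
  overlap <- NULL
  if (!is.null(cfg$signature) && !is.null(calls)) {
    sc <- names(roles)[roles != "query_bulk"]
    pool_ids <- unlist(lapply(sc, function(nm) cell_ids(norm[[nm]])))
    quad_ids <- calls$cell_id[calls$quad]
    other_ids <- setdiff(pool_ids, quad_ids)
    if (length(quad_ids) >= 3 && length(other_ids) >= 3) {
      pooled <- norm[sc]
      common <- Reduce(intersect,
                       lapply(pooled, function(m) rownames(m$values)))
      vals <- do.call(cbind, lapply(pooled, function(m)
        m$values[common, , drop = FALSE]))
      pooled_m <- structure(list(values = vals, layer = "lognorm",
                                 cell_meta =
                                   data.frame(row.names = colnames(vals))),
                            class = "ExpressionMatrix")
      de <- simple_de(pooled_m, intersect(quad_ids, colnames(vals)),
                      intersect(other_ids, colnames(vals)))
      ov <- signature_overlap(de, cfg$signature)
      overlap <- data.frame(signature = cfg$signature$name,
                            n_overlap = ov$n_overlap,
                            n_up_in_quad = ov$n_up_in_group1,
                            n_down_in_quad = ov$n_down_in_group1)
    }
  }

  tables <- list(pseudotime = pt, contrasts = contrasts,
                 hybrid_calls = calls, hybrid_proportions = props,
                 esc_scores = esc,
                 corgi_genes = data.frame(gene = genes_used$genes),
                 signature_overlap = overlap)
  tables <- Filter(Negate(is.null), tables)
  manifest <- list(config_hash = hash,
                   seeds = seeds,
                   checksums = lapply(tables, object_hash),
                   n_alignment_genes = length(sel),
                   version = as.character(utils::packageVersion("mammatlas")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      write_pipeline_table(tables[[nm]], nm, cfg$outdir, hash)
  }
  c(tables, list(manifest = manifest))
}
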
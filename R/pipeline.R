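#' Pipeline orchestration
#'
#' Thin orchestration over the package's stages: every stage reads and
#' writes plain TSV, so any stage can be re-run from its upstream files
#' alone. A YAML config (or an equivalent R list) names the inputs,
#' output directory and stage parameters; a manifest JSON with checksums
#' records what each run produced.
#'
#' @name pipeline
NULL

#' Load a run configuration
#'
#' @param config A YAML file path or a named list. Recognized fields:
#'   \code{counts, nodes, edges, design, clinical, regulons, hallmarks}
#'   (input paths), \code{out_dir}, \code{contrasts} (list of
#'   c(case, control)), \code{stages}, \code{seed}, and stage parameters
#'   (\code{trunc_quantile, impute_value, tol, max_iter, node_summary,
#'   length_norm, alpha, min_confidence, min_targets, chat_cutoff,
#'   rank_by, standardize_activity}).
#' @return Config list with defaults filled in.
#' @export
load_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(out_dir = ".", contrasts = list(c("tumor", "normal")),
                   stages = c("activity", "diff", "survive", "tftea",
                              "hallmarks"),
                   seed = 1L, trunc_quantile = 0.99, impute_value = NULL,
                   tol = 1e-6, max_iter = 1000L, node_summary = "mean",
                   length_norm = "geometric", alpha = 0.05,
                   min_confidence = "C", min_targets = 5L,
                   chat_cutoff = 0.15, rank_by = "t_mod",
                   standardize_activity = FALSE)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.character(cfg$contrasts)) cfg$contrasts <- list(cfg$contrasts)
  cfg
}

.require_inputs <- function(cfg, fields) {
  for (f in fields) {
    if (is.null(cfg[[f]])) stop("config is missing input '", f, "'")
    if (!file.exists(cfg[[f]]))
      stop("input file for '", f, "' not found: ", cfg[[f]])
  }
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the activity stage
#'
#' Counts -> TMM -> log-CPM -> unit rescale -> impute pathway genes ->
#' propagate -> length-normalize. Writes \code{activity.tsv} (circuits x
#' samples) and \code{convergence.tsv}.
#'
#' @param config See [load_config()].
#' @return Invisibly, the \code{activity_matrix} (with the catalog and
#'   graphs attached as attributes).
#' @export
run_activity <- function(config) {
  cfg <- load_config(config)
  .require_inputs(cfg, c("counts", "nodes", "edges"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- read_counts(cfg$counts)
  graphs <- parse_pathways(cfg$nodes, cfg$edges)
  catalog <- build_catalog(graphs)
  factors <- tmm_factors(counts)
  scaled <- rescale_unit(log_cpm(counts, factors),
                         trunc_quantile = cfg$trunc_quantile)
  imp <- impute_missing(scaled, catalog_genes(catalog),
                        impute_value = cfg$impute_value)
  pcfg <- propagation_config(tol = cfg$tol, max_iter = cfg$max_iter,
                             node_summary = cfg$node_summary,
                             length_norm = cfg$length_norm)
  act <- compute_activity_matrix(catalog, imp$values, graphs, pcfg)
  .write_tsv(data.frame(circuit_id = rownames(act$values), act$values,
                        check.names = FALSE),
             file.path(cfg$out_dir, "activity.tsv"))
  .write_tsv(data.frame(circuit_id = names(act$converged),
                        converged = act$converged),
             file.path(cfg$out_dir, "convergence.tsv"))
  attr(act, "catalog") <- catalog
  attr(act, "graphs") <- graphs
  attr(act, "imputed") <- imp$imputed
  invisible(act)
}

.read_activity_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the full pipeline
#'
#' activity -> differential (circuits per contrast + cross-contrast
#' intersection; genes for the TF enrichment ranking) -> per-circuit Cox
#' survival screen on case samples -> TF target enrichment -> hallmark
#' profile. Writes one TSV per result table plus \code{manifest.json}
#' listing every output with an md5 checksum. Stage failures halt the
#' pipeline; prior outputs are kept and the manifest marks the failed
#' stage.
#'
#' @param config See [load_config()]; \code{stages} selects a subset.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_full <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), outputs = list())
  results <- list()
  record <- function(stage, paths) {
    manifest$stages[[stage]] <<- "ok"
    for (p in paths)
      manifest$outputs[[basename(p)]] <<- unname(tools::md5sum(p))
  }
  finish <- function() {
    mpath <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    ok <- tryCatch({ fn(); TRUE }, error = function(e) e)
    if (!isTRUE(ok)) {
      manifest$stages[[stage]] <<- paste("failed:", conditionMessage(ok))
      finish()
      stop("stage '", stage, "' failed: ", conditionMessage(ok))
    }
  }

  act <- NULL
  run_stage("activity", function() {
    act <<- run_activity(cfg)
    record("activity", file.path(cfg$out_dir,
                                 c("activity.tsv", "convergence.tsv")))
  })
  if (is.null(act) && any(c("diff", "survive", "tftea", "hallmarks") %in%
                          cfg$stages)) {
    apath <- file.path(cfg$out_dir, "activity.tsv")
    if (!file.exists(apath))
      stop("downstream stages need activity.tsv (run the activity stage)")
    act <- structure(list(values = .read_activity_tsv(apath)),
                     class = "activity_matrix")
  }
  results$activity <- act

  design <- NULL
  diff_res <- NULL
  gene_diff <- NULL
  if (any(c("diff", "tftea", "hallmarks") %in% cfg$stages)) {
    .require_inputs(cfg, "design")
    design <- .read_table_arg(cfg$design)
  }
  run_stage("diff", function() {
    vals <- act$values[, design$sample_id, drop = FALSE]
    diff_res <<- differential_table(vals, design$condition, design$batch,
                                    cfg$contrasts, alpha = cfg$alpha)
    paths <- character()
    for (nm in names(diff_res$tables))
      paths <- c(paths, .write_tsv(diff_res$tables[[nm]],
                                   file.path(cfg$out_dir,
                                             paste0("differential_circuits_",
                                                    nm, ".tsv"))))
    paths <- c(paths, .write_tsv(diff_res$intersection,
                                 file.path(cfg$out_dir,
                                           "differential_intersection.tsv")))
    record("diff", paths)
  })
  results$differential <- diff_res

  surv_res <- NULL
  run_stage("survive", function() {
    .require_inputs(cfg, "clinical")
    records <- build_survival(cfg$clinical)
    surv_res <<- cox_per_circuit(act, records,
                                 standardize = cfg$standardize_activity)
    record("survive",
           .write_tsv(surv_res, file.path(cfg$out_dir,
                                          "survival_cox.tsv")))
  })
  results$survival <- surv_res

  tftea_res <- NULL
  run_stage("tftea", function() {
    .require_inputs(cfg, c("regulons", "counts"))
    # gene-level moderated statistics feed the enrichment ranking
    counts <- read_counts(cfg$counts)
    norm <- log_cpm(counts, tmm_factors(counts))
    vals <- norm$values[, design$sample_id, drop = FALSE]
    gene_diff <<- differential_table(vals, design$condition, design$batch,
                                     cfg$contrasts, alpha = cfg$alpha)
    regs <- load_regulons(cfg$regulons,
                          min_confidence = cfg$min_confidence,
                          min_targets = cfg$min_targets)
    ranked <- lapply(gene_diff$tables, ranked_genes,
                     rank_by = cfg$rank_by)
    tftea_res <<- tftea_all(ranked, regs, alpha = cfg$alpha,
                            min_targets = cfg$min_targets)
    paths <- character()
    for (nm in names(tftea_res$tables))
      paths <- c(paths, .write_tsv(tftea_res$tables[[nm]],
                                   file.path(cfg$out_dir,
                                             paste0("tftea_", nm, ".tsv"))))
    paths <- c(paths, .write_tsv(tftea_res$summary,
                                 file.path(cfg$out_dir,
                                           "tftea_summary.tsv")))
    record("tftea", paths)
  })
  results$tftea <- tftea_res

  hm_res <- NULL
  run_stage("hallmarks", function() {
    .require_inputs(cfg, "hallmarks")
    if (is.null(diff_res))
      stop("hallmark profiling needs the diff stage's significant circuits")
    catalog <- attr(act, "catalog")
    if (is.null(catalog)) {
      .require_inputs(cfg, c("nodes", "edges"))
      catalog <- build_catalog(parse_pathways(cfg$nodes, cfg$edges))
    }
    ann <- filter_chat(cfg$hallmarks, cutoff = cfg$chat_cutoff)
    hm_res <<- hallmark_profile(diff_res$significant, catalog, ann)
    record("hallmarks",
           .write_tsv(hm_res, file.path(cfg$out_dir,
                                        "hallmark_profile.tsv")))
  })
  results$hallmarks <- hm_res

  finish()
  invisible(results)
}
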
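#' Synthetic data with known ground truth
#'
#' Generates toy pathway catalogs, negative-binomial count matrices with
#' library-size variation and a batch effect, censored survival outcomes
#' driven by selected circuit activities through a Cox model, and TF
#' regulons with planted rank enrichment — everything needed to exercise
#' every pipeline stage with a recoverable truth record and no external
#' downloads.
#'
#' @name synthetic-data
NULL

.HALLMARKS <- c(
  "sustaining proliferative signaling", "evading growth suppressors",
  "resisting cell death", "enabling replicative immortality",
  "inducing angiogenesis", "activating invasion and metastasis",
  "genome instability and mutation", "tumor-promoting inflammation",
  "deregulating cellular energetics", "avoiding immune destruction"
)

#' Simulation specification
#'
#' Defaults describe the study conditions the test-bed emulates: a small
#' catalog of signed pathway DAGs with occasional cycles and inhibitions,
#' 30 case vs 30 control RNA-seq samples with moderate negative-binomial
#' overdispersion and 3-fold library-size variation, three circuits
#' planted at log2 effect 1.5, a mild orthogonal two-site batch effect, a
#' survival signal of beta = 1 per standardized activity unit on one
#' circuit with 30% censoring, and one rank-enriched TF among twenty.
#'
#' @param seed Integer seed funneling all randomness.
#' @param n_pathways,nodes_per_pathway Catalog size (range of node
#'   counts).
#' @param cycle_prob Probability a pathway gets a feedback edge.
#' @param inhibition_prob Probability an edge is inhibitory.
#' @param n_case,n_control Sample sizes.
#' @param nb_dispersion Negative-binomial dispersion (0 = Poisson).
#' @param lib_size_range Uniform range of library sizes.
#' @param n_planted,planted_effect Circuits shifted in cases and their
#'   log2 effect (positive = up in cases).
#' @param batch_effect_sd SD of the additive log-scale batch effect.
#' @param n_batches Number of batches (assigned round-robin within each
#'   condition, so batch is orthogonal to condition unless
#'   \code{confound}).
#' @param confound Make batch identical to condition (to exercise the
#'   rank-deficiency error path).
#' @param baseline_hazard Exponential baseline hazard per day.
#' @param survival_beta Cox log-hazard per standardized activity unit of
#'   the planted survival circuit.
#' @param censoring_fraction Target fraction of censored records.
#' @param n_tfs,targets_per_tf,enrichment_tilt Regulon set size and the
#'   sampling tilt of the planted TF toward the top of the true effect
#'   ranking (0 = null).
#' @param n_background_genes Genes outside every pathway.
#' @return List of class \code{simulation_spec}.
#' @export
simulation_spec <- function(seed = 1L,
                            n_pathways = 12L,
                            nodes_per_pathway = c(5L, 9L),
                            cycle_prob = 0.1,
                            inhibition_prob = 0.15,
                            n_case = 30L, n_control = 30L,
                            nb_dispersion = 0.1,
                            lib_size_range = c(2e5, 6e5),
                            n_planted = 3L,
                            planted_effect = 1.5,
                            batch_effect_sd = 0.1,
                            n_batches = 2L,
                            confound = FALSE,
                            baseline_hazard = 1 / 1000,
                            survival_beta = 1,
                            censoring_fraction = 0.3,
                            n_tfs = 20L,
                            targets_per_tf = 20L,
                            enrichment_tilt = 16,
                            n_background_genes = 1000L) {
  stopifnot(cycle_prob >= 0, cycle_prob <= 1,
            inhibition_prob >= 0, inhibition_prob <= 1,
            n_case >= 2L, n_control >= 2L,
            censoring_fraction >= 0, censoring_fraction < 1)
  structure(as.list(environment()), class = "simulation_spec")
}

#' Generate toy pathway graphs and their circuit catalog
#'
#' Each pathway is a random connected DAG (every node past the first gets
#' a parent among earlier nodes, plus extra forward edges), optionally
#' with one feedback edge (probability \code{cycle_prob}), edge signs
#' inhibitory with probability \code{inhibition_prob}, and 1-3 synthetic
#' gene ids per node.
#'
#' @param spec A [simulation_spec()].
#' @return List with \code{graphs}, \code{catalog}, and \code{truth}
#'   (per-circuit member genes).
#' @export
make_toy_pathways <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  gene_counter <- 0L
  graphs <- lapply(seq_len(spec$n_pathways), function(p) {
    pid <- sprintf("toy%02d", p)
    n <- sample(seq(spec$nodes_per_pathway[1], spec$nodes_per_pathway[2]),
                1L)
    ids <- sprintf("N%02d", seq_len(n))
    src <- character(); tgt <- character()
    for (j in 2:n) {
      src <- c(src, ids[sample.int(j - 1L, 1L)])
      tgt <- c(tgt, ids[j])
    }
    for (j in 3:n) {
      extra <- which(stats::runif(j - 2L) < 0.25)
      src <- c(src, ids[extra])
      tgt <- c(tgt, rep(ids[j], length(extra)))
    }
    if (stats::runif(1) < spec$cycle_prob && n >= 3L) {
      k <- sample.int(n - 2L, 1L)  # strictly earlier than the source
      src <- c(src, ids[n - 1L])   # feedback from a late node ...
      tgt <- c(tgt, ids[k])        # ... to an earlier one
    }
    dup <- duplicated(paste(src, tgt))
    src <- src[!dup]; tgt <- tgt[!dup]
    sign <- ifelse(stats::runif(length(src)) < spec$inhibition_prob,
                   -1L, 1L)
    genes <- lapply(seq_len(n), function(i) {
      k <- sample.int(3L, 1L)
      g <- sprintf("gene%04d", gene_counter + seq_len(k))
      gene_counter <<- gene_counter + k
      g
    })
    nodes <- data.frame(node_id = ids, label = ids, is_function = FALSE)
    nodes$genes <- genes
    pathway_graph(pid, name = pid, nodes = nodes,
                  edges = data.frame(source = src, target = tgt,
                                     sign = sign))
  })
  names(graphs) <- vapply(graphs, `[[`, "", "pathway_id")
  catalog <- build_catalog(graphs)
  truth <- list(circuit_genes = lapply(catalog, function(cc)
    sort(unique(unlist(cc$genes)))))
  list(graphs = graphs, catalog = catalog, truth = truth)
}

# circuits whose member edges are all activating (planted effects act in
# a known direction there)
.activation_only_circuits <- function(catalog) {
  names(catalog)[vapply(catalog, function(cc)
    nrow(cc$member_edges) > 0L && all(cc$member_edges$sign > 0), TRUE)]
}

#' Simulate a count matrix with planted circuit effects
#'
#' Gene mean profiles are log-normal; counts are negative binomial with
#' the spec's dispersion; case samples shift the member genes of the
#' planted circuits by the planted log2 effect; batch labels are
#' round-robin within condition (orthogonal to it) with an additive
#' log-scale batch effect; library sizes are uniform in
#' \code{lib_size_range}.
#'
#' @param spec A [simulation_spec()].
#' @param pathways Output of [make_toy_pathways()].
#' @return List with \code{counts}, \code{design} (data frame
#'   \code{sample_id, condition, batch}) and \code{truth} (planted
#'   circuits, per-gene true log2 effects).
#' @export
simulate_counts <- function(spec, pathways) {
  force(pathways)  # evaluate before seeding: the generator may be a call
  set.seed(spec$seed + 1L)
  catalog <- pathways$catalog
  pw_genes <- catalog_genes(catalog)
  bg <- if (spec$n_background_genes > 0L)
    sprintf("bg%04d", seq_len(spec$n_background_genes)) else character()
  genes <- c(pw_genes, bg)
  G <- length(genes)

  n <- spec$n_case + spec$n_control
  samples <- sprintf("S%03d", seq_len(n))
  condition <- rep(c("tumor", "normal"), c(spec$n_case, spec$n_control))
  batch <- if (spec$confound) {
    condition
  } else {
    # round-robin within condition keeps batch orthogonal to condition
    unlist(lapply(c(spec$n_case, spec$n_control), function(k)
      sprintf("site%d", (seq_len(k) - 1L) %% spec$n_batches + 1L)))
  }

  mu <- exp(stats::rnorm(G, mean = log(150), sd = 1))
  names(mu) <- genes

  eligible <- .activation_only_circuits(catalog)
  if (length(eligible) < spec$n_planted)
    eligible <- names(catalog)
  # greedy gene-disjoint selection so planted effects never overwrite
  # one another through circuits that share upstream genes
  planted <- character()
  used_genes <- character()
  for (id in sample(eligible)) {
    if (length(planted) >= spec$n_planted) break
    gset <- pathways$truth$circuit_genes[[id]]
    if (!length(intersect(gset, used_genes))) {
      planted <- c(planted, id)
      used_genes <- c(used_genes, gset)
    }
  }
  planted <- sort(planted)
  directions <- rep(c(1, -1), length.out = length(planted))
  gene_effect <- stats::setNames(rep(0, G), genes)
  for (i in seq_along(planted)) {
    gset <- pathways$truth$circuit_genes[[planted[i]]]
    gene_effect[gset] <- directions[i] * spec$planted_effect
  }

  batch_shift <- matrix(stats::rnorm(G * spec$n_batches, 0,
                                     spec$batch_effect_sd),
                        nrow = G,
                        dimnames = list(genes,
                                        sprintf("site%d",
                                                seq_len(spec$n_batches))))
  lib <- stats::runif(n, spec$lib_size_range[1], spec$lib_size_range[2])

  counts <- matrix(0, G, n, dimnames = list(genes, samples))
  for (s in seq_len(n)) {
    lmu <- log(mu)
    if (condition[s] == "tumor") lmu <- lmu + gene_effect * log(2)
    if (!spec$confound && batch[s] %in% colnames(batch_shift))
      lmu <- lmu + batch_shift[, batch[s]]
    m <- exp(lmu)
    lambda <- m / sum(m) * lib[s]
    counts[, s] <- if (spec$nb_dispersion > 0) {
      stats::rnbinom(G, mu = lambda, size = 1 / spec$nb_dispersion)
    } else {
      stats::rpois(G, lambda)
    }
  }
  list(counts = counts,
       design = data.frame(sample_id = samples, condition = condition,
                           batch = batch),
       truth = list(planted_circuits = planted,
                    planted_direction = stats::setNames(directions,
                                                        planted),
                    gene_log2_effect = gene_effect))
}

# largest censor bound such that uniform censoring on (0, cmax) yields
# the target censored fraction for the observed event-time sample
.calibrate_censoring <- function(times, fraction) {
  if (fraction <= 0) return(Inf)
  f <- function(cmax) mean(pmin(times, cmax)) / cmax - fraction
  upper <- max(times) * 100
  if (f(upper) > 0) return(upper)
  stats::uniroot(f, c(min(times) / 1e3, upper))$root
}

#' Simulate survival outcomes from circuit activities
#'
#' Hazard for sample i is \code{baseline_hazard * exp(beta * z_i)} with
#' z the standardized activity of the planted survival circuit; event
#' times are exponential, censoring is independent uniform with its bound
#' calibrated to the requested censored fraction.
#'
#' @param spec A [simulation_spec()].
#' @param activity An \code{activity_matrix} (or matrix) over the case
#'   samples.
#' @param circuit_id Circuit driving survival (default: first catalog
#'   circuit with nonzero activity variance).
#' @return List with \code{clinical} (data frame \code{sample_id,
#'   days_to_death, days_to_last_follow_up, vital_status}) and
#'   \code{truth} (circuit, beta, linear predictor).
#' @export
simulate_survival <- function(spec, activity, circuit_id = NULL) {
  force(activity)
  set.seed(spec$seed + 2L)
  vals <- if (inherits(activity, "activity_matrix")) activity$values
          else activity
  if (is.null(circuit_id)) {
    sds <- apply(vals, 1L, stats::sd)
    circuit_id <- rownames(vals)[which(sds > 0)[1]]
  }
  a <- vals[circuit_id, ]
  z <- if (stats::sd(a) > 0) (a - mean(a)) / stats::sd(a) else a * 0
  rate <- spec$baseline_hazard * exp(spec$survival_beta * z)
  t_event <- stats::rexp(length(rate), rate)
  cmax <- .calibrate_censoring(t_event, spec$censoring_fraction)
  c_time <- if (is.finite(cmax)) stats::runif(length(rate), 0, cmax)
            else rep(Inf, length(rate))
  event <- t_event <= c_time
  time <- ceiling(pmin(t_event, c_time))
  clinical <- data.frame(
    sample_id = colnames(vals),
    days_to_death = ifelse(event, time, NA_real_),
    days_to_last_follow_up = ifelse(event, NA_real_, time),
    vital_status = ifelse(event, "Dead", "Alive")
  )
  list(clinical = clinical,
       truth = list(circuit = circuit_id, beta = spec$survival_beta,
                    linear_predictor = z))
}

#' Simulate TF regulons with planted rank enrichment
#'
#' One planted TF samples its targets with probability proportional to
#' \code{exp(tilt * r)} over the true effect ranking r in [0, 1] (so its
#' targets concentrate among the most up-regulated genes); the remaining
#' TFs sample uniformly. Confidence grades are drawn from A-C.
#'
#' @param spec A [simulation_spec()].
#' @param gene_effect Named per-gene true log2 effects (from
#'   [simulate_counts()] truth).
#' @return List with \code{regulons} (graded interaction data frame
#'   \code{tf, target, confidence}) and \code{truth} (planted TF ids).
#' @export
make_regulons <- function(spec, gene_effect) {
  force(gene_effect)
  set.seed(spec$seed + 3L)
  genes <- names(gene_effect)
  # true-effect ranking with midranks for ties, so the bulk of
  # unaffected genes shares one middling weight and the tilt
  # concentrates on genuinely shifted genes
  r <- (rank(gene_effect, ties.method = "average") - 1) /
    (length(gene_effect) - 1)
  tfs <- sprintf("TF%02d", seq_len(spec$n_tfs))
  planted_tf <- if (spec$enrichment_tilt > 0) tfs[1] else character()
  rows <- lapply(tfs, function(tf) {
    w <- if (tf %in% planted_tf) exp(spec$enrichment_tilt * r)
         else rep(1, length(genes))
    targets <- sample(genes, spec$targets_per_tf, prob = w)
    data.frame(tf = tf, target = targets,
               confidence = sample(c("A", "B", "C"), spec$targets_per_tf,
                                   replace = TRUE))
  })
  list(regulons = do.call(rbind, rows),
       truth = list(planted_tfs = planted_tf))
}

#' Random hallmark annotation for catalog effector genes
#'
#' Assigns each effector gene 1-3 hallmarks with scores drawn so that
#' roughly the upper 5% of scores exceed the conventional 0.15 cutoff.
#'
#' @param spec A [simulation_spec()].
#' @param catalog A \code{circuit_catalog}.
#' @return Data frame \code{gene, hallmark, score}.
#' @export
make_hallmark_annotation <- function(spec, catalog) {
  force(catalog)
  set.seed(spec$seed + 4L)
  eff_genes <- sort(unique(unlist(lapply(catalog, function(cc)
    cc$genes[[cc$effector]]))))
  rows <- lapply(eff_genes, function(g) {
    k <- sample.int(3L, 1L)
    data.frame(gene = g, hallmark = sample(.HALLMARKS, k),
               # exponential scores: ~5% above 0.15
               score = round(stats::rexp(k, rate = 20), 4))
  })
  out <- do.call(rbind, rows)
  out[!duplicated(out[c("gene", "hallmark")]), ]
}

#' Write a full synthetic input bundle to disk
#'
#' Generates pathways, counts, clinical metadata, regulons and hallmark
#' annotations, runs the activity stage to drive the survival generator,
#' and writes everything in the pipeline's TSV dialects plus a
#' \code{truth.json} record sufficient to score every downstream stage.
#' Byte-identical across runs for a fixed spec.
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written paths plus the truth record.
#' @export
simulate_bundle <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pw <- make_toy_pathways(spec)
  cm <- simulate_counts(spec, pw)

  node_rows <- do.call(rbind, lapply(pw$graphs, function(g)
    data.frame(pathway_id = g$pathway_id, node_id = g$nodes$node_id,
               label = g$nodes$label,
               genes = vapply(g$nodes$genes, paste, "", collapse = ";"),
               is_function = g$nodes$is_function)))
  edge_rows <- do.call(rbind, lapply(pw$graphs, function(g)
    if (nrow(g$edges)) data.frame(pathway_id = g$pathway_id, g$edges)))

  # activity on tumor samples drives the survival generator
  factors <- tmm_factors(cm$counts)
  scaled <- rescale_unit(log_cpm(cm$counts, factors))
  scaled <- impute_missing(scaled, catalog_genes(pw$catalog))$values
  tumor <- cm$design$sample_id[cm$design$condition == "tumor"]
  act <- compute_activity_matrix(pw$catalog,
                                 scaled[, tumor, drop = FALSE],
                                 pw$graphs)
  surv_circuit <- if (length(cm$truth$planted_circuits))
    cm$truth$planted_circuits[1] else NULL
  sv <- simulate_survival(spec, act, circuit_id = surv_circuit)
  rg <- make_regulons(spec, cm$truth$gene_log2_effect)
  hm <- make_hallmark_annotation(spec, pw$catalog)

  paths <- list(
    nodes = file.path(out_dir, "pathway_nodes.tsv"),
    edges = file.path(out_dir, "pathway_edges.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    design = file.path(out_dir, "design.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    regulons = file.path(out_dir, "regulons.tsv"),
    hallmarks = file.path(out_dir, "hallmark_annotation.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  wr <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(node_rows, paths$nodes)
  wr(edge_rows, paths$edges)
  wr(data.frame(gene_id = rownames(cm$counts), cm$counts,
                check.names = FALSE), paths$counts)
  wr(cm$design, paths$design)
  wr(sv$clinical, paths$clinical)
  wr(rg$regulons, paths$regulons)
  wr(hm, paths$hallmarks)
  truth <- list(planted_circuits = cm$truth$planted_circuits,
                planted_direction = as.list(cm$truth$planted_direction),
                survival = sv$truth[c("circuit", "beta")],
                planted_tfs = rg$truth$planted_tfs,
                seed = spec$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(truth_record = truth, spec = spec)))
}
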
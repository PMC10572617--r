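#' Signal propagation through signaling circuits
#'
#' The signal intensity of a node n is
#'
#'   S_n = v_n * (1 - prod_{a in A}(1 - s_a)) * prod_{i in I}(1 - s_i)
#'
#' where v_n is the node's normalized expression summary in [0, 1], A the
#' incoming activation signals and I the incoming inhibition signals. A
#' node with no incoming activation edge is a receptor and receives an
#' implicit activating signal of 1, so it emits its own v_n; an empty
#' inhibition product is 1. The effector's S is the circuit activity:
#' signal flows only while the whole chain of proteins is present and no
#' inhibitor blocks it.
#'
#' @name propagation
NULL

#' Propagation configuration
#'
#' @param tol Convergence threshold for cyclic circuits (default 1e-6).
#' @param max_iter Iteration cap for cyclic circuits (default 1000).
#' @param node_summary How multi-gene node values summarize their genes:
#'   \code{"mean"}, \code{"median"}, or \code{"percentile"} with
#'   \code{percentile_q}.
#' @param length_norm Circuit-length correction of the raw effector
#'   signal: \code{"geometric"} (divide by 0.5^L, L = longest
#'   activation-only receptor-to-effector path, in nodes),
#'   \code{"reference"} (divide by the saturated-signal reference), or
#'   \code{"none"}. Downstream per-circuit statistics are invariant to
#'   this choice because it is a per-circuit positive constant.
#' @param percentile_q Quantile for \code{node_summary = "percentile"}.
#' @return List of class \code{propagation_config}.
#' @export
propagation_config <- function(tol = 1e-6, max_iter = 1000,
                               node_summary = c("mean", "median",
                                                "percentile"),
                               length_norm = c("geometric", "reference",
                                               "none"),
                               percentile_q = 0.9) {
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 node_summary = match.arg(node_summary),
                 length_norm = match.arg(length_norm),
                 percentile_q = percentile_q),
            class = "propagation_config")
}

#' Node values from scaled expression
#'
#' A node's value per sample is the \code{node_summary} of its genes'
#' scaled expression. Non-function nodes without genes (metabolites,
#' unannotated complexes) act as transparent relays with value 1.
#'
#' @param scaled Genes x samples matrix in [0, 1] (post-imputation).
#' @param graph A [pathway_graph()].
#' @param config A [propagation_config()].
#' @param nodes Optional subset of node ids to compute (default: all
#'   nodes of the graph).
#' @return Nodes x samples matrix.
#' @export
node_values <- function(scaled, graph, config = propagation_config(),
                        nodes = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  fn <- switch(config$node_summary,
               mean = function(x) colMeans(x),
               median = function(x) apply(x, 2L, stats::median),
               percentile = function(x)
                 apply(x, 2L, stats::quantile, probs = config$percentile_q,
                       names = FALSE))
  ids <- if (is.null(nodes)) graph$nodes$node_id
         else intersect(graph$nodes$node_id, nodes)
  vals <- matrix(NA_real_, length(ids), ncol(scaled),
                 dimnames = list(ids, colnames(scaled)))
  for (k in seq_along(ids)) {
    g <- graph$nodes$genes[[match(ids[k], graph$nodes$node_id)]]
    if (!length(g)) {
      vals[k, ] <- 1
      next
    }
    miss <- setdiff(g, rownames(scaled))
    if (length(miss))
      stop("gene(s) missing after imputation: ",
           paste(miss, collapse = ", "))
    vals[k, ] <- fn(scaled[g, , drop = FALSE])
  }
  vals
}

# incoming activation / inhibition source lists per member node
.circuit_inputs <- function(circuit) {
  nodes <- circuit$member_nodes
  e <- circuit$member_edges
  act <- lapply(nodes, function(n)
    match(e$source[e$target == n & e$sign > 0], nodes))
  inh <- lapply(nodes, function(n)
    match(e$source[e$target == n & e$sign < 0], nodes))
  names(act) <- names(inh) <- nodes
  list(act = act, inh = inh)
}

.is_acyclic <- function(nodes, edges) {
  # Kahn's algorithm on the member sub-graph
  indeg <- table(factor(edges$target, levels = nodes))
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  queue <- nodes[indeg == 0L]
  seen <- 0L
  order <- character()
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    order <- c(order, n)
    seen <- seen + 1L
    out <- edges$target[edges$source == n]
    for (m in out) {
      indeg[m] <- indeg[m] - 1L
      if (indeg[m] == 0L) queue <- c(queue, m)
    }
    edges <- edges[edges$source != n, , drop = FALSE]
  }
  if (seen == length(nodes)) order else NULL
}

#' Propagate signal through one circuit
#'
#' Acyclic circuits are solved exactly by one sweep in topological order.
#' Cyclic circuits use Jacobi iteration from S0 = v with a fixed sweep
#' order (sorted node ids) until the largest update falls below
#' \code{config$tol} or \code{config$max_iter} is reached (then flagged
#' unconverged). Raw signals stay in [0, 1] at every iteration.
#'
#' @param circuit A circuit from [extract_circuits()].
#' @param node_vals Nodes x samples matrix from [node_values()] (may
#'   contain nodes beyond the circuit's members).
#' @param config A [propagation_config()].
#' @return List with \code{signal} (per-sample raw effector signal) and
#'   \code{converged} (logical).
#' @export
propagate_circuit <- function(circuit, node_vals,
                              config = propagation_config()) {
  nodes <- circuit$member_nodes
  miss <- setdiff(nodes, rownames(node_vals))
  if (length(miss))
    stop("member node(s) without values: ", paste(miss, collapse = ", "))
  v <- node_vals[nodes, , drop = FALSE]
  io <- .circuit_inputs(circuit)
  topo <- .is_acyclic(nodes, circuit$member_edges)

  step_node <- function(k, S) {
    a <- io$act[[k]]
    i <- io$inh[[k]]
    act_term <- if (length(a)) {
      1 - apply(1 - S[a, , drop = FALSE], 2L, prod)
    } else 1
    inh_term <- if (length(i)) {
      apply(1 - S[i, , drop = FALSE], 2L, prod)
    } else 1
    v[k, ] * act_term * inh_term
  }

  if (!is.null(topo)) {
    S <- v
    for (n in topo) {
      k <- match(n, nodes)
      S[k, ] <- step_node(k, S)
    }
    converged <- TRUE
  } else {
    S <- v
    converged <- FALSE
    for (it in seq_len(config$max_iter)) {
      S_new <- S
      for (k in seq_along(nodes)) S_new[k, ] <- step_node(k, S)
      delta <- max(abs(S_new - S))
      S <- S_new
      if (delta < config$tol) {
        converged <- TRUE
        break
      }
    }
  }
  sig <- S[match(circuit$effector, nodes), ]
  list(signal = pmin(pmax(sig, 0), 1), converged = converged)
}

# L = number of nodes on the longest activation-only simple path ending
# at the effector (receptors included); DFS with a path-visited set so
# cycles terminate. Circuits are small, so this is cheap.
.longest_activation_path <- function(circuit) {
  e <- circuit$member_edges
  e <- e[e$sign > 0, , drop = FALSE]
  longest <- function(node, on_path) {
    preds <- setdiff(e$source[e$target == node], on_path)
    if (!length(preds)) return(1L)
    1L + max(vapply(preds, function(p) longest(p, c(on_path, node)), 0L))
  }
  longest(circuit$effector, character())
}

#' Circuit-length normalization of raw effector signals
#'
#' Circuits of different depths attenuate signal differently (a chain of
#' L half-activated nodes yields 0.5^L). The default geometric correction
#' divides by 0.5^L with L the longest activation-only path into the
#' effector; the reference mode divides by the circuit's saturated signal
#' (all v = 1, inhibitor-chain nodes at 0). Either way the correction is
#' a per-circuit positive constant, so sample ordering and downstream
#' test statistics are unchanged.
#'
#' @param raw Per-sample raw effector signal in [0, 1].
#' @param circuit The circuit it came from.
#' @param config A [propagation_config()].
#' @return Normalized per-sample signal (non-negative).
#' @export
normalize_path_activity <- function(raw, circuit,
                                    config = propagation_config()) {
  switch(config$length_norm,
         none = raw,
         geometric = {
           L <- .longest_activation_path(circuit)
           raw / 0.5^L
         },
         reference = {
           nodes <- circuit$member_nodes
           e <- circuit$member_edges
           v_ref <- matrix(1, length(nodes), 1L,
                           dimnames = list(nodes, "ref"))
           inh_src <- unique(e$source[e$sign < 0])
           inh_chain <- unique(unlist(lapply(inh_src, function(s)
             .reverse_reachable(e, s, exclude = character()))))
           v_ref[intersect(inh_chain, nodes), ] <- 0
           ref <- propagate_circuit(circuit, v_ref, config)$signal
           if (!is.finite(ref) || ref < 1e-12) raw else raw / ref
         })
}

#' Compute the circuit-by-sample activity matrix
#'
#' Runs node summarization, per-circuit propagation, and circuit-length
#' normalization for every circuit of a catalog.
#'
#' @param catalog A \code{circuit_catalog} from [build_catalog()] or
#'   [extract_circuits()].
#' @param scaled Genes x samples matrix in [0, 1] (post-imputation).
#' @param graphs Named list of the [pathway_graph()] objects the catalog
#'   came from.
#' @param config A [propagation_config()].
#' @return Object of class \code{activity_matrix}: list with
#'   \code{values} (circuits x samples), \code{converged} (per circuit),
#'   \code{config}, and \code{failures} (per-circuit error messages).
#' @export
compute_activity_matrix <- function(catalog, scaled, graphs,
                                    config = propagation_config()) {
  stopifnot(inherits(catalog, "circuit_catalog"), length(catalog) > 0)
  used_nodes <- lapply(catalog, `[[`, "member_nodes")
  by_pathway <- split(used_nodes, vapply(catalog, `[[`, "", "pathway_id"))
  nv <- lapply(graphs, function(g) {
    nodes <- unique(unlist(by_pathway[[g$pathway_id]]))
    node_values(scaled, g, config, nodes = nodes)
  })
  names(nv) <- vapply(graphs, `[[`, "", "pathway_id")
  ids <- names(catalog)
  vals <- matrix(NA_real_, length(ids), ncol(scaled),
                 dimnames = list(ids, colnames(scaled)))
  converged <- logical(length(ids))
  names(converged) <- ids
  failures <- character()
  for (id in ids) {
    cc <- catalog[[id]]
    res <- tryCatch({
      pr <- propagate_circuit(cc, nv[[cc$pathway_id]], config)
      list(sig = normalize_path_activity(pr$signal, cc, config),
           conv = pr$converged)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
    } else {
      vals[id, ] <- res$sig
      converged[id] <- res$conv
    }
  }
  if (length(failures) == length(ids))
    stop("all circuits failed: ", failures[1])
  structure(list(values = vals, converged = converged, config = config,
                 failures = failures),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat("activity_matrix: ", nrow(x$values), " circuits x ",
      ncol(x$values), " samples\n", sep = "")
  if (any(!x$converged))
    cat("  unconverged circuits: ", sum(!x$converged), "\n", sep = "")
  if (length(x$failures))
    cat("  failed circuits: ", length(x$failures), "\n", sep = "")
  invisible(x)
}
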
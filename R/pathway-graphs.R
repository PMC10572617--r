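#' Signed directed pathway graphs and effector circuits
#'
#' A pathway is represented as a signed directed graph whose nodes are
#' (possibly multi-gene) protein complexes and whose edges carry an
#' activation (+1) or inhibition (-1) sign. Every node with no outgoing
#' signaling edge is an effector: the terminal protein that triggers the
#' pathway's cellular function. The sub-graph of all nodes with a directed
#' path into one effector is a signaling circuit, the unit at which
#' activity, differential signaling and survival association are
#' quantified.
#'
#' @name pathway-graphs
NULL

.SIGN_TOKENS <- c(
  "+1" = 1, "1" = 1, "-1" = -1,
  "activation" = 1, "activates" = 1,
  "inhibition" = -1, "inhibits" = -1
)

#' Construct a pathway graph
#'
#' @param pathway_id Single string identifying the pathway (e.g. a
#'   KEGG-style id such as \code{"hsa04010"}).
#' @param name Display name; defaults to \code{pathway_id}.
#' @param nodes Data frame with columns \code{node_id}, \code{label},
#'   \code{genes} (list column of character vectors), \code{is_function}.
#' @param edges Data frame with columns \code{source}, \code{target},
#'   \code{sign} (+1 or -1).
#' @param allow_self_loops Drop self-loops silently instead of erroring.
#'   The propagation rule is ill-defined for a node feeding itself, so
#'   they are rejected by default.
#' @return An object of class \code{pathway_graph}.
#' @export
pathway_graph <- function(pathway_id, name = pathway_id, nodes, edges,
                          allow_self_loops = FALSE) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L,
            nzchar(pathway_id))
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (nrow(nodes) < 1L) stop("pathway '", pathway_id, "' has no nodes")
  if (anyNA(nodes$node_id) || any(!nzchar(nodes$node_id)))
    stop("empty node_id in pathway '", pathway_id, "'")
  dup <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(dup))
    stop("duplicate node_id in pathway '", pathway_id, "': ",
         paste(unique(dup), collapse = ", "))
  if (!is.list(nodes$genes)) nodes$genes <- as.list(nodes$genes)
  nodes$genes <- lapply(nodes$genes, function(g) {
    g <- as.character(g[!is.na(g) & nzchar(g)])
    unique(g)
  })
  nodes$is_function <- as.logical(nodes$is_function)

  if (nrow(edges)) {
    edges$sign <- as.integer(edges$sign)
    if (any(!edges$sign %in% c(1L, -1L)))
      stop("edge sign must be +1 or -1")
    missing_ep <- setdiff(c(edges$source, edges$target), nodes$node_id)
    if (length(missing_ep))
      stop("edge endpoint(s) not declared as nodes: ",
           paste(missing_ep, collapse = ", "))
    loops <- edges$source == edges$target
    if (any(loops)) {
      if (!allow_self_loops)
        stop("self-loop on node(s): ",
             paste(unique(edges$source[loops]), collapse = ", "),
             " (set allow_self_loops = TRUE to drop them)")
      edges <- edges[!loops, , drop = FALSE]
    }
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer())
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(
    list(pathway_id = pathway_id, name = name, nodes = nodes, edges = edges),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph '", x$pathway_id, "' (", x$name, ")\n", sep = "")
  cat("  nodes: ", nrow(x$nodes),
      " (", sum(x$nodes$is_function), " function annotations)\n", sep = "")
  cat("  edges: ", nrow(x$edges),
      " (", sum(x$edges$sign < 0), " inhibitions)\n", sep = "")
  invisible(x)
}

#' Parse pathway node/edge tables into pathway graphs
#'
#' Reads the tab-separated pathway dialect: a node table with columns
#' \code{pathway_id, node_id, label, genes, is_function} (genes
#' ";"-separated, empty for non-gene nodes) and an edge table with columns
#' \code{pathway_id, source, target, sign} where sign is one of
#' \code{+1, 1, -1, activation, activates, inhibition, inhibits}.
#'
#' @param node_table,edge_table Paths to TSV files, or data frames with
#'   the same columns.
#' @param allow_self_loops Passed on to [pathway_graph()].
#' @return A named list of \code{pathway_graph} objects, one per
#'   \code{pathway_id}.
#' @export
parse_pathways <- function(node_table, edge_table, allow_self_loops = FALSE) {
  nt <- .read_table_arg(node_table)
  et <- .read_table_arg(edge_table)
  req_n <- c("pathway_id", "node_id", "label", "genes", "is_function")
  req_e <- c("pathway_id", "source", "target", "sign")
  if (!all(req_n %in% names(nt)))
    stop("node table must have columns: ", paste(req_n, collapse = ", "))
  if (!all(req_e %in% names(et)) && nrow(et))
    stop("edge table must have columns: ", paste(req_e, collapse = ", "))

  sign_chr <- trimws(as.character(et$sign))
  sign_num <- unname(.SIGN_TOKENS[sign_chr])
  bad <- which(is.na(sign_num))
  if (length(bad))
    stop("unknown sign token '", sign_chr[bad[1]], "' in edge table row ",
         bad[1])

  pws <- unique(nt$pathway_id)
  out <- lapply(pws, function(pid) {
    ni <- nt[nt$pathway_id == pid, , drop = FALSE]
    ei_idx <- which(et$pathway_id == pid)
    dup_i <- which(duplicated(ni$node_id))
    if (length(dup_i))
      stop("duplicate node_id '", ni$node_id[dup_i[1]],
           "' in node table row ",
           which(nt$pathway_id == pid)[dup_i[1]], " (pathway ", pid, ")")
    undecl <- setdiff(c(et$source[ei_idx], et$target[ei_idx]), ni$node_id)
    if (length(undecl)) {
      row <- ei_idx[which(et$source[ei_idx] %in% undecl |
                          et$target[ei_idx] %in% undecl)[1]]
      stop("edge table row ", row, " (pathway ", pid,
           ") references undeclared node '", undecl[1], "'")
    }
    nodes <- data.frame(node_id = as.character(ni$node_id),
                        label = as.character(ni$label),
                        is_function = .parse_logical(ni$is_function))
    nodes$genes <- strsplit(ifelse(is.na(ni$genes), "", ni$genes), ";",
                            fixed = TRUE)
    pathway_graph(pid, name = pid, nodes = nodes,
                  edges = data.frame(source = as.character(et$source[ei_idx]),
                                     target = as.character(et$target[ei_idx]),
                                     sign = sign_num[ei_idx]),
                  allow_self_loops = allow_self_loops)
  })
  names(out) <- pws
  out
}

.read_table_arg <- function(x) {
  if (is.data.frame(x)) return(x)
  utils::read.delim(x, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

#' Find effector nodes of a pathway graph
#'
#' An effector is a non-function node whose outgoing edges lead only to
#' function-annotation nodes (or nowhere): the signal terminates there and
#' triggers a cellular function. Function nodes themselves are carried as
#' annotations and never act as effectors.
#'
#' @param graph A [pathway_graph()].
#' @return Character vector of effector node ids, sorted.
#' @export
find_effectors <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  fun_nodes <- graph$nodes$node_id[graph$nodes$is_function]
  signaling <- setdiff(graph$nodes$node_id, fun_nodes)
  # outgoing edges that stay within the signaling sub-graph
  out_sig <- graph$edges$source[!(graph$edges$target %in% fun_nodes)]
  eff <- sort(setdiff(signaling, unique(out_sig)))
  if (!length(eff))
    warning("pathway '", graph$pathway_id,
            "' has no effectors (pure cycle?)")
  eff
}

# reverse reachability over the signaling (non-function) sub-graph
.reverse_reachable <- function(edges, start, exclude) {
  keep <- !(edges$source %in% exclude) & !(edges$target %in% exclude)
  src <- edges$source[keep]
  tgt <- edges$target[keep]
  seen <- start
  frontier <- start
  while (length(frontier)) {
    preds <- unique(src[tgt %in% frontier])
    frontier <- setdiff(preds, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Decompose a pathway graph into single-effector circuits
#'
#' One circuit per effector: its members are all non-function nodes with a
#' directed path to the effector (cycles retained), and its edges are the
#' induced signed edges among the members. Circuits of sibling effectors
#' may share an upstream receptor sub-tree.
#'
#' @param graph A [pathway_graph()].
#' @return A \code{circuit_catalog}: list of circuits indexed by
#'   \code{circuit_id} (\code{"<pathway_id>:<effector>"}).
#' @export
extract_circuits <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  fun_nodes <- graph$nodes$node_id[graph$nodes$is_function]
  effs <- suppressWarnings(find_effectors(graph))
  circuits <- lapply(effs, function(e) {
    members <- sort(.reverse_reachable(graph$edges, e, exclude = fun_nodes))
    keep <- graph$edges$source %in% members & graph$edges$target %in% members
    genes <- graph$nodes$genes[match(members, graph$nodes$node_id)]
    names(genes) <- members
    structure(
      list(circuit_id = paste0(graph$pathway_id, ":", e),
           pathway_id = graph$pathway_id,
           effector = e,
           member_nodes = members,
           member_edges = graph$edges[keep, , drop = FALSE],
           genes = genes),
      class = "circuit"
    )
  })
  names(circuits) <- vapply(circuits, `[[`, "", "circuit_id")
  structure(circuits, class = "circuit_catalog")
}

#' @export
print.circuit <- function(x, ...) {
  cat("circuit ", x$circuit_id, ": ", length(x$member_nodes), " nodes, ",
      nrow(x$member_edges), " edges, effector '", x$effector, "'\n",
      sep = "")
  invisible(x)
}

#' @export
print.circuit_catalog <- function(x, ...) {
  cat("circuit_catalog with", length(x), "circuits from",
      length(unique(vapply(x, `[[`, "", "pathway_id"))), "pathway(s)\n")
  invisible(x)
}

#' Combine circuit catalogs from several pathways
#' @param graphs List of [pathway_graph()] objects.
#' @return A \code{circuit_catalog} over all pathways.
#' @export
build_catalog <- function(graphs) {
  cats <- lapply(graphs, extract_circuits)
  all <- do.call(c, unname(lapply(cats, unclass)))
  if (anyDuplicated(names(all))) stop("duplicate circuit ids across pathways")
  structure(all, class = "circuit_catalog")
}

#' All gene ids used by the circuits of a catalog
#' @param catalog A \code{circuit_catalog}.
#' @return Sorted character vector of gene ids.
#' @export
catalog_genes <- function(catalog) {
  sort(unique(unlist(lapply(catalog, function(cc) unlist(cc$genes)))))
}

#' Export a circuit catalog as a data frame
#' @param catalog A \code{circuit_catalog}.
#' @return Data frame with one row per circuit
#'   (\code{circuit_id, pathway_id, effector, n_nodes, n_edges, genes}).
#' @export
catalog_table <- function(catalog) {
  data.frame(
    circuit_id = vapply(catalog, `[[`, "", "circuit_id"),
    pathway_id = vapply(catalog, `[[`, "", "pathway_id"),
    effector = vapply(catalog, `[[`, "", "effector"),
    n_nodes = vapply(catalog, function(x) length(x$member_nodes), 0L),
    n_edges = vapply(catalog, function(x) nrow(x$member_edges), 0L),
    genes = vapply(catalog, function(x)
      paste(sort(unique(unlist(x$genes))), collapse = ";"), ""),
    row.names = NULL
  )
}

#' Diagnostic validation of a pathway graph
#'
#' Reports (without failing) structural oddities: duplicate same-sign
#' edges, non-gene signaling nodes, nodes that reach no effector, and
#' self-loops. Opposite-sign duplicate edges between one pair are legal
#' and retained.
#'
#' @param graph A [pathway_graph()].
#' @return Data frame of diagnostics (\code{kind, node_or_edge, message}).
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  diags <- list()
  add <- function(kind, what, msg)
    diags[[length(diags) + 1L]] <<- data.frame(kind = kind,
                                               node_or_edge = what,
                                               message = msg)
  e <- graph$edges
  if (nrow(e)) {
    key <- paste(e$source, e$target, e$sign)
    for (k in unique(key[duplicated(key)])) {
      parts <- strsplit(k, " ")[[1]]
      add("duplicate_edge", paste0(parts[1], "->", parts[2]),
          paste0("duplicate edge with sign ", parts[3]))
    }
    loops <- e$source == e$target
    for (n in unique(e$source[loops])) add("self_loop", n, "self-loop")
  }
  no_genes <- !graph$nodes$is_function &
    vapply(graph$nodes$genes, length, 0L) == 0L
  for (n in graph$nodes$node_id[no_genes])
    add("non_gene_node", n,
        "signaling node without genes (treated as transparent relay)")
  effs <- suppressWarnings(find_effectors(graph))
  reach <- unique(unlist(lapply(effs, function(x)
    .reverse_reachable(e, x,
                       exclude = graph$nodes$node_id[graph$nodes$is_function]))))
  dangling <- setdiff(graph$nodes$node_id[!graph$nodes$is_function], reach)
  for (n in dangling) add("unreachable", n, "node reaches no effector")
  if (!length(diags))
    return(data.frame(kind = character(), node_or_edge = character(),
                      message = character()))
  do.call(rbind, diags)
}
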
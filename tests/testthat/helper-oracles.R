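# Independent oracles and fixture builders. Everything here is written
# from first principles so that it never shares code paths with the
# package implementation it checks.

# --- graph fixtures ---------------------------------------------------

toy_graph <- function(edges_df, gene_map = NULL, is_function = NULL,
                      pathway_id = "pw") {
  ids <- sort(unique(c(edges_df$source, edges_df$target)))
  if (is.null(gene_map))
    gene_map <- stats::setNames(as.list(paste0("g_", ids)), ids)
  fn <- if (is.null(is_function)) rep(FALSE, length(ids))
        else ids %in% is_function
  nodes <- data.frame(node_id = ids, label = ids, is_function = fn)
  nodes$genes <- lapply(ids, function(i)
    if (i %in% names(gene_map)) gene_map[[i]] else character())
  pathway_graph(pathway_id, nodes = nodes, edges = edges_df)
}

chain_graph <- function(n = 3, sign = 1, pathway_id = "chain") {
  ids <- LETTERS[seq_len(n)]
  toy_graph(data.frame(source = ids[-n], target = ids[-1], sign = sign),
            pathway_id = pathway_id)
}

# random signed digraph for property tests; acyclic unless cycle_back
random_graph <- function(n_nodes, p_edge = 0.4, p_inhib = 0.3,
                         cycle_back = FALSE) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  src <- character(); tgt <- character()
  for (j in 2:n_nodes) {
    parents <- which(stats::runif(j - 1) < p_edge)
    if (!length(parents)) parents <- sample.int(j - 1, 1)
    src <- c(src, ids[parents])
    tgt <- c(tgt, rep(ids[j], length(parents)))
  }
  if (cycle_back && n_nodes >= 3) {
    j <- sample(2:(n_nodes - 1), 1)
    src <- c(src, ids[n_nodes])
    tgt <- c(tgt, ids[j])
  }
  sign <- ifelse(stats::runif(length(src)) < p_inhib, -1, 1)
  toy_graph(data.frame(source = src, target = tgt, sign = sign),
            pathway_id = "rand")
}

# brute-force reverse reachability by exhaustive edge-path enumeration
brute_reachable_to <- function(graph, effector) {
  e <- graph$edges
  nodes <- graph$nodes$node_id[!graph$nodes$is_function]
  can_reach <- function(from, visited) {
    if (from == effector) return(TRUE)
    nexts <- e$target[e$source == from]
    nexts <- setdiff(intersect(nexts, nodes), visited)
    for (nx in nexts)
      if (can_reach(nx, c(visited, from))) return(TRUE)
    FALSE
  }
  sort(nodes[vapply(nodes, function(n) can_reach(n, character()), TRUE)])
}

# --- propagation oracle: direct memoized recursion of the signal rule -
# S_n = v_n (1 - prod(1 - s_a)) prod(1 - s_i); only valid on acyclic
# circuits.
recursive_signal <- function(circuit, v) {
  e <- circuit$member_edges
  memo <- new.env()
  S <- function(n) {
    if (!is.null(memo[[n]])) return(memo[[n]])
    act <- e$source[e$target == n & e$sign > 0]
    inh <- e$source[e$target == n & e$sign < 0]
    a_term <- if (length(act)) {
      prod_term <- rep(1, length(v[n, , drop = TRUE]))
      for (a in act) prod_term <- prod_term * (1 - S(a))
      1 - prod_term
    } else 1
    i_term <- 1
    for (i in inh) i_term <- i_term * (1 - S(i))
    memo[[n]] <- v[n, ] * a_term * i_term
    memo[[n]]
  }
  S(circuit$effector)
}

# --- BH step-up from the definition ----------------------------------
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (k in m:1) {
    running_min <- min(running_min, p[o[k]] * m / k)
    adj[o[k]] <- running_min
  }
  pmin(adj, 1)
}

# --- logistic regression by bare Newton-Raphson IRLS ------------------
irls_logistic <- function(y, x, max_iter = 100, tol = 1e-12) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- drop(t(X) %*% (y - mu))
    info <- t(X) %*% (X * W)
    delta <- solve(info, score)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  beta
}

# --- misc fixtures ----------------------------------------------------

small_counts <- function(seed = 42, genes = 50, samples = 4) {
  set.seed(seed)
  m <- matrix(rnbinom(genes * samples, mu = 100, size = 5),
              genes, samples,
              dimnames = list(sprintf("g%03d", 1:genes),
                              sprintf("s%d", 1:samples)))
  m
}

clinical_fixture <- function() {
  data.frame(
    sample_id = c("a", "b", "c", "d"),
    days_to_death = c(100, NA, NA, 50),
    days_to_last_follow_up = c(80, 400, NA, 70),
    vital_status = c("Dead", "Alive", "Alive", "Dead")
  )
}
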
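scaled_fixture <- function(graph, values) {
  genes <- unlist(graph$nodes$genes)
  m <- matrix(values, length(genes), length(values) / length(genes),
              dimnames = list(genes, paste0("s", seq_len(
                length(values) / length(genes)))))
  m
}

test_that("node values summarize genes and relay nodes are transparent", {
  nodes <- data.frame(node_id = c("A", "B", "R"), label = c("A", "B", "R"),
                      is_function = FALSE)
  nodes$genes <- list(c("g1", "g2"), "g3", character())
  g <- pathway_graph("pw", nodes = nodes,
                     edges = data.frame(source = c("A", "R"),
                                        target = c("B", "B"),
                                        sign = 1))
  sc <- matrix(c(0.2, 0.4, 0.7), 3, 1, dimnames = list(c("g1", "g2", "g3"),
                                                       "s1"))
  nv <- node_values(sc, g)
  expect_equal(nv["A", "s1"], 0.3)   # mean of g1, g2
  expect_equal(nv["B", "s1"], 0.7)   # single gene
  expect_equal(nv["R", "s1"], 1)     # empty-gene relay
  expect_error(node_values(sc[1:2, , drop = FALSE], g), "missing after")
})

test_that("single-step signal rule matches hand evaluation", {
  # effector E with v=1, one activation input at 0.5
  g <- chain_graph(2)
  sc <- matrix(c(0.5, 1), 2, 1, dimnames = list(c("g_A", "g_B"), "s1"))
  cc <- extract_circuits(g)[[1]]
  pr <- propagate_circuit(cc, node_values(sc, g))
  expect_equal(unname(pr$signal), 0.5)  # 1 * (1 - (1 - 0.5))

  # v=0.8, activations {0.5, 0.5}, inhibition {0.25}:
  # 0.8 * (1 - 0.5^2) * (1 - 0.25) = 0.45
  e <- data.frame(source = c("A1", "A2", "I1"),
                  target = "E", sign = c(1, 1, -1))
  g2 <- toy_graph(e)
  sc2 <- matrix(c(0.5, 0.5, 0.8, 0.25), 4, 1,
                dimnames = list(c("g_A1", "g_A2", "g_E", "g_I1"), "s1"))
  cc2 <- extract_circuits(g2)[[1]]
  expect_equal(unname(propagate_circuit(cc2, node_values(sc2, g2))$signal),
               0.45)

  # a saturated inhibitor zeroes the node
  sc2["g_I1", ] <- 1
  expect_equal(unname(propagate_circuit(cc2, node_values(sc2, g2))$signal),
               0)
})

test_that("a 3-node half-activated chain attenuates to 0.125 and renormalizes to 1", {
  g <- chain_graph(3)
  cc <- extract_circuits(g)[[1]]
  sc <- scaled_fixture(g, rep(0.5, 3))
  pr <- propagate_circuit(cc, node_values(sc, g))
  expect_equal(unname(pr$signal), 0.125)
  cfg <- propagation_config()
  expect_equal(unname(normalize_path_activity(pr$signal, cc, cfg)), 1)
  cfg_none <- propagation_config(length_norm = "none")
  expect_equal(normalize_path_activity(pr$signal, cc, cfg_none),
               pr$signal)
})

test_that("length normalization is a per-circuit positive constant", {
  g <- chain_graph(4)
  cc <- extract_circuits(g)[[1]]
  raw <- c(s1 = 0.1, s2 = 0.2)
  for (mode in c("geometric", "reference", "none")) {
    cfg <- propagation_config(length_norm = mode)
    out <- normalize_path_activity(raw, cc, cfg)
    expect_equal(unname(out[2] / out[1]), 2, tolerance = 1e-12)
    expect_true(all(out >= 0))
  }
})

test_that("iterative solution equals direct recursion on random acyclic circuits", {
  set.seed(202)
  worst <- 0
  for (i in 1:60) {
    g <- random_graph(sample(3:8, 1))
    sc <- scaled_fixture(g, runif(sum(lengths(g$nodes$genes)) * 2))
    nv <- node_values(sc, g)
    for (cc in extract_circuits(g)) {
      got <- propagate_circuit(cc, nv)
      expect_true(got$converged)
      want <- recursive_signal(cc, nv)
      worst <- max(worst, max(abs(got$signal - want)))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("signals stay in [0,1] and respect monotonicity", {
  set.seed(303)
  for (i in 1:50) {
    g <- random_graph(sample(3:8, 1), cycle_back = i %% 5 == 0)
    n_genes <- sum(lengths(g$nodes$genes))
    sc <- scaled_fixture(g, runif(n_genes))
    nv <- node_values(sc, g)
    cats <- extract_circuits(g)
    for (cc in cats) {
      pr <- propagate_circuit(cc, nv)
      expect_true(all(pr$signal >= 0 & pr$signal <= 1))
    }
  }

  # activator monotonicity on an all-activation chain: raising any node
  # value cannot decrease the effector signal
  g <- chain_graph(4)
  cc <- extract_circuits(g)[[1]]
  set.seed(304)
  for (i in 1:30) {
    v <- runif(4)
    sc <- scaled_fixture(g, v)
    base <- propagate_circuit(cc, node_values(sc, g))$signal
    k <- sample(4, 1)
    v2 <- v
    v2[k] <- min(1, v2[k] + runif(1, 0, 1 - v2[k]))
    up <- propagate_circuit(cc, node_values(scaled_fixture(g, v2), g))$signal
    expect_gte(up + 1e-12, base)
  }

  # raising a pure inhibitor cannot increase the effector signal
  gi <- toy_graph(data.frame(source = c("A", "I"), target = c("E", "E"),
                             sign = c(1, -1)))
  cci <- extract_circuits(gi)[[1]]
  for (i in 1:20) {
    v <- runif(3)
    names(v) <- c("g_A", "g_E", "g_I")
    sc <- matrix(v, 3, 1, dimnames = list(names(v), "s1"))
    base <- propagate_circuit(cci, node_values(sc, gi))$signal
    sc["g_I", ] <- min(1, v["g_I"] + runif(1, 0, 1 - v["g_I"]))
    up <- propagate_circuit(cci, node_values(sc, gi))$signal
    expect_lte(up - 1e-12, base)
  }
})

test_that("cyclic circuits converge and cap is flagged, never silent", {
  set.seed(404)
  n_conv <- 0; n_tot <- 0
  for (i in 1:100) {
    g <- random_graph(sample(4:12, 1), cycle_back = TRUE)
    sc <- scaled_fixture(g, runif(sum(lengths(g$nodes$genes))))
    nv <- node_values(sc, g)
    for (cc in extract_circuits(g)) {
      pr <- propagate_circuit(cc, nv)
      n_tot <- n_tot + 1
      n_conv <- n_conv + pr$converged
    }
  }
  expect_gte(n_conv / n_tot, 0.99)

  # a tight iteration cap must surface as converged = FALSE
  g <- toy_graph(data.frame(source = c("A", "B", "B"),
                            target = c("B", "A", "C"), sign = 1))
  sc <- scaled_fixture(g, c(0.9, 0.9, 0.9))
  cc <- extract_circuits(g)[[1]]
  pr <- propagate_circuit(cc, node_values(sc, g),
                          propagation_config(max_iter = 1))
  expect_false(pr$converged)
})

test_that("activity matrix covers the catalog with saturation limits", {
  set.seed(505)
  g1 <- chain_graph(3, pathway_id = "p1")
  g2 <- toy_graph(data.frame(source = "A", target = "B", sign = 1),
                  pathway_id = "p2")
  graphs <- list(p1 = g1, p2 = g2)
  catalog <- build_catalog(graphs)
  genes <- unique(c(unlist(g1$nodes$genes), unlist(g2$nodes$genes)))
  ones <- matrix(1, length(genes), 3,
                 dimnames = list(genes, c("s1", "s2", "s3")))
  cfg <- propagation_config(length_norm = "none")
  act1 <- compute_activity_matrix(catalog, ones, graphs, cfg)
  expect_equal(dim(act1$values), c(length(catalog), 3))
  expect_true(all(act1$values == 1))   # full presence, no inhibitors
  act0 <- compute_activity_matrix(catalog, ones * 0, graphs, cfg)
  expect_true(all(act0$values == 0))   # any absent link kills the signal
})

test_that("downstream statistics are invariant to the length-norm choice", {
  set.seed(606)
  g <- chain_graph(4)
  graphs <- list(chain = g)
  catalog <- build_catalog(graphs)
  genes <- unlist(g$nodes$genes)
  sc <- matrix(runif(length(genes) * 20), length(genes), 20,
               dimnames = list(genes, sprintf("s%02d", 1:20)))
  cond <- rep(c("tumor", "normal"), each = 10)
  tstats <- lapply(stats::setNames(nm = c("geometric", "reference",
                                          "none")), function(mode) {
    act <- compute_activity_matrix(catalog, sc, graphs,
                                   propagation_config(length_norm = mode))
    fit <- fit_linear_model(act$values,
                            design_spec(cond,
                                        contrast = c("tumor", "normal")))
    ebayes_moderate(fit, d0 = 0)$t_mod
  })
  expect_equal(unname(tstats$geometric), unname(tstats$none),
               tolerance = 1e-9)
  expect_equal(unname(tstats$reference), unname(tstats$none),
               tolerance = 1e-9)
})
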
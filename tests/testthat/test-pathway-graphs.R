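test_that("pathway tables parse into graphs with sign-token mapping", {
  nodes <- data.frame(
    pathway_id = "p1",
    node_id = c("A", "B", "C"),
    label = c("rec", "mid", "eff"),
    genes = c("g1;g2", "g3", "g4"),
    is_function = "false"
  )
  edges <- data.frame(
    pathway_id = "p1",
    source = c("A", "B"), target = c("B", "C"),
    sign = c("activates", "inhibits")
  )
  gl <- parse_pathways(nodes, edges)
  expect_named(gl, "p1")
  g <- gl$p1
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$sign, c(1L, -1L))
  expect_equal(g$nodes$genes[[1]], c("g1", "g2"))
})

test_that("parse errors name the offending row", {
  nodes <- data.frame(pathway_id = "p1", node_id = c("A", "B"),
                      label = c("A", "B"), genes = c("g1", "g2"),
                      is_function = "false")
  bad_sign <- data.frame(pathway_id = "p1", source = "A", target = "B",
                         sign = "promotes")
  expect_error(parse_pathways(nodes, bad_sign), "promotes.*row 1")
  dangling <- data.frame(pathway_id = "p1", source = "D", target = "A",
                         sign = "+1")
  expect_error(parse_pathways(nodes, dangling), "row 1.*'D'")
  dup <- rbind(nodes, nodes[1, ])
  edges <- data.frame(pathway_id = "p1", source = "A", target = "B",
                      sign = "+1")
  expect_error(parse_pathways(dup, edges), "duplicate node_id 'A'")
})

test_that("self-loops are rejected unless explicitly dropped", {
  e <- data.frame(source = c("A", "B"), target = c("B", "B"),
                  sign = c(1, 1))
  expect_error(toy_graph(e), "self-loop")
  nodes <- data.frame(node_id = c("A", "B"), label = c("A", "B"),
                      is_function = FALSE)
  nodes$genes <- list("g1", "g2")
  g <- pathway_graph("p", nodes = nodes, edges = e,
                     allow_self_loops = TRUE)
  expect_equal(nrow(g$edges), 1)
})

test_that("effectors are sinks of the signaling sub-graph", {
  expect_equal(find_effectors(chain_graph(3)), "C")
  fan <- toy_graph(data.frame(source = c("A", "A"),
                              target = c("B", "C"), sign = 1))
  expect_equal(find_effectors(fan), c("B", "C"))
  # function nodes are annotations: B keeps effector status, F never has it
  gf <- toy_graph(data.frame(source = c("A", "B"),
                             target = c("B", "F"), sign = 1),
                  is_function = "F")
  expect_equal(find_effectors(gf), "B")
  cyc <- toy_graph(data.frame(source = c("A", "B"),
                              target = c("B", "A"), sign = 1))
  expect_warning(eff <- find_effectors(cyc), "no effectors")
  expect_length(eff, 0)
})

test_that("circuit extraction covers branching, degenerate and cyclic cases", {
  g <- toy_graph(data.frame(source = c("A", "B", "B"),
                            target = c("B", "C", "D"), sign = 1))
  cat <- extract_circuits(g)
  expect_length(cat, 2)
  expect_equal(cat[["pw:C"]]$member_nodes, c("A", "B", "C"))
  expect_equal(cat[["pw:D"]]$member_nodes, c("A", "B", "D"))
  # overlapping receptor sub-tree is shared between sibling circuits
  expect_equal(intersect(cat[["pw:C"]]$member_nodes,
                         cat[["pw:D"]]$member_nodes), c("A", "B"))

  nodes <- data.frame(node_id = "X", label = "X", is_function = FALSE)
  nodes$genes <- list("gx")
  iso <- pathway_graph("pw", nodes = nodes,
                       edges = data.frame(source = character(),
                                          target = character(),
                                          sign = integer()))
  cat_iso <- extract_circuits(iso)
  expect_length(cat_iso, 1)
  expect_equal(cat_iso[[1]]$member_nodes, "X")
  expect_equal(cat_iso[[1]]$effector, "X")

  cyc <- toy_graph(data.frame(source = c("A", "B", "B"),
                              target = c("B", "A", "C"), sign = 1))
  cat_cyc <- extract_circuits(cyc)
  expect_length(cat_cyc, 1)
  expect_equal(cat_cyc[[1]]$member_nodes, c("A", "B", "C"))
  expect_equal(nrow(cat_cyc[[1]]$member_edges), 3)  # cycle preserved
})

test_that("circuit membership matches brute-force reachability on random graphs", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    g <- random_graph(n, cycle_back = rep %% 4 == 0)
    cat <- extract_circuits(g)
    effs <- suppressWarnings(find_effectors(g))
    expect_length(cat, length(effs))  # one circuit per effector
    for (cc in cat) {
      expect_equal(cc$member_nodes, brute_reachable_to(g, cc$effector))
      expect_true(cc$effector %in% cc$member_nodes)
    }
  }
})

test_that("extraction is deterministic and row-order independent", {
  set.seed(7)
  g <- random_graph(8)
  perm <- sample(nrow(g$edges))
  g2 <- pathway_graph(g$pathway_id, nodes = g$nodes[sample(nrow(g$nodes)), ],
                      edges = g$edges[perm, ])
  c1 <- extract_circuits(g)
  c2 <- extract_circuits(g2)
  expect_equal(names(c1), names(c2))
  for (id in names(c1)) {
    expect_equal(c1[[id]]$member_nodes, c2[[id]]$member_nodes)
    e1 <- c1[[id]]$member_edges
    e2 <- c2[[id]]$member_edges
    k1 <- sort(paste(e1$source, e1$target, e1$sign))
    k2 <- sort(paste(e2$source, e2$target, e2$sign))
    expect_equal(k1, k2)
  }
})

test_that("validate_graph flags structural oddities without failing", {
  e <- data.frame(source = c("A", "A", "A"), target = c("B", "B", "B"),
                  sign = c(1, 1, -1))
  g <- toy_graph(e)
  d <- validate_graph(g)
  expect_true("duplicate_edge" %in% d$kind)
  # opposite-sign pair is legal: only the same-sign duplicate is flagged
  expect_equal(sum(d$kind == "duplicate_edge"), 1)

  nodes <- data.frame(node_id = c("A", "B"), label = c("A", "B"),
                      is_function = FALSE)
  nodes$genes <- list("g1", character())
  g2 <- pathway_graph("pw", nodes = nodes,
                      edges = data.frame(source = "A", target = "B",
                                         sign = 1))
  d2 <- validate_graph(g2)
  expect_true("non_gene_node" %in% d2$kind)
})

test_that("catalog export table carries sizes and gene lists", {
  g <- chain_graph(3)
  tab <- catalog_table(extract_circuits(g))
  expect_equal(tab$n_nodes, 3L)
  expect_equal(tab$n_edges, 2L)
  expect_equal(tab$genes, "g_A;g_B;g_C")
  expect_equal(catalog_genes(extract_circuits(g)),
               c("g_A", "g_B", "g_C"))
})
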
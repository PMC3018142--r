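# Network mapping: Rc/Nc/fusion formulas, greedy fusion vs exhaustive
# oracle, planted-module recovery, id mapping, coverage.

tri_graph <- function() {
  build_network(tibble::tibble(node_a = c("a", "a", "b"),
                               node_b = c("b", "c", "c"),
                               score = c(0.95, 0.95, 0.95)), 0.9)
}

test_that("score cutoff, deduplication and self-loops follow the contract", {
  e <- tibble::tibble(node_a = c("a", "a", "b", "c", "d"),
                      node_b = c("b", "b", "a", "c", "e"),
                      score = c(0.89, 0.92, 0.95, 0.99, 0.90))
  g <- build_network(e, cutoff = 0.9)
  # duplicate a-b rows collapse to one edge with max score 0.95
  expect_equal(igraph::ecount(g), 2L)            # a-b and d-e; c-c dropped
  eid <- igraph::get_edge_ids(g, c("a", "b"))
  expect_equal(igraph::E(g)$score[eid], 0.95)
  # 0.89 would have been dropped, 0.90 kept (boundary is >=)
  expect_true(igraph::are_adjacent(g, "d", "e"))
  g2 <- build_network(tibble::tibble(node_a = "x", node_b = "y", score = 0.89),
                      cutoff = 0.9)
  expect_equal(igraph::ecount(g2), 0L)
  expect_equal(igraph::vcount(g2), 2L)           # isolated nodes retained
  expect_error(build_network(tibble::tibble(node_a = "x", node_b = "y",
                                            score = 1.2)), "Malformed")
})

test_that("Rc and level-1 extraction match the small enumerated graphs", {
  g <- tri_graph()
  sn <- extract_subnetworks(g, c("a", "b", "c"))
  expect_true(all(sn$rc == 1))                   # triangle: clique
  expect_true(all(sn$n_nodes == 3))

  # path a-b-c: seed b has 2 unconnected neighbours -> Rc = 2/3
  gp <- build_network(tibble::tibble(node_a = c("a", "b"),
                                     node_b = c("b", "c"),
                                     score = c(0.95, 0.95)), 0.9)
  snp <- extract_subnetworks(gp, "b")
  expect_equal(snp$n_edges, 2)
  expect_equal(snp$rc, 2 / 3)

  # isolated seed: singleton sub-network, Rc = 1 by convention
  gi <- build_network(tibble::tibble(node_a = "a", node_b = "b", score = 0.95),
                      cutoff = 0.9, nodes = "z")
  sni <- extract_subnetworks(gi, "z")
  expect_equal(sni$n_nodes, 1L)
  expect_equal(sni$rc, 1)
  expect_error(extract_subnetworks(gi, "missing"), "not in the network")
})

test_that("Nc and the fusion criterion reproduce the published arithmetic", {
  expect_equal(nc_score(c("a", "b", "c", "d"), c("c", "d", "e")), 2 / 3)
  expect_equal(nc_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(nc_score(c("a"), c("b")), 0)
  expect_error(nc_score(character(0), "a"), "undefined")

  # (1 - Nc) = 0 annihilates the product: always fuses
  f1 <- should_fuse(0.1, 0.2, nc = 1)
  expect_true(f1$fuse)
  expect_equal(f1$score, 1)
  # Nc = 0.5, Rc = 0: score 0.5 < 0.7 -> no fuse
  f2 <- should_fuse(0, 0, nc = 0.5)
  expect_false(f2$fuse)
  expect_equal(f2$score, 0.5)
  # Nc = 0.4 fails the Nc >= 0.5 arm regardless of score
  f3 <- should_fuse(1, 1, nc = 0.4)
  expect_false(f3$fuse)
  expect_equal(f3$score, 1)
})

test_that("fusion score is monotone in each argument on a grid", {
  vals <- seq(0, 1, by = 0.25)
  for (rc_a in vals) for (rc_b in vals) for (nc in vals) {
    s0 <- should_fuse(rc_a, rc_b, nc)$score
    expect_gte(should_fuse(min(rc_a + 0.25, 1), rc_b, nc)$score, s0)
    expect_gte(should_fuse(rc_a, min(rc_b + 0.25, 1), nc)$score, s0)
    expect_gte(should_fuse(rc_a, rc_b, min(nc + 0.25, 1))$score, s0)
  }
})

test_that("fuse_all equals the exhaustive oracle on random small instances", {
  set.seed(401)
  for (trial in 1:100) {
    n <- sample(6:10, 1)
    nodes <- letters[1:n]
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.45
    edges <- tibble::tibble(node_a = pairs[keep, 1], node_b = pairs[keep, 2],
                            score = 0.95)
    g <- build_network(edges, 0.9, nodes = nodes)
    seeds <- sample(nodes, sample(3:6, 1))
    sn <- extract_subnetworks(g, seeds)
    got <- fuse_all(sn, g)
    want <- oracle_fuse(sn$nodes, g)
    got_sets <- lapply(got$nodes, identity)
    got_sets <- got_sets[order(vapply(got_sets, paste, character(1),
                                      collapse = "\r"))]
    expect_equal(got_sets, want)
  }
})

test_that("fuse_all is idempotent, order-invariant and strictly shrinking", {
  g <- tri_graph()
  sn <- extract_subnetworks(g, c("a", "b"))
  fused <- fuse_all(sn, g)
  # identical node sets collapse to one sub-network, unchanged nodes
  expect_equal(nrow(fused), 1L)
  expect_equal(fused$nodes[[1]], c("a", "b", "c"))
  # input order invariance
  set.seed(402)
  nodes <- letters[1:12]
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.4
  edges <- tibble::tibble(node_a = pairs[keep, 1], node_b = pairs[keep, 2],
                          score = 0.95)
  g2 <- build_network(edges, 0.9, nodes = nodes)
  sn2 <- extract_subnetworks(g2, nodes)
  f_fwd <- fuse_all(sn2, g2)
  f_rev <- fuse_all(sn2[rev(seq_len(nrow(sn2))), ], g2)
  expect_equal(f_fwd$nodes, f_rev$nodes)
  expect_lte(nrow(f_fwd), nrow(sn2))
})

test_that("planted modules are recovered by extraction + fusion", {
  jacc_med <- numeric(20)
  for (s in 1:20) {
    pp <- sim_ppi(5, 12, p_in = 0.9, p_out = 0.01, seed = 600 + s)
    g <- build_network(pp$edges, cutoff = 0.9, nodes = pp$nodes$node)
    sn <- extract_subnetworks(g, pp$nodes$node)
    fused <- fuse_all(sn, g)
    jac <- vapply(unique(pp$nodes$module), function(m) {
      truth <- pp$nodes$node[pp$nodes$module == m]
      best <- 0
      for (k in seq_len(nrow(fused))) {
        got <- fused$nodes[[k]]
        j <- length(intersect(truth, got)) / length(union(truth, got))
        best <- max(best, j)
      }
      best
    }, numeric(1))
    jacc_med[s] <- median(jac)
  }
  expect_gte(median(jacc_med), 0.9)
})

test_that("identifier mapping follows the stated priority order", {
  ids <- tibble::tibble(
    query = c("q1", "q1", "q2", "q2", "q3"),
    id_type = c("uniprot_id", "gene_name", "gene_name", "gene_name", "refseq"),
    node = c("N1", "N9", "N2", "N3", "N4"))
  hits <- tibble::tibble(query = c("q4", "q5"), node = c("N5", "N6"),
                         evalue = c(1e-10, 1e-4))
  out <- suppressWarnings(
    map_to_network(c("q1", "q2", "q3", "q4", "q5", "q6"), ids, hits))
  # uniprot beats gene name
  expect_equal(out$node[out$query == "q1"], "N1")
  expect_equal(out$method[out$query == "q1"], "textual:uniprot_id")
  # ambiguous gene_name falls through (here to similarity/unmapped)
  expect_warning(map_to_network("q2", ids), "Ambiguous")
  expect_true(is.na(suppressWarnings(map_to_network("q2", ids))$node))
  expect_equal(out$node[out$query == "q3"], "N4")
  expect_equal(out$method[out$query == "q4"], "similarity")
  # hit at E = 1e-4 fails the 1e-5 cutoff
  expect_true(is.na(out$node[out$query == "q5"]))
  expect_equal(out$method[out$query == "q6"], "unmapped")
})

test_that("pathway coverage counts distinct enzymes and flags > 50%", {
  pw <- tibble::tibble(
    pathway = c(rep("P1", 11), rep("P2", 4)),
    enzyme = c(paste0("e", c(1:10, 10)), paste0("f", 1:4)))
  mapping <- tibble::tibble(node = c(paste0("e", 1:6), "f1"))
  out <- coverage_summary(mapping, pw)
  p1 <- out$pathway_coverage[out$pathway_coverage$pathway == "P1", ]
  expect_equal(p1$n_enzymes, 10L)     # e10 repeated, counted once
  expect_equal(p1$coverage, 0.6)
  expect_true(p1$flagged)
  p2 <- out$pathway_coverage[out$pathway_coverage$pathway == "P2", ]
  expect_equal(p2$coverage, 0.25)
  expect_false(p2$flagged)
  expect_equal(out$pathway_summary$flagged_fraction, 0.5)
  # no queries map -> all coverage zero
  none <- coverage_summary(tibble::tibble(node = character(0)), pw)
  expect_true(all(none$pathway_coverage$coverage == 0))
  # sub-network population
  sn <- tibble::tibble(nodes = list(c("e1", "x"), c("y", "z")))
  out2 <- coverage_summary(mapping, pw, subnets = sn)
  expect_equal(out2$subnet_summary$populated_fraction, 0.5)
})
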
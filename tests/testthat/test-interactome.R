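mating_rows <- function(bait, prey, positives, total = 4L) {
  tibble::tibble(bait = bait, prey = prey, replicate = seq_len(total),
                 growth = seq_len(total) <= positives)
}

test_that("edge calling pools both orientations against min_support", {
  m <- dplyr::bind_rows(mating_rows("A", "B", 3), mating_rows("B", "A", 0))
  edges <- call_interactions(m, min_support = 3)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$support, 3L)
  weak <- dplyr::bind_rows(mating_rows("A", "B", 1),
                           mating_rows("B", "A", 1))
  expect_equal(nrow(call_interactions(weak, min_support = 3)), 0L)
  self <- mating_rows("A", "A", 4)
  se <- call_interactions(self)
  expect_equal(se$a, "A")
  expect_equal(se$b, "A")
  expect_equal(se$support, 4L)
})

test_that("raising min_support never adds an edge (monotonicity)", {
  scr <- gen_y2h_screen(paste0("E", 1:12), rep(c("B", "C", "D"), 4),
                        y2h_model(edge_p = 0.4, self_p = 0.3, fn = 0.2,
                                  fp = 0.05), seed = 41)
  prev <- call_interactions(scr$matings, min_support = 1)
  for (ms in 2:8) {
    cur <- call_interactions(scr$matings, min_support = ms)
    expect_true(all(paste(cur$a, cur$b) %in% paste(prev$a, prev$b)))
    prev <- cur
  }
})

test_that("duplicate replicate rows are rejected", {
  dup <- dplyr::bind_rows(mating_rows("A", "B", 2), mating_rows("A", "B", 1))
  expect_error(call_interactions(dup), "Duplicate")
})

test_that("network summary counts match the published definitions", {
  edges <- tibble::tibble(a = c("a", "a", "b"), b = c("a", "b", "c"),
                          support = c(4L, 5L, 6L))
  net <- ecc_network(edges, nodes = c("a", "b", "c", "d"))
  s <- network_summary(net)
  expect_equal(s$n_nodes, 4L)
  expect_equal(s$n_self, 1L)
  expect_equal(s$n_hetero, 2L)
  expect_equal(s$n_nodes_with_hetero, 3L)
  empty <- ecc_network(edges[0, ], nodes = letters[1:5])
  se <- network_summary(empty)
  expect_equal(se$n_nodes, 5L)
  expect_equal(se$n_self + se$n_hetero + se$n_nodes_with_hetero, 0L)
  # complete heteromeric graph on 4 nodes: 4 choose 2 edges
  cmb <- utils::combn(letters[1:4], 2)
  complete <- ecc_network(tibble::tibble(a = cmb[1, ], b = cmb[2, ],
                                         support = 8L))
  expect_equal(network_summary(complete)$n_hetero, 6L)
  # degree bookkeeping: sum of partner counts is twice the edge count
  deg <- network_degrees(net)
  expect_equal(sum(deg$n_partners), 2L * s$n_hetero)
  expect_equal(deg$degree[deg$id == "a"], 2L)  # one partner + self
})

test_that("degree-phenotype correlation matches the direct formula", {
  edges <- tibble::tibble(a = c("x", "x", "y"), b = c("y", "z", "z"),
                          support = 5L)
  net3 <- ecc_network(tibble::tibble(a = c("x", "y"), b = c("y", "z"),
                                     support = 4L),
                      nodes = c("x", "y", "z"))
  ph <- tibble::tibble(ecc_id = c("x", "y", "z"), species = "At",
                       category = c(2L, 1L, 0L))
  # degrees 1, 2, 1 vs categories 2, 1, 0
  r <- degree_phenotype_correlation(net3, ph)
  x <- c(1, 2, 1); y <- c(2, 1, 0)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r, r_direct)
  # perfect anticorrelation example
  net_line <- ecc_network(tibble::tibble(a = c("y", "y", "z"),
                                         b = c("z", "x", "z"),
                                         support = 4L),
                          nodes = c("w", "x", "y", "z"))
  ph4 <- tibble::tibble(ecc_id = c("w", "x", "y", "z"), species = "At",
                        category = c(3L, 2L, 1L, 0L))
  # degrees 0, 1, 2, 2+1(self); categories 3, 2, 1, 0
  rr <- degree_phenotype_correlation(net_line, ph4)
  expect_lt(rr$r, -0.9)
  flat <- tibble::tibble(ecc_id = c("x", "y", "z"), species = "At",
                         category = 2L)
  expect_error(degree_phenotype_correlation(net3, flat), "zero variance")
})

test_that("group-pair Fisher test matches hypergeometric enumeration", {
  set.seed(52)
  for (i in 1:10) {
    ids <- paste0("n", 1:10)
    groups <- stats::setNames(sample(c("A", "B"), 10, replace = TRUE,
                                     prob = c(0.4, 0.6)), ids)
    if (length(unique(groups)) < 2L) next
    cmb <- utils::combn(ids, 2)
    present <- stats::runif(ncol(cmb)) < 0.35
    edges <- tibble::tibble(a = cmb[1, present], b = cmb[2, present],
                            support = 4L)
    net <- ecc_network(edges, nodes = ids)
    res <- group_pair_interaction_test(
      net, groups,
      focal = list("A", "B"),
      reference = list("B", "B"))
    tab <- matrix(c(res$focal_edges, res$reference_edges,
                    res$focal_dyads - res$focal_edges,
                    res$reference_dyads - res$reference_edges),
                  2, byrow = TRUE)
    expect_equal(res$p, oracle_fisher_p(tab), tolerance = 1e-9)
  }
})

test_that("equal dyad densities give an odds ratio of exactly one", {
  # 2 A-nodes, 4 B-nodes; one A-B edge of 8 dyads, one B-B edge of 6
  ids <- c("a1", "a2", "b1", "b2", "b3", "b4")
  groups <- stats::setNames(c("A", "A", "B", "B", "B", "B"), ids)
  edges <- tibble::tibble(a = c("a1", "a1", "b1", "b2", "b1"),
                          b = c("b1", "b2", "b2", "b3", "b4"),
                          support = 4L)
  net <- ecc_network(edges, nodes = ids)
  res <- group_pair_interaction_test(net, groups,
                                     focal = list("A", "B"),
                                     reference = list("B", "B"))
  # focal: 2/8 = 0.25; reference: 3/6 = 0.5 -> OR (2*3)/(6*3) = 1/3
  expect_equal(res$odds_ratio, (2 * 3) / (6 * 3))
  # equal densities exactly: focal 4/8, reference 3/6
  balanced <- tibble::tibble(
    a = c("a1", "a1", "a2", "a2", "b1", "b1", "b1"),
    b = c("b1", "b2", "b1", "b2", "b2", "b3", "b4"),
    support = 4L)
  res2 <- group_pair_interaction_test(ecc_network(balanced, nodes = ids),
                                      groups,
                                      focal = list("A", "B"),
                                      reference = list("B", "B"))
  expect_equal(res2$odds_ratio, 1)
  expect_error(group_pair_interaction_test(net, groups,
                                           focal = list("E", "E"),
                                           reference = list("B", "B")),
               "Degenerate")
})

test_that("higher-affinity clones beat their own self support", {
  edges <- tibble::tibble(
    a = c("a", "a", "b", "c"),
    b = c("a", "b", "c", "c"),
    support = c(4L, 6L, 5L, 7L))
  net <- ecc_network(edges, nodes = c("a", "b", "c", "d"))
  # a: self 4 < best hetero 6 -> in; b: no self, hetero 6 -> in
  # c: self 7 > hetero 5 -> out; d: isolated -> out
  expect_equal(higher_affinity_partners(net), c("a", "b"))
  only_self <- ecc_network(tibble::tibble(a = "a", b = "a", support = 4L),
                           nodes = c("a", "b"))
  expect_equal(higher_affinity_partners(only_self), character(0))
})

test_that("cross-species persistence counts active species per clone", {
  ph <- tibble::tibble(
    ecc_id = rep(c("e1", "e2", "e3"), each = 3),
    species = rep(c("At", "Nb", "Ls"), 3),
    category = c(4L, 3L, 2L,   0L, 1L, 0L,   5L, 0L, 3L))
  res <- cross_species_persistence(ph)
  per <- res$per_ecc
  expect_equal(per$persistence[per$ecc_id == "e1"], 3L)
  expect_equal(per$persistence[per$ecc_id == "e2"], 0L)
  expect_equal(per$persistence[per$ecc_id == "e3"], 2L)
  expect_equal(per$active_in[per$ecc_id == "e3"], "At+Ls")
  expect_equal(sum(res$per_species$n_scored), nrow(ph))
})

test_that("recovered screen density sits in the binomial CI of the planted one", {
  p_edge <- 0.1
  n_ids <- 30L
  hits <- 0L
  dyads <- 0L
  for (s in 1:20) {
    scr <- gen_y2h_screen(paste0("E", 1:n_ids),
                          rep(c("B", "C", "D"), each = 10),
                          y2h_model(edge_p = p_edge, self_p = 0,
                                    fn = 0.1, fp = 0),
                          seed = 500 + s)
    edges <- call_interactions(scr$matings, min_support = 3)
    hits <- hits + nrow(edges[edges$a != edges$b, ])
    dyads <- dyads + choose(n_ids, 2)
  }
  # with fn = 0.1 an edge is missed only if >5 of 8 replicates drop out:
  # recovery per true edge is ~1, so the recovered density estimates p_edge
  ci <- p_edge + c(-1, 1) * 1.96 * sqrt(p_edge * (1 - p_edge) / dyads)
  expect_gte(hits / dyads, ci[1])
  expect_lte(hits / dyads, ci[2])
})

test_that("network exports write edge TSV and GraphML", {
  edges <- tibble::tibble(a = c("a", "b"), b = c("b", "c"), support = 5L)
  net <- ecc_network(edges, nodes = c("a", "b", "c"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, tsv)
  write_network(net, gml)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 2L)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
})
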
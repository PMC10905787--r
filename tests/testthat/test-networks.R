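ppi_path <- function() {
  write_tmp(c("gene_a\tgene_b", "A\tB", "B\tC", "C\tD", "D\tE"))
}

test_that("node weights follow sqrt(score x literature count)", {
  ppi <- read_ppi(write_tmp(c("gene_a\tgene_b", "A\tB")))
  dg <- tibble::tibble(symbol = c("A", "B"),
                       relevance_score = c(4, 2),
                       literature_count = c(9L, 8L))
  net <- build_weighted_network(ppi, dg)
  expect_equal(net$nodes$weight[net$nodes$symbol == "A"], 6)
  expect_equal(net$nodes$weight[net$nodes$symbol == "B"], 4)
  expect_equal(igraph::V(net$graph)$weight,
               net$nodes$weight[match(igraph::V(net$graph)$name,
                                      net$nodes$symbol)])
})

test_that("weight scales as sqrt: doubling both factors doubles the weight", {
  ppi <- read_ppi(write_tmp(c("gene_a\tgene_b", "A\tB")))
  dg1 <- tibble::tibble(symbol = c("A", "B"), relevance_score = 3,
                        literature_count = 7L)
  dg2 <- dplyr::mutate(dg1, relevance_score = 6, literature_count = 14L)
  w1 <- build_weighted_network(ppi, dg1)$nodes$weight
  w2 <- build_weighted_network(ppi, dg2)$nodes$weight
  expect_equal(w2, 2 * w1)
})

test_that("disease genes induce the subgraph; isolates drop unless kept", {
  ppi <- read_ppi(ppi_path())
  dg <- tibble::tibble(symbol = c("A", "B", "D"), relevance_score = 1,
                       literature_count = 1L)
  net <- build_weighted_network(ppi, dg)
  expect_setequal(net$nodes$symbol, c("A", "B"))
  expect_equal(nrow(net$edges), 1)
  net2 <- build_weighted_network(ppi, dg, keep_isolates = TRUE)
  expect_setequal(net2$nodes$symbol, c("A", "B", "D"))
  dg_off <- tibble::tibble(symbol = "ZZZ", relevance_score = 1,
                           literature_count = 1L)
  expect_error(build_weighted_network(ppi, dg_off), "no overlap")
})

test_that("C-T network counts components, targets and edges", {
  net <- ct_from_sets(list(C1 = "TNF", C2 = "TNF"))
  expect_equal(net$n_components, 2)
  expect_equal(net$n_targets, 1)
  expect_equal(net$n_edges, 2)
  expect_error(build_ct_network(comp_row("C1"), comp_row("C1")[0, 1:2]))
})

test_that("edges of non-active components are dropped with a warning", {
  comps <- comp_row("C1")
  edges <- tibble::tibble(component_id = c("C1", "GHOST"),
                          target_symbol = c("TNF", "IL6"))
  expect_warning(net <- build_ct_network(comps, edges), "not active")
  expect_equal(net$n_edges, 1)
  expect_equal(net$n_targets, 1)
})

test_that("targetless components stay as nodes but leave degree rankings", {
  comps <- dplyr::bind_rows(comp_row("C1"), comp_row("C2"))
  edges <- tibble::tibble(component_id = "C1", target_symbol = c("A", "B"))
  net <- build_ct_network(comps, edges)
  expect_equal(net$n_components, 2)
  expect_false(net$components$has_targets[net$components$component_id == "C2"])
  stats <- ct_statistics(net)
  expect_false("C2" %in% stats$component_degrees$component_id)
})

test_that("mean degrees are |E|/C exact before rounding, half-up after", {
  net <- ct_from_sets(list(C1 = c("A", "B", "C")))
  s <- ct_statistics(net)$summary
  expect_equal(s$mean_targets_per_component, 3)
  for (seed in 1:5) {
    net <- random_ct(6, 8, seed)
    s <- ct_statistics(net)$summary
    raw_c <- net$n_edges / net$n_components
    raw_t <- net$n_edges / net$n_targets
    expect_equal(raw_c * net$n_components, net$n_edges)
    expect_equal(raw_t * net$n_targets, net$n_edges)
    expect_lte(abs(s$mean_targets_per_component - raw_c), 0.005)
    expect_lte(abs(s$mean_components_per_target - raw_t), 0.005)
  }
  # half-up, not half-to-even: 7.905 prints as 7.91
  expect_equal(netpharm:::round_half_up(7.905, 2), 7.91)
  expect_equal(netpharm:::round_half_up(40.625, 2), 40.63)
})

test_that("bipartite igraph conversion types the two node sides", {
  net <- ct_from_sets(list(C1 = c("A", "B"), C2 = "B"))
  g <- as_igraph(net)
  expect_equal(sum(igraph::V(g)$type == "component"), 2)
  expect_equal(sum(igraph::V(g)$type == "target"), 2)
  expect_equal(igraph::gsize(g), 3)
})
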
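#' Build the weighted disease-gene regulatory network
#'
#' Maps disease genes onto a merged PPI table and returns the induced
#' subgraph, with each gene weighted by the square root of its relevance
#' score multiplied by its literature count:
#' \eqn{w(g) = \sqrt{\mathrm{score}(g) \times \mathrm{lit}(g)}}. Genes with
#' no retained PPI edge are dropped by default.
#'
#' @param ppi PPI edge tibble from [read_ppi()].
#' @param disease_genes Disease-gene tibble from [read_disease_genes()].
#' @param keep_isolates Keep mapped genes without any induced edge
#'   (default `FALSE`).
#' @return An object of class `gene_network`: a list with `nodes` (tibble of
#'   `symbol`, `relevance_score`, `literature_count`, `weight`), `edges`
#'   (induced PPI edges) and `graph` (igraph with a `weight` vertex
#'   attribute).
#' @export
build_weighted_network <- function(ppi, disease_genes, keep_isolates = FALSE) {
  dsym <- unique(norm_symbol(disease_genes$symbol))
  ppi_genes <- unique(c(ppi$gene_a, ppi$gene_b))
  mapped <- intersect(dsym, ppi_genes)
  if (length(mapped) == 0) {
    abort("no overlap between disease genes and PPI network")
  }
  edges <- filter(ppi, gene_a %in% mapped & gene_b %in% mapped)
  nodes <- disease_genes %>%
    mutate(symbol = norm_symbol(symbol)) %>%
    filter(symbol %in% mapped) %>%
    mutate(weight = sqrt(relevance_score * literature_count))
  if (!keep_isolates) {
    connected <- unique(c(edges$gene_a, edges$gene_b))
    nodes <- filter(nodes, symbol %in% connected)
  }
  nodes <- arrange(nodes, symbol)
  g <- igraph::graph_from_data_frame(
    select(edges, gene_a, gene_b),
    directed = FALSE,
    vertices = select(nodes, symbol, weight)
  )
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "gene_network")
}

#' @method print gene_network
#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Weighted gene regulatory network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @method as_igraph gene_network
#' @export
as_igraph.gene_network <- function(x, ...) x$graph

#' Build the bipartite compound-target (C-T) network
#'
#' Links active components to their protein targets. Edges whose component is
#' not in the active set are dropped with a warning. Active components without
#' any target are retained as nodes with empty target sets (flagged in
#' `components$has_targets`) but excluded from degree rankings, since they can
#' never enter the function response space.
#'
#' @param active Tibble of active components (needs `component_id`; other
#'   columns are carried along).
#' @param edges C-T edge tibble from [read_ct_edges()].
#' @return An object of class `ct_network`: a list with `components` (tibble
#'   incl. `degree` and `has_targets`), `targets` (character vector),
#'   `edges`, `target_sets` (named list component -> target character vector)
#'   and counts `n_components`, `n_targets`, `n_edges`.
#' @export
build_ct_network <- function(active, edges) {
  if (nrow(edges) == 0) abort("C-T edge list is empty")
  edges <- distinct(edges, component_id, target_symbol)
  known <- edges$component_id %in% active$component_id
  if (any(!known)) {
    warn(sprintf("dropping %d C-T edge(s) whose component is not active",
                 sum(!known)))
    edges <- edges[known, , drop = FALSE]
  }
  if (nrow(edges) == 0) abort("no C-T edges left after filtering to active components")
  edges <- arrange(edges, component_id, target_symbol)
  target_sets <- split(edges$target_symbol, edges$component_id)
  comps <- active %>%
    arrange(component_id) %>%
    mutate(
      degree = purrr::map_int(component_id,
                              ~ length(target_sets[[.x]] %||% character())),
      has_targets = degree > 0L
    )
  targets <- sort(unique(edges$target_symbol))
  structure(list(
    components = comps,
    targets = targets,
    edges = edges,
    target_sets = target_sets,
    n_components = nrow(comps),
    n_targets = length(targets),
    n_edges = nrow(edges)
  ), class = "ct_network")
}

#' @method print ct_network
#' @export
print.ct_network <- function(x, ...) {
  cat(sprintf("C-T network: %d components, %d targets, %d edges\n",
              x$n_components, x$n_targets, x$n_edges))
  invisible(x)
}

#' @method as_igraph ct_network
#' @export
as_igraph.ct_network <- function(x, ...) {
  verts <- tibble(
    name = c(x$components$component_id, x$targets),
    type = c(rep("component", x$n_components),
             rep("target", x$n_targets))
  )
  igraph::graph_from_data_frame(x$edges, directed = FALSE, vertices = verts)
}

#' Topology statistics of a C-T network
#'
#' Summarises the bipartite compound-target network: mean targets per
#' component (`|E| / C_com`), mean components per target (`|E| / C_tar`), and
#' degree tables for both sides. The two means satisfy
#' `mean_targets_per_component * C_com = mean_components_per_target * C_tar
#' = |E|` exactly before rounding; reported means are rounded half-up to two
#' decimals to match the convention of printed network summaries.
#' Components without targets are excluded from the component degree ranking.
#'
#' @param net A `ct_network`.
#' @param top_k Number of top-degree nodes listed per side.
#' @return A list of class `ct_statistics` with `summary` (one-row tibble),
#'   `component_degrees`, `target_degrees` and `top_components`,
#'   `top_targets`.
#' @export
ct_statistics <- function(net, top_k = 10) {
  stopifnot(inherits(net, "ct_network"))
  comp_deg <- net$components %>%
    filter(has_targets) %>%
    select(component_id, degree) %>%
    arrange(desc(degree), component_id)
  tar_deg <- net$edges %>%
    count(target_symbol, name = "degree") %>%
    arrange(desc(degree), target_symbol)
  summary <- tibble(
    n_components = net$n_components,
    n_targets = net$n_targets,
    n_edges = net$n_edges,
    mean_targets_per_component =
      round_half_up(net$n_edges / net$n_components, 2),
    mean_components_per_target =
      round_half_up(net$n_edges / net$n_targets, 2)
  )
  structure(list(
    summary = summary,
    component_degrees = comp_deg,
    target_degrees = tar_deg,
    top_components = head(comp_deg, top_k),
    top_targets = head(tar_deg, top_k)
  ), class = "ct_statistics")
}

#' @method print ct_statistics
#' @export
print.ct_statistics <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' @method glance ct_statistics
#' @export
glance.ct_statistics <- function(x, ...) x$summary
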
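#' Select the maximal-degree component subset
#'
#' Returns the `k` components with the largest C-T degree, ties broken by
#' component id ascending. Because bipartite degrees do not depend on which
#' other components are co-selected, the total degree of this subset equals
#' the maximum over all size-`k` subsets, so top-k selection is exact.
#'
#' @param net A `ct_network`.
#' @param k Subset size, `0 <= k <= n_components`.
#' @return Character vector of `k` component ids.
#' @export
select_max_degree_subset <- function(net, k) {
  stopifnot(inherits(net, "ct_network"))
  if (k < 0 || k > net$n_components) {
    abort(sprintf("k = %d out of range [0, %d]", k, net$n_components))
  }
  if (k == 0) return(character())
  net$components %>%
    arrange(desc(degree), component_id) %>%
    slice_head(n = k) %>%
    pull(component_id)
}

#' Solve the deviation-variable goal program for the FRS
#'
#' Chooses how many components (`C_com'`) and induced targets (`C_tar'`)
#' delimit the function response space, by minimising deviations from three
#' prioritised goals:
#'
#' 1. `C_com' + C_tar' + d1- - d1+ = a1 * C_tar` — the selection should span
#'    about `a1` of the target space (under-attainment `d1-` penalised first);
#' 2. `C_com' + d2- - d2+ = a2 * C_overlap` — at least about `a2` times the
#'    number of targets shared with the disease genes should be selectable
#'    (under-attainment `d2-` penalised second);
#' 3. `C_com' + d3- - d3+ <= a3 * C_com` — no more than about `a3` of the
#'    components should be kept (overshoot `d3+` penalised last).
#'
#' In the default induced mode the goal program is coupled to the graph:
#' for each candidate `k` the selection is the top-`k` maximal-degree
#' component subset and `C_tar'(k)` is the size of its induced target set;
#' deviations follow from the three goals and the best `k` is the one that
#' minimises `(d1-, d2-, d3+)` lexicographically under preemptive priorities
#' (ties: smallest `k`). In analytic mode `C_tar'` is a free variable in
#' `[0, C_tar]` and the pure goal program is solved in closed form.
#' Complementary slackness (`d- * d+ = 0` per goal) holds by construction.
#'
#' @param net A `ct_network`.
#' @param disease_genes Disease-gene tibble; `C_overlap` is the number of
#'   unique network targets shared with its symbols.
#' @param coefficients Goal coefficients `c(a1, a2, a3)` in (0, 1];
#'   defaults `c(0.70, 0.80, 0.40)`.
#' @param priorities Either `"preemptive"` (lexicographic `p1 > p2 > p3`,
#'   default) or a numeric vector of three positive weights for a weighted
#'   objective `Z = p1 d1- + p2 d2- + p3 d3+`.
#' @param mode `"induced"` (default) or `"analytic"`.
#' @return An object of class `goal_program_solution`: list with
#'   `c_com_sel`, `c_tar_sel`, `deviations` (tibble of d-/d+ per goal),
#'   `z`, `c_overlap`, goal `targets`, the per-`k` `candidates` table
#'   (induced mode) and the `mode` used. `z` is reported under the weights
#'   used (preemptive mode uses nominal weights 1e6, 1e3, 1).
#' @export
solve_goal_program <- function(net, disease_genes,
                               coefficients = c(0.70, 0.80, 0.40),
                               priorities = "preemptive",
                               mode = c("induced", "analytic")) {
  stopifnot(inherits(net, "ct_network"), length(coefficients) == 3,
            all(coefficients > 0), all(coefficients <= 1))
  mode <- match.arg(mode)
  if (net$n_components == 0 || net$n_edges == 0) abort("C-T network is empty")
  a <- coefficients
  dsym <- unique(norm_symbol(disease_genes$symbol))
  c_overlap <- length(intersect(net$targets, dsym))
  c_com <- net$n_components
  c_tar <- net$n_targets

  goal1 <- a[1] * c_tar
  goal2 <- a[2] * c_overlap
  goal3 <- a[3] * c_com

  weights <- if (identical(priorities, "preemptive")) c(1e6, 1e3, 1)
             else {
               stopifnot(is.numeric(priorities), length(priorities) == 3,
                         all(priorities > 0))
               priorities
             }
  preemptive <- identical(priorities, "preemptive")

  if (mode == "induced") {
    ranked <- net$components %>%
      arrange(desc(degree), component_id)
    # running induced-target count of the top-k prefix
    seen <- character(0)
    c_tar_k <- integer(c_com)
    for (i in seq_len(c_com)) {
      seen <- union(seen, net$target_sets[[ranked$component_id[i]]] %||%
                      character())
      c_tar_k[i] <- length(seen)
    }
    cand <- tibble(
      k = seq_len(c_com),
      c_tar_sel = c_tar_k,
      d1_minus = pmax(0, goal1 - (k + c_tar_sel)),
      d1_plus = pmax(0, (k + c_tar_sel) - goal1),
      d2_minus = pmax(0, goal2 - k),
      d2_plus = pmax(0, k - goal2),
      d3_minus = pmax(0, goal3 - k),
      d3_plus = pmax(0, k - goal3)
    )
    best <- if (preemptive) {
      with(cand, order(d1_minus, d2_minus, d3_plus, k))[1]
    } else {
      z <- with(cand, weights[1] * d1_minus + weights[2] * d2_minus +
                  weights[3] * d3_plus)
      order(z, cand$k)[1]
    }
    sol <- cand[best, ]
    k_sel <- sol$k
    tar_sel <- sol$c_tar_sel
  } else {
    # analytic: C_tar' free in [0, C_tar]; preemptive closed form:
    # goal 2 fixes C_com' (p2 beats the overshoot penalty p3),
    # then goal 1 fixes C_tar', goal 3 absorbs any overshoot.
    k_sel <- min(c_com, max(0L, as.integer(ceiling(goal2))))
    tar_sel <- min(c_tar, max(0L, as.integer(ceiling(goal1 - k_sel))))
    cand <- NULL
    sol <- tibble(
      k = k_sel, c_tar_sel = tar_sel,
      d1_minus = max(0, goal1 - (k_sel + tar_sel)),
      d1_plus = max(0, (k_sel + tar_sel) - goal1),
      d2_minus = max(0, goal2 - k_sel),
      d2_plus = max(0, k_sel - goal2),
      d3_minus = max(0, goal3 - k_sel),
      d3_plus = max(0, k_sel - goal3)
    )
  }

  deviations <- tibble(
    goal = c("span_targets", "cover_shared", "limit_components"),
    target = c(goal1, goal2, goal3),
    d_minus = c(sol$d1_minus, sol$d2_minus, sol$d3_minus),
    d_plus = c(sol$d1_plus, sol$d2_plus, sol$d3_plus)
  )
  z <- weights[1] * sol$d1_minus + weights[2] * sol$d2_minus +
    weights[3] * sol$d3_plus

  structure(list(
    c_com_sel = as.integer(k_sel),
    c_tar_sel = as.integer(tar_sel),
    deviations = deviations,
    z = z,
    weights = weights,
    preemptive = preemptive,
    coefficients = a,
    c_com = c_com, c_tar = c_tar, c_overlap = c_overlap,
    candidates = cand,
    mode = mode
  ), class = "goal_program_solution")
}

#' @method print goal_program_solution
#' @export
print.goal_program_solution <- function(x, ...) {
  cat(sprintf(
    "Goal program (%s mode): C_com' = %d, C_tar' = %d, Z = %g\n",
    x$mode, x$c_com_sel, x$c_tar_sel, x$z))
  print(x$deviations)
  invisible(x)
}

#' @method tidy goal_program_solution
#' @export
tidy.goal_program_solution <- function(x, ...) x$deviations

#' @method glance goal_program_solution
#' @export
glance.goal_program_solution <- function(x, ...) {
  tibble(c_com_sel = x$c_com_sel, c_tar_sel = x$c_tar_sel, z = x$z,
         c_com = x$c_com, c_tar = x$c_tar, c_overlap = x$c_overlap,
         mode = x$mode)
}

#' Build the function response space (FRS)
#'
#' Extracts the induced bipartite subgraph on the goal program's selected
#' components: the `C_com'` maximal-degree components and every target they
#' hit. The target side of the FRS defines the effective proteins, so
#' `length(effective_proteins)` always equals the solution's `C_tar'`.
#'
#' @param net A `ct_network`.
#' @param solution A `goal_program_solution` obtained from `net`.
#' @return An object of class `frs`: list with `components` (character),
#'   `effective_proteins` (character), `edges` (induced C-T edges),
#'   `target_sets` (restricted to selected components), `n_nodes`,
#'   `n_edges`.
#' @export
build_frs <- function(net, solution) {
  stopifnot(inherits(net, "ct_network"),
            inherits(solution, "goal_program_solution"))
  comps <- select_max_degree_subset(net, solution$c_com_sel)
  edges <- filter(net$edges, component_id %in% comps)
  proteins <- sort(unique(edges$target_symbol))
  structure(list(
    components = comps,
    effective_proteins = proteins,
    edges = edges,
    target_sets = net$target_sets[comps],
    n_nodes = length(comps) + length(proteins),
    n_edges = nrow(edges)
  ), class = "frs")
}

#' Construct an FRS object directly
#'
#' Lower-level constructor used by the synthetic-fixture generators and by
#' callers that already know the component set and effective-protein universe.
#'
#' @param edges C-T edge tibble restricted to the FRS components.
#' @param effective_proteins Optional character vector; defaults to the
#'   target side of `edges`.
#' @return An `frs` object.
#' @export
new_frs <- function(edges, effective_proteins = NULL) {
  comps <- sort(unique(edges$component_id))
  proteins <- effective_proteins %||% sort(unique(edges$target_symbol))
  structure(list(
    components = comps,
    effective_proteins = sort(proteins),
    edges = arrange(edges, component_id, target_symbol),
    target_sets = split(edges$target_symbol, edges$component_id)[comps],
    n_nodes = length(comps) + length(proteins),
    n_edges = nrow(edges)
  ), class = "frs")
}

#' @method print frs
#' @export
print.frs <- function(x, ...) {
  cat(sprintf(
    "FRS: %d nodes (%d components + %d effective proteins), %d edges\n",
    x$n_nodes, length(x$components), length(x$effective_proteins),
    x$n_edges))
  invisible(x)
}

#' @method as_igraph frs
#' @export
as_igraph.frs <- function(x, ...) {
  verts <- tibble(
    name = c(x$components, x$effective_proteins),
    type = c(rep("component", length(x$components)),
             rep("target", length(x$effective_proteins)))
  )
  # induced edges only; targets outside the effective set are not FRS nodes
  edges <- filter(x$edges, target_symbol %in% x$effective_proteins)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}
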
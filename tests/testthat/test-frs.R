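test_that("top-k max-degree subset matches pairwise enumeration", {
  net <- ct_from_sets(list(
    A = c("T1", "T2", "T3", "T4", "T5"),
    B = c("T1", "T2", "T3", "T4"),
    C = c("T1", "T2", "T3"),
    D = c("T1", "T2")
  ))
  sel <- select_max_degree_subset(net, 2)
  expect_setequal(sel, c("A", "B"))
  deg <- setNames(net$components$degree, net$components$component_id)
  pairs <- utils::combn(names(deg), 2, simplify = FALSE)
  best <- max(vapply(pairs, function(p) sum(deg[p]), numeric(1)))
  expect_equal(sum(deg[sel]), best)
  expect_equal(best, 9)

  expect_equal(select_max_degree_subset(net, 0), character())
  expect_setequal(select_max_degree_subset(net, 4), c("A", "B", "C", "D"))
  expect_error(select_max_degree_subset(net, 5), "out of range")
})

test_that("ties in degree break by component id ascending", {
  net <- ct_from_sets(list(B = c("T1", "T2"), A = c("T3", "T4"),
                           C = "T5"))
  expect_equal(select_max_degree_subset(net, 1), "A")
})

test_that("a fixture meeting all goals exactly yields zero deviations", {
  # C_com = 10, C_tar = 10, C_overlap = 5:
  # goals: k + tar = 7, k = 4, k <= 4; top-4 induces {T1,T2,T3} -> all met
  sets <- list(
    C01 = c("T1", "T2", "T3"), C02 = c("T1", "T2"), C03 = c("T2", "T3"),
    C04 = c("T1", "T3"), C05 = c("T4", "T10"), C06 = "T5", C07 = "T6",
    C08 = "T7", C09 = "T8", C10 = "T9"
  )
  net <- ct_from_sets(sets)
  dg <- tibble::tibble(symbol = c("T1", "T2", "T3", "T4", "T5"),
                       relevance_score = 1, literature_count = 1L)
  sol <- solve_goal_program(net, dg)
  expect_equal(sol$c_com_sel, 4L)
  expect_equal(sol$c_tar_sel, 3L)
  expect_true(all(sol$deviations$d_minus[1:2] == 0))
  expect_equal(sol$deviations$d_plus[3], 0)
  expect_equal(sol$z, 0)
  brute <- brute_goal_program(net, dg)
  expect_equal(sol$c_com_sel, unname(brute["k"]))
  expect_equal(sol$c_tar_sel, unname(brute["tark"]))
  expect_equal(sol$deviations$d_minus[1], unname(brute["d1m"]))
  expect_equal(sol$deviations$d_minus[2], unname(brute["d2m"]))
  expect_equal(sol$deviations$d_plus[3], unname(brute["d3p"]))
})

test_that("induced-mode solutions equal full enumeration on random fixtures", {
  for (seed in 1:12) {
    n_comp <- sample(4:9, 1)
    net <- random_ct(n_comp, sample(5:10, 1), seed = seed * 13)
    dg <- random_disease(10, seed = seed * 13)
    sol <- solve_goal_program(net, dg)
    brute <- brute_goal_program(net, dg)
    expect_equal(sol$c_com_sel, unname(brute["k"]), info = paste("seed", seed))
    expect_equal(sol$c_tar_sel, unname(brute["tark"]))
    expect_equal(sol$deviations$d_minus[1], unname(brute["d1m"]))
    expect_equal(sol$deviations$d_minus[2], unname(brute["d2m"]))
    expect_equal(sol$deviations$d_plus[3], unname(brute["d3p"]))
  }
})

test_that("induced target counts are monotone and slackness holds per goal", {
  for (seed in 1:5) {
    net <- random_ct(8, 10, seed = seed)
    dg <- random_disease(10, seed = seed)
    sol <- solve_goal_program(net, dg)
    expect_true(all(diff(sol$candidates$c_tar_sel) >= 0))
    expect_true(all(sol$deviations$d_minus * sol$deviations$d_plus == 0))
    expect_true(all(sol$deviations$d_minus >= 0))
    expect_true(all(sol$deviations$d_plus >= 0))
  }
})

test_that("weighted priority mode reproduces preemptive choice when p1>>p2>>p3", {
  net <- random_ct(8, 10, seed = 42)
  dg <- random_disease(10, seed = 42)
  pre <- solve_goal_program(net, dg)
  wtd <- solve_goal_program(net, dg, priorities = c(1e6, 1e3, 1))
  expect_equal(wtd$c_com_sel, pre$c_com_sel)
  expect_equal(wtd$z, pre$z)
})

test_that("analytic mode frees C_tar' and satisfies the priority structure", {
  net <- random_ct(10, 10, seed = 3)
  dg <- random_disease(10, seed = 3)
  sol <- solve_goal_program(net, dg, mode = "analytic")
  # goal 2 saturated first: k >= ceil(0.8 * overlap) unless capped
  expect_gte(sol$c_com_sel, min(net$n_components,
                                ceiling(0.8 * sol$c_overlap)))
  expect_true(all(sol$deviations$d_minus * sol$deviations$d_plus == 0))
})

test_that("the FRS is the induced subgraph and its target side is C_tar'", {
  net <- ct_from_sets(list(C1 = c("A", "B", "C")))
  dg <- tibble::tibble(symbol = "A", relevance_score = 1,
                       literature_count = 1L)
  sol <- solve_goal_program(net, dg)
  frs <- build_frs(net, sol)
  expect_equal(frs$n_nodes, 4)
  expect_equal(frs$n_edges, 3)
  expect_equal(length(frs$effective_proteins), sol$c_tar_sel)

  for (seed in 1:5) {
    net <- random_ct(7, 9, seed = seed + 100)
    dg <- random_disease(9, seed = seed + 100)
    sol <- solve_goal_program(net, dg)
    frs <- build_frs(net, sol)
    expect_equal(length(frs$effective_proteins), sol$c_tar_sel)
    expect_equal(length(frs$components), sol$c_com_sel)
    expect_true(all(frs$edges$component_id %in% frs$components))
    expect_true(all(frs$edges$target_symbol %in% frs$effective_proteins))
  }
})

test_that("tidy and glance expose deviations and headline counts", {
  net <- random_ct(6, 8, seed = 9)
  dg <- random_disease(8, seed = 9)
  sol <- solve_goal_program(net, dg)
  td <- tidy(sol)
  expect_equal(td$goal,
               c("span_targets", "cover_shared", "limit_components"))
  gl <- glance(sol)
  expect_equal(gl$c_com_sel, sol$c_com_sel)
  expect_equal(gl$mode, "induced")
})
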
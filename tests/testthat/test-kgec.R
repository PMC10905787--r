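spec_items <- tibble::tibble(item = c("a", "b", "c"),
                             value = c(6, 10, 12), weight = c(1, 2, 3))

test_that("dynamic-programming oracle matches subset enumeration", {
  expect_equal(dp_knapsack(spec_items, 5)$V,
               exhaustive_knapsack(c(6, 10, 12), c(1, 2, 3), 5))
  expect_equal(dp_knapsack(spec_items, 5)$V, 22)
  expect_setequal(dp_knapsack(spec_items, 5)$selection, c("b", "c"))
  expect_equal(dp_knapsack(spec_items, 0)$V, 0)
  expect_equal(dp_knapsack(spec_items, 0)$selection, character())
  # all weights above capacity
  heavy <- tibble::tibble(item = "x", value = 5, weight = 9)
  expect_equal(dp_knapsack(heavy, 3)$V, 0)
  bad <- tibble::tibble(item = "x", value = 1, weight = 0.5)
  expect_error(dp_knapsack(bad, 3), "integer")
})

test_that("the GA solves the three-item instance and stays feasible", {
  res <- ga_knapsack(spec_items, 5, fitness = "sumvalue",
                     config = ga_config(seed = 2))
  expect_equal(res$V, 22)
  expect_lte(res$W, 5)
  one <- ga_knapsack(spec_items[1, ], 2, fitness = "sumvalue",
                     config = ga_config(seed = 1))
  expect_equal(one$V, 6)
  zero <- ga_knapsack(spec_items, 0, fitness = "sumvalue")
  expect_equal(sum(zero$x), 0)
})

test_that("GA runs are reproducible bit-for-bit under a fixed seed", {
  cfg <- ga_config(seed = 77, max_generations = 60)
  r1 <- ga_knapsack(spec_items, 4, fitness = "sumvalue", config = cfg)
  r2 <- ga_knapsack(spec_items, 4, fitness = "sumvalue", config = cfg)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$trace, r2$trace)
  r3 <- ga_knapsack(spec_items, 4, fitness = "sumvalue",
                    config = ga_config(seed = 78, max_generations = 60))
  expect_equal(r3$V, r1$V)  # same optimum even if the path differs
})

test_that("GA matches the exact optimum on random small instances", {
  hits <- 0
  n_draws <- 25
  for (i in seq_len(n_draws)) {
    set.seed(500 + i)
    n <- sample(5:12, 1)
    items <- tibble::tibble(item = sprintf("i%02d", 1:n),
                            value = sample(1:20, n, TRUE),
                            weight = sample(1:9, n, TRUE))
    C <- max(1, round(sum(items$weight) * 0.4))
    opt <- dp_knapsack(items, C)$V
    res <- ga_knapsack(items, C, fitness = "sumvalue",
                       config = ga_config(seed = i, max_generations = 120))
    expect_lte(res$V, opt)
    expect_lte(res$W, C)
    hits <- hits + (res$V == opt)
  }
  expect_gte(hits, ceiling(0.95 * n_draws))
})

test_that("greedy cover achieves full coverage and sane sizes", {
  sets <- list(a = c("P1", "P2", "P3"))
  expect_equal(greedy_cover(sets, c("P1", "P2", "P3")), "a")
  part <- list(a = c("P1", "P2", "P3"), b = c("P4", "P5", "P6"),
               c = c("P7", "P8", "P9"))
  expect_setequal(greedy_cover(part, unlist(part)), c("a", "b", "c"))
  expect_error(greedy_cover(sets, c("P1", "P99")), "P99")

  for (seed in 1:5) {
    set.seed(seed)
    universe <- sprintf("P%02d", 1:12)
    sets <- lapply(1:10, function(i) sample(universe, sample(2:6, 1)))
    names(sets) <- sprintf("i%02d", 1:10)
    if (!all(universe %in% unlist(sets))) next
    g <- greedy_cover(sets, universe)
    expect_true(all(universe %in% unlist(sets[g])))
    expect_gte(length(g), exhaustive_min_cover(sets, universe))
  }
})

test_that("coverage never decreases when an item is added", {
  frs <- gen_planted_frs(n_components = 15, n_effective = 40,
                         planted_cover_size = 3, seed = 5)
  ep <- frs$effective_proteins
  cov_of <- function(ids) {
    length(unique(unlist(frs$target_sets[ids]))) / length(ep)
  }
  set.seed(1)
  for (i in 1:10) {
    base <- sample(frs$components, sample(1:10, 1))
    extra <- sample(setdiff(frs$components, base), 1)
    expect_gte(cov_of(c(base, extra)), cov_of(base))
  }
})

test_that("KGEC selection covers a planted exact cover at its true size", {
  frs <- gen_planted_frs(n_components = 40, n_effective = 200,
                         planted_cover_size = 5, seed = 1)
  planted <- attr(frs, "planted")
  expect_length(planted$components, 5)
  res <- select_kgec(frs, config = ga_config(seed = 1))
  expect_equal(res$coverage, 1)
  expect_lte(length(res$components), 6)
  expect_lte(res$W, res$C)
  # single component covering everything -> KGEC of size one
  tiny <- new_frs(tibble::tibble(component_id = "X",
                                 target_symbol = c("P1", "P2")))
  one <- select_kgec(tiny, config = ga_config(seed = 1))
  expect_equal(one$components, "X")
  expect_equal(one$coverage, 1)
})

test_that("uncoverable effective proteins abort KGEC selection", {
  frs <- new_frs(tibble::tibble(component_id = "X", target_symbol = "P1"),
                 effective_proteins = c("P1", "P2"))
  expect_error(select_kgec(frs), "P2")
})

test_that("custom weights let capacity count something else than items", {
  frs <- gen_planted_frs(n_components = 10, n_effective = 30,
                         planted_cover_size = 2, seed = 8)
  w <- setNames(rep(2, 10), frs$components)
  res <- select_kgec(frs, config = ga_config(seed = 1), weights = w)
  expect_equal(res$coverage, 1)
  expect_equal(res$W, 2 * length(res$components))
})

test_that("tidy/glance report the selection table and headline numbers", {
  frs <- gen_planted_frs(n_components = 12, n_effective = 30,
                         planted_cover_size = 3, seed = 2)
  res <- select_kgec(frs, config = ga_config(seed = 4))
  td <- tidy(res)
  expect_equal(sum(td$selected), length(res$components))
  expect_false("targets" %in% names(td))
  gl <- glance(res)
  expect_equal(gl$coverage, res$coverage)
})
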
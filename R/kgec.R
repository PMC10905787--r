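#' Genetic algorithm configuration
#'
#' @param pop_size Population size (>= 2).
#' @param crossover_rate Probability that a selected pair undergoes
#'   single-point crossover.
#' @param mutation_rate Probability that a chromosome has one randomly chosen
#'   locus inverted.
#' @param max_generations Iteration cap.
#' @param elitism Number of best chromosomes carried unchanged into the next
#'   generation.
#' @param stagnation Generations without fitness improvement (at saturated
#'   capacity, `W = C`) after which the run stops.
#' @param seed Integer seed controlling every stochastic step.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100, crossover_rate = 0.8,
                      mutation_rate = 0.02, max_generations = 500,
                      elitism = 1, stagnation = 25, seed = 1) {
  stopifnot(pop_size >= 2, crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, max_generations >= 1,
            elitism >= 0, elitism < pop_size)
  structure(list(pop_size = as.integer(pop_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 max_generations = as.integer(max_generations),
                 elitism = as.integer(elitism),
                 stagnation = as.integer(stagnation),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Solve a 0/1 knapsack with a genetic algorithm
#'
#' Maximises either the summed item value (`fitness = "sumvalue"`, the
#' classical `max V = sum v_i x_i` objective) or the fraction of effective
#' proteins covered by the union of the selected items' target sets
#' (`fitness = "coverage"`), subject to `sum w_i x_i <= C`.
#'
#' The algorithm follows the standard genetic-knapsack recipe: binary
#' chromosomes of length `n`; random initial population; roulette-wheel
#' selection proportional to fitness (uniform when all fitnesses are zero);
#' single-point crossover at a random cut; one-locus bit-flip mutation per
#' chromosome; elitism. Chromosomes exceeding capacity are repaired by
#' dropping the selected item with the lowest value-per-weight ratio until
#' feasible, so roulette fitness stays non-negative and interpretable.
#' The run stops when full coverage is reached (coverage mode), when the
#' best chromosome saturates capacity (`W = C`) with no fitness improvement
#' for `stagnation` generations, or at `max_generations`.
#'
#' @param items Tibble with columns `item` (id), `value`, `weight`, and for
#'   coverage mode a list-column `targets` of protein identifiers.
#' @param capacity Knapsack capacity `C` (>= 0).
#' @param fitness `"sumvalue"` or `"coverage"`.
#' @param config A [ga_config()].
#' @param effective_proteins Character vector of proteins defining coverage
#'   (required for coverage mode).
#' @param init Optional 0/1 matrix (or single vector) of chromosomes used to
#'   seed the first rows of the initial population, e.g. a greedy solution.
#' @return An object of class `kgec_result`; see [select_kgec()].
#' @examples
#' items <- tibble::tibble(item = c("a", "b", "c"),
#'                         value = c(6, 10, 12), weight = c(1, 2, 3))
#' ga_knapsack(items, capacity = 5, fitness = "sumvalue")$V
#' @export
ga_knapsack <- function(items, capacity, fitness = c("coverage", "sumvalue"),
                        config = ga_config(), effective_proteins = NULL,
                        init = NULL) {
  fitness <- match.arg(fitness)
  stopifnot(is.data.frame(items), capacity >= 0,
            all(c("item", "value", "weight") %in% names(items)))
  n <- nrow(items)
  v <- as.numeric(items$value)
  w <- as.numeric(items$weight)
  stopifnot(all(v >= 0), all(w >= 0))
  ids <- as.character(items$item)

  memb <- NULL
  if (fitness == "coverage") {
    if (is.null(effective_proteins) || !"targets" %in% names(items)) {
      abort("coverage fitness needs `effective_proteins` and items$targets")
    }
    ep <- unique(effective_proteins)
    memb <- matrix(FALSE, nrow = n, ncol = length(ep),
                   dimnames = list(NULL, ep))
    for (i in seq_len(n)) {
      hit <- intersect(items$targets[[i]], ep)
      memb[i, hit] <- TRUE
    }
  }

  if (capacity == 0 || n == 0) {
    sel <- rep(0L, n)
    return(new_kgec_result(items, sel, capacity, memb, effective_proteins,
                           generations = 0L, trace = NULL,
                           seed = config$seed, fitness = fitness))
  }

  # drop order for repair: lowest value-per-weight first; among ties the
  # later item goes first so earlier ids are kept deterministically
  ratio <- ifelse(w > 0, v / w, Inf)
  drop_order <- order(ratio, -seq_len(n))

  repair <- function(pop) {
    load <- as.vector(pop %*% w)
    for (r in which(load > capacity)) {
      for (j in drop_order) {
        if (pop[r, j] == 1L) {
          pop[r, j] <- 0L
          load[r] <- load[r] - w[j]
          if (load[r] <= capacity) break
        }
      }
    }
    pop
  }

  eval_fit <- function(pop) {
    if (fitness == "sumvalue") as.vector(pop %*% v)
    else rowSums((pop %*% memb) > 0) / ncol(memb)
  }

  res <- with_seed(config$seed, {
    ps <- config$pop_size
    pop <- matrix(stats::rbinom(ps * n, 1L, 0.5), nrow = ps, ncol = n)
    if (!is.null(init)) {
      init <- matrix(as.integer(init), ncol = n)
      take <- min(nrow(init), ps)
      pop[seq_len(take), ] <- init[seq_len(take), , drop = FALSE]
    }
    pop <- repair(pop)

    best_chrom <- NULL
    best_fit <- -Inf
    best_gen <- 0L
    trace <- vector("list", config$max_generations)
    gen <- 0L
    for (gen in seq_len(config$max_generations)) {
      fit <- eval_fit(pop)
      gbest <- which.max(fit)
      if (fit[gbest] > best_fit) {
        best_fit <- fit[gbest]
        best_chrom <- pop[gbest, ]
        best_gen <- gen
      }
      best_w <- sum(best_chrom * w)
      trace[[gen]] <- c(gen, best_fit, best_w)
      if (fitness == "coverage" && best_fit >= 1) break
      if (best_w == capacity && gen - best_gen >= config$stagnation) break
      if (gen == config$max_generations) break

      # roulette-wheel selection
      probs <- if (all(fit <= 0)) rep(1 / ps, ps) else fit / sum(fit)
      parents <- pop[sample.int(ps, ps, replace = TRUE, prob = probs), ,
                     drop = FALSE]
      # single-point crossover on consecutive pairs
      if (n >= 2) {
        for (p in seq(1, ps - 1, by = 2)) {
          if (stats::runif(1) < config$crossover_rate) {
            cut <- sample.int(n - 1L, 1L)
            tail_idx <- (cut + 1L):n
            tmp <- parents[p, tail_idx]
            parents[p, tail_idx] <- parents[p + 1L, tail_idx]
            parents[p + 1L, tail_idx] <- tmp
          }
        }
      }
      # one-locus mutation per chromosome
      mut <- which(stats::runif(ps) < config$mutation_rate)
      for (r in mut) {
        loc <- sample.int(n, 1L)
        parents[r, loc] <- 1L - parents[r, loc]
      }
      parents <- repair(parents)
      # elitism: best chromosomes of the old generation replace the worst new
      if (config$elitism > 0) {
        elite <- pop[order(fit, decreasing = TRUE)[seq_len(config$elitism)], ,
                     drop = FALSE]
        newfit <- eval_fit(parents)
        worst <- order(newfit)[seq_len(config$elitism)]
        parents[worst, ] <- elite
      }
      pop <- parents
    }
    list(best = best_chrom, generations = gen,
         trace = do.call(rbind, trace[seq_len(gen)]))
  })

  trace <- tibble(generation = as.integer(res$trace[, 1]),
                  best_fitness = res$trace[, 2],
                  best_weight = res$trace[, 3])
  new_kgec_result(items, res$best, capacity, memb, effective_proteins,
                  generations = res$generations, trace = trace,
                  seed = config$seed, fitness = fitness)
}

new_kgec_result <- function(items, selection, capacity, memb,
                            effective_proteins, generations, trace, seed,
                            fitness) {
  selection <- as.integer(selection)
  sel <- selection == 1L
  coverage <- if (!is.null(memb) && ncol(memb) > 0) {
    if (any(sel)) sum(colSums(memb[sel, , drop = FALSE]) > 0) / ncol(memb)
    else 0
  } else NA_real_
  tab <- items %>%
    mutate(selected = sel,
           n_covered = if (!is.null(memb)) as.integer(rowSums(memb)) else
             NA_integer_)
  structure(list(
    selection = tab,
    components = as.character(items$item[sel]),
    x = selection,
    V = sum(items$value[sel]),
    W = sum(items$weight[sel]),
    C = capacity,
    coverage = coverage,
    generations_run = generations,
    trace = trace,
    seed = seed,
    fitness = fitness
  ), class = "kgec_result")
}

#' @method print kgec_result
#' @export
print.kgec_result <- function(x, ...) {
  cov <- if (is.na(x$coverage)) "" else
    sprintf(", coverage %.1f%%", 100 * x$coverage)
  cat(sprintf("KGEC: %d/%d items selected (V = %g, W = %g <= C = %g%s)\n",
              length(x$components), nrow(x$selection), x$V, x$W, x$C, cov))
  invisible(x)
}

#' @method tidy kgec_result
#' @export
tidy.kgec_result <- function(x, ...) {
  select(x$selection, -dplyr::any_of("targets"))
}

#' @method glance kgec_result
#' @export
glance.kgec_result <- function(x, ...) {
  tibble(n_selected = length(x$components), V = x$V, W = x$W, C = x$C,
         coverage = x$coverage, generations_run = x$generations_run,
         seed = x$seed, fitness = x$fitness)
}

#' Exact dynamic-programming knapsack oracle
#'
#' Classic DP over capacity for 0/1 knapsack with integer weights; optimal by
#' construction. Used as the independent validator for the genetic algorithm.
#'
#' @param items Tibble with columns `item`, `value`, `weight` (weights must
#'   be non-negative integers).
#' @param capacity Integer capacity.
#' @return A list with `V` (optimal value) and `selection` (character vector
#'   of selected item ids).
#' @export
dp_knapsack <- function(items, capacity) {
  v <- as.numeric(items$value)
  w <- items$weight
  if (any(w != as.integer(w)) || any(w < 0)) {
    abort("dp_knapsack requires non-negative integer weights")
  }
  w <- as.integer(w)
  capacity <- as.integer(capacity)
  n <- length(v)
  if (n == 0 || capacity == 0) return(list(V = 0, selection = character()))
  # best[c+1] = optimal value at capacity c; keep[i, c+1] = item i taken
  best <- numeric(capacity + 1)
  keep <- matrix(FALSE, nrow = n, ncol = capacity + 1)
  for (i in seq_len(n)) {
    if (w[i] > capacity) next
    cs <- seq(capacity, w[i])  # descending
    cand <- best[cs - w[i] + 1] + v[i]
    take <- cand > best[cs + 1]
    best[cs + 1][take] <- cand[take]
    keep[i, cs[take] + 1] <- TRUE
  }
  # backtrack
  sel <- logical(n)
  cc <- capacity
  for (i in rev(seq_len(n))) {
    if (keep[i, cc + 1]) {
      sel[i] <- TRUE
      cc <- cc - w[i]
    }
  }
  list(V = sum(v[sel]), selection = as.character(items$item[sel]))
}

#' Greedy set-cover baseline
#'
#' Standard greedy cover: repeatedly pick the item covering the most
#' still-uncovered effective proteins (ties by item id ascending) until all
#' are covered. Provides the starting capacity for [select_kgec()]'s outer
#' search and a size baseline for the GA.
#'
#' @param target_sets Named list mapping item id to its protein set.
#' @param effective_proteins Character vector to cover.
#' @return Character vector of selected item ids, in pick order.
#' @export
greedy_cover <- function(target_sets, effective_proteins) {
  uncovered <- unique(effective_proteins)
  reachable <- unique(unlist(target_sets))
  missing <- setdiff(uncovered, reachable)
  if (length(missing) > 0) {
    abort(paste0("effective proteins not coverable by any item: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) " ..." else ""))
  }
  ids <- sort(names(target_sets))
  picked <- character()
  while (length(uncovered) > 0) {
    gains <- vapply(ids, function(i) {
      length(intersect(target_sets[[i]], uncovered))
    }, integer(1))
    best <- ids[which.max(gains)]  # which.max: first max = smallest id
    picked <- c(picked, best)
    uncovered <- setdiff(uncovered, target_sets[[best]])
    ids <- setdiff(ids, best)
  }
  picked
}

#' Select the key group of effective components (KGEC)
#'
#' Runs the genetic knapsack over the FRS components to find a smallest-
#' capacity component group whose targets cover every effective protein.
#' Item values default to the number of effective proteins each component
#' targets and item weights default to 1, so the capacity `C` counts
#' components; both can be overridden (e.g. weight by molecular weight or
#' formula concentration).
#'
#' When `capacity` is not given, the outer search starts at the greedy-cover
#' size and walks downward to the smallest capacity at which the GA still
#' attains full coverage (walking upward instead if the GA cannot certify
#' the greedy size). By default the greedy-cover chromosome seeds the GA's
#' initial population (memetic seeding), so the search always starts from a
#' feasible full cover and the GA can only improve on the greedy baseline.
#'
#' @param frs An `frs` object.
#' @param config A [ga_config()]; each capacity probe derives its RNG seed
#'   from `config$seed` plus the capacity.
#' @param capacity Optional fixed capacity; skips the outer search.
#' @param values,weights Optional named numeric vectors (by component id)
#'   overriding the default item values/weights.
#' @param fitness Fitness mode passed to [ga_knapsack()]; coverage is the
#'   pipeline default.
#' @param seed_greedy Seed the initial population with the greedy cover
#'   (default `TRUE`).
#' @return A `kgec_result` with the selection table, value `V`, weight `W`,
#'   capacity `C`, effective-protein `coverage`, `generations_run`, the
#'   fitness `trace` and the `greedy_size` baseline (attribute).
#' @export
select_kgec <- function(frs, config = ga_config(), capacity = NULL,
                        values = NULL, weights = NULL,
                        fitness = "coverage", seed_greedy = TRUE) {
  stopifnot(inherits(frs, "frs"))
  ep <- frs$effective_proteins
  if (length(ep) == 0) abort("FRS has no effective proteins")
  sets <- purrr::map(frs$target_sets, ~ intersect(.x, ep))
  items <- tibble(
    item = frs$components,
    value = if (is.null(values)) lengths(sets)[frs$components]
            else unname(values[frs$components]),
    weight = if (is.null(weights)) rep(1, length(frs$components))
             else unname(weights[frs$components]),
    targets = unname(sets[frs$components])
  )
  greedy <- greedy_cover(sets, ep)  # errors if uncoverable
  greedy_chrom <- as.integer(items$item %in% greedy)
  greedy_w <- sum(items$weight[items$item %in% greedy])

  run_ga <- function(C) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + C)
    init <- if (seed_greedy && greedy_w <= C) greedy_chrom else NULL
    ga_knapsack(items, capacity = C, fitness = fitness, config = cfg,
                effective_proteins = ep, init = init)
  }

  if (!is.null(capacity)) {
    res <- run_ga(capacity)
  } else {
    C <- greedy_w
    res <- run_ga(C)
    if (!isTRUE(res$coverage >= 1)) {
      # walk upward until the GA certifies a full cover
      max_c <- sum(items$weight)
      while (!isTRUE(res$coverage >= 1) && C < max_c) {
        C <- C + 1
        res <- run_ga(C)
      }
      if (!isTRUE(res$coverage >= 1)) {
        abort("full effective-protein coverage unattainable")
      }
    } else {
      # walk downward while the GA still attains full coverage; a returned
      # selection of weight W certifies capacity W, so tighten C to W first
      repeat {
        res$C <- res$W
        if (res$W <= 1) break
        cand <- run_ga(res$W - 1)
        if (isTRUE(cand$coverage >= 1)) res <- cand else break
      }
    }
  }
  attr(res, "greedy_size") <- length(greedy)
  res
}
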
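# independent brute-force oracles, deliberately naive

# hypergeometric upper tail by direct combinatorial counting
hyper_tail_enum <- function(k, K, N, n) {
  if (k <= 0) return(1)
  kk <- k:min(K, n)
  kk <- kk[n - kk <= N - K]
  if (length(kk) == 0) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# step-up BH written from the definition
bh_enum <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive 0/1 knapsack over all subsets
exhaustive_knapsack <- function(v, w, C) {
  n <- length(v)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (sum(w[sel]) <= C) best <- max(best, sum(v[sel]))
  }
  best
}

# smallest full cover by exhaustive search (n <= 15)
exhaustive_min_cover <- function(sets, universe) {
  n <- length(sets)
  for (size in 1:n) {
    combos <- utils::combn(n, size, simplify = FALSE)
    for (cb in combos) {
      if (all(universe %in% unlist(sets[cb]))) return(size)
    }
  }
  Inf
}

# goal program solved by full enumeration: every k, every size-k subset
brute_goal_program <- function(net, disease_genes,
                               coefficients = c(0.7, 0.8, 0.4)) {
  a <- coefficients
  ids <- sort(net$components$component_id)
  deg <- setNames(net$components$degree, net$components$component_id)[ids]
  c_com <- net$n_components
  c_tar <- net$n_targets
  c_overlap <- length(intersect(net$targets,
                                toupper(trimws(disease_genes$symbol))))
  best <- NULL
  for (k in 1:c_com) {
    combos <- utils::combn(ids, k, simplify = FALSE)  # lexicographic order
    totals <- vapply(combos, function(s) sum(deg[s]), numeric(1))
    sel <- combos[[which.max(totals)]]  # first max = lexicographically first
    tark <- length(unique(unlist(net$target_sets[sel])))
    cand <- c(
      d1m = max(0, a[1] * c_tar - (k + tark)),
      d2m = max(0, a[2] * c_overlap - k),
      d3p = max(0, k - a[3] * c_com),
      k = k, tark = tark
    )
    if (is.null(best) ||
        cand["d1m"] < best["d1m"] ||
        (cand["d1m"] == best["d1m"] && cand["d2m"] < best["d2m"]) ||
        (cand["d1m"] == best["d1m"] && cand["d2m"] == best["d2m"] &&
         cand["d3p"] < best["d3p"])) {
      best <- cand
    }
  }
  best
}
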
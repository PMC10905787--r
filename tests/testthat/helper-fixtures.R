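# small in-code fixtures shared across test files

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a component row with all-passing defaults; override any property
comp_row <- function(component_id = "C1", mw = 300, hbd = 2L, hba = 4L,
                     clogp = 2, rotatable_bonds = 5L, herbs = "GZ",
                     name = component_id) {
  tibble::tibble(component_id = component_id, name = name, herbs = herbs,
                 mw = mw, hbd = hbd, hba = hba, clogp = clogp,
                 rotatable_bonds = rotatable_bonds)
}

# ct network from a named list of target sets (components all "active")
ct_from_sets <- function(sets) {
  comps <- dplyr::bind_rows(lapply(names(sets), comp_row))
  edges <- dplyr::bind_rows(lapply(names(sets), function(id) {
    tibble::tibble(component_id = id, target_symbol = sets[[id]])
  }))
  build_ct_network(comps, edges)
}

# random small C-T fixture for oracle comparisons
random_ct <- function(n_comp, n_tar, seed) {
  set.seed(seed)
  sets <- lapply(seq_len(n_comp), function(i) {
    sample(sprintf("T%02d", seq_len(n_tar)), sample(1:min(4, n_tar), 1))
  })
  names(sets) <- sprintf("C%02d", seq_len(n_comp))
  ct_from_sets(sets)
}

random_disease <- function(n_tar, seed, frac = 0.5) {
  set.seed(seed + 1000)
  syms <- sample(sprintf("T%02d", seq_len(n_tar)),
                 max(1, round(frac * n_tar)))
  tibble::tibble(symbol = syms, relevance_score = 1,
                 literature_count = 1L)
}
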
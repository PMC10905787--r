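#' Generate a synthetic scale-free PPI table
#'
#' Seeded preferential-attachment (Barabasi-Albert) graph over gene labels
#' `G0001..`, emulating the heavy-tailed degree structure of merged public
#' PPI databases. Confidence scores are uniform on \[0.4, 1\]. With
#' attachment `m`, the construction yields `1 + m * (n - 2)` edges for
#' `n > 2` (the second vertex can only attach once).
#'
#' @param n_genes Number of genes (>= 3).
#' @param attachment Edges added per new vertex (preferential attachment
#'   parameter, >= 1).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param source_db Source label stamped on every edge.
#' @return A PPI tibble in the [read_ppi()] layout.
#' @export
gen_ppi <- function(n_genes, attachment = 2, seed = 1,
                    source_db = "SYNPPI") {
  if (n_genes < 3) abort("n_genes must be at least 3")
  stopifnot(attachment >= 1)
  with_seed(seed, {
    g <- igraph::sample_pa(n_genes, power = 1, m = attachment,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("G%04d", seq_len(n_genes))
    el <- igraph::as_edgelist(g, names = TRUE)
    tibble(
      gene_a = pmin(el[, 1], el[, 2]),
      gene_b = pmax(el[, 1], el[, 2]),
      confidence = round(runif(nrow(el), 0.4, 1), 3),
      source_db = source_db
    ) %>% arrange(gene_a, gene_b)
  })
}

#' Generate a synthetic disease-gene table
#'
#' Samples disease genes from the PPI node universe, with a fraction of
#' off-network symbols to exercise mapping loss (mirroring how curated
#' disease lists only partly map onto a PPI). Relevance scores are
#' log-normal; literature counts are `1 + Poisson` so every curated gene
#' carries at least one reference.
#'
#' @param ppi PPI tibble (defines the on-network gene universe).
#' @param n_genes Number of disease genes to emit.
#' @param off_network_fraction Fraction of symbols absent from the PPI
#'   (default 0.15).
#' @param score_meanlog,score_sdlog Log-normal parameters of the relevance
#'   score.
#' @param lit_lambda Poisson rate of the literature count minus one.
#' @param seed Integer seed.
#' @return A disease-gene tibble in the [read_disease_genes()] layout.
#' @export
gen_disease_genes <- function(ppi, n_genes, off_network_fraction = 0.15,
                              score_meanlog = 1, score_sdlog = 0.75,
                              lit_lambda = 4, seed = 1) {
  pool <- sort(unique(c(ppi$gene_a, ppi$gene_b)))
  n_off <- round(n_genes * off_network_fraction)
  n_on <- n_genes - n_off
  if (n_on > length(pool)) {
    abort("not enough PPI genes to sample the on-network fraction")
  }
  with_seed(seed, {
    syms <- c(sample(pool, n_on),
              sprintf("OFFG%04d", seq_len(n_off)))
    tibble(
      symbol = syms,
      relevance_score = round(rlnorm(n_genes, score_meanlog, score_sdlog), 3),
      literature_count = 1L + rpois(n_genes, lit_lambda)
    ) %>% arrange(symbol)
  })
}

#' Generate a synthetic component property table
#'
#' Draws physicochemical properties so that each Lipinski rule fails
#' independently with a stated probability; with the default per-rule
#' failure probability of 0.07 about 70% of components pass all five rules,
#' the active fraction typical of herbal-formula screens. Each component
#' belongs to one herb, with a 15% chance of a second herb label.
#'
#' @param n_components Number of components.
#' @param rule_fail_prob Per-rule probability of a violating draw.
#' @param herbs Herb label pool.
#' @param seed Integer seed.
#' @param id_prefix Component id prefix.
#' @return A component tibble in the [read_components()] layout.
#' @export
gen_components <- function(n_components, rule_fail_prob = 0.07,
                           herbs = c("GZ", "BZ", "ZX", "FL", "ZL"),
                           seed = 1, id_prefix = "SYNC") {
  stopifnot(n_components >= 1, rule_fail_prob >= 0, rule_fail_prob <= 1)
  with_seed(seed, {
    n <- n_components
    fail <- function() runif(n) < rule_fail_prob
    mw <- ifelse(fail(), runif(n, 500, 800), runif(n, 120, 480))
    hbd <- ifelse(fail(), sample(6:10, n, TRUE), sample(0:5, n, TRUE))
    hba <- ifelse(fail(), sample(10:15, n, TRUE), sample(0:9, n, TRUE))
    clogp <- ifelse(fail(), runif(n, 5.5, 9), runif(n, -2, 5))
    rot <- ifelse(fail(), sample(11:20, n, TRUE), sample(0:10, n, TRUE))
    herb1 <- sample(herbs, n, TRUE)
    herb2 <- ifelse(runif(n) < 0.15,
                    sample(herbs, n, TRUE), NA_character_)
    herb_lab <- ifelse(is.na(herb2) | herb2 == herb1, herb1,
                       paste(herb1, herb2, sep = ";"))
    tibble(
      component_id = sprintf("%s%03d", id_prefix, seq_len(n)),
      name = sprintf("synthetic compound %03d", seq_len(n)),
      herbs = herb_lab,
      mw = round(mw, 2),
      hbd = as.integer(hbd),
      hba = as.integer(hba),
      clogp = round(clogp, 2),
      rotatable_bonds = as.integer(rot),
      concentration_mg_g = round(rlnorm(n, -2, 1), 4)
    )
  })
}

# truncated discrete power-law degree sampler (xmin = 1)
rpowerlaw_degree <- function(n, exponent, max_degree) {
  u <- runif(n)
  d <- floor((1 - u)^(-1 / (exponent - 1)))
  pmin(pmax(d, 1), max_degree)
}

#' Generate a synthetic compound-target edge table
#'
#' Assigns each component a heavy-tailed (power-law) number of targets drawn
#' from a gene pool. Optionally plants an exact cover: `planted_cover_size`
#' components whose target sets partition a designated protein set (sizes
#' differing by at most one when not divisible), giving downstream selection
#' stages an unambiguous ground truth.
#'
#' @param components Component tibble (ids are used; planted components are
#'   taken from the head of the table, preferring rows that pass the
#'   Lipinski screen so the planted signal survives ADME filtering).
#' @param targets Character vector: the target gene pool.
#' @param planted_cover_size Number of planted cover components (0 = none).
#' @param planted_protein_count Size of the planted protein set (sampled
#'   from `targets`).
#' @param degree_exponent Power-law exponent of decoy degrees.
#' @param max_degree Decoy degree cap.
#' @param seed Integer seed.
#' @return A list with `edges` (C-T tibble) and `planted`
#'   (list of `components`, `proteins`; `NULL` when nothing is planted).
#' @export
gen_ct <- function(components, targets, planted_cover_size = 0,
                   planted_protein_count = 0, degree_exponent = 2.5,
                   max_degree = 30, seed = 1) {
  stopifnot(planted_cover_size <= nrow(components),
            planted_protein_count <= length(targets))
  with_seed(seed, {
    ids <- components$component_id
    planted <- NULL
    edges <- list()
    if (planted_cover_size > 0) {
      if (planted_protein_count < planted_cover_size) {
        abort("planted_protein_count must be >= planted_cover_size")
      }
      ok <- lipinski_verdict(components, strict = TRUE)$passed
      cand <- c(ids[ok], ids[!ok])  # prefer screen-passing carriers
      pc <- cand[seq_len(planted_cover_size)]
      pp <- sample(targets, planted_protein_count)
      blocks <- split(pp, rep(seq_len(planted_cover_size), length.out =
                                length(pp)))
      edges <- purrr::map2(pc, blocks, ~ tibble(component_id = .x,
                                                target_symbol = .y))
      planted <- list(components = sort(pc), proteins = sort(pp))
    } else {
      pc <- character()
    }
    decoys <- setdiff(ids, pc)
    deg <- rpowerlaw_degree(length(decoys), degree_exponent,
                            min(max_degree, length(targets)))
    decoy_edges <- purrr::map2(decoys, deg, function(id, d) {
      tibble(component_id = id, target_symbol = sample(targets, d))
    })
    out <- bind_rows(c(edges, decoy_edges)) %>%
      distinct(component_id, target_symbol) %>%
      arrange(component_id, target_symbol)
    list(edges = out, planted = planted)
  })
}

#' Generate synthetic gene-set annotations
#'
#' Random decoy terms over a gene pool, plus optional planted terms drawn
#' from a designated gene subset so that a query containing that subset is
#' guaranteed to be enrichable.
#'
#' @param genes Character vector: the annotation gene universe.
#' @param n_terms Number of decoy terms.
#' @param term_size Two-element range of decoy term sizes.
#' @param planted_genes Optional character vector the planted terms draw
#'   from.
#' @param n_planted Number of planted terms.
#' @param planted_size Genes per planted term (drawn from `planted_genes`).
#' @param seed Integer seed.
#' @return An annotation tibble in the [read_gmt()] layout.
#' @export
gen_annotations <- function(genes, n_terms = 30, term_size = c(10, 40),
                            planted_genes = NULL, n_planted = 0,
                            planted_size = 20, seed = 1) {
  with_seed(seed, {
    decoys <- purrr::map(seq_len(n_terms), function(i) {
      sz <- sample(seq(term_size[1], term_size[2]), 1)
      sort(sample(genes, min(sz, length(genes))))
    })
    planted <- if (n_planted > 0) {
      stopifnot(!is.null(planted_genes))
      purrr::map(seq_len(n_planted), function(i) {
        sort(sample(planted_genes, min(planted_size, length(planted_genes))))
      })
    } else list()
    tibble(
      term_id = c(sprintf("PLANT%02d", seq_along(planted)),
                  sprintf("TERM%03d", seq_len(n_terms))),
      term_name = c(sprintf("planted term %d", seq_along(planted)),
                    sprintf("decoy term %d", seq_len(n_terms))),
      genes = c(planted, decoys)
    )
  })
}

#' Generate a synthetic FRS with a planted exact cover
#'
#' Builds a function response space directly: `planted_cover_size` components
#' whose disjoint target sets exactly partition the effective-protein set,
#' plus decoy components with heavy-tailed target counts drawn from the same
#' proteins. The planted components are the unique minimum full cover
#' whenever the decoy degree cap stays below the planted block size.
#'
#' @param n_components Total components (planted + decoys).
#' @param n_effective Number of effective proteins.
#' @param planted_cover_size Planted cover size `m`.
#' @param degree_exponent,max_degree Decoy degree distribution.
#' @param seed Integer seed.
#' @return An `frs` object; the planted ground truth is in
#'   `attr(x, "planted")`.
#' @export
gen_planted_frs <- function(n_components = 40, n_effective = 200,
                            planted_cover_size = 5, degree_exponent = 2.5,
                            max_degree = 30, seed = 1) {
  stopifnot(planted_cover_size >= 1,
            planted_cover_size <= n_components)
  proteins <- sprintf("EP%04d", seq_len(n_effective))
  comps <- tibble(component_id = sprintf("FRSC%03d", seq_len(n_components)),
                  name = "synthetic", herbs = "GZ",
                  mw = 300, hbd = 2L, hba = 4L, clogp = 2,
                  rotatable_bonds = 5L)
  ct <- gen_ct(comps, proteins,
               planted_cover_size = planted_cover_size,
               planted_protein_count = n_effective,
               degree_exponent = degree_exponent,
               max_degree = max_degree, seed = seed)
  frs <- new_frs(ct$edges, effective_proteins = proteins)
  attr(frs, "planted") <- ct$planted
  frs
}

#' Write a complete synthetic input bundle
#'
#' Generates a mutually consistent set of pipeline inputs (PPI, disease
#' genes, components, C-T edges, annotations) with a planted component cover
#' and planted enriched terms, writes them in the exact formats the readers
#' consume, and emits a manifest JSON describing the bundle.
#'
#' By default the planted protein set spans the entire target pool, so the
#' planted components form an exact cover of whatever effective-protein set
#' the downstream goal program induces; end-to-end recovery of the planted
#' cover is then well defined. Setting `n_targets > planted_protein_count`
#' adds decoy-only targets and breaks that guarantee deliberately.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param n_genes,n_disease_genes,n_components,n_targets Problem sizes.
#' @param planted_cover_size,planted_protein_count Planted cover shape.
#' @param rule_fail_prob Per-rule Lipinski failure probability.
#' @return Invisibly, the manifest as a list (`paths`, `seed`, `params`,
#'   `planted`).
#' @export
make_fixture <- function(dir, seed = 1, n_genes = 300, n_disease_genes = 120,
                         n_components = 60, n_targets = 60,
                         planted_cover_size = 5, planted_protein_count = 60,
                         rule_fail_prob = 0.07) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ppi <- gen_ppi(n_genes, seed = seed)
  dgenes <- gen_disease_genes(ppi, n_disease_genes, seed = seed + 1)
  comps <- gen_components(n_components, rule_fail_prob = rule_fail_prob,
                          seed = seed + 2)
  pool <- sort(unique(c(ppi$gene_a, ppi$gene_b)))
  target_pool <- sort(sample_targets(pool, dgenes$symbol, n_targets,
                                     seed + 3))
  ct <- gen_ct(comps, target_pool,
               planted_cover_size = planted_cover_size,
               planted_protein_count = planted_protein_count,
               seed = seed + 4)
  ann <- gen_annotations(pool, n_terms = 30,
                         planted_genes = ct$planted$proteins %||% target_pool,
                         n_planted = 3, planted_size = 20, seed = seed + 5)

  paths <- list(
    ppi = file.path(dir, "ppi.tsv"),
    disease_genes = file.path(dir, "disease_genes.tsv"),
    components = file.path(dir, "components.csv"),
    ct_edges = file.path(dir, "ct_edges.tsv"),
    gmt = file.path(dir, "annotations.gmt")
  )
  readr::write_tsv(rename(ppi, source = source_db), paths$ppi,
                   progress = FALSE)
  readr::write_tsv(dgenes, paths$disease_genes, progress = FALSE)
  readr::write_csv(comps, paths$components, progress = FALSE)
  readr::write_tsv(ct$edges, paths$ct_edges, progress = FALSE)
  write_gmt(ann, paths$gmt)

  manifest <- list(seed = seed,
                   params = list(n_genes = n_genes,
                                 n_disease_genes = n_disease_genes,
                                 n_components = n_components,
                                 n_targets = n_targets,
                                 planted_cover_size = planted_cover_size,
                                 planted_protein_count =
                                   planted_protein_count,
                                 rule_fail_prob = rule_fail_prob),
                   planted = ct$planted,
                   paths = paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# targets biased toward disease genes so C-T targets overlap pathogenic
# genes (C_overlap > 0 downstream)
sample_targets <- function(pool, disease_symbols, n_targets, seed) {
  with_seed(seed, {
    on_disease <- intersect(pool, disease_symbols)
    n_dis <- min(length(on_disease), ceiling(n_targets / 2))
    rest <- setdiff(pool, on_disease)
    c(sample(on_disease, n_dis),
      sample(rest, min(n_targets - n_dis, length(rest))))
  })
}

#' Write gene sets in GMT format
#'
#' @param annotations Annotation tibble (`term_id`, `term_name`, list-column
#'   `genes`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  lines <- purrr::pmap_chr(annotations, function(term_id, term_name, genes) {
    paste(c(term_id, term_name, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
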
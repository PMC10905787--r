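#' Default pipeline configuration
#'
#' Builds a validated run configuration. All elements can be supplied via a
#' YAML file ([read_run_config()]) or programmatically; unspecified fields
#' take these defaults.
#'
#' @param ppi Character vector of PPI file paths.
#' @param disease_genes,components,ct_edges Input file paths.
#' @param gmt Optional GMT path; enables the enrichment/coverage stage.
#' @param out_dir Output directory.
#' @param min_confidence PPI confidence threshold (see [read_ppi()]).
#' @param strict_screen Strict Lipinski mode (see [screen_components()]).
#' @param keep_isolates Keep isolated genes in the weighted network.
#' @param coefficients Goal-program coefficients `c(a1, a2, a3)`.
#' @param priorities `"preemptive"` or three numeric weights.
#' @param ga A [ga_config()]; its seed is overridden by `seed`.
#' @param alpha,p_on Enrichment significance cutoff and which p-value it
#'   applies to (`"raw"` or `"adjusted"`).
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ppi, disease_genes, components, ct_edges,
                       gmt = NULL, out_dir = "netpharm_out",
                       min_confidence = 0.7, strict_screen = TRUE,
                       keep_isolates = FALSE,
                       coefficients = c(0.70, 0.80, 0.40),
                       priorities = "preemptive",
                       ga = ga_config(), alpha = 0.05, p_on = "raw",
                       seed = 1) {
  cfg <- list(ppi = ppi, disease_genes = disease_genes,
              components = components, ct_edges = ct_edges, gmt = gmt,
              out_dir = out_dir, min_confidence = min_confidence,
              strict_screen = strict_screen, keep_isolates = keep_isolates,
              coefficients = coefficients, priorities = priorities,
              ga = ga, alpha = alpha, p_on = p_on, seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  for (f in c(cfg$ppi, cfg$disease_genes, cfg$components, cfg$ct_edges,
              cfg$gmt)) {
    if (!file.exists(f)) abort(paste0("input file does not exist: ", f))
  }
  stopifnot(length(cfg$coefficients) == 3,
            all(cfg$coefficients > 0), all(cfg$coefficients <= 1),
            cfg$alpha > 0, cfg$alpha < 1)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [run_config()]; `ga` may be a
#' mapping of [ga_config()] fields. Relative input paths are resolved
#' against the YAML file's directory.
#'
#' @param path Path to a YAML configuration.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  ga <- if (!is.null(y$ga)) do.call(ga_config, y$ga) else ga_config()
  run_config(
    ppi = rel(unlist(y$ppi)),
    disease_genes = rel(y$disease_genes),
    components = rel(y$components),
    ct_edges = rel(y$ct_edges),
    gmt = rel(y$gmt),
    out_dir = y$out_dir %||% "netpharm_out",
    min_confidence = y$min_confidence %||% 0.7,
    strict_screen = y$strict_screen %||% TRUE,
    keep_isolates = y$keep_isolates %||% FALSE,
    coefficients = unlist(y$coefficients) %||% c(0.70, 0.80, 0.40),
    priorities = y$priorities %||% "preemptive",
    ga = ga, alpha = y$alpha %||% 0.05, p_on = y$p_on %||% "raw",
    seed = y$seed %||% 1
  )
}

#' Run the full network-pharmacology pipeline
#'
#' Executes every stage in order — Lipinski screen, weighted disease-gene
#' network, C-T network, goal program + FRS, genetic-knapsack KGEC, and
#' (when a GMT is configured) enrichment of the KGEC targets against the
#' enrichment of the CAP genes (targets shared with the disease genes) with
#' the pathway-coverage statistic. Stage outputs are written to
#' `cfg$out_dir` as plain-text tables/graphs plus a `manifest.json` with the
#' config snapshot, seeds, per-file MD5 checksums and timings. Outputs are
#' pure functions of (inputs, config, seed): re-running an identical config
#' reproduces byte-identical stage outputs.
#'
#' @param cfg A `run_config` (or a path to a YAML config).
#' @return A list of class `netpharm_run` holding every stage result
#'   (`screen`, `gene_network`, `ct_network`, `ct_stats`, `goal_program`,
#'   `frs`, `kgec`, optional `enrichment`, `coverage`) and the `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  out <- function(name) file.path(cfg$out_dir, name)

  ppi <- read_ppi(cfg$ppi, min_confidence = cfg$min_confidence)
  dgenes <- read_disease_genes(cfg$disease_genes)
  comps <- read_components(cfg$components)
  ct_edges <- read_ct_edges(cfg$ct_edges)

  screen <- screen_components(comps, strict = cfg$strict_screen)
  readr::write_tsv(screen$report, out("screen_report.tsv"), progress = FALSE)
  readr::write_tsv(screen$by_herb, out("screen_by_herb.tsv"),
                   progress = FALSE)
  readr::write_csv(screen$active, out("active_components.csv"),
                   progress = FALSE)

  gnet <- build_weighted_network(ppi, dgenes,
                                 keep_isolates = cfg$keep_isolates)
  readr::write_tsv(gnet$nodes, out("gene_network_nodes.tsv"),
                   progress = FALSE)
  write_network(gnet, out("gene_network.graphml"), format = "graphml")

  ctnet <- build_ct_network(screen$active, ct_edges)
  stats <- ct_statistics(ctnet)
  readr::write_tsv(stats$component_degrees, out("component_degrees.tsv"),
                   progress = FALSE)
  readr::write_tsv(stats$target_degrees, out("target_degrees.tsv"),
                   progress = FALSE)
  jsonlite::write_json(as.list(stats$summary), out("ct_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  gp <- solve_goal_program(ctnet, dgenes, coefficients = cfg$coefficients,
                           priorities = cfg$priorities)
  jsonlite::write_json(
    list(c_com_sel = gp$c_com_sel, c_tar_sel = gp$c_tar_sel, z = gp$z,
         c_overlap = gp$c_overlap,
         deviations = gp$deviations),
    out("goal_program.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  frs <- build_frs(ctnet, gp)
  readr::write_tsv(tibble(component_id = frs$components),
                   out("frs_components.tsv"), progress = FALSE)
  readr::write_tsv(tibble(symbol = frs$effective_proteins),
                   out("effective_proteins.tsv"), progress = FALSE)
  write_network(frs, out("frs.sif"), format = "sif")

  ga <- cfg$ga
  ga$seed <- cfg$seed
  kgec <- select_kgec(frs, config = ga)
  readr::write_tsv(tidy(kgec) %>% filter(selected), out("kgec.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    c(as.list(glance(kgec)), list(components = kgec$components)),
    out("kgec_run.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  enrichment <- NULL
  coverage <- NULL
  if (!is.null(cfg$gmt)) {
    ann <- read_gmt(cfg$gmt)
    kgec_targets <- unique(unlist(frs$target_sets[kgec$components]))
    cap <- intersect(ctnet$targets, norm_symbol(dgenes$symbol))
    enr_kgec <- hypergeom_enrich(kgec_targets, ann)
    readr::write_tsv(enr_kgec, out("enrichment_kgec.tsv"), progress = FALSE)
    enrichment <- enr_kgec
    if (length(intersect(cap, unique(unlist(ann$genes)))) > 0) {
      enr_cap <- hypergeom_enrich(cap, ann)
      readr::write_tsv(enr_cap, out("enrichment_cap.tsv"), progress = FALSE)
      coverage <- pathway_coverage(enr_kgec, enr_cap, alpha = cfg$alpha,
                                   on = cfg$p_on)
      jsonlite::write_json(
        list(n_reference = coverage$n_reference, n_query = coverage$n_query,
             n_shared = coverage$n_shared,
             coverage_fraction = coverage$coverage_fraction),
        out("coverage.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    config = cfg[setdiff(names(cfg), "ga")],
    ga = unclass(cfg$ga),
    seed = cfg$seed,
    outputs = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files))),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  structure(list(screen = screen, gene_network = gnet, ct_network = ctnet,
                 ct_stats = stats, goal_program = gp, frs = frs,
                 kgec = kgec, enrichment = enrichment, coverage = coverage,
                 manifest = manifest),
            class = "netpharm_run")
}

#' @method print netpharm_run
#' @export
print.netpharm_run <- function(x, ...) {
  cat("netpharm pipeline run\n")
  print(x$screen)
  print(x$ct_network)
  print(x$goal_program)
  print(x$frs)
  print(x$kgec)
  if (!is.null(x$coverage)) {
    cat(sprintf("Pathway coverage: %.2f%% of reference terms recovered\n",
                100 * x$coverage$coverage_fraction))
  }
  invisible(x)
}
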
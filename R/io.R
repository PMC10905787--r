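#' Read and merge protein-protein interaction tables
#'
#' Loads one or more PPI edge files and merges them into a single undirected
#' edge table. Each file is either a headered TSV with columns `gene_a`,
#' `gene_b` and optionally `confidence` and `source`, or a SIF file
#' (`A <relation> B`, whitespace- or tab-delimited). Edges present in several
#' files (in either orientation) collapse to one record whose `source_db`
#' field is the `;`-joined, sorted union of source labels and whose
#' `confidence` is the maximum reported score. Self-loops are dropped with a
#' warning. Gene symbols are uppercased and whitespace-trimmed.
#'
#' @param paths Character vector of file paths (TSV or SIF).
#' @param min_confidence Minimum confidence score kept when a file carries a
#'   score column; edges without a score are always kept. Default 0.7
#'   (STRING-style medium-high confidence). Use `NULL` to disable filtering.
#' @param default_source Source label used for files without a source column;
#'   defaults to the file's base name.
#'
#' @return A tibble with columns `gene_a`, `gene_b`, `confidence` (NA when the
#'   input had none) and `source_db`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_a\tgene_b\tconfidence", "tp53\tMDM2\t0.95"), f)
#' read_ppi(f)
#' @export
read_ppi <- function(paths, min_confidence = 0.7, default_source = NULL) {
  stopifnot(length(paths) >= 1)
  recs <- purrr::map(paths, function(path) {
    if (!file.exists(path)) {
      abort(paste0("PPI file not found: ", path))
    }
    src_default <- default_source %||% tools::file_path_sans_ext(basename(path))
    tab <- read_one_ppi(path, src_default)
    if (!is.null(min_confidence) && any(!is.na(tab$confidence))) {
      tab <- filter(tab, is.na(confidence) | confidence >= min_confidence)
    }
    tab
  })
  edges <- bind_rows(recs) %>%
    mutate(gene_a = norm_symbol(gene_a), gene_b = norm_symbol(gene_b))
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical undirected orientation, then merge duplicates
  edges %>%
    mutate(
      a = pmin(gene_a, gene_b),
      b = pmax(gene_a, gene_b)
    ) %>%
    group_by(a, b) %>%
    summarise(
      confidence = if (all(is.na(confidence))) NA_real_ else
        max(confidence, na.rm = TRUE),
      source_db = paste(sort(unique(unlist(
        strsplit(source_db, ";", fixed = TRUE)
      ))), collapse = ";"),
      .groups = "drop"
    ) %>%
    rename(gene_a = a, gene_b = b) %>%
    arrange(gene_a, gene_b)
}

read_one_ppi <- function(path, src_default) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first) && grepl("gene_a", first, fixed = TRUE)) {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    for (col in c("gene_a", "gene_b")) {
      if (!col %in% names(tab)) {
        abort(paste0("PPI file ", path, " is missing column '", col, "'"))
      }
    }
    tibble(
      gene_a = as.character(tab$gene_a),
      gene_b = as.character(tab$gene_b),
      confidence = if ("confidence" %in% names(tab))
        as.numeric(tab$confidence) else NA_real_,
      source_db = if ("source" %in% names(tab))
        as.character(tab$source) else src_default
    )
  } else {
    # SIF: "A relation B [B2 ...]"; blank lines ignored
    lines <- readLines(path)
    lines <- lines[nzchar(stringr::str_trim(lines))]
    if (length(lines) == 0) {
      return(tibble(gene_a = character(), gene_b = character(),
                    confidence = numeric(), source_db = character()))
    }
    parts <- strsplit(lines, "[\t ]+")
    bad <- which(lengths(parts) < 3)
    if (length(bad) > 0) {
      abort(paste0("SIF line ", bad[1], " in ", path,
                   " has fewer than 3 fields"))
    }
    purrr::map_df(parts, function(f) {
      tibble(gene_a = f[1], gene_b = f[-(1:2)],
             confidence = NA_real_, source_db = src_default)
    })
  }
}

#' Read a disease-gene table
#'
#' Loads a TSV of disease-associated genes with GeneCards-style relevance
#' scores and literature counts. Rows duplicated by symbol are merged keeping
#' the maximum relevance score and summing literature counts (conservative
#' weight, additive evidence).
#'
#' @param path Path to a TSV with columns `symbol`, `relevance_score`,
#'   `literature_count`.
#' @return A tibble with one row per unique gene symbol.
#' @export
read_disease_genes <- function(path) {
  if (!file.exists(path)) abort(paste0("disease-gene file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) {
    warn(paste0("disease-gene file is empty: ", path))
    return(tibble(symbol = character(), relevance_score = numeric(),
                  literature_count = integer()))
  }
  for (col in c("symbol", "relevance_score", "literature_count")) {
    if (!col %in% names(tab)) {
      abort(paste0("disease-gene file is missing column '", col, "'"))
    }
  }
  if (any(tab$relevance_score < 0, na.rm = TRUE)) {
    abort("negative relevance_score in disease-gene file")
  }
  if (any(!is.finite(tab$relevance_score))) {
    abort("non-finite relevance_score in disease-gene file")
  }
  tab %>%
    mutate(symbol = norm_symbol(symbol)) %>%
    group_by(symbol) %>%
    summarise(
      relevance_score = max(relevance_score),
      literature_count = as.integer(sum(literature_count)),
      .groups = "drop"
    ) %>%
    arrange(symbol)
}

#' Read a component property table
#'
#' Loads a CSV of formula components with the physicochemical properties used
#' by the Lipinski screen. Missing property values are loaded as `NA` and
#' flagged at screening time rather than dropped here.
#'
#' @param path Path to a CSV with columns `component_id`, `name`, `herbs`
#'   (`;`-joined herb labels), `mw`, `hbd`, `hba`, `clogp`, `rotatable_bonds`
#'   and optionally `concentration_mg_g`.
#' @return A tibble, one row per component.
#' @export
read_components <- function(path) {
  if (!file.exists(path)) abort(paste0("component file not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("component_id", "name", "herbs", "mw", "hbd", "hba", "clogp",
            "rotatable_bonds")
  for (col in need) {
    if (!col %in% names(tab)) {
      abort(paste0("component file is missing column '", col, "'"))
    }
  }
  if (!"concentration_mg_g" %in% names(tab)) {
    tab$concentration_mg_g <- NA_real_
  }
  if (any(!is.na(tab$mw) & tab$mw <= 0)) {
    abort("component molecular weight must be positive")
  }
  tab %>%
    mutate(
      component_id = stringr::str_trim(component_id),
      across(c(mw, clogp, concentration_mg_g), as.numeric),
      across(c(hbd, hba, rotatable_bonds), as.integer)
    ) %>%
    distinct(component_id, .keep_all = TRUE) %>%
    arrange(component_id)
}

#' Read a compound-target edge table
#'
#' @param path Path to a TSV with columns `component_id`, `target_symbol`.
#'   Duplicate pairs collapse to a single edge; target symbols are normalized.
#' @return A tibble of unique component-target pairs.
#' @export
read_ct_edges <- function(path) {
  if (!file.exists(path)) abort(paste0("C-T edge file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("component_id", "target_symbol")) {
    if (!col %in% names(tab)) {
      abort(paste0("C-T edge file is missing column '", col, "'"))
    }
  }
  tab %>%
    mutate(component_id = stringr::str_trim(component_id),
           target_symbol = norm_symbol(target_symbol)) %>%
    distinct(component_id, target_symbol) %>%
    arrange(component_id, target_symbol)
}

#' Read gene sets in GMT format
#'
#' @param path Path to a standard GMT file: one term per line,
#'   tab-separated as `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return A tibble with columns `term_id`, `term_name` and a list-column
#'   `genes` of normalized gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(paste0("GMT line ", bad[1], " has fewer than 3 fields"))
  }
  sets <- tibble(
    term_id = purrr::map_chr(fields, 1),
    term_name = purrr::map_chr(fields, 2),
    genes = purrr::map(fields, ~ unique(norm_symbol(.x[-(1:2)])))
  )
  if (anyDuplicated(sets$term_id)) {
    abort("duplicate term_id in GMT file")
  }
  sets
}

#' Export a network to SIF, GraphML or TSV
#'
#' Writes an [igraph][igraph::igraph-package] graph (or any netpharm network
#' object convertible with [as_igraph()]) to a plain-text graph format.
#' GraphML preserves node attributes (`type`, `weight`) on round trip; SIF and
#' TSV carry the edge list only.
#'
#' @param graph An igraph object or a netpharm network object.
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @param relation Interaction label used in SIF output.
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
write_network <- function(graph, path, format = c("sif", "graphml", "tsv"),
                          relation = "interacts") {
  format <- match.arg(format)
  g <- as_igraph(graph)
  el <- igraph::as_edgelist(g, names = TRUE)
  switch(format,
    sif = {
      lines <- if (nrow(el) == 0) character() else
        paste(el[, 1], relation, el[, 2])
      writeLines(lines, path)
    },
    tsv = {
      tab <- tibble(node_a = as.character(el[, 1]),
                    node_b = as.character(el[, 2]))
      readr::write_tsv(tab, path, progress = FALSE)
    },
    graphml = igraph::write_graph(g, path, format = "graphml")
  )
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Input file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`; guessed from the file
#'   extension when missing.
#' @return An igraph object.
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path)) abort(paste0("network file not found: ", path))
  format <- format %||% switch(tools::file_ext(path),
    sif = "sif", graphml = "graphml", tsv = "tsv",
    abort(paste0("cannot guess network format from path: ", path))
  )
  switch(format,
    graphml = igraph::read_graph(path, format = "graphml"),
    sif = {
      lines <- readLines(path)
      lines <- lines[nzchar(stringr::str_trim(lines))]
      if (length(lines) == 0) return(igraph::make_empty_graph(directed = FALSE))
      parts <- strsplit(lines, "[\t ]+")
      el <- purrr::map_df(parts, ~ tibble(a = .x[1], b = .x[3]))
      igraph::graph_from_data_frame(el, directed = FALSE)
    },
    tsv = {
      tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
      if (nrow(tab) == 0) return(igraph::make_empty_graph(directed = FALSE))
      igraph::graph_from_data_frame(tab, directed = FALSE)
    },
    abort(paste0("unknown network format: ", format))
  )
}

#' Convert a netpharm network object to igraph
#'
#' @param x A network object (`gene_network`, `ct_network`, `frs`) or an
#'   igraph object (returned as is).
#' @param ... Unused.
#' @return An igraph object. Bipartite networks carry a `type` vertex
#'   attribute (`"component"`/`"target"`); weighted gene networks carry
#'   `weight`.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @method as_igraph igraph
#' @export
as_igraph.igraph <- function(x, ...) x

#' @method as_igraph default
#' @export
as_igraph.default <- function(x, ...) {
  abort(paste0("cannot convert object of class '", class(x)[1],
               "' to igraph"))
}
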
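#' Lipinski rule-of-five verdicts
#'
#' Evaluates each component against the five drug-likeness rules used to
#' define active components of a herbal formula:
#'
#' * R1 — molecular weight below 500 Da (strictly `mw < 500`);
#' * R2 — at most 5 hydrogen-bond donors (`hbd <= 5`);
#' * R3 — fewer than 10 hydrogen-bond acceptors (`hba < 10`);
#' * R4 — cLogP between -2 and 5 inclusive;
#' * R5 — 10 or fewer rotatable bonds (`rotatable_bonds <= 10`).
#'
#' The rule boundaries are deliberately literal (strict `< 500`, inclusive
#' logP range) rather than the looser classical formulations. A rule with a
#' missing (`NA`) property can neither pass nor fail; in strict mode any
#' unknown property blocks the overall verdict, in lenient mode unknowns are
#' ignored.
#'
#' @param components A component tibble as returned by [read_components()]
#'   (columns `component_id`, `mw`, `hbd`, `hba`, `clogp`, `rotatable_bonds`).
#' @param strict If `TRUE` (default), a component with any unknown property is
#'   not passed; if `FALSE`, unknown properties are ignored.
#' @return A tibble with columns `component_id`, `passed`, `failed_rules`
#'   (`;`-joined subset of R1..R5, `""` when none) and `unknown_properties`
#'   (`;`-joined property names, `""` when none).
#' @examples
#' comps <- tibble::tibble(
#'   component_id = c("A", "B"), name = c("a", "b"), herbs = "GZ",
#'   mw = c(444.65, 500), hbd = c(2L, 2L), hba = c(4L, 4L),
#'   clogp = c(4.1, 1), rotatable_bonds = c(6L, 3L)
#' )
#' lipinski_verdict(comps)
#' @export
lipinski_verdict <- function(components, strict = TRUE) {
  props <- c(R1 = "mw", R2 = "hbd", R3 = "hba", R4 = "clogp",
             R5 = "rotatable_bonds")
  for (col in props) {
    if (!col %in% names(components)) {
      abort(paste0("component table is missing property column '", col, "'"))
    }
  }
  checks <- list(
    R1 = components$mw < 500,
    R2 = components$hbd <= 5,
    R3 = components$hba < 10,
    R4 = components$clogp >= -2 & components$clogp <= 5,
    R5 = components$rotatable_bonds <= 10
  )
  failed <- purrr::imap(checks, ~ !is.na(.x) & !.x)
  unknown <- purrr::map(props, ~ is.na(components[[.x]]))
  failed_rules <- purrr::pmap_chr(failed, function(...) {
    paste(names(checks)[c(...)], collapse = ";")
  })
  unknown_props <- purrr::pmap_chr(unknown, function(...) {
    paste(unname(props)[c(...)], collapse = ";")
  })
  passed <- failed_rules == ""
  if (strict) passed <- passed & unknown_props == ""
  tibble(
    component_id = components$component_id,
    passed = passed,
    failed_rules = failed_rules,
    unknown_properties = unknown_props
  )
}

#' Screen components into active components
#'
#' Applies [lipinski_verdict()] to a component table and splits it into the
#' active set and a full screening report. Screening is strictly
#' per-component: no cross-component coupling, so screening a union of tables
#' equals the union of the screens.
#'
#' @inheritParams lipinski_verdict
#' @return A list of class `screen_result` with elements
#'   `active` (tibble of components that passed), `report` (verdict tibble for
#'   all components) and `by_herb` (per-herb tallies of collected and active
#'   components, with a `Total` row; a component carrying several herb labels
#'   counts once in each herb).
#' @export
screen_components <- function(components, strict = TRUE) {
  report <- lipinski_verdict(components, strict = strict)
  active <- components[report$passed, , drop = FALSE]
  by_herb <- if ("herbs" %in% names(components)) {
    tallies <- components %>%
      mutate(passed = report$passed) %>%
      tidyr::separate_rows(herbs, sep = ";") %>%
      mutate(herbs = stringr::str_trim(herbs)) %>%
      group_by(herb = herbs) %>%
      summarise(components = n(), active = sum(passed), .groups = "drop") %>%
      arrange(desc(components))
    bind_rows(tallies, tibble(herb = "Total",
                              components = sum(tallies$components),
                              active = sum(tallies$active)))
  } else {
    tibble(herb = character(), components = integer(), active = integer())
  }
  structure(list(active = active, report = report, by_herb = by_herb),
            class = "screen_result")
}

#' @method print screen_result
#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Lipinski screen: %d of %d components active\n",
              nrow(x$active), nrow(x$report)))
  print(x$by_herb)
  invisible(x)
}

#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) x$report

#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble(n_components = nrow(x$report),
         n_active = nrow(x$active),
         n_failed = sum(!x$report$passed & x$report$failed_rules != ""),
         n_unknown = sum(x$report$unknown_properties != ""))
}
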
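#' Plot degree distributions of a C-T network
#'
#' Log-log degree histograms for both sides of the bipartite compound-target
#' graph; heavy right tails are the expected shape for herbal-formula C-T
#' networks.
#'
#' @param object A `ct_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ct_network
#' @export
autoplot.ct_network <- function(object, ...) {
  stats <- ct_statistics(object)
  df <- bind_rows(
    mutate(stats$component_degrees, side = "components",
           node = component_id),
    mutate(stats$target_degrees, side = "targets", node = target_symbol)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = degree)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~side, scales = "free") +
    ggplot2::labs(x = "degree (log scale)", y = "nodes",
                  title = "C-T network degree distributions")
}

#' Plot the goal-program deviation profile
#'
#' Shows the three penalised deviations across candidate selection sizes
#' `k`, with the chosen `C_com'` marked; only available for induced-mode
#' solutions (analytic mode has no per-`k` profile).
#'
#' @param object A `goal_program_solution` solved in induced mode.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot goal_program_solution
#' @export
autoplot.goal_program_solution <- function(object, ...) {
  if (is.null(object$candidates)) {
    abort("no candidate profile: solution was computed in analytic mode")
  }
  df <- object$candidates %>%
    select(k, d1_minus, d2_minus, d3_plus) %>%
    tidyr::pivot_longer(-k, names_to = "deviation", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(k, value, colour = deviation)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$c_com_sel, linetype = 2) +
    ggplot2::labs(x = "components selected (k)", y = "deviation",
                  title = "Goal-program deviations by selection size")
}

#' Plot the GA fitness trace of a KGEC run
#'
#' @param object A `kgec_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kgec_result
#' @export
autoplot.kgec_result <- function(object, ...) {
  if (is.null(object$trace) || nrow(object$trace) == 0) {
    abort("no trace recorded for this result")
  }
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(generation, best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "best fitness",
                  title = sprintf("GA fitness trace (%s mode, C = %g)",
                                  object$fitness, object$C))
}

#' Dot plot of top enrichment records
#'
#' @param records Enrichment tibble from [hypergeom_enrich()].
#' @param top_n Number of terms shown (by p-value).
#' @param on Colour by `"raw"` or `"adjusted"` p.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(records, top_n = 15, on = c("raw", "adjusted")) {
  on <- match.arg(on)
  col <- if (on == "raw") "p" else "p_adj"
  df <- records %>%
    arrange(p) %>%
    slice_head(n = top_n) %>%
    mutate(term_name = factor(term_name, levels = rev(term_name)))
  ggplot2::ggplot(df, ggplot2::aes(x = k, y = term_name,
                                   size = k / K,
                                   colour = -log10(.data[[col]]))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "genes in overlap", y = NULL, size = "k / K",
                  colour = sprintf("-log10(%s p)", on),
                  title = "Over-representation analysis")
}
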
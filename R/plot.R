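# ggplot2 display of simulated traces.

#' Plot a simulated trace
#'
#' Faceted ggplot of a trace: membrane potential, gate variables, branch
#' current densities and conductances (plus memristances for the memristive
#' model), against time.
#'
#' @param object A `memhh_trace`.
#' @param panels Which panels to draw, a subset of
#'   `c("V", "gates", "currents", "conductances", "memristance")`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' tr <- run_current_clamp("hh", stim_constant(0.08, 20))
#' ggplot2::autoplot(tr)
#' @export
autoplot.memhh_trace <- function(object,
                                 panels = c("V", "gates", "currents",
                                            "conductances"),
                                 ...) {
  panels <- match.arg(panels, several.ok = TRUE,
                      choices = c("V", "gates", "currents", "conductances",
                                  "memristance"))
  pick <- list(
    V = c("V"),
    gates = c("m", "n", "h"),
    currents = c("J_Na", "J_K", "J_L", "J_total", "J_ext"),
    conductances = c("g_Na", "g_K"),
    memristance = c("M_Na", "M_K"))
  long <- purrr::map_dfr(panels, function(p) {
    cols <- intersect(pick[[p]], names(object))
    if (!length(cols)) return(NULL)
    tibble::as_tibble(object)[, c("t", cols)] |>
      tidyr::pivot_longer(-"t", names_to = "series", values_to = "value") |>
      dplyr::mutate(panel = p)
  })
  long$panel <- factor(long$panel, levels = panels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
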
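#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_hline labs
#'   autoplot theme_bw scale_y_log10
NULL

#' Plot scored hotspots along the genome
#'
#' A Manhattan-style view: one point per hotspot at its midpoint,
#' height `-log10(q)`, colored by region category, with the chosen FDR
#' level drawn as a dashed line.
#'
#' @param object a `hotspot_results` tibble.
#' @param alpha FDR level for the reference line.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot hotspot_results
#' @export
autoplot.hotspot_results <- function(object, alpha = 0.05, ...) {
  d <- as_tibble(object) |>
    mutate(mid = (.data$start + .data$end) / 2,
           neglog_q = -log10(pmax(.data$q_value, 1e-300)))
  ggplot(d, aes(x = .data$mid, y = .data$neglog_q,
                colour = .data$region_category)) +
    geom_point(size = 2) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    labs(x = "genomic position (bp)", y = expression(-log[10](q)),
         colour = "region category") +
    theme_bw()
}

#' Plot variant recurrence across carriers
#'
#' @param collapsed collapsed-variant tibble.
#' @param top show the `top` most recurrent sites.
#' @return a ggplot object.
#' @export
plot_recurrence <- function(collapsed, top = 20L) {
  d <- recurrence_table(collapsed) |>
    head(top) |>
    mutate(site = sprintf("%s:%d %s>%s", .data$chrom, .data$pos,
                          .data$ref, .data$alt))
  ggplot(d, aes(x = stats::reorder(.data$site, .data$n_carriers),
                y = .data$n_carriers)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "carrier samples") +
    theme_bw()
}

#' Plot the verdict composition of a validation run
#'
#' @param verdicts verdict tibble from [validate_hotspots()].
#' @return a ggplot object.
#' @export
plot_verdicts <- function(verdicts) {
  d <- dplyr::count(verdicts, .data$status)
  ggplot(d, aes(x = .data$status, y = .data$n, fill = .data$status)) +
    geom_col(show.legend = FALSE) +
    labs(x = "verdict", y = "(variant, carrier) pairs") +
    theme_bw()
}
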
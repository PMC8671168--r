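#' Plot a distance map
#'
#' @param m distance map (Angstroms).
#' @param cap colour-scale cap in Angstroms.
#' @return A ggplot object.
#' @export
plot_distance_map <- function(m, cap = 16) {
  m <- check_distance_map(m)
  df <- data.frame(i = as.vector(row(m)), j = as.vector(col(m)),
                   d = pmin(as.vector(m), cap))
  ggplot2::ggplot(df, ggplot2::aes(x = j, y = i,
                                   fill = d)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "distance (Å)",
                                  direction = -1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue j", y = "residue i") +
    ggplot2::theme_minimal()
}

#' Plot predicted against true model quality for a pool
#'
#' @param ranking a [new_ranking()] of predicted scores.
#' @param true_scores named numeric vector of true scores.
#' @return A ggplot object.
#' @export
plot_ranking_quality <- function(ranking, true_scores) {
  df <- data.frame(predicted = ranking$score,
                   true = true_scores[ranking$model_id])
  ggplot2::ggplot(df, ggplot2::aes(x = true, y = predicted)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "true GDT-TS", y = "predicted score") +
    ggplot2::theme_minimal()
}
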
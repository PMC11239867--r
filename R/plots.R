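## Figure exports: polar effect-spectrum heatmap, chapter chord-style flow
## plot, and constellation maps.

#' Polar heatmap of the pairwise effect spectrum
#'
#' Rays (angular sectors) are exposure diseases, rings (radial bands) are
#' outcome diseases; cells are coloured red for increasing, blue for
#' decreasing and white for null effects, with skipped pairs grey.
#'
#' @param em An `effect_matrix`.
#' @return A ggplot object.
#' @export
plot_effect_spectrum <- function(em) {
  df <- as.data.frame(em)
  df$fill <- df$psi
  df$fill[df$class %in% c("null", "skipped")] <- 0
  df$a <- factor(df$a); df$b <- factor(df$b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$fill)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "risk difference") +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "exposure disease (ray)", y = "outcome disease (ring)")
}

#' Chapter flow plot
#'
#' Arc-style summary of the chord table: chapters on a circle, one segment
#' per chapter pair, width proportional to the flow count; bi-directional
#' flows red, uni-directional blue, self-links drawn as loops at the chapter.
#'
#' @param chord Chord table from [chord_export()].
#' @return A ggplot object.
#' @export
plot_chapter_flows <- function(chord) {
  labs <- sort(unique(c(chord$from, chord$to)))
  ang <- setNames(2 * pi * (seq_along(labs) - 1) / length(labs), labs)
  df <- chord
  df$x <- cos(ang[df$from]); df$y <- sin(ang[df$from])
  df$xend <- cos(ang[df$to]); df$yend <- sin(ang[df$to])
  nodes <- data.frame(lab = labs, x = cos(ang), y = sin(ang))
  ggplot2::ggplot() +
    ggplot2::geom_curve(data = df[!df$self_link, ],
                        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                                     yend = .data$yend, linewidth = .data$weight,
                                     colour = .data$direction),
                        curvature = 0.3, alpha = 0.7) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::geom_text(data = nodes, ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                                  label = .data$lab), size = 3) +
    ggplot2::scale_colour_manual(values = c(bi = "red", uni = "blue")) +
    ggplot2::scale_linewidth(range = c(0.2, 3)) +
    ggplot2::theme_void()
}

#' Constellation map
#'
#' Nodes at the Kamada-Kawai coordinates, coloured by ICD-10 chapter; green
#' segments mark bi-directional progression, grey segments uni-directional,
#' with segment width proportional to the effect size. Hub diseases are
#' labelled.
#'
#' @param pg A `progress_graph`.
#' @param cs A `constellation_set`.
#' @param coords Coordinate matrix from [layout_components()] or
#'   [kamada_kawai_layout()].
#' @param hubs Hub table from [identify_hubs()].
#' @return A ggplot object.
#' @export
plot_constellations <- function(pg, cs, coords, hubs = NULL) {
  ed <- pg$edges
  ed <- ed[ed$from %in% rownames(coords) & ed$to %in% rownames(coords), ]
  ed$x <- coords[ed$from, 1]; ed$y <- coords[ed$from, 2]
  ed$xend <- coords[ed$to, 1]; ed$yend <- coords[ed$to, 2]
  nodes <- data.frame(node = rownames(coords), x = coords[, 1], y = coords[, 2],
                      chapter = map_chapter(rownames(coords)),
                      constellation = factor(cs$membership[rownames(coords)]))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                                       yend = .data$yend, linewidth = .data$weight,
                                       colour = .data$bi), alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "darkgreen", `FALSE` = "grey50"),
                                 labels = c(`TRUE` = "bi-directional",
                                            `FALSE` = "uni-directional"),
                                 name = NULL) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, shape = .data$constellation),
                        size = 3) +
    ggplot2::geom_text(data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                                  label = .data$node),
                       vjust = -1, size = 2.5) +
    ggplot2::theme_void()
  if (!is.null(hubs)) {
    hub_nodes <- nodes[nodes$node %in% hubs$hub, ]
    p <- p + ggplot2::geom_point(data = hub_nodes,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 shape = 1, size = 6, stroke = 1.2, colour = "black")
  }
  p
}
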
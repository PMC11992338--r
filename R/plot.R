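# Rendering: ternary (N=3), quaternary (N=4, fixed-view projection), and
# segment (N=2) plots. All geometry is assembled into plain tibbles first
# (simplex_geometry) so tests assert on coordinates, never on pixels.

default_palette <- function(labels) {
  base <- c("#E41A1C", "#377EB8", "#4DAF4A", "#FF7F00", "#984EA3",
            "#A65628", "#F781BF", "#999999")
  labels <- sort(unique(labels))
  stats::setNames(rep(base, length.out = length(labels)), labels)
}

tetrahedron_edges <- function() {
  rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
}

#' Geometry layer of a fate-simplex plot
#'
#' Returns the exact coordinates every plot function draws — vertices,
#' simplex edges, one point per cell, and velocity arrows — as tibbles, so
#' downstream tooling and tests can consume the plot content without
#' rasterizing anything.
#'
#' @param x A `fate_simplex` object.
#' @param arrow_max_len Length of a weight-1 arrow; default 0.15.
#' @param color_all Color non-terminal clusters too? Default FALSE (they
#'   are drawn gray so the terminal fates stand out).
#' @param vertex_colors Optional named or positional vector of N colors for
#'   the terminal vertices; defaults to a deterministic palette over sorted
#'   labels.
#' @return A list of tibbles: `vertices` (terminal, coordinates, color),
#'   `edges` (segment endpoints), `points` (barcode, cluster, coordinates,
#'   color), and `arrows` (possibly empty).
#' @export
simplex_geometry <- function(x, arrow_max_len = 0.15, color_all = FALSE,
                             vertex_colors = NULL) {
  stopifnot(inherits(x, "fate_simplex"))
  n <- length(x$terminals)
  v <- x$vertices
  ax <- colnames(v)
  pal <- default_palette(x$terminals)
  if (!is.null(vertex_colors)) {
    if (length(vertex_colors) != n) {
      stop_validation("vertex_colors must have one color per terminal")
    }
    pal <- stats::setNames(as.character(vertex_colors), x$terminals)
  }
  vertices <- tibble(terminal = x$terminals)
  for (j in seq_along(ax)) vertices[[ax[j]]] <- v[, j]
  vertices$color <- unname(pal[x$terminals])

  edge_idx <- if (n == 4) tetrahedron_edges() else
    cbind(seq_len(n), c(seq_len(n)[-1], 1))[seq_len(if (n == 2) 1 else n), , drop = FALSE]
  edges <- tibble(from = edge_idx[, 1], to = edge_idx[, 2])
  for (j in seq_along(ax)) {
    edges[[ax[j]]] <- v[edge_idx[, 1], j]
    edges[[paste0(ax[j], "end")]] <- v[edge_idx[, 2], j]
  }

  points <- x$coords[, c("barcode", "cluster", ax)]
  if (color_all) {
    full_pal <- default_palette(x$annotation$cluster)
    full_pal[names(pal)] <- pal
    points$color <- unname(full_pal[points$cluster])
  } else {
    points$color <- ifelse(points$cluster %in% x$terminals,
                           unname(pal[points$cluster]), "#BEBEBE")
  }

  arrows <- if (!is.null(x$field) && nrow(x$field) > 0) {
    a <- velocity_arrows(x$field, x$vertices, max_len = arrow_max_len)
    a$color <- unname(pal[a$terminal])
    a
  } else {
    tibble()
  }
  list(vertices = vertices, edges = edges, points = points, arrows = arrows)
}

finish_simplex_plot <- function(p, title) {
  p + ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = title) +
    ggplot2::theme(legend.position = "right")
}

#' Ternary plot of a three-vertex fate simplex
#'
#' Draws the triangle outline with labeled, colored vertices, one point per
#' cell at its barycentric position, and velocity arrows per occupied grid
#' bin when a transition graph was supplied.
#'
#' @param x A `fate_simplex` with exactly 3 terminals.
#' @param point_size Point size; default 0.8.
#' @param arrow_max_len Length of a weight-1 arrow; default 0.15.
#' @param color_all Color non-terminal clusters? Default FALSE.
#' @param vertex_colors Optional N colors for the vertices.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_ternary <- function(x, point_size = 0.8, arrow_max_len = 0.15,
                         color_all = FALSE, vertex_colors = NULL,
                         title = NULL) {
  stopifnot(inherits(x, "fate_simplex"))
  if (length(x$terminals) != 3) {
    stop_validation(paste0("plot_ternary needs 3 terminals; use ",
                           if (length(x$terminals) == 2) "plot_binary()" else "plot_quaternary()"))
  }
  g <- simplex_geometry(x, arrow_max_len, color_all, vertex_colors)
  lab_off <- 0.04
  vlab <- g$vertices
  vlab$y <- vlab$y + ifelse(vlab$y > 0.1, lab_off, -lab_off)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = g$edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey30") +
    ggplot2::geom_point(data = g$points,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$cluster),
                        size = point_size) +
    ggplot2::scale_color_manual(
      values = stats::setNames(
        g$points$color[!duplicated(g$points$cluster)],
        g$points$cluster[!duplicated(g$points$cluster)])) +
    ggplot2::geom_text(data = vlab,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$terminal),
                       color = vlab$color, fontface = "bold")
  if (nrow(g$arrows) > 0) {
    p <- p + ggplot2::geom_segment(
      data = g$arrows,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      color = g$arrows$color, linewidth = 0.4,
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm")))
  }
  finish_simplex_plot(p, title)
}

#' Orthographic projection of 3-D coordinates for the quaternary view
#'
#' @param xyz Matrix or data frame with columns x, y, z.
#' @param azimuth,elevation View angles in degrees.
#' @return A two-column matrix (`u`, `v`) of projected coordinates.
#' @export
project_view <- function(xyz, azimuth = 30, elevation = 20) {
  xyz <- as.matrix(xyz)
  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  u <- xyz[, 2] * cos(az) - xyz[, 1] * sin(az)
  v <- xyz[, 3] * cos(el) -
    (xyz[, 1] * cos(az) + xyz[, 2] * sin(az)) * sin(el)
  cbind(u = u, v = v)
}

#' Quaternary (tetrahedron) plot of a four-vertex fate simplex
#'
#' Projects the tetrahedron, cells, and arrows orthographically at fixed
#' view angles and draws them in 2-D. Multiple view-angle pairs produce a
#' list of plots (one per view).
#'
#' @param x A `fate_simplex` with exactly 4 terminals.
#' @param view_angles List of `c(azimuth, elevation)` pairs in degrees;
#'   default a single `c(30, 20)` view.
#' @inheritParams plot_ternary
#' @return A ggplot object, or a list of them when several views are
#'   requested.
#' @export
plot_quaternary <- function(x, view_angles = list(c(30, 20)),
                            point_size = 0.8, arrow_max_len = 0.15,
                            color_all = FALSE, vertex_colors = NULL,
                            title = NULL) {
  stopifnot(inherits(x, "fate_simplex"))
  if (length(x$terminals) != 4) {
    stop_validation("plot_quaternary needs 4 terminals; use plot_ternary() or plot_binary()")
  }
  g <- simplex_geometry(x, arrow_max_len, color_all, vertex_colors)
  one_view <- function(angles) {
    az <- angles[1]; el <- angles[2]
    pv <- project_view(g$vertices[, c("x", "y", "z")], az, el)
    vt <- dplyr::mutate(g$vertices, u = pv[, 1], v = pv[, 2])
    e1 <- project_view(g$edges[, c("x", "y", "z")], az, el)
    e2 <- project_view(g$edges[, c("xend", "yend", "zend")], az, el)
    ed <- tibble(u = e1[, 1], v = e1[, 2], uend = e2[, 1], vend = e2[, 2])
    pp <- project_view(g$points[, c("x", "y", "z")], az, el)
    pt <- dplyr::mutate(g$points, u = pp[, 1], v = pp[, 2])
    p <- ggplot2::ggplot() +
      ggplot2::geom_segment(data = ed,
                            ggplot2::aes(x = .data$u, y = .data$v,
                                         xend = .data$uend, yend = .data$vend),
                            color = "grey30") +
      ggplot2::geom_point(data = pt,
                          ggplot2::aes(x = .data$u, y = .data$v,
                                       color = .data$cluster),
                          size = point_size) +
      ggplot2::scale_color_manual(
        values = stats::setNames(
          pt$color[!duplicated(pt$cluster)],
          pt$cluster[!duplicated(pt$cluster)])) +
      ggplot2::geom_text(data = vt,
                         ggplot2::aes(x = .data$u, y = .data$v,
                                      label = .data$terminal),
                         color = vt$color, fontface = "bold", nudge_y = 0.04)
    if (nrow(g$arrows) > 0) {
      a1 <- project_view(g$arrows[, c("x", "y", "z")], az, el)
      a2 <- project_view(g$arrows[, c("xend", "yend", "zend")], az, el)
      ar <- tibble(u = a1[, 1], v = a1[, 2], uend = a2[, 1], vend = a2[, 2],
                   color = g$arrows$color)
      p <- p + ggplot2::geom_segment(
        data = ar,
        ggplot2::aes(x = .data$u, y = .data$v,
                     xend = .data$uend, yend = .data$vend),
        color = ar$color, linewidth = 0.4,
        arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm")))
    }
    finish_simplex_plot(p, title)
  }
  plots <- lapply(view_angles, one_view)
  if (length(plots) == 1) plots[[1]] else plots
}

#' Segment plot of a two-vertex fate simplex
#'
#' Cells are placed along the unit segment at their barycentric coordinate
#' toward the second vertex, with seeded vertical jitter for visibility.
#'
#' @param x A `fate_simplex` with exactly 2 terminals.
#' @param jitter_seed Seed for the jitter RNG so renders are reproducible;
#'   default 42.
#' @param jitter_amount Maximum vertical jitter; default 0.15.
#' @inheritParams plot_ternary
#' @return A ggplot object.
#' @export
plot_binary <- function(x, jitter_seed = 42, jitter_amount = 0.15,
                        point_size = 0.8, color_all = FALSE,
                        vertex_colors = NULL, title = NULL) {
  stopifnot(inherits(x, "fate_simplex"))
  if (length(x$terminals) != 2) {
    stop_validation("plot_binary needs 2 terminals; use plot_ternary() or plot_quaternary()")
  }
  g <- simplex_geometry(x, color_all = color_all, vertex_colors = vertex_colors)
  pts <- g$points
  pts$yj <- withr::with_seed(jitter_seed,
                             runif(nrow(pts), -jitter_amount, jitter_amount))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = tibble(x = 0, xend = 1),
                          ggplot2::aes(x = .data$x, xend = .data$xend),
                          y = 0, yend = 0, color = "grey30") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$x, y = .data$yj,
                                     color = .data$cluster),
                        size = point_size) +
    ggplot2::scale_color_manual(
      values = stats::setNames(
        pts$color[!duplicated(pts$cluster)],
        pts$cluster[!duplicated(pts$cluster)])) +
    ggplot2::geom_text(data = g$vertices,
                       ggplot2::aes(x = .data$x, label = .data$terminal),
                       y = jitter_amount + 0.08,
                       color = g$vertices$color, fontface = "bold") +
    ggplot2::ylim(-jitter_amount - 0.15, jitter_amount + 0.15)
  finish_simplex_plot(p, title)
}

#' @rdname plot_ternary
#' @param object A `fate_simplex` object.
#' @param ... Passed to the N-specific plot function.
#' @export
autoplot.fate_simplex <- function(object, ...) {
  switch(as.character(length(object$terminals)),
         "2" = plot_binary(object, ...),
         "3" = plot_ternary(object, ...),
         "4" = plot_quaternary(object, ...))
}

#' @export
plot.fate_simplex <- function(x, ...) {
  print(autoplot(x, ...))
  invisible(x)
}
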
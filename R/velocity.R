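# Fate-potential aggregation: mean transition-edge weight from each cell
# into each terminal cluster, grid binning on the simplex, and arrow
# construction for the velocity overlay.

#' Per-cell fate potential from a transition graph
#'
#' For each cell c and terminal cluster n, the potential is the mean
#' outgoing edge weight from c into the cells of cluster n:
#' `P[c, n] = sum_{j in n, j != c} W[c, j] / |n \ {c}|`. The denominator is
#' the full target-cluster size (absent edges count as zero), which keeps
#' the score deterministic and monotone in connectivity regardless of kNN
#' sparsity; a cell's self-edge is excluded when it belongs to the target
#' cluster.
#'
#' @param graph Square cells x cells non-negative sparse matrix, rows =
#'   source cells, aligned to `annotation`.
#' @param annotation Data frame with `barcode`, `cluster`.
#' @param terminals Character vector of 2-4 terminal labels.
#' @return A cells x N non-negative dense matrix with terminal labels as
#'   column names.
#' @export
fate_potential <- function(graph, annotation, terminals) {
  ann <- as_cell_annotation(annotation)
  terminals <- check_terminals(terminals, ann)
  C <- nrow(ann)
  if (nrow(graph) != C || ncol(graph) != C) {
    stop_validation("transition graph dimensions do not match the annotation")
  }
  self_w <- Matrix::diag(graph)
  P <- matrix(0, C, length(terminals),
              dimnames = list(ann$barcode, terminals))
  for (t in terminals) {
    members <- ann$cluster == t
    size <- sum(members)
    s <- Matrix::rowSums(graph[, members, drop = FALSE])
    denom <- rep.int(size, C)
    # self-exclusion for cells inside the target cluster
    s[members] <- s[members] - self_w[members]
    denom[members] <- size - 1
    if (any(denom == 0)) {
      stop_validation(paste0("terminal cluster '", t,
                             "' has no other cells after self-exclusion"))
    }
    P[, t] <- s / denom
  }
  P
}

#' Bin cells into a square/cube grid and aggregate fate potentials
#'
#' The bounding box of the simplex vertex polytope (not of the data) is
#' divided into `resolution` equal bins per axis — squares for a ternary
#' plot, cubes for a quaternary one — with half-open intervals and a closed
#' final bin, so bin boundaries are dataset-independent. Within each
#' occupied bin, member cells' potentials are averaged and then
#' L1-normalized across the N fates; the bin centroid is the mean of the
#' member cells' Cartesian positions.
#'
#' @param cartesian Cells x (N-1) coordinate matrix from
#'   [barycentric_to_cartesian()].
#' @param potential Cells x N fate-potential matrix from
#'   [fate_potential()].
#' @param resolution Positive integer number of bins per axis; default 10.
#' @param vertices Optional vertex matrix fixing the bounding box; defaults
#'   to [simplex_vertices()].
#' @return A tibble with one row per occupied bin: `grid_id`, the centroid
#'   coordinates (`x`, `y`, `z` as applicable), `n_cells`, and one weight
#'   column `w_<terminal>` per fate (each row of weights sums to 1).
#' @export
bin_velocity_grid <- function(cartesian, potential, resolution = 10,
                              vertices = NULL) {
  if (resolution < 1) stop_validation("resolution must be a positive integer")
  n_fates <- ncol(potential)
  vertices <- vertices %||% simplex_vertices(n_fates)
  ndim <- ncol(vertices)
  if (ncol(cartesian) != ndim) {
    stop_validation("cartesian coordinates and vertices disagree in dimension")
  }
  lo <- apply(vertices, 2, min)
  hi <- apply(vertices, 2, max)
  width <- (hi - lo) / resolution
  idx <- vapply(seq_len(ndim), function(d) {
    i <- floor((cartesian[, d] - lo[d]) / width[d]) + 1L
    pmin(pmax(as.integer(i), 1L), as.integer(resolution)) # last bin closed
  }, integer(nrow(cartesian)))
  idx <- matrix(idx, ncol = ndim)
  key <- apply(idx, 1, paste, collapse = "-")

  groups <- split(seq_len(nrow(cartesian)), key)
  terminals <- colnames(potential)
  rows <- purrr::map(names(groups), function(k) {
    cells <- groups[[k]]
    w <- colMeans(potential[cells, , drop = FALSE])
    s <- sum(w)
    if (s == 0) {
      warn(sprintf("bin %s: all member potentials are zero; uniform weights assigned", k))
      w <- rep(1 / n_fates, n_fates)
    } else {
      w <- w / s
    }
    ctr <- colMeans(cartesian[cells, , drop = FALSE])
    out <- c(list(grid_id = k),
             as.list(stats::setNames(ctr, colnames(vertices))),
             list(n_cells = length(cells)),
             as.list(stats::setNames(w, paste0("w_", terminals))))
    tibble::as_tibble(out)
  })
  field <- dplyr::bind_rows(rows)
  attr(field, "terminals") <- terminals
  attr(field, "vertices") <- vertices
  field
}

#' Arrows from grid centroids toward each vertex
#'
#' For every occupied grid bin and every fate with non-zero weight, an
#' arrow points from the bin centroid toward that fate's vertex, with
#' length `weight * max_len`; per bin, arrow lengths therefore sum to
#' `max_len`. Zero-weight arrows are omitted, as is any degenerate arrow
#' whose origin coincides with its target vertex.
#'
#' @param field Tibble from [bin_velocity_grid()].
#' @param vertices Optional vertex coordinate matrix; defaults to the one
#'   recorded on `field`.
#' @param max_len Length of a weight-1 arrow in plot units; default 0.15.
#' @return A tibble with `grid_id`, `terminal`, origin coordinates
#'   (`x`, `y`, `z`), unit direction (`dx`, `dy`, `dz`), `length`, and
#'   arrow endpoints (`xend`, ...).
#' @export
velocity_arrows <- function(field, vertices = NULL, max_len = 0.15) {
  if (max_len <= 0) stop_validation("max_len must be positive")
  vertices <- vertices %||% attr(field, "vertices")
  terminals <- attr(field, "terminals") %||%
    sub("^w_", "", grep("^w_", names(field), value = TRUE))
  ndim <- ncol(vertices)
  ax <- colnames(vertices)
  rows <- purrr::map_dfr(seq_len(nrow(field)), function(i) {
    origin <- as.numeric(field[i, ax])
    purrr::map_dfr(seq_along(terminals), function(n) {
      w <- field[[paste0("w_", terminals[n])]][i]
      if (w <= 0) return(NULL)
      dir <- vertices[n, ] - origin
      nrm <- sqrt(sum(dir^2))
      if (nrm == 0) return(NULL)
      dir <- dir / nrm
      len <- w * max_len
      out <- c(list(grid_id = field$grid_id[i], terminal = terminals[n]),
               as.list(stats::setNames(origin, ax)),
               as.list(stats::setNames(dir, paste0("d", ax))),
               list(length = len),
               as.list(stats::setNames(origin + dir * len, paste0(ax, "end"))))
      tibble::as_tibble(out)
    })
  })
  rows
}

#' Export a velocity field as TSV
#'
#' One row per occupied grid bin: grid index, centroid coordinates, cell
#' count, and one normalized weight column per terminal.
#'
#' @param field Tibble from [bin_velocity_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(field, path) {
  readr::write_tsv(field, path, col_names = TRUE)
  invisible(path)
}
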
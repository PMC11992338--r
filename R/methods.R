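# broom-style accessors and printing for fitted fate_simplex objects.

#' @export
print.fate_simplex <- function(x, ...) {
  n <- length(x$terminals)
  cat(sprintf("<fate_simplex> %d cells on a %d-vertex simplex\n",
              nrow(x$coords), n))
  cat("  terminals:", paste(x$terminals, collapse = ", "), "\n")
  cat(sprintf("  feature space: %s\n",
              if (x$params$method == "markers")
                sprintf("%d marker genes (top %d per fate, Wilcoxon)",
                        length(unique(x$markers$feature)), x$params$top_k)
              else sprintf("%d principal components", x$params$n_components)))
  if (!is.null(x$field)) {
    cat(sprintf("  velocity field: %d occupied grid bins\n", nrow(x$field)))
  }
  invisible(x)
}

#' Tidy a fate_simplex into one row per cell
#'
#' @param x A `fate_simplex` object.
#' @param ... Unused.
#' @return A tibble: `barcode`, `cluster`, one barycentric-coordinate
#'   column per terminal label, and Cartesian `x`, `y` (and `z` for four
#'   vertices).
#' @export
tidy.fate_simplex <- function(x, ...) {
  x$coords
}

#' One-row summary of a fate_simplex fit
#'
#' @param x A `fate_simplex` object.
#' @param ... Unused.
#' @return A one-row tibble: cell and vertex counts, feature-space method
#'   and size, kernel bandwidth, and the number of occupied velocity bins
#'   (NA when no transition graph was supplied).
#' @export
glance.fate_simplex <- function(x, ...) {
  tibble(
    n_cells = nrow(x$coords),
    n_vertices = length(x$terminals),
    method = x$params$method,
    n_features = if (x$params$method == "markers")
      length(unique(x$markers$feature)) else x$params$n_components,
    sigma = x$params$sigma,
    n_grid_bins = if (is.null(x$field)) NA_integer_ else nrow(x$field))
}
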
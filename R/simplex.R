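# The mathematical core: terminal-cluster centroids, cell-to-centroid
# Euclidean distances, distance row-normalization, exponential-kernel
# similarities, per-vertex range scaling, L1 normalization into barycentric
# coordinates, and the fixed Cartesian projections for plotting.

#' Mean-centroids of the terminal clusters
#'
#' @param mat Feature-subspace expression matrix or PCA embedding
#'   (features/components x cells).
#' @param annotation Data frame with `barcode`, `cluster` aligned to `mat`
#'   columns.
#' @param terminals Character vector of 2-4 terminal labels.
#' @return A dense features x N matrix; column n is the arithmetic mean of
#'   the cells annotated with terminal n.
#' @export
compute_centroids <- function(mat, annotation, terminals) {
  ann <- as_cell_annotation(annotation)
  terminals <- check_terminals(terminals, ann)
  if (ncol(mat) != nrow(ann)) {
    stop_validation("matrix columns and annotation rows differ; align first")
  }
  cent <- vapply(terminals, function(t) {
    idx <- which(ann$cluster == t)
    Matrix::rowMeans(mat[, idx, drop = FALSE])
  }, numeric(nrow(mat)))
  dimnames(cent) <- list(rownames(mat), terminals)
  cent
}

#' Euclidean distance from every cell to every centroid
#'
#' @param mat Features x cells matrix.
#' @param centroids Features x N centroid matrix from [compute_centroids()].
#' @return A cells x N non-negative matrix of Euclidean distances.
#' @export
compute_distances <- function(mat, centroids) {
  if (nrow(mat) != nrow(centroids)) {
    stop_validation(sprintf("feature dimensions disagree: matrix %d, centroids %d",
                            nrow(mat), nrow(centroids)))
  }
  X <- base::t(as.matrix(mat))                       # cells x features
  V <- as.matrix(centroids)                          # features x N
  # |x - v|^2 = |x|^2 - 2 x.v + |v|^2, clipped at 0 against roundoff
  sq <- rowSums(X^2) %*% matrix(1, 1, ncol(V)) -
    2 * (X %*% V) +
    matrix(1, nrow(X), 1) %*% colSums(V^2)
  D <- sqrt(pmax(sq, 0))
  dimnames(D) <- list(colnames(mat), colnames(centroids))
  D
}

# Row sums accumulated in a canonical column order (sorted by column name),
# so listing the terminals in a different order permutes results exactly
# instead of up to floating-point summation order.
canonical_row_sums <- function(M) {
  cn <- colnames(M)
  if (is.null(cn)) rowSums(M) else rowSums(M[, order(cn), drop = FALSE])
}

#' Normalize each cell's distances to unit sum
#'
#' The N distances of each cell are divided by their sum so every cell's
#' distances live on the same scale before the similarity kernel. A cell at
#' zero distance from every centroid can only occur when the centroids
#' coincide, which is reported as an error.
#'
#' @param D Cells x N non-negative distance matrix.
#' @return Matrix of the same shape with rows summing to 1.
#' @export
row_normalize_distances <- function(D) {
  rs <- canonical_row_sums(D)
  if (any(rs == 0)) {
    stop_validation("cell(s) at zero distance from every centroid: the terminal centroids coincide")
  }
  D / rs
}

#' Convert normalized distances to similarities
#'
#' Applies the exponential kernel `S = exp(-D / sigma)` entrywise, mapping
#' distances in `[0, 1]` to similarities in `(0, 1]`. Because distances are
#' row-normalized to unit sum first, a single scalar bandwidth is
#' well-posed; the default 0.08 makes the kernel sharp enough that a cell
#' sitting on its own centroid dominates its row.
#'
#' @param D Row-normalized cells x N distance matrix.
#' @param sigma Positive scalar kernel bandwidth; default 0.08.
#' @return Cells x N similarity matrix with entries in (0, 1].
#' @export
gaussian_similarity <- function(D, sigma = 0.08) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop_validation("sigma must be a positive scalar")
  }
  exp(-D / sigma)
}

#' Range-scale similarities per vertex
#'
#' Each column (vertex) is mapped affinely onto `[0, 1]`: the columnwise
#' minimum goes to 0 and the maximum to 1. A constant column (every cell
#' equally similar to that vertex) carries no ordering information and is
#' mapped to 0.5 with a warning.
#'
#' @param S Cells x N similarity matrix.
#' @return Matrix of the same shape with columnwise range `[0, 1]`.
#' @export
range_scale <- function(S) {
  lo <- apply(S, 2, min)
  hi <- apply(S, 2, max)
  flat <- hi == lo
  if (any(flat)) {
    warn(paste0("range_scale: constant similarity column(s) mapped to 0.5: ",
                paste(colnames(S)[flat] %||% which(flat), collapse = ", ")))
  }
  out <- S
  for (j in seq_len(ncol(S))) {
    out[, j] <- if (flat[j]) 0.5 else (S[, j] - lo[j]) / (hi[j] - lo[j])
  }
  out
}

#' L1-normalize scaled similarities into barycentric coordinates
#'
#' Each row is divided by its sum, producing the convex-combination weights
#' that place the cell inside the simplex. A cell sitting at the columnwise
#' minimum for every vertex has an all-zero row; it is assigned the uniform
#' coordinate `1/N` with a warning rather than failing.
#'
#' @param S Cells x N range-scaled similarity matrix.
#' @return Row-stochastic cells x N matrix of barycentric coordinates.
#' @export
l1_normalize <- function(S) {
  rs <- canonical_row_sums(S)
  zero <- rs == 0
  if (any(zero)) {
    warn(sprintf("l1_normalize: %d cell(s) with all-zero scaled similarity assigned uniform 1/N",
                 sum(zero)))
    rs[zero] <- 1
  }
  B <- S / rs
  if (any(zero)) B[zero, ] <- 1 / ncol(S)
  B
}

#' Cartesian vertex coordinates of the reference simplex
#'
#' Fixed conventions so plots are reproducible across runs: N=2 the unit
#' segment (vertices 0 and 1); N=3 the triangle (0,0), (1,0),
#' (1/2, sqrt(3)/2); N=4 the regular tetrahedron (0,0,0), (1,0,0),
#' (1/2, sqrt(3)/2, 0), (1/2, sqrt(3)/6, sqrt(6)/3).
#'
#' @param n Number of vertices, 2-4.
#' @return An n x (n-1) matrix of vertex coordinates, columns named
#'   `x`, `y`, `z` as applicable.
#' @export
simplex_vertices <- function(n) {
  if (!n %in% 2:4) stop_validation("simplexes with 2-4 vertices are supported")
  v <- switch(as.character(n),
    "2" = matrix(c(0, 1), ncol = 1),
    "3" = rbind(c(0, 0), c(1, 0), c(1 / 2, sqrt(3) / 2)),
    "4" = rbind(c(0, 0, 0), c(1, 0, 0),
                c(1 / 2, sqrt(3) / 2, 0),
                c(1 / 2, sqrt(3) / 6, sqrt(6) / 3)))
  colnames(v) <- c("x", "y", "z")[seq_len(ncol(v))]
  v
}

#' Project barycentric coordinates to Cartesian plotting coordinates
#'
#' @param B Row-stochastic cells x N matrix (N in 2-4).
#' @param vertices Optional N x (N-1) vertex matrix; defaults to
#'   [simplex_vertices()].
#' @param tol Tolerance on row sums; default 1e-6.
#' @return A cells x (N-1) coordinate matrix `B %*% vertices`.
#' @export
barycentric_to_cartesian <- function(B, vertices = NULL, tol = 1e-6) {
  n <- ncol(B)
  vertices <- vertices %||% simplex_vertices(n)
  if (any(abs(rowSums(B) - 1) > tol)) {
    stop_validation("barycentric rows must sum to 1")
  }
  out <- B %*% vertices
  rownames(out) <- rownames(B)
  out
}

#' Map cells onto a terminal-fate simplex
#'
#' The full pipeline: depth normalization, feature-subspace selection
#' (per-fate Wilcoxon markers or PCA), terminal centroids, Euclidean
#' distances, row normalization, exponential-kernel similarities, per-vertex
#' range scaling, and L1 normalization into barycentric coordinates. When a
#' cell-cell transition graph is supplied, per-cell fate potentials are
#' aggregated into a grid-binned velocity field as well.
#'
#' @param counts Raw feature-by-cell count matrix (features in rows).
#' @param annotation Data frame with `barcode`, `cluster`.
#' @param terminals Character vector of 2-4 terminal cluster labels; their
#'   order fixes the vertex order.
#' @param graph Optional square cell-cell transition matrix (rows = source)
#'   with barcode dimnames.
#' @param method `"markers"` (default; Wilcoxon per-fate markers) or
#'   `"pca"`.
#' @param top_k Markers per fate for `method = "markers"`; default 30.
#' @param n_components Components for `method = "pca"`; default 10.
#' @param sigma Kernel bandwidth; default 0.08.
#' @param normalize Depth-normalize and log1p the counts first? Default
#'   TRUE; set FALSE if `counts` is already normalized.
#' @param grid_resolution Bins per axis for the velocity grid; default 10.
#' @return A `fate_simplex` object: list with `coords` (tibble: barcode,
#'   cluster, one barycentric column per terminal, Cartesian `x`, `y`,
#'   `z`), `bary` (cells x N matrix), `markers` (tibble or NULL),
#'   `potential`, `field` (velocity tibbles or NULL), `vertices`,
#'   `terminals`, and `params`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
map_cell_fates <- function(counts, annotation, terminals, graph = NULL,
                           method = c("markers", "pca"), top_k = 30,
                           n_components = 10, sigma = 0.08,
                           normalize = TRUE, grid_resolution = 10) {
  method <- match.arg(method)
  aligned <- align_cells(counts, annotation, graph)
  counts <- aligned$counts
  ann <- aligned$annotation
  graph <- aligned$graph
  terminals <- check_terminals(terminals, ann)

  norm <- if (normalize) normalize_counts(counts) else counts
  markers <- NULL
  if (method == "markers") {
    markers <- rank_markers(norm, ann, terminals, top_k = top_k)
    feats <- marker_features(markers, rownames(norm))
    if (length(feats) == 0) {
      stop_validation("no marker features selected; clusters may be indistinguishable")
    }
    sub <- norm[feats, , drop = FALSE]
  } else {
    sub <- embed_pca(norm, n_components)
  }

  cent <- compute_centroids(sub, ann, terminals)
  D <- compute_distances(sub, cent)
  Dn <- row_normalize_distances(D)
  S <- gaussian_similarity(Dn, sigma = sigma)
  Ss <- range_scale(S)
  B <- l1_normalize(Ss)
  vertices <- simplex_vertices(length(terminals))
  cart <- barycentric_to_cartesian(B, vertices)

  coords <- tibble(barcode = ann$barcode, cluster = ann$cluster)
  for (t in terminals) coords[[t]] <- B[, t]
  for (j in seq_len(ncol(cart))) coords[[colnames(vertices)[j]]] <- cart[, j]

  potential <- NULL
  field <- NULL
  if (!is.null(graph)) {
    potential <- fate_potential(graph, ann, terminals)
    field <- bin_velocity_grid(cart, potential, resolution = grid_resolution,
                               vertices = vertices)
  }

  structure(
    list(coords = coords, bary = B, cartesian = cart, markers = markers,
         potential = potential, field = field, vertices = vertices,
         terminals = terminals, annotation = ann,
         params = list(method = method, top_k = top_k,
                       n_components = n_components, sigma = sigma,
                       normalize = normalize,
                       grid_resolution = grid_resolution)),
    class = "fate_simplex")
}

#' Export barycentric coordinates as TSV
#'
#' Writes one row per cell: barcode, cluster, one column per terminal
#' label, and the Cartesian plotting coordinates.
#'
#' @param x A `fate_simplex` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(x, path) {
  stopifnot(inherits(x, "fate_simplex"))
  readr::write_tsv(x$coords, path, col_names = TRUE)
  invisible(path)
}
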
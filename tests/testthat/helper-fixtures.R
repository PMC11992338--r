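# Shared helpers: small in-code fixtures and an independent scalar oracle
# for the distance -> kernel -> range-scale -> L1 chain.

tiny_counts <- function(values, n_features, n_cells,
                        features = sprintf("g%d", seq_len(n_features)),
                        barcodes = sprintf("c%d", seq_len(n_cells))) {
  matrix(values, n_features, n_cells, dimnames = list(features, barcodes))
}

random_counts <- function(n_features, n_cells, seed = 1, density = 0.3) {
  withr::with_seed(seed, {
    m <- matrix(0, n_features, n_cells)
    nnz <- round(density * length(m))
    idx <- sample(length(m), nnz)
    m[idx] <- rpois(nnz, 5) + 1
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_features)),
                        sprintf("c%03d", seq_len(n_cells)))
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  })
}

make_ann <- function(barcodes, clusters) {
  tibble::tibble(barcode = barcodes, cluster = clusters)
}

# minimal fitted object for geometry-layer tests: cells placed by a given
# barycentric matrix, no expression data involved
make_fit <- function(B, terminals, clusters = NULL, field = NULL) {
  n <- length(terminals)
  colnames(B) <- terminals
  vertices <- fatesimplex::simplex_vertices(n)
  cart <- B %*% vertices
  clusters <- clusters %||% terminals[apply(B, 1, which.max)]
  coords <- tibble::tibble(barcode = sprintf("c%d", seq_len(nrow(B))),
                           cluster = clusters)
  for (t in terminals) coords[[t]] <- B[, t]
  for (j in seq_len(ncol(cart))) coords[[colnames(vertices)[j]]] <- cart[, j]
  structure(list(coords = coords, bary = B, cartesian = cart, markers = NULL,
                 potential = NULL, field = field, vertices = vertices,
                 terminals = terminals,
                 annotation = coords[, c("barcode", "cluster")],
                 params = list(method = "markers", top_k = 30,
                               n_components = 10, sigma = 0.08,
                               normalize = TRUE, grid_resolution = 10)),
            class = "fate_simplex")
}

# straight-line scalar reimplementation of the coordinate chain, written
# with explicit loops and kept independent of the package internals
oracle_barycentric <- function(E, V, sigma = 0.08) {
  C <- ncol(E); N <- ncol(V); G <- nrow(E)
  D <- matrix(0, C, N)
  for (c in seq_len(C)) {
    for (n in seq_len(N)) {
      s <- 0
      for (i in seq_len(G)) s <- s + (E[i, c] - V[i, n])^2
      D[c, n] <- sqrt(s)
    }
  }
  for (c in seq_len(C)) D[c, ] <- D[c, ] / sum(D[c, ])
  S <- exp(-D / sigma)
  for (n in seq_len(N)) {
    S[, n] <- (S[, n] - min(S[, n])) / (max(S[, n]) - min(S[, n]))
  }
  for (c in seq_len(C)) S[c, ] <- S[c, ] / sum(S[c, ])
  S
}

# exhaustive permutation p-value for the two-sided rank-sum test,
# conditional on the pooled sample
exact_rank_sum_p <- function(x, in_group) {
  r <- rank(x)
  n1 <- sum(in_group)
  mu <- n1 * (length(x) + 1) / 2
  obs <- abs(sum(r[in_group]) - mu)
  subsets <- utils::combn(length(x), n1)
  stats <- apply(subsets, 2, function(idx) abs(sum(r[idx]) - mu))
  mean(stats >= obs - 1e-9)
}
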
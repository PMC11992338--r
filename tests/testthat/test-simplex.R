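test_that("centroids are per-cluster arithmetic means", {
  m <- tiny_counts(c(0, 0, 2, 4, 7, 9), 2, 3)
  ann <- make_ann(colnames(m), c("A", "A", "B"))
  cent <- compute_centroids(m, ann, c("A", "B"))
  expect_equal(unname(cent[, "A"]), c(1, 2))
  expect_equal(unname(cent[, "B"]), c(7, 9)) # singleton cluster = the cell
  expect_error(compute_centroids(m, ann, c("A", "Missing")), "Missing")
})

test_that("identical cells give a centroid equal to the shared vector", {
  k <- 7
  m <- tiny_counts(rep(c(3, 1, 4), k), 3, k,
                   barcodes = sprintf("c%d", 1:k))
  ann <- make_ann(colnames(m), c(rep("A", k - 2), "B", "B"))
  cent <- compute_centroids(m, ann, c("A", "B"))
  expect_equal(unname(cent[, "A"]), c(3, 1, 4))
})

test_that("cell-to-centroid distances are Euclidean", {
  m <- tiny_counts(c(0, 0, 3, 4), 2, 2)
  cent <- matrix(c(3, 4, 0, 0), 2, 2, dimnames = list(NULL, c("A", "B")))
  D <- compute_distances(m, cent)
  expect_equal(unname(D[1, "A"]), 5) # 3-4-5 triangle
  expect_equal(unname(D[2, "A"]), 0) # cell on its centroid
  expect_error(compute_distances(m, cent[1, , drop = FALSE]), "disagree")
})

test_that("distances match a naive double-loop oracle", {
  m <- withr::with_seed(17, matrix(abs(rnorm(8 * 20)), 8, 20,
                                   dimnames = list(paste0("g", 1:8),
                                                   paste0("c", 1:20))))
  cent <- withr::with_seed(18, matrix(abs(rnorm(8 * 3)), 8, 3,
                                      dimnames = list(paste0("g", 1:8),
                                                      c("A", "B", "C"))))
  D <- compute_distances(m, cent)
  for (c in 1:20) {
    for (n in 1:3) {
      expect_equal(D[c, n], sqrt(sum((m[, c] - cent[, n])^2)),
                   tolerance = 1e-10)
    }
  }
})

test_that("distance rows normalize to unit sum, zeros preserved", {
  D <- rbind(c(1, 1, 2), c(0, 5, 5))
  Dn <- row_normalize_distances(D)
  expect_equal(Dn[1, ], c(0.25, 0.25, 0.5))
  expect_equal(Dn[2, ], c(0, 0.5, 0.5))
  expect_error(row_normalize_distances(rbind(c(0, 0, 0))), "centroids")
  Dr <- withr::with_seed(3, matrix(runif(60, 0.1, 5), 20, 3))
  expect_equal(rowSums(row_normalize_distances(Dr)), rep(1, 20))
})

test_that("the exponential kernel maps normalized distances into (0,1]", {
  expect_equal(gaussian_similarity(matrix(0))[1], 1)
  expect_equal(gaussian_similarity(matrix(0.08), sigma = 0.08)[1],
               exp(-1), tolerance = 1e-12)
  expect_error(gaussian_similarity(matrix(1), sigma = 0), "positive")
  D <- withr::with_seed(4, matrix(sort(runif(30)), 10, 3))
  S <- gaussian_similarity(D)
  expect_true(all(S > 0 & S <= 1))
  # strictly decreasing in distance
  ord <- order(as.numeric(D))
  expect_true(all(diff(as.numeric(S)[ord]) < 0))
})

test_that("range scaling maps each column onto [0,1]", {
  S <- cbind(a = c(0.2, 0.5, 0.8), b = c(0.1, 0.9, 0.3))
  Ss <- range_scale(S)
  expect_equal(unname(Ss[, "a"]), c(0, 0.5, 1))
  expect_equal(min(Ss[, "b"]), 0)
  expect_equal(max(Ss[, "b"]), 1)
  expect_warning(flat <- range_scale(cbind(a = c(0.4, 0.4), b = c(0, 1))),
                 "constant")
  expect_equal(unname(flat[, "a"]), c(0.5, 0.5))
})

test_that("L1 normalization yields row-stochastic coordinates", {
  expect_equal(l1_normalize(rbind(c(1, 1)))[1, ], c(0.5, 0.5))
  expect_equal(l1_normalize(rbind(c(0, 0, 3)))[1, ], c(0, 0, 1))
  expect_warning(u <- l1_normalize(rbind(c(0, 0, 0), c(1, 3, 0))), "uniform")
  expect_equal(u[1, ], rep(1 / 3, 3))
  expect_equal(u[2, ], c(0.25, 0.75, 0))
})

test_that("Cartesian projection sends vertices and centroids where expected", {
  B <- rbind(c(1, 0, 0), c(1, 1, 1) / 3)
  cart <- barycentric_to_cartesian(B)
  expect_equal(unname(cart[1, ]), c(0, 0))
  expect_equal(unname(cart[2, ]), c(0.5, sqrt(3) / 6))
  expect_error(barycentric_to_cartesian(rbind(c(0.5, 0.2, 0.1))), "sum to 1")
})

test_that("projected points stay inside the simplex hull", {
  for (n in 2:4) {
    B <- withr::with_seed(n, {
      raw <- matrix(runif(40 * n), 40, n)
      raw / rowSums(raw)
    })
    cart <- barycentric_to_cartesian(B, simplex_vertices(n))
    v <- simplex_vertices(n)
    # hull membership: the barycentric preimage is non-negative, so each
    # coordinate must lie within the vertex bounding box and, for n = 3,
    # inside the three edge half-planes
    for (d in seq_len(ncol(v))) {
      expect_true(all(cart[, d] >= min(v[, d]) - 1e-12))
      expect_true(all(cart[, d] <= max(v[, d]) + 1e-12))
    }
    if (n == 3) {
      expect_true(all(cart[, 2] >= -1e-12))
      expect_true(all(cart[, 2] <= sqrt(3) * cart[, 1] + 1e-12))
      expect_true(all(cart[, 2] <= sqrt(3) * (1 - cart[, 1]) + 1e-12))
    }
  }
})

test_that("noiseless clusters land on their own vertices", {
  # each cluster's cells equal its centroid exactly
  proto <- cbind(A = c(10, 0, 0), B = c(0, 10, 0), C = c(0, 0, 10))
  m <- proto[, rep(1:3, each = 4)]
  colnames(m) <- sprintf("c%d", 1:12)
  rownames(m) <- paste0("g", 1:3)
  ann <- make_ann(colnames(m), rep(c("A", "B", "C"), each = 4))
  fit <- suppressWarnings(
    map_cell_fates(m, ann, c("A", "B", "C"), normalize = FALSE,
                   method = "pca", n_components = 2))
  own <- colnames(fit$bary)[apply(fit$bary, 1, which.max)]
  expect_identical(own, ann$cluster)
})

test_that("a two-vertex simplex gives complementary coordinates", {
  sim <- simulate_fate_data(n_terminals = 2, cells_per_cluster = 25,
                            n_progenitors = 10, n_features = 60, seed = 41)
  fit <- map_cell_fates(sim$counts, sim$annotation, c("T1", "T2"))
  expect_equal(fit$bary[, "T1"] + fit$bary[, "T2"],
               rep(1, nrow(fit$bary)), ignore_attr = TRUE)
  expect_equal(unname(fit$cartesian[, 1]), unname(fit$bary[, "T2"]))
})

test_that("permuting terminal order permutes coordinate columns exactly", {
  sim <- simulate_fate_data(cells_per_cluster = 25, n_progenitors = 20,
                            n_features = 80, seed = 42)
  f1 <- map_cell_fates(sim$counts, sim$annotation, c("T1", "T2", "T3"))
  f2 <- map_cell_fates(sim$counts, sim$annotation, c("T3", "T1", "T2"))
  expect_identical(f2$bary[, c("T1", "T2", "T3")],
                   f1$bary[, c("T1", "T2", "T3")])
})

test_that("permuting cell order permutes coordinate rows identically", {
  sim <- simulate_fate_data(cells_per_cluster = 20, n_progenitors = 10,
                            n_features = 60, seed = 43)
  f1 <- map_cell_fates(sim$counts, sim$annotation, c("T1", "T2", "T3"))
  perm <- withr::with_seed(2, sample(ncol(sim$counts)))
  f2 <- map_cell_fates(sim$counts[, perm], sim$annotation[perm, ],
                       c("T1", "T2", "T3"))
  expect_equal(f2$bary[rownames(f1$bary), ], f1$bary, tolerance = 1e-12)
})

test_that("moving a cell toward a vertex never lowers that coordinate", {
  # perturb one cell's distances directly through the scalar chain, holding
  # every other cell fixed
  withr::with_seed(7, {
    D <- matrix(runif(30, 0.2, 2), 10, 3)
    run <- function(D) {
      l1_normalize(range_scale(gaussian_similarity(row_normalize_distances(D))))
    }
    base <- run(D)
    for (step in c(0.9, 0.7, 0.5)) {
      D2 <- D
      D2[4, 2] <- D[4, 2] * step
      expect_gte(run(D2)[4, 2], base[4, 2] - 1e-12)
    }
  })
})
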
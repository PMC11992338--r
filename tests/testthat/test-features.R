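test_that("normalize_counts scales each cell to the target total", {
  m <- tiny_counts(c(1, 1, 2), 3, 1)
  out <- normalize_counts(m, log_transform = FALSE)
  expect_equal(as.numeric(out), c(2500, 2500, 5000))
})

test_that("all-zero cells pass through with a warning", {
  m <- tiny_counts(c(1, 2, 0, 0), 2, 2)
  expect_warning(out <- normalize_counts(m, log_transform = FALSE),
                 "all-zero")
  expect_equal(as.numeric(out[, 2]), c(0, 0))
})

test_that("normalized column sums are the scale factor or zero", {
  m <- random_counts(30, 20, seed = 8)
  m[, 3] <- 0
  suppressWarnings(out <- normalize_counts(m, log_transform = FALSE))
  cs <- Matrix::colSums(out)
  expect_true(all(abs(cs - 1e4) < 1e-8 | cs == 0))
  # log1p path transforms every stored value
  suppressWarnings(lout <- normalize_counts(m, log_transform = TRUE))
  expect_equal(as.matrix(lout), log1p(as.matrix(out)), tolerance = 1e-12)
})

test_that("rank-sum statistic and approximate p match independent references", {
  # separated groups: in-group ranks 4,5,6 sum to 15
  x <- c(5, 6, 7, 1, 2, 3)
  grp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- fatesimplex:::wilcoxon_rank_sum(x, grp)
  expect_equal(unname(res["statistic"]), 15)
  ref <- suppressWarnings(
    stats::wilcox.test(x[grp], x[!grp], exact = FALSE, correct = TRUE))
  expect_equal(unname(res["statistic"]) - 3 * 4 / 2,
               unname(ref$statistic))
  expect_equal(unname(res["p_value"]), ref$p.value, tolerance = 1e-12)
  # exhaustive permutation reference is close at these sizes
  expect_lt(abs(res["p_value"] - exact_rank_sum_p(x, grp)), 0.1)
})

test_that("a feature identical in both groups is never a marker", {
  counts <- rbind(flat = rep(4, 6), up = c(9, 8, 9, 1, 1, 2))
  colnames(counts) <- paste0("c", 1:6)
  ann <- make_ann(colnames(counts), rep(c("A", "B"), each = 3))
  res <- fatesimplex:::wilcoxon_rank_sum(counts["flat", ], ann$cluster == "A")
  expect_equal(unname(res["p_value"]), 1)
  mk <- rank_markers(counts, ann, c("A", "B"), top_k = 2)
  expect_false("flat" %in% mk$feature)
  expect_true("up" %in% mk$feature[mk$terminal == "A"])
})

test_that("top_k beyond the feature count warns and keeps all positive markers", {
  counts <- rbind(a = c(5, 6, 1, 2), b = c(1, 2, 7, 8))
  colnames(counts) <- paste0("c", 1:4)
  ann <- make_ann(colnames(counts), rep(c("A", "B"), each = 2))
  expect_warning(mk <- rank_markers(counts, ann, c("A", "B"), top_k = 10),
                 "exceeds")
  expect_true(all(mk$log2_fc > 0))
  expect_lte(max(table(mk$terminal)), 2)
})

test_that("a terminal cluster with fewer than 2 cells errors by name", {
  counts <- tiny_counts(1:6, 2, 3)
  ann <- make_ann(colnames(counts), c("A", "B", "B"))
  expect_error(rank_markers(counts, ann, c("A", "B")), "'A'")
})

test_that("marker selection ignores non-terminal cells entirely", {
  sim <- simulate_fate_data(cells_per_cluster = 20, n_progenitors = 15,
                            n_features = 60, seed = 21)
  norm <- suppressWarnings(normalize_counts(sim$counts))
  mk1 <- rank_markers(norm, sim$annotation, c("T1", "T2", "T3"), top_k = 10)
  relabeled <- sim$annotation
  relabeled$cluster[relabeled$cluster == "Progenitor"] <-
    rep(c("Junk1", "Junk2"), length.out = sum(relabeled$cluster == "Progenitor"))
  mk2 <- rank_markers(norm, relabeled, c("T1", "T2", "T3"), top_k = 10)
  expect_equal(mk1, mk2)
})

test_that("marker selection is invariant to cell order", {
  sim <- simulate_fate_data(cells_per_cluster = 15, n_progenitors = 0,
                            n_features = 50, seed = 22)
  norm <- normalize_counts(sim$counts)
  perm <- withr::with_seed(1, sample(ncol(norm)))
  mk1 <- rank_markers(norm, sim$annotation, c("T1", "T2", "T3"), top_k = 10)
  mk2 <- rank_markers(norm[, perm], sim$annotation[perm, ],
                      c("T1", "T2", "T3"), top_k = 10)
  expect_equal(mk1, mk2)
})

test_that("strong simulated markers are recovered at the top of each list", {
  sim <- simulate_fate_data(cells_per_cluster = 40, n_progenitors = 0,
                            n_features = 100, markers_per_cluster = 8,
                            marker_effect = 6, seed = 23)
  norm <- normalize_counts(sim$counts)
  mk <- rank_markers(norm, sim$annotation, sim$ground_truth$terminals,
                     top_k = 8)
  for (t in sim$ground_truth$terminals) {
    expect_setequal(mk$feature[mk$terminal == t],
                    sim$ground_truth$marker_blocks[[t]])
  }
})

test_that("PCA embedding captures rank-1 data in one component", {
  # 3 features, cells on a line
  s <- seq(0, 1, length.out = 10)
  m <- rbind(1 + 2 * s, 3 - s, 2 + 4 * s)
  dimnames(m) <- list(paste0("g", 1:3), paste0("c", 1:10))
  emb <- embed_pca(m, 1)
  expect_identical(dim(emb), c(1L, 10L))
  # all pairwise distances preserved by the single component
  expect_equal(as.matrix(dist(t(emb))), as.matrix(dist(t(m))),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(embed_pca(m, 3), "rank")
})

test_that("full-rank PCA preserves pairwise cell distances", {
  m <- withr::with_seed(13, matrix(rnorm(10 * 30), 10, 30,
                                   dimnames = list(paste0("g", 1:10),
                                                   paste0("c", 1:30))))
  emb <- embed_pca(m, 10)
  expect_equal(as.matrix(dist(t(emb))), as.matrix(dist(t(m))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA component variances are non-increasing and signs deterministic", {
  m <- random_counts(20, 50, seed = 31)
  emb <- embed_pca(m, 5)
  vars <- apply(emb, 1, stats::var)
  expect_true(all(diff(vars) <= 1e-10))
  # sign convention: the largest-magnitude loading of each PC is positive,
  # so repeated runs and sign-flipped inputs agree
  expect_identical(emb, embed_pca(m, 5))
})
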
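# Synthetic-data generator with known ground truth: terminal clusters with
# disjoint marker blocks, multipotent progenitors drawn from a mixture of
# the terminal mean profiles, and a transition graph whose edge mass into
# each terminal is proportional to the mixture weights. Emulates, at desk
# scale, a stromal-tissue setup of terminal fates surrounding a multipotent
# cluster expected to land in the middle of the simplex.

#' Simulate counts, annotation, and a transition graph with ground truth
#'
#' Each terminal cluster's cells are drawn around a flat base expression
#' rate, uplifted by `marker_effect` on that cluster's own block of marker
#' features. Progenitor cells are drawn from the mixture of the terminal
#' mean profiles weighted by `progenitor_mixture`. The transition graph
#' gives every progenitor outgoing edges to a random half of each terminal
#' cluster with total edge mass proportional to the mixture weight for that
#' fate; terminal cells get unit edge mass into their own cluster
#' (self-renewal). Counts are integer (Poisson or negative binomial) so the
#' sparse-integer code paths real droplet data exercises are stressed.
#'
#' @param n_terminals Number of terminal clusters (2-4); default 3.
#' @param cells_per_cluster Cells in each terminal cluster; default 100.
#' @param n_progenitors Progenitor cells; default 100 (0 allowed).
#' @param n_features Total features; default 200.
#' @param markers_per_cluster Marker-block size per terminal; default 10.
#' @param marker_effect Mean count uplift on a cluster's own markers;
#'   default 5 (over `base_rate` 1, i.e. a sixfold mean increase).
#' @param base_rate Baseline mean count per feature; default 1.
#' @param noise `"poisson"` (default) or `"nb"` (negative binomial).
#' @param dispersion NB size parameter when `noise = "nb"`; default 2.
#' @param progenitor_mixture Non-negative weights of length `n_terminals`
#'   summing to 1; default uniform.
#' @param seed Integer seed; the whole fixture is reproducible from it.
#' @return A list: `counts` (sparse `dgCMatrix`, features x cells),
#'   `annotation` (tibble barcode/cluster; terminal labels `T1..Tn`,
#'   progenitors `Progenitor`), `graph` (sparse cells x cells), and
#'   `ground_truth` (marker blocks, mixture, rates).
#' @export
simulate_fate_data <- function(n_terminals = 3, cells_per_cluster = 100,
                               n_progenitors = 100, n_features = 200,
                               markers_per_cluster = 10, marker_effect = 5,
                               base_rate = 1, noise = c("poisson", "nb"),
                               dispersion = 2, progenitor_mixture = NULL,
                               seed = NULL) {
  noise <- match.arg(noise)
  if (!n_terminals %in% 2:4) stop_validation("n_terminals must be 2-4")
  if (n_features < n_terminals * markers_per_cluster) {
    stop_validation("n_features must accommodate all marker blocks")
  }
  mixture <- progenitor_mixture %||% rep(1 / n_terminals, n_terminals)
  if (length(mixture) != n_terminals || any(mixture < 0) ||
      abs(sum(mixture) - 1) > 1e-9) {
    stop_validation("progenitor_mixture must be non-negative and sum to 1")
  }
  run <- function() {
    terminals <- paste0("T", seq_len(n_terminals))
    C <- n_terminals * cells_per_cluster + n_progenitors
    barcodes <- sprintf("cell_%04d", seq_len(C))
    features <- sprintf("gene_%04d", seq_len(n_features))
    cluster <- c(rep(terminals, each = cells_per_cluster),
                 rep("Progenitor", n_progenitors))
    blocks <- lapply(seq_len(n_terminals), function(n) {
      ((n - 1) * markers_per_cluster + 1):(n * markers_per_cluster)
    })
    names(blocks) <- terminals
    mu <- matrix(base_rate, n_features, n_terminals)
    for (n in seq_len(n_terminals)) {
      mu[blocks[[n]], n] <- base_rate + marker_effect
    }
    mu_prog <- as.numeric(mu %*% mixture)
    cell_mu <- cbind(mu[, rep(seq_len(n_terminals), each = cells_per_cluster),
                        drop = FALSE],
                     matrix(rep(mu_prog, n_progenitors), n_features,
                            n_progenitors))
    draw <- if (noise == "poisson") {
      function(m) rpois(length(m), m)
    } else {
      function(m) rnbinom(length(m), size = dispersion, mu = m)
    }
    counts <- matrix(draw(cell_mu), n_features, C,
                     dimnames = list(features, barcodes))
    counts <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

    # transition graph: progenitor edge mass per fate proportional to the
    # mixture; terminal cells self-renew into their own cluster
    src <- integer(0); dst <- integer(0); wts <- numeric(0)
    cluster_idx <- lapply(terminals, function(t) which(cluster == t))
    names(cluster_idx) <- terminals
    add_edges <- function(from, targets, mass) {
      if (mass <= 0 || length(targets) == 0) return(NULL)
      k <- max(1L, floor(length(targets) / 2))
      chosen <- sample(targets, k)
      w <- runif(k)
      list(from = rep.int(from, k), to = chosen, w = w / sum(w) * mass)
    }
    prog_idx <- which(cluster == "Progenitor")
    for (c0 in prog_idx) {
      for (n in seq_len(n_terminals)) {
        e <- add_edges(c0, cluster_idx[[n]], mixture[n])
        if (!is.null(e)) {
          src <- c(src, e$from); dst <- c(dst, e$to); wts <- c(wts, e$w)
        }
      }
    }
    for (n in seq_len(n_terminals)) {
      for (c0 in cluster_idx[[n]]) {
        e <- add_edges(c0, setdiff(cluster_idx[[n]], c0), 1)
        if (!is.null(e)) {
          src <- c(src, e$from); dst <- c(dst, e$to); wts <- c(wts, e$w)
        }
      }
    }
    graph <- sparseMatrix(i = src, j = dst, x = wts, dims = c(C, C),
                          dimnames = list(barcodes, barcodes))
    list(
      counts = counts,
      annotation = tibble(barcode = barcodes, cluster = cluster),
      graph = graph,
      ground_truth = list(
        terminals = terminals,
        marker_blocks = lapply(blocks, function(b) features[b]),
        mixture = mixture,
        base_rate = base_rate,
        marker_effect = marker_effect,
        noise = noise))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write a simulated fixture to disk in the formats the readers consume
#'
#' Writes `matrix.mtx` (+ sibling `features.tsv`/`barcodes.tsv`),
#' `annotation.tsv`, `graph.mtx`, and `ground_truth.json` into `dir`.
#'
#' @param sim List from [simulate_fate_data()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_matrix(sim$counts, file.path(dir, "matrix.mtx"))
  write_cell_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_transition_graph(sim$graph, file.path(dir, "graph.mtx"))
  jsonlite::write_json(sim$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
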
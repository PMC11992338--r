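# Count normalization and feature-subspace selection: per-fate marker genes
# ranked by Wilcoxon rank-sum test, or a PCA embedding as the alternative.

#' Depth-normalize a count matrix
#'
#' Scales every cell (column) to a constant total of `scale_factor` counts,
#' then optionally applies `log(1 + x)`. Euclidean distances on raw counts
#' are dominated by sequencing depth, so this is applied before marker
#' testing and distance computation by default. All-zero cells pass through
#' as zeros with a warning.
#'
#' @param counts Non-negative feature-by-cell matrix.
#' @param scale_factor Target column total; default 10,000 (counts per ten
#'   thousand, the de-facto single-cell convention).
#' @param log_transform Apply `log1p` after scaling? Default TRUE.
#' @return A matrix of the same class and dimnames as `counts`.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4, log_transform = TRUE) {
  validate_expression_matrix(counts)
  cs <- Matrix::colSums(counts)
  if (any(cs == 0)) {
    warn(sprintf("normalize_counts: %d all-zero cell(s) left as zeros", sum(cs == 0)))
  }
  mult <- ifelse(cs > 0, scale_factor / cs, 0)
  if (is(counts, "sparseMatrix")) {
    out <- as(counts, "CsparseMatrix")
    out@x <- out@x * rep.int(mult, diff(out@p))
    if (log_transform) out@x <- log1p(out@x)
  } else {
    out <- sweep(counts, 2, mult, "*")
    if (log_transform) out <- log1p(out)
  }
  out
}

# Rank-sum statistic (sum of in-group ranks, midranks for ties) and
# two-sided p-value from the normal approximation with tie-corrected
# variance and continuity correction. Identical groups give p = 1.
wilcoxon_rank_sum <- function(x, in_group) {
  n1 <- sum(in_group)
  n <- length(x)
  n2 <- n - n1
  r <- rank(x)
  stat <- sum(r[in_group])
  mu <- n1 * (n + 1) / 2
  tie_tab <- table(x)
  tie_corr <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr / (n * (n - 1)))
  if (sigma2 <= 0) {
    p <- 1
  } else {
    d <- stat - mu
    z <- sign(d) * max(0, abs(d) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  c(statistic = stat, p_value = p)
}

#' Rank marker genes for each terminal fate by Wilcoxon rank-sum test
#'
#' For each terminal cluster, tests every feature in the cells of that
#' cluster against the cells of the other chosen terminal clusters
#' (one-vs-rest-of-terminals; non-terminal cells never enter the test), with
#' a two-sided normal approximation using midranks, tie-corrected variance,
#' and continuity correction. Features are ranked by ascending p-value, ties
#' broken by descending log2 fold change then feature id, and the top `top_k`
#' features with strictly positive log2 fold change are kept as that fate's
#' markers. The union of all fates' markers is the feature subspace used for
#' centroid distances downstream.
#'
#' @param counts Normalized feature-by-cell matrix (see [normalize_counts()]).
#' @param annotation Data frame with `barcode`, `cluster` aligned to
#'   `counts` columns.
#' @param terminals Character vector of 2-4 terminal cluster labels.
#' @param top_k Markers kept per fate; default 30.
#' @return A tibble with columns `terminal`, `rank`, `feature`, `statistic`
#'   (rank-sum of the in-group), `p_value`, `log2_fc` (pseudocount 1e-9),
#'   sorted within terminal by the selection order.
#' @export
rank_markers <- function(counts, annotation, terminals, top_k = 30) {
  validate_expression_matrix(counts)
  ann <- as_cell_annotation(annotation)
  check_terminals(terminals, ann)
  if (top_k < 1) stop_validation("top_k must be a positive integer")
  in_terminal <- ann$cluster %in% terminals
  labels <- ann$cluster[in_terminal]
  for (t in terminals) {
    if (sum(labels == t) < 2) {
      stop_validation(paste0("terminal cluster '", t, "' has fewer than 2 cells"))
    }
  }
  if (top_k > nrow(counts)) {
    warn(sprintf("top_k = %d exceeds the %d available features; keeping all positive-fold-change features",
                 top_k, nrow(counts)))
    top_k <- nrow(counts)
  }
  X <- as.matrix(counts[, in_terminal, drop = FALSE])
  feats <- rownames(counts)
  purrr::map_dfr(terminals, function(t) {
    grp <- labels == t
    res <- vapply(seq_len(nrow(X)),
                  function(i) wilcoxon_rank_sum(X[i, ], grp),
                  c(statistic = 0, p_value = 0))
    mean_in <- rowMeans(X[, grp, drop = FALSE])
    mean_out <- rowMeans(X[, !grp, drop = FALSE])
    lfc <- log2((mean_in + 1e-9) / (mean_out + 1e-9))
    tab <- tibble(terminal = t, feature = feats,
                  statistic = res["statistic", ],
                  p_value = res["p_value", ],
                  log2_fc = lfc)
    tab <- tab[order(tab$p_value, -tab$log2_fc, tab$feature), ]
    tab <- tab[tab$log2_fc > 0, , drop = FALSE]
    tab <- head(tab, top_k)
    tab$rank <- seq_len(nrow(tab))
    tab[, c("terminal", "rank", "feature", "statistic", "p_value", "log2_fc")]
  })
}

#' Feature subspace defined by a marker table
#'
#' Union of all terminals' selected markers, returned in the row order of
#' the matrix they were selected from (so the subspace is invariant to the
#' order terminals were listed in).
#'
#' @param markers Tibble from [rank_markers()].
#' @param feature_ids Full feature-id vector giving the canonical order.
#' @return Character vector of feature ids.
#' @export
marker_features <- function(markers, feature_ids) {
  feature_ids[feature_ids %in% unique(markers$feature)]
}

#' Write a marker table as TSV
#'
#' @param markers Tibble from [rank_markers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  readr::write_tsv(markers, path, col_names = TRUE)
  invisible(path)
}

#' Embed cells on principal components
#'
#' The alternative to marker selection: cells are represented by their
#' scores on the top principal components of the feature-centered matrix
#' (centering only, no scaling). The sign of each component is fixed so its
#' largest-magnitude loading is positive, making the embedding
#' deterministic. Downstream distance computation treats the embedding
#' exactly like a (components x cells) expression matrix.
#'
#' @param counts Feature-by-cell matrix (normalized or raw).
#' @param n_components Number of components; must not exceed the matrix
#'   numerical rank.
#' @return A dense `n_components x cells` matrix, rows `PC1..PCk`, columns
#'   the barcodes.
#' @export
embed_pca <- function(counts, n_components) {
  # unlike counts, the input here may legitimately be signed (e.g. already
  # centered), so only finiteness and identifiers are checked
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_validation("matrix must carry feature ids (rownames) and barcodes (colnames)")
  }
  vals <- if (is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop_validation("matrix contains NA or non-finite entries")
  }
  if (n_components < 1 || n_components > min(dim(counts))) {
    stop_validation(sprintf("n_components must be in [1, %d]", min(dim(counts))))
  }
  X <- base::t(as.matrix(counts)) # cells x features
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  rank_tol <- pc$sdev[1] * 1e-8
  eff_rank <- sum(pc$sdev > rank_tol)
  if (n_components > eff_rank) {
    stop_validation(sprintf("n_components = %d exceeds the matrix rank (%d)",
                            n_components, eff_rank))
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # deterministic sign: each component's largest-magnitude loading positive
  flip <- vapply(seq_len(n_components),
                 function(j) sign(load[which.max(abs(load[, j])), j]),
                 numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, "*")
  emb <- base::t(scores)
  dimnames(emb) <- list(paste0("PC", seq_len(n_components)), colnames(counts))
  emb
}

check_terminals <- function(terminals, ann) {
  terminals <- as.character(terminals)
  if (length(terminals) < 2 || length(terminals) > 4) {
    stop_validation("between 2 and 4 terminal labels are supported")
  }
  if (anyDuplicated(terminals)) stop_validation("terminal labels must be distinct")
  missing <- setdiff(terminals, unique(ann$cluster))
  if (length(missing)) {
    stop_validation(paste0("terminal label(s) not present in annotation: ",
                           paste(missing, collapse = ", ")))
  }
  terminals
}
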
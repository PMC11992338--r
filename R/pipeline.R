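# End-to-end run: read inputs, fit the simplex map, write coordinate /
# marker / velocity tables, the plot, and a JSON run manifest. This is the
# surface the command-line wrapper (inst/cli/fatesimplex.R) drives.

default_run_config <- function() {
  list(matrix = NULL, annotation = NULL, graph = NULL,
       terminals = NULL, method = "markers", top_k = 30,
       n_components = 10, sigma = 0.08, normalize = TRUE,
       grid_resolution = 10, arrow_max_len = 0.15,
       plot_format = "png", dpi = 150, seed = 1,
       out_dir = NULL)
}

#' Run the full fate-simplex pipeline from a configuration
#'
#' Reads the count matrix, annotation, and optional transition graph,
#' aligns them, fits [map_cell_fates()], and writes into `out_dir`:
#' `coordinates.tsv`, `markers.tsv` (marker method only), `velocity.tsv`
#' (graph supplied only), a plot file, and `manifest.json` recording every
#' parameter and the package version so the run is reproducible from the
#' manifest alone. Any stage failure removes the partial outputs and
#' re-raises with the stage name.
#'
#' @param config A named list, or a path to a JSON file with the same
#'   fields: `matrix`, `annotation`, optional `graph` (file paths),
#'   `terminals` (2-4 labels), `method` ("markers"/"pca"), `top_k`,
#'   `n_components`, `sigma`, `normalize`, `grid_resolution`,
#'   `arrow_max_len`, `plot_format` ("png"/"pdf"/"svg"), `dpi`, `seed`,
#'   `out_dir`.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_run_config(), as.list(config))
  for (req in c("matrix", "annotation", "terminals", "out_dir")) {
    if (is.null(cfg[[req]])) stop_validation(paste0("config field missing: ", req))
  }
  if (length(cfg$terminals) < 2 || length(cfg$terminals) > 4) {
    stop_validation("between 2 and 4 terminal labels are supported")
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "': ", conditionMessage(e)),
            class = "fatesimplex_error_pipeline", parent = e)
    })
  }
  set.seed(cfg$seed)

  counts <- stage("read-matrix", read_expression_matrix(cfg$matrix))
  ann <- stage("read-annotation", read_cell_annotation(cfg$annotation))
  graph <- if (!is.null(cfg$graph)) {
    stage("read-graph", read_transition_graph(cfg$graph, colnames(counts)))
  } else NULL

  fit <- stage("fit", map_cell_fates(
    counts, ann, cfg$terminals, graph = graph, method = cfg$method,
    top_k = cfg$top_k, n_components = cfg$n_components, sigma = cfg$sigma,
    normalize = cfg$normalize, grid_resolution = cfg$grid_resolution))

  out <- function(f) file.path(cfg$out_dir, f)
  stage("write-coordinates", {
    write_coordinates(fit, out("coordinates.tsv"))
    written <<- c(written, out("coordinates.tsv"))
  })
  if (!is.null(fit$markers)) {
    stage("write-markers", {
      write_marker_table(fit$markers, out("markers.tsv"))
      written <<- c(written, out("markers.tsv"))
    })
  }
  if (!is.null(fit$field)) {
    stage("write-velocity", {
      write_velocity_field(fit$field, out("velocity.tsv"))
      written <<- c(written, out("velocity.tsv"))
    })
  }
  plot_file <- out(paste0("simplex.", cfg$plot_format))
  stage("plot", {
    p <- autoplot(fit, arrow_max_len = cfg$arrow_max_len)
    if (inherits(p, "list")) p <- p[[1]]
    ggplot2::ggsave(plot_file, p, width = 6, height = 5, dpi = cfg$dpi)
    written <<- c(written, plot_file)
  })
  stage("manifest", {
    manifest <- c(cfg[setdiff(names(cfg), "out_dir")],
                  list(out_dir = cfg$out_dir,
                       package_version = as.character(packageVersion("fatesimplex")),
                       n_cells = nrow(fit$coords),
                       n_features_used = unname(glance(fit)$n_features)))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <<- c(written, out("manifest.json"))
  })
  ok <- TRUE
  invisible(cfg$out_dir)
}
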
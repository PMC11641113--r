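# End-to-end pipeline: synthetic generation or STAR input -> lattice graph
# -> curvature -> axis angle -> census, with a consolidated JSON report and
# a deterministic markdown summary.

#' Assemble a pipeline configuration
#'
#' Exactly one particle source must be given: a synthetic lattice spec or
#' an input STAR file. Stage toggles select which analyses run; the census
#' runs on the configured cell geometry (or, for synthetic input, the
#' generator's geometry).
#'
#' @param synthetic A [lattice_spec()] (optionally with an
#'   `envelope = envelope_spec()` attached in a list:
#'   `list(lattice = ..., envelope = ...)`).
#' @param input List `list(star = path, pixel_size = ..., truth = path)`
#'   describing an externally produced particle table.
#' @param stages Character subset of
#'   `c("graph", "curvature", "axis", "census")`.
#' @param seed Integer seed recorded in the report and used for any
#'   stage-level randomness.
#' @param tol_fraction Neighbour window for [build_graph()].
#' @param curvature_threshold Threshold (1/nm) for [classify_particles()];
#'   default `0.5 / (2 * R_fit)` from the cylinder fit.
#' @param bins Histogram bins for [aggregate_angles()].
#' @param min_edges Minimum class-1 edges per cell for the angle stage.
#' @param geometry A [cell_geometry()] for the census stage.
#' @param pores A [pore_spec()] for the census stage.
#' @param dimple_model Dimple-surface model name.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input = NULL,
                            stages = c("graph", "curvature", "axis", "census"),
                            seed = 1L, tol_fraction = 0.2,
                            curvature_threshold = NULL,
                            bins = seq(0, 30, by = 1), min_edges = 10,
                            geometry = cell_geometry(), pores = pore_spec(),
                            dimple_model = "sinusoidal") {
  if (is.null(synthetic) == is.null(input))
    stop("exactly one of 'synthetic' or 'input' must be provided")
  stages <- match.arg(stages, c("graph", "curvature", "axis", "census"),
                      several.ok = TRUE)
  if (!is.null(synthetic) && inherits(synthetic, "lattice_spec"))
    synthetic <- list(lattice = synthetic)
  structure(list(synthetic = synthetic, input = input, stages = stages,
                 seed = as.integer(seed), tol_fraction = tol_fraction,
                 curvature_threshold = curvature_threshold, bins = bins,
                 min_edges = min_edges, geometry = geometry, pores = pores,
                 dimple_model = dimple_model),
            class = "pipeline_config")
}

#' Run the full lattice-analysis pipeline
#'
#' Executes the configured stages, writes per-stage tables (STAR particle
#' file, edge/node TSVs, curvature TSV, subset STAR files) plus a
#' consolidated versioned JSON report under `out_dir`, and returns the
#' report. Runs are idempotent for a fixed config: the report payload
#' contains no timestamps, and its config hash identifies the run.
#'
#' @param config A [pipeline_config()] (or a YAML file path readable into
#'   one: top-level keys mirroring the constructor arguments).
#' @param out_dir Output directory (created if needed).
#' @return The report, a list of class `pipeline_report`, invisibly also
#'   written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("slayermap_run_")) {
  if (is.character(config)) config <- config_from_yaml(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(schema_version = 1L,
                 package = "slayermap",
                 version = as.character(utils::packageVersion("slayermap")),
                 seed = config$seed,
                 config_hash = rlang::hash(unclass(config)),
                 stages = character())
  stage <- function(name, expr) {
    message(sprintf("[slayermap] stage %-10s starting", name))
    res <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[slayermap] stage %-10s done", name))
    res
  }

  particles <- stage("particles", {
    if (!is.null(config$synthetic)) {
      generate_cylinder_lattice(config$synthetic$lattice)
    } else {
      read_particles(config$input$star, pixel_size = config$input$pixel_size,
                     truth_path = config$input$truth)
    }
  })
  write_particles(particles, file.path(out_dir, "particles.star"),
                  pixel_size = 10,
                  truth_path = file.path(out_dir, "particle_truth.tsv"))
  report$particles <- list(n = nrow(particles),
                           n_cells = length(unique(particles$cell_id)))

  graph <- NULL
  fit <- NULL
  if (any(c("graph", "curvature", "axis") %in% config$stages)) {
    graph <- stage("graph", {
      a_est <- estimate_unit_distance(particles)
      g <- build_graph(particles, a_est, tol_fraction = config$tol_fraction)
      fit <- tryCatch(fit_cylinder(particles), error = function(e) NULL)
      assign_edge_directions(g, fit = fit)
    })
    utils::write.table(as.data.frame(graph$edges),
                       file.path(out_dir, "edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(graph$nodes),
                       file.path(out_dir, "nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    defects <- detect_defects(graph)
    report$graph <- list(
      a_est = graph$a_est, n_edges = nrow(graph$edges),
      n_defects = nrow(defects),
      coordination_table = as.list(table(graph$nodes$coordination)),
      cylinder_fit = if (!is.null(fit))
        list(radius = fit$radius, rms_residual = fit$rms_residual,
             axis_direction = fit$axis_direction) else NULL)
  }

  if ("curvature" %in% config$stages) {
    curv <- stage("curvature", estimate_curvature(particles, a_est = graph$a_est))
    thr <- config$curvature_threshold %||%
      if (!is.null(fit)) curvature_threshold(fit) else
        stats::median(abs(curv$mean_curvature), na.rm = TRUE)
    part <- classify_particles(curv, thr)
    utils::write.table(as.data.frame(curv), file.path(out_dir, "curvature.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (w in c("curved", "flat")) {
      sub <- suppressWarnings(export_subset(particles, part, w))
      write_particles(sub, file.path(out_dir, paste0(w, "_particles.star")),
                      pixel_size = 10)
    }
    report$curvature <- list(
      threshold = thr, n_curved = part$n_curved, n_flat = part$n_flat,
      n_invalid = part$n_invalid,
      median_mean_curvature = stats::median(curv$mean_curvature, na.rm = TRUE))
  }

  if ("axis" %in% config$stages) {
    angles <- stage("axis", {
      pc <- direction1_angle(graph, fit = fit, min_edges = config$min_edges)
      aggregate_angles(pc, bins = config$bins)
    })
    utils::write.table(as.data.frame(angles$per_cell),
                       file.path(out_dir, "angles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$axis <- list(mean_angle = angles$mean_angle,
                        n_cells = angles$n_cells,
                        per_cell = angles$per_cell,
                        histogram = angles$histogram)
  }

  if ("census" %in% config$stages) {
    census <- stage("census", run_census(config$geometry, config$pores,
                                         dimple_model = config$dimple_model))
    report$census <- unclass(census)
  }

  report$stages <- intersect(c("graph", "curvature", "axis", "census"),
                             config$stages)
  class(report) <- "pipeline_report"
  jsonlite::write_json(unclass_deep(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_summary(report), file.path(out_dir, "summary.md"))
  invisible(report)
}

# Strip S3 classes recursively so jsonlite serialises plain lists/frames.
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic))
    args$synthetic <- list(lattice = do.call(lattice_spec, y$synthetic))
  if (!is.null(y$input)) args$input <- y$input
  for (k in c("stages", "seed", "tol_fraction", "curvature_threshold",
              "bins", "min_edges", "dimple_model"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$geometry)) args$geometry <- do.call(cell_geometry, y$geometry)
  if (!is.null(y$pores)) args$pores <- do.call(pore_spec, y$pores)
  do.call(pipeline_config, args)
}

#' Render a human-readable summary of a pipeline report
#'
#' Pure function of the report: regenerating the summary from the saved
#' JSON reproduces it exactly.
#'
#' @param report A `pipeline_report` (or path to a saved `report.json`).
#' @return Character vector of markdown lines.
#' @export
render_summary <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report, simplifyVector = TRUE)
  fmtn <- function(x) format(round(x), big.mark = ",", scientific = FALSE, trim = TRUE)
  out <- c("# S-layer lattice analysis summary", "",
           sprintf("- package: slayermap %s", report$version),
           sprintf("- seed: %d | config hash: %s", report$seed, report$config_hash),
           sprintf("- particles: %s in %d cell(s)", fmtn(report$particles$n),
                   report$particles$n_cells), "")
  if (!is.null(report$graph)) {
    out <- c(out, "## Lattice graph", "",
             sprintf("- unit distance estimate: %.3f nm", report$graph$a_est),
             sprintf("- edges: %s | interior coordination defects: %s",
                     fmtn(report$graph$n_edges), fmtn(report$graph$n_defects)))
    if (!is.null(report$graph$cylinder_fit))
      out <- c(out, sprintf("- cylinder fit: radius %.2f nm, rms residual %.3f nm",
                            report$graph$cylinder_fit$radius,
                            report$graph$cylinder_fit$rms_residual))
    out <- c(out, "")
  }
  if (!is.null(report$curvature)) {
    out <- c(out, "## Curvature partition", "",
             sprintf("- threshold: %.5f /nm", report$curvature$threshold),
             sprintf("- curved: %s | flat: %s | invalid: %s",
                     fmtn(report$curvature$n_curved), fmtn(report$curvature$n_flat),
                     fmtn(report$curvature$n_invalid)), "")
  }
  if (!is.null(report$axis)) {
    out <- c(out, "## Direction-1 / cell-axis angle", "")
    pc <- report$axis$per_cell
    if (is.null(pc) || NROW(pc) == 0) {
      out <- c(out, "- no valid cells", "")
    } else {
      pc <- as.data.frame(pc)
      out <- c(out,
               sprintf("- mean angle over %d cell(s): %.2f deg",
                       report$axis$n_cells, report$axis$mean_angle),
               "", "| cell | angle (deg) | edges |", "|---|---|---|",
               sprintf("| %s | %.2f | %d |", pc$cell_id, pc$angle_deg,
                       pc$n_edges_used), "")
    }
  }
  if (!is.null(report$census)) {
    cs <- report$census
    out <- c(out, "## Geometric census", "",
             sprintf("- repeats: %d axial x %d circumferential",
                     cs$n_axial, cs$n_circumferential),
             sprintf("- %s hexamers / %s monomers",
                     fmtn(cs$n_hexamers), fmtn(cs$n_monomers)),
             sprintf("- pores: %.1f per hexamer, %s per cell",
                     cs$pores_per_hexamer, fmtn(cs$n_pores_cell)),
             sprintf("- SA/V ratio vs equal-volume sphere: %.3f", cs$sa_v_ratio),
             sprintf("- dimple area factor: %.3f (%s model)",
                     cs$dimple_area_factor, cs$dimple_model), "")
  }
  out
}
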
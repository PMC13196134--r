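# Per-specimen orchestration: build -> sweep -> disarticulation filter ->
# inclusion check -> cosine correction -> alpha shape -> moment arms ->
# torsion -> architecture, with stage-level logging and provenance, plus a
# fault-tolerant batch driver.

.stage_log <- function(enabled, stage, fmt, ...) {
  if (enabled) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Validate a specimen configuration
#'
#' A configuration is a named list (or YAML file) with:
#' * `specimen`: identifier.
#' * `model`: a `joint_model`, or `generator` (list with `type`
#'   `"ball_socket"`, `"saddle"` or `"two_pose"` plus generator arguments),
#'   or `meshes` (list with `proximal`/`distal` paths) together with
#'   numeric `cor_sphere`, `gap_sphere` (center, radius), `jcs_axes`,
#'   `metatarsal_frame` (origin + axes) and `convention`.
#' * `grid`: optional list `fe_range`, `abad_range`, `ie_range`, `step`.
#' * `disarticulation`: optional `z_positive_max` / `z_negative_min`.
#' * `min_viable` (default 4), `alpha_floor` (default 50).
#' * `muscles`: optional list of lists (`name`, `origin`, `insertion`,
#'   `length_mm`) evaluated for moment arms.
#' * `scale`: optional list `a_mm`, `b_model` (default 1/1).
#' * `torsion`: optional list passed to [measure_metatarsal_torsion()].
#' * `architecture`: optional data frame for [architecture_table()].
#' * `out_dir`: optional output directory for CSV/JSON artifacts.
#'
#' @param config list or path to a YAML file.
#' @return The validated config list.
#' @export
validate_specimen_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path")
  if (is.null(config$specimen)) stop("config$specimen is required")
  if (is.null(config$model) && is.null(config$generator) &&
      is.null(config$meshes)) {
    stop("config needs one of: model, generator, meshes")
  }
  if (!is.null(config$meshes)) {
    for (p in unlist(config$meshes)) {
      if (!file.exists(p)) stop("mesh file not found: ", p)
    }
    for (field in c("cor_sphere", "gap_sphere", "jcs_axes",
                    "metatarsal_frame", "convention")) {
      if (is.null(config[[field]])) {
        stop("mesh-based config requires field: ", field)
      }
    }
  }
  grid <- config$grid %||% list()
  config$grid <- list(fe_range = grid$fe_range %||% 270,
                      abad_range = grid$abad_range %||% 180,
                      ie_range = grid$ie_range %||% 180,
                      step = grid$step %||% 5)
  if (!is.null(config$disarticulation)) {
    zp <- config$disarticulation$z_positive_max
    zn <- config$disarticulation$z_negative_min
    if (!is.null(zp) && abs(zp) > config$grid$fe_range / 2) {
      stop("disarticulation threshold outside grid range")
    }
    if (!is.null(zn) && abs(zn) > config$grid$fe_range / 2) {
      stop("disarticulation threshold outside grid range")
    }
  }
  config$min_viable <- config$min_viable %||% 4
  config$alpha_floor <- config$alpha_floor %||% 50
  config
}

.config_model <- function(config) {
  if (!is.null(config$model)) return(config$model)
  if (!is.null(config$generator)) {
    g <- config$generator
    return(switch(g$type,
                  ball_socket = do.call(make_ball_and_socket,
                                        g[setdiff(names(g), "type")])$model,
                  saddle = do.call(make_saddle_joint,
                                   g[setdiff(names(g), "type")]),
                  two_pose = make_two_pose_fixture()$model,
                  stop("unknown generator type: ", g$type)))
  }
  ax <- config$jcs_axes
  mf <- config$metatarsal_frame
  build_joint_model(
    proximal_mesh = read_mesh(config$meshes$proximal),
    distal_mesh = read_mesh(config$meshes$distal),
    cor_sphere = sphere(config$cor_sphere$center, config$cor_sphere$radius),
    gap_sphere = sphere(config$gap_sphere$center, config$gap_sphere$radius),
    articular_surface_frame = frame(config$cor_sphere$center,
                                    ax$x, ax$y, ax$z),
    metatarsal_proximal_frame = frame(mf$origin, mf$x, mf$y, mf$z),
    convention = config$convention)
}

#' Run the full analysis for one specimen
#'
#' Executes the stages in order: model build, pose-grid sweep,
#' disarticulation filtering, inclusion check, cosine correction, alpha
#' shape, per-muscle moment-arm fields, torsion, architecture.  When the
#' viable-pose count is below `min_viable` the specimen is excluded: the
#' report carries `included = FALSE` and no pose-space or moment-arm
#' fields.
#'
#' @param config see [validate_specimen_config()].
#' @param verbose log stage progress.
#' @return List of class `specimen_report`.
#' @export
run_specimen <- function(config, verbose = TRUE) {
  config <- validate_specimen_config(config)
  t0 <- Sys.time()
  model <- .config_model(config)
  .stage_log(verbose, "build", "specimen %s: model ready (%d + %d faces)",
             config$specimen, nrow(model$proximal_mesh$faces),
             nrow(model$distal_mesh$faces))
  grid <- generate_pose_grid(config$grid$fe_range, config$grid$abad_range,
                             config$grid$ie_range, config$grid$step)
  .stage_log(verbose, "sweep", "%d grid poses", nrow(grid))
  table <- sweep_poses(model, grid)
  .stage_log(verbose, "sweep", "%d viable", sum(table$code == 1L))
  if (!is.null(config$disarticulation)) {
    table <- filter_disarticulated(table,
                                   config$disarticulation$z_positive_max,
                                   config$disarticulation$z_negative_min)
    .stage_log(verbose, "filter", "%d flagged disarticulated",
               sum(table$disarticulated))
  }
  included <- check_inclusion(table, config$min_viable)
  report <- list(specimen = config$specimen,
                 n_viable = attr(included, "n_viable"),
                 included = as.logical(included),
                 table = table,
                 provenance = list(
                   n_viable = "sweep_poses + filter_disarticulated",
                   included = "check_inclusion"))
  if (report$included) {
    ps <- pose_space_summary(table, config$alpha_floor)
    .stage_log(verbose, "posespace",
               "alpha %.4g (critical %.4g), volume %.6g deg^3",
               ps$alpha_radius, ps$critical_alpha, ps$volume_deg3)
    report$alpha_radius <- ps$alpha_radius
    report$critical_alpha <- ps$critical_alpha
    report$volume_deg3 <- ps$volume_deg3
    report$excursions <- ps$excursions
    report$cloud <- ps$cloud
    report$provenance$volume_deg3 <- "cosine_correct + select_alpha + alpha_shape"
    if (!is.null(config$muscles)) {
      sc <- scale_factor(config$scale$a_mm %||% 1,
                         config$scale$b_model %||% 1)
      report$imma <- lapply(config$muscles, function(m) {
        mp <- if (inherits(m, "muscle_path")) m else {
          muscle_path(m$name, m$origin, m$insertion, m$length_mm)
        }
        fld <- imma_field(model, mp, table, sc, ps$cloud)
        .stage_log(verbose, "imma", "%s: max normalized IMMA %.4g",
                   fld$muscle, fld$max_imma_norm)
        fld
      })
      report$provenance$imma <- "imma_field (point_line_distance about COR)"
    }
  }
  if (!is.null(config$torsion)) {
    report$torsion <- do.call(measure_metatarsal_torsion, config$torsion)
    .stage_log(verbose, "torsion", "alpha = %.2f deg",
               report$torsion$alpha_deg)
    report$provenance$torsion <- "fit_cylinder + build_epiphysis_frames + torsion_angle"
  }
  if (!is.null(config$architecture)) {
    report$architecture <- architecture_table(config$architecture)
    report$provenance$architecture <- "architecture_table"
  }
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "specimen_report"
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

#' @export
print.specimen_report <- function(x, ...) {
  cat("specimen_report:", x$specimen, "\n")
  cat("  viable poses:", x$n_viable, if (!x$included) "(excluded)", "\n")
  if (x$included) {
    cat(sprintf("  alpha volume: %.6g deg^3 (alpha %.4g)\n", x$volume_deg3,
                x$alpha_radius))
  }
  if (!is.null(x$torsion)) {
    cat(sprintf("  torsion: %.2f deg\n", x$torsion$alpha_deg))
  }
  invisible(x)
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(out_dir, report$specimen)
  write_viability_csv(report$table, paste0(base, "_viability.csv"))
  summary <- list(specimen = report$specimen, n_viable = report$n_viable,
                  included = report$included,
                  provenance = report$provenance)
  if (report$included) {
    utils::write.csv(report$cloud, paste0(base, "_corrected_poses.csv"),
                     row.names = FALSE)
    summary$alpha <- report$alpha_radius
    summary$critical_alpha <- report$critical_alpha
    summary$volume_deg3 <- report$volume_deg3
    summary$excursions <- report$excursions
    if (!is.null(report$imma)) {
      for (fld in report$imma) {
        utils::write.csv(fld$records,
                         paste0(base, "_imma_", fld$muscle, ".csv"),
                         row.names = FALSE)
      }
      summary$imma_max <- lapply(report$imma, function(fld) {
        list(muscle = fld$muscle, max_imma_norm = fld$max_imma_norm,
             argmax = fld$argmax[1, c("z_deg", "y_deg", "x_deg")])
      })
    }
  }
  if (!is.null(report$torsion)) summary$torsion_deg <- report$torsion$alpha_deg
  jsonlite::write_json(summary, paste0(base, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(base)
}

#' Run a batch of specimen configurations
#'
#' Per-specimen failures are caught and recorded; the batch continues.
#'
#' @param configs list of specimen configurations.
#' @param verbose log stage progress.
#' @return List of class `batch_report` with `reports`, `failures` and
#'   cross-specimen long-format `tables` (`volumes`, `excursions`,
#'   `imma_maxima`, `torsion`).
#' @export
run_batch <- function(configs, verbose = FALSE) {
  stopifnot(length(configs) >= 1)
  reports <- list()
  failures <- list()
  for (cfg in configs) {
    id <- tryCatch(cfg$specimen %||% "<unnamed>", error = function(e) "<unnamed>")
    res <- tryCatch(run_specimen(cfg, verbose = verbose), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      message(sprintf("specimen %s failed: %s", id, conditionMessage(res)))
    } else {
      reports[[res$specimen]] <- res
    }
  }
  volumes <- do.call(rbind, lapply(reports, function(r) {
    data.frame(specimen = r$specimen, n_viable = r$n_viable,
               included = r$included,
               volume_deg3 = if (r$included) r$volume_deg3 else NA_real_)
  }))
  excursions <- do.call(rbind, lapply(reports, function(r) {
    if (!r$included) return(NULL)
    cbind(specimen = r$specimen, r$excursions)
  }))
  imma <- do.call(rbind, lapply(reports, function(r) {
    if (is.null(r$imma)) return(NULL)
    do.call(rbind, lapply(r$imma, function(fld) {
      data.frame(specimen = r$specimen, muscle = fld$muscle,
                 max_imma_norm = fld$max_imma_norm,
                 argmax_z = fld$argmax$z_deg[1],
                 argmax_y = fld$argmax$y_deg[1],
                 argmax_x = fld$argmax$x_deg[1])
    }))
  }))
  torsion <- do.call(rbind, lapply(reports, function(r) {
    if (is.null(r$torsion)) return(NULL)
    data.frame(specimen = r$specimen, alpha_deg = r$torsion$alpha_deg)
  }))
  structure(list(reports = reports, failures = failures,
                 tables = list(volumes = volumes, excursions = excursions,
                               imma_maxima = imma, torsion = torsion)),
            class = "batch_report")
}

#' Measure metatarsal torsion from surface samples and patches
#'
#' Fits cylinders to the sampled head and proximal articular surfaces,
#' builds the epiphysis frames per convention, and extracts the torsion
#' angle.
#'
#' @param proximal_patch,distal_patch [articular_patch] objects.
#' @param head_points,proximal_points cylinder surface samples (n x 3).
#' @param head_axis_init,proximal_axis_init seed axis directions for the
#'   deterministic cylinder fits.
#' @param convention clade convention tag.
#' @return List: `alpha_deg`, `head_cylinder`, `proximal_cylinder`,
#'   `frames`, `proximal_area_mm2`, `distal_area_mm2`.
#' @export
measure_metatarsal_torsion <- function(proximal_patch, distal_patch,
                                       head_points, proximal_points,
                                       head_axis_init, proximal_axis_init,
                                       convention) {
  head_cyl <- fit_cylinder(head_points, head_axis_init)
  prox_cyl <- fit_cylinder(proximal_points, proximal_axis_init)
  frames <- build_epiphysis_frames(proximal_patch, distal_patch, head_cyl,
                                   prox_cyl, convention)
  list(alpha_deg = torsion_angle(frames$proximal_frame, frames$distal_frame),
       head_cylinder = head_cyl, proximal_cylinder = prox_cyl,
       frames = frames,
       proximal_area_mm2 = patch_area(proximal_patch),
       distal_area_mm2 = patch_area(distal_patch))
}
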
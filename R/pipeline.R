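#' Run configuration
#'
#' Collects everything an end-to-end aspiration analysis needs: input
#' paths, ROI, pipette geometry, physical constants, and the RNG seed.
#' Configurations round-trip losslessly through JSON.
#'
#' @param stack_path path to a multi-page TIFF stack (or \code{NULL} when a
#'   trace CSV is supplied instead).
#' @param schedule_path path to a schedule JSON.
#' @param out_dir output directory (created if missing).
#' @param roi list \code{(row, col, length, width)} or an
#'   \code{\link{roi_spec}}.
#' @param pipette_diameter_um pipette inner diameter (um).
#' @param delta_h_um reservoir displacement (um).
#' @param pixel_size,frame_interval metadata overrides.
#' @param trace_path optional trace CSV for image-free runs (geometry and
#'   mechanics only).
#' @param seed integer RNG seed recorded in the provenance log.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(stack_path = NULL, schedule_path = NULL,
                       out_dir = tempfile("rbcswitch-run-"),
                       roi = NULL, pipette_diameter_um = 2.1,
                       delta_h_um = 979, pixel_size = NULL,
                       frame_interval = NULL, trace_path = NULL, seed = 1) {
  if (!is.null(roi) && !inherits(roi, "roi_spec"))
    roi <- roi_spec(roi$row, roi$col, roi$length, roi$width)
  structure(list(stack_path = stack_path, schedule_path = schedule_path,
                 out_dir = out_dir, roi = roi,
                 pipette_diameter_um = pipette_diameter_um,
                 delta_h_um = delta_h_um, pixel_size = pixel_size,
                 frame_interval = frame_interval, trace_path = trace_path,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a run configuration as JSON
#'
#' @param config a \code{\link{run_config}}.
#' @param path JSON path.
#' @return \code{path} / the restored \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (!is.null(x$roi)) x$roi <- unclass(x$roi)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(run_config, x)
}

#' End-to-end aspiration analysis
#'
#' Chains the full measurement pipeline: interface tracking on the image
#' stack, cycle segmentation and averaging against the illumination
#' schedule, exponential relaxation fits per phase, the three-section
#' geometry conversion of the cycle-averaged tongue displacement into a
#' membrane-area change, and the pressure/work mechanics. When
#' \code{config$trace_path} is set instead of a stack, tracking is skipped
#' and the pipeline starts from the stored trace. All stage outputs are
#' written under \code{config$out_dir} (trace CSV, fits CSV, geometry CSV,
#' mechanics JSON, and a provenance log with package version, seed, and
#' the config snapshot); any stage failure aborts with the stage name.
#'
#' @param config a \code{\link{run_config}}.
#' @return A list: \code{trace}, \code{fits} (data frame),
#'   \code{cycle_average}, \code{geometry}, \code{area_change},
#'   \code{mechanics}, \code{out_dir}; invisibly also written to disk.
#' @export
run_aspiration_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  schedule <- stage("schedule", read_schedule(config$schedule_path))
  if (!is.null(config$trace_path)) {
    trace <- stage("load-trace", read_trace(config$trace_path))
  } else {
    stk <- stage("load-stack",
                 read_image_stack(config$stack_path,
                                  pixel_size = config$pixel_size,
                                  frame_interval = config$frame_interval))
    if (is.null(config$roi)) stop("stage 'track' failed: no ROI configured")
    trace <- stage("track", track_interface(stk, config$roi))
  }
  write_trace(trace, file.path(config$out_dir, "trace.csv"))

  segs <- stage("segment", segment_cycles(trace, schedule))
  ca <- stage("average", average_cycles(segs))
  fits2 <- stage("fit", fit_cycle_average(ca))
  fits <- data.frame(
    phase = c("UV", "VIS"),
    a_um = c(fits2$uv$a, fits2$vis$a),
    b_um = c(fits2$uv$b, fits2$vis$b),
    tau_s = c(fits2$uv$tau, fits2$vis$tau),
    rmse_um = c(fits2$uv$rmse, fits2$vis$rmse),
    n_points = c(fits2$uv$n_points, fits2$vis$n_points))
  utils::write.csv(fits, file.path(config$out_dir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(time_s = ca$time_s, mean_um = ca$mean_um, sd_um = ca$sd_um),
    file.path(config$out_dir, "cycle_average.csv"), row.names = FALSE)

  # plateau-to-plateau displacement from the two fitted offsets
  delta_d <- abs(fits2$vis$a - fits2$uv$a)
  a_pip <- config$pipette_diameter_um / 2
  geom <- stage("geometry", solve_reference_geometry(a_pip))
  area <- stage("area", apply_tongue_displacement(geom, delta_d))
  utils::write.csv(
    cbind(data.frame(a_um = a_pip, r_um = geom$r, l_um = geom$l), area),
    file.path(config$out_dir, "geometry.csv"), row.names = FALSE)

  dP <- suction_pressure(config$delta_h_um)
  W <- aspiration_work(cross_section_area(config$pipette_diameter_um),
                       delta_d, dP)
  mech <- list(delta_h_um = config$delta_h_um, delta_P_pN_um2 = dP,
               A_cross_um2 = cross_section_area(config$pipette_diameter_um),
               delta_d_um = delta_d, W_aJ = W$W_aJ, W_kBT = W$W_kBT,
               dA_abs_um2 = area$dA_abs, dA_rel_pct = area$dA_rel,
               mol_pct = mol_fraction_estimate(area$dA_rel))
  jsonlite::write_json(mech, file.path(config$out_dir, "mechanics.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- list(package = "rbcswitch",
               version = as.character(utils::packageVersion("rbcswitch")),
               r_version = R.version.string,
               seed = config$seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = unclass(write_config_snapshot(config)))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(trace = trace, fits = fits, cycle_average = ca,
                 geometry = geom, area_change = area, mechanics = mech,
                 out_dir = config$out_dir))
}

write_config_snapshot <- function(config) {
  x <- unclass(config)
  if (!is.null(x$roi)) x$roi <- unclass(x$roi)
  x
}
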
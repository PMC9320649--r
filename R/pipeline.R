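# End-to-end orchestration: configuration, the segment -> track -> summarize
# -> count workflow, and run manifests.

#' Assemble and validate a run configuration
#'
#' Builds the per-dataset configuration driving [runTracking()].  Physical
#' keys mirror the usual dataset tables: domain length, total time, frame
#' interval, characteristic force; `tau_bar` is computed from the friction
#' coefficient when not given explicitly, and `eps_bar` is the numerical
#' interfacial width (which overrides the physical ratio).
#'
#' @param domain_length_um domain side length L, um.
#' @param total_time_s duration of the tracked experiment, s.
#' @param frame_interval_s frame interval TI, s.
#' @param characteristic_force_pN characteristic force F, pN.
#' @param eps_bar numerical interfacial width.
#' @param RTS reconstructed time steps per frame pair.
#' @param tau_bar optional dimensionless friction; computed from
#'   `friction_pNs_um2` if absent.
#' @param surface_tension_pN surface tension delta, pN.
#' @param friction_pNs_um2 friction tau, pN s / um^2.
#' @param theta control regularisation weight.
#' @param max_iter,tol optimiser options per frame pair.
#' @param grid_n solver grid nodes per side.
#' @param substeps solver steps per reconstructed step (NA = automatic).
#' @param euler_band band half-width c for the Euler number.
#' @param cells_bright,min_area segmentation options.
#' @param pixel_size_um pixel size of the input frames; defaults to
#'   `domain_length_um / npix` at ingestion.
#' @param output_dir output directory.
#' @param seed integer seed for any synthetic rendering.
#' @param write_fields write state/control TIFF stacks per pair?
#' @return validated configuration list of class `"cellforceConfig"`.
#' @export
runConfig <- function(domain_length_um, total_time_s, frame_interval_s,
                      eps_bar, RTS, characteristic_force_pN = 10,
                      tau_bar = NULL, surface_tension_pN = 10,
                      friction_pNs_um2 = 2.62, theta = 1e-3, max_iter = 200L,
                      tol = 1e-6, grid_n = 64L, substeps = NA,
                      euler_band = 0.8, cells_bright = TRUE, min_area = 50L,
                      pixel_size_um = NULL, output_dir = "cellforce_run",
                      seed = 1L, write_fields = TRUE) {
  phys <- physicalParams(delta = surface_tension_pN, tau = friction_pNs_um2,
                         eps = eps_bar * domain_length_um,
                         L = domain_length_um, T_total = total_time_s,
                         TI = frame_interval_s, F_char = characteristic_force_pN)
  dimless <- nondimensionalize(phys, eps_bar = eps_bar, theta = theta,
                               RTS = RTS, substeps = substeps)
  if (!is.null(tau_bar)) dimless@tau_bar <- tau_bar
  validObject(dimless)
  cfg <- list(phys = phys, dimless = dimless, grid_n = as.integer(grid_n),
              euler_band = euler_band, max_iter = as.integer(max_iter),
              tol = tol,
              seg = segmentationConfig(cells_bright = cells_bright,
                                       min_area = min_area),
              pixel_size_um = pixel_size_um, output_dir = output_dir,
              seed = as.integer(seed), write_fields = isTRUE(write_fields))
  class(cfg) <- "cellforceConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path path to a YAML file whose keys are the arguments of
#'   [runConfig()].
#' @return a validated configuration, see [runConfig()].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(runConfig, y)
}

#' Run the full tracking pipeline on a frame sequence
#'
#' Executes segmentation, pair-by-pair optimal-control tracking, force
#' summarisation and Euler-number cell counting, and writes the results
#' (forces CSV, Euler trace CSV, optional field TIFFs, JSON manifest) to the
#' configured output directory.
#'
#' @param config a configuration from [runConfig()] / [readRunConfig()].
#' @param frames list of [ImageFrame]s or a [SyntheticMovie].
#' @return the run manifest (a list), invisibly; the manifest is also
#'   written as `manifest.json`.
#' @export
runTracking <- function(config, frames) {
  stopifnot(inherits(config, "cellforceConfig"))
  phys <- config$phys; dimless <- config$dimless
  grid <- gridSpec(config$grid_n)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  message("stage 1/4: segmentation")
  ft <- framesToTargets(frames, grid, dimless@eps_bar, TI = phys@TI,
                        T_total = phys@T_total, L = phys@L, cfg = config$seg)

  message("stage 2/4: tracking (", length(ft$targets@observations),
          " frame pairs)")
  pairs <- trackSequence(ft$targets, ft$phi0, dimless,
                         max_iter = config$max_iter, tol = config$tol)

  message("stage 3/4: force summaries")
  forces <- do.call(rbind, lapply(pairs, forceSummary, p = phys))
  forcesPath <- file.path(out, "forces.csv")
  utils::write.csv(forces, forcesPath, row.names = FALSE)

  message("stage 4/4: cell counting")
  euler <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    tr <- cellCountTrace(pairs[[i]]@trajectory, c = config$euler_band)
    tr <- if (i == 1L) tr else tr[-1L, , drop = FALSE]
    tr$pair <- pairs[[i]]@label
    tr
  }))
  eulerPath <- file.path(out, "euler.csv")
  utils::write.csv(euler[, c("step", "time", "euler", "count")], eulerPath,
                   row.names = FALSE)

  files <- c(forces = "forces.csv", euler = "euler.csv")
  if (config$write_fields) {
    for (i in seq_along(pairs)) {
      sp <- sprintf("states_pair_%02d.tif", i)
      cp <- sprintf("states_pair_%02d.csv", i)
      writeTrajectory(pairs[[i]]@trajectory, file.path(out, sp),
                      file.path(out, cp))
      ep <- sprintf("control_pair_%02d.tif", i)
      writeControl(pairs[[i]]@control, file.path(out, ep))
      files <- c(files, sp, cp, ep)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cellforce")),
    config = list(
      domain_length_um = phys@L, total_time_s = phys@T_total,
      frame_interval_s = phys@TI, characteristic_force_pN = phys@F_char,
      surface_tension_pN = phys@delta, friction_pNs_um2 = phys@tau,
      eps_bar = dimless@eps_bar, tau_bar = dimless@tau_bar,
      delta_bar = dimless@delta_bar, theta = dimless@theta,
      RTS = dimless@RTS, grid_n = config$grid_n,
      euler_band = config$euler_band, max_iter = config$max_iter,
      tol = config$tol, seed = config$seed),
    n_frames = length(ft$targets@observations) + 1L,
    pairs = lapply(pairs, function(p) list(
      label = p@label, converged = p@converged,
      iterations = length(p@objectiveHistory) - 1L,
      objective = p@objectiveHistory[length(p@objectiveHistory)],
      misfit = p@misfit,
      rts = max(p@trajectory@controlIndex),
      substeps = p@trajectory@params@substeps)),
    files = as.list(files))
  manifestPath <- file.path(out, "manifest.json")
  tmp <- paste0(manifestPath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, manifestPath)
  manifest$results <- list(pairs = pairs, forces = forces, euler = euler)
  invisible(manifest)
}

#' Write a control field as a multi-page TIFF
#'
#' One 32-bit page per reconstructed step; values are affinely mapped from
#' `[-m, m]` (m = max absolute forcing) to `[0, 1]`, with the scale recorded
#' in a sidecar text file.
#'
#' @param eta a [ControlField].
#' @param path output TIFF path.
#' @export
writeControl <- function(eta, path) {
  m <- max(1e-12, max(vapply(eta@values, function(v) max(abs(v)), numeric(1))))
  pages <- lapply(eta@values, function(v) {
    r <- fieldToRaster(v)
    (r / m + 1) / 2
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  writeLines(sprintf("scale: values = (stored * 2 - 1) * %.10g", m),
             paste0(path, ".scale.txt"))
  invisible(path)
}

#' Write a synthetic movie to a directory
#'
#' Numbered PNG frames, ground-truth mask PNGs and a JSON meta file.
#'
#' @param movie a [SyntheticMovie].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeSyntheticMovie <- function(movie, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(movie@frames)) {
    png::writePNG(movie@frames[[i]]@pixels,
                  file.path(dir, sprintf("frame_%03d.png", i)))
    writeMaskPNG(movie@masks[[i]], file.path(dir, sprintf("mask_%03d.png", i)))
  }
  meta <- movie@meta
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
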
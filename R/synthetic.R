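# Synthetic data generators: analytic phase fields, rendered grayscale
# movies of moving/dividing cells with ground-truth masks, and
# forward-model-generated ("inverse crime") target sequences with known
# forcing.  All generators are pure functions of their parameters and seed.

# Run expr with a private RNG state derived from `seed`, restoring the
# caller's state afterwards.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Analytic tanh disk phase field
#'
#' Equilibrium profile of the exact signed distance to a circle: positive
#' inside, zero on the circle.
#'
#' @param center length-2 numeric, dimensionless disk centre.
#' @param radius dimensionless radius (> 2 * eps_bar).
#' @param eps_bar interfacial width.
#' @param grid a [GridSpec].
#' @param time dimensionless time stamp.
#' @return a [PhaseField].
#' @export
makeDiskField <- function(center, radius, eps_bar, grid, time = 0) {
  if (radius <= 2 * eps_bar)
    stop("radius must exceed twice the interfacial width")
  co <- gridCoords(grid)
  r <- sqrt(outer((co - center[1])^2, (co - center[2])^2, `+`))
  tanhProfile(radius - r, eps_bar, grid = grid, time = time)
}

# Exact circle mask on a pixel raster (row 1 = top), pixel centres at
# (i - 0.5)/npix in dimensionless units.
diskMaskRaster <- function(center, radius, npix) {
  px <- (seq_len(npix) - 0.5) / npix
  xg <- matrix(px, npix, npix, byrow = TRUE)        # column -> x
  yg <- matrix(rev(px), npix, npix)                 # row 1 -> top (y high)
  (xg - center[1])^2 + (yg - center[2])^2 <= radius^2
}

renderMask <- function(mask, fg, bg, noise_sd, quantize = TRUE) {
  img <- bg + (fg - bg) * mask
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img))
  img <- pmin(pmax(img, 0), 1)
  if (quantize) img <- round(img * 255) / 255
  img
}

#' Rendered movie of a disk translating at constant velocity
#'
#' Ground-truth masks are exact circle rasters; per-frame displacements are
#' snapped to the pixel lattice so every mask is an exact translate of the
#' first (area-constant, centroid shifts known exactly).  Frames are
#' rendered with two grayscale levels plus seeded Gaussian noise and 8-bit
#' quantisation, emulating a segmented bright-on-dark cell video.  The
#' snapped centres are recorded in `meta$centers`.
#'
#' @param v length-2 numeric, dimensionless velocity (displacement per unit
#'   dimensionless time).
#' @param n_frames number of frames (the first is at time 0).
#' @param center0 disk centre at time 0.
#' @param radius disk radius.
#' @param npix raster size in pixels.
#' @param L domain length in um (sets the pixel size).
#' @param TI frame interval in seconds (timestamps only).
#' @param fg,bg foreground/background gray levels.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed; identical seeds give identical pixel data.
#' @return a [SyntheticMovie].
#' @export
makeTranslatingDiskMovie <- function(v = c(0.2, 0), n_frames = 5L,
                                     center0 = c(0.35, 0.5), radius = 0.2,
                                     npix = 128L, L = 100, TI = 60,
                                     fg = 0.8, bg = 0.2, noise_sd = 0.05,
                                     seed = 1L) {
  dtbar <- if (n_frames > 1L) 1 / (n_frames - 1L) else 0
  centers <- lapply(seq_len(n_frames) - 1L, function(k)
    center0 + round(v * k * dtbar * npix) / npix)
  for (ce in centers)
    if (any(ce - radius < 0) || any(ce + radius > 1))
      stop("disk leaves the domain; shrink v or the radius")
  masks <- lapply(centers, diskMaskRaster, radius = radius, npix = npix)
  frames <- withLocalSeed(seed, lapply(seq_along(masks), function(k) {
    imageFrame(renderMask(masks[[k]], fg, bg, noise_sd),
               pixelSize = L / npix, index = k, timestamp = (k - 1L) * TI)
  }))
  new("SyntheticMovie", frames = frames, masks = masks,
      meta = list(generator = "translating_disk", v = v, n_frames = n_frames,
                  center0 = center0, radius = radius, npix = npix, L = L,
                  TI = TI, fg = fg, bg = bg, noise_sd = noise_sd, seed = seed,
                  centers = centers))
}

#' Rendered movie of one cell dividing into two
#'
#' Two equal disks whose centres separate linearly; early frames overlap
#' into a single blob which pinches into two disjoint cells.  The first
#' frame with disjoint masks is recorded as `meta$division_frame`.
#'
#' @param n_frames number of frames.
#' @param radius disk radius.
#' @param center blob centre.
#' @param sep_start,sep_end centre separation at the first and last frame;
#'   `sep_end` must exceed `2 * radius` so the final cells are disjoint.
#' @param npix,L,TI,fg,bg,noise_sd,seed as in [makeTranslatingDiskMovie()].
#' @return a [SyntheticMovie].
#' @export
makeDivisionMovie <- function(n_frames = 5L, radius = 0.12,
                              center = c(0.5, 0.5), sep_start = 0.06,
                              sep_end = 0.54, npix = 128L, L = 100, TI = 60,
                              fg = 0.8, bg = 0.2, noise_sd = 0.05, seed = 1L) {
  if (sep_end <= 2 * radius)
    stop("final separation must exceed the cell diameter")
  seps <- seq(sep_start, sep_end, length.out = n_frames)
  masks <- lapply(seps, function(s) {
    m1 <- diskMaskRaster(center + c(-s / 2, 0), radius, npix)
    m2 <- diskMaskRaster(center + c(s / 2, 0), radius, npix)
    m1 | m2
  })
  division <- which(seps > 2 * radius)[1]
  frames <- withLocalSeed(seed, lapply(seq_along(masks), function(k) {
    imageFrame(renderMask(masks[[k]], fg, bg, noise_sd),
               pixelSize = L / npix, index = k, timestamp = (k - 1L) * TI)
  }))
  new("SyntheticMovie", frames = frames, masks = masks,
      meta = list(generator = "division", n_frames = n_frames, radius = radius,
                  center = center, sep_start = sep_start, sep_end = sep_end,
                  npix = npix, L = L, TI = TI, fg = fg, bg = bg,
                  noise_sd = noise_sd, seed = seed, separations = seps,
                  division_frame = division))
}

#' Forward-model-generated target sequence with known forcing
#'
#' Runs the forward solver under a known control \eqn{\bar\eta^*} and emits
#' its states at the requested frame times as observations — the standard
#' "inverse crime" fixture for verifying the optimal-control solver, since a
#' perfect fit is attainable by construction.
#'
#' @param eta_star a [ControlField] (the ground-truth forcing).
#' @param phi0 initial [PhaseField].
#' @param params a [DimensionlessParams].
#' @param times dimensionless observation times (must align with
#'   reconstructed step boundaries); default is the final time 1.
#' @param mass passed to [solveForward()] (`NULL` disables the constraint).
#' @param duration total solved time.
#' @return list with `targets` (a [TargetSequence]), `trajectory` and
#'   `eta_star`.
#' @export
makeInverseCrimeDataset <- function(eta_star, phi0, params, times = 1,
                                    mass = NULL, duration = 1) {
  traj <- solveForward(phi0, eta_star, params, mass = mass,
                       duration = duration)
  obs <- lapply(times, function(tt) {
    k <- which(abs(traj@times - tt) < 1e-9)
    if (length(k) != 1L)
      stop(sprintf("observation time %.6g not on the step grid", tt))
    traj@states[[k]]
  })
  targets <- targetSequence(obs, times, phi0@grid)
  list(targets = targets, trajectory = traj, eta_star = eta_star)
}

#' Band-supported forcing that translates a disk
#'
#' Convenience ground-truth control for inverse-crime experiments: at each
#' reconstructed step the forcing is `amp * cos(angle to the direction of
#' motion)` modulated by a Gaussian band around the analytically advected
#' circle, i.e. protrusive at the leading edge and retractive at the rear.
#'
#' @param v length-2 velocity of the nominal disk centre.
#' @param center0,radius nominal disk at time 0.
#' @param amp force amplitude; the default `tau_bar * |v|` is the
#'   sharp-interface estimate for rigid translation.
#' @param params a [DimensionlessParams].
#' @param grid a [GridSpec].
#' @param duration total time covered by the `params@RTS` steps.
#' @return a [ControlField].
#' @export
makeTranslationControl <- function(v, center0, radius, params, grid,
                                   amp = NULL, duration = 1) {
  if (is.null(amp)) amp <- params@tau_bar * sqrt(sum(v^2))
  speed <- sqrt(sum(v^2))
  vhat <- if (speed > 0) v / speed else c(1, 0)
  co <- gridCoords(grid)
  bw <- 2 * params@eps_bar
  vals <- lapply(seq_len(params@RTS), function(j) {
    tmid <- (j - 0.5) / params@RTS * duration
    ce <- center0 + v * tmid
    dx <- outer(co - ce[1], rep(1, grid@n))
    dy <- outer(rep(1, grid@n), co - ce[2])
    r <- sqrt(dx^2 + dy^2)
    cosang <- (dx * vhat[1] + dy * vhat[2]) / pmax(r, 1e-12)
    amp * cosang * exp(-(r - radius)^2 / (2 * bw^2))
  })
  masks <- lapply(vals, function(v) abs(v) > 0)
  new("ControlField", values = vals, masks = masks, grid = grid)
}
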
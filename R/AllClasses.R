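#' @import methods
#' @importFrom Matrix Diagonal sparseMatrix forceSymmetric Cholesky solve
NULL

#' Uniform vertex-centred grid on the unit square
#'
#' Discretisation of the dimensionless domain \eqn{[0,1]^2} with `n` nodes per
#' side, spacing `1/(n-1)`, origin at the bottom-left corner and \eqn{\bar y}
#' increasing upward.  All fields in the package are `n x n` matrices indexed
#' `[i, j]` with `i` the \eqn{\bar x} index and `j` the \eqn{\bar y} index.
#'
#' @slot n integer, nodes per side (>= 8).
#' @slot spacing numeric, node spacing `1/(n-1)`.
#' @export
setClass("GridSpec", representation(n = "integer", spacing = "numeric"))

setValidity("GridSpec", function(object) {
  if (length(object@n) != 1L || object@n < 8L)
    return("grid must have at least 8 nodes per side")
  if (abs(object@spacing - 1 / (object@n - 1L)) > 1e-14)
    return("spacing must equal 1/(n-1)")
  TRUE
})

#' @param n integer number of nodes per side.
#' @rdname GridSpec-class
#' @export
gridSpec <- function(n) {
  n <- as.integer(n)
  new("GridSpec", n = n, spacing = 1 / (n - 1L))
}

#' Physical parameters of the membrane force model
#'
#' Dimensional parameters of the forced, volume-constrained Allen--Cahn model
#' of a migrating cell.  Units follow the conventions of the field: forces in
#' piconewtons (pN), lengths in micrometres, times in seconds.
#'
#' @slot delta surface tension, pN (typically 1--10).
#' @slot tau effective friction with the extracellular matrix, pN s / um^2.
#' @slot eps membrane thickness, um.
#' @slot L domain side length, um.
#' @slot T_total duration of the tracked experiment (the characteristic
#'   time), s.
#' @slot TI frame interval of the video, s.
#' @slot F_char characteristic force used in the nondimensionalization, pN.
#' @slot height assumed constant cell height, um.
#' @export
setClass("PhysicalParams", representation(
  delta = "numeric", tau = "numeric", eps = "numeric", L = "numeric",
  T_total = "numeric", TI = "numeric", F_char = "numeric", height = "numeric"))

setValidity("PhysicalParams", function(object) {
  v <- c(delta = object@delta, tau = object@tau, eps = object@eps,
         L = object@L, T_total = object@T_total, TI = object@TI,
         F_char = object@F_char, height = object@height)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all physical parameters must be finite and strictly positive")
  if (object@TI > object@T_total)
    return("frame interval TI must not exceed T_total")
  if (object@eps >= object@L)
    return("membrane thickness must be smaller than the domain length")
  TRUE
})

#' @param delta,tau,eps,L,T_total,TI,F_char,height see slot documentation.
#' @rdname PhysicalParams-class
#' @export
physicalParams <- function(delta = 10, tau = 2.62, eps = 1.0, L, T_total, TI,
                           F_char = 10, height = 0.1) {
  new("PhysicalParams", delta = delta, tau = tau, eps = eps, L = L,
      T_total = T_total, TI = TI, F_char = F_char, height = height)
}

#' Dimensionless model and solver parameters
#'
#' @slot eps_bar dimensionless interfacial width (0, 0.2].
#' @slot tau_bar dimensionless friction.
#' @slot delta_bar dimensionless surface tension.
#' @slot theta control regularisation weight (> 0).
#' @slot RTS reconstructed time steps per frame pair (>= 1).
#' @slot substeps internal solver steps per reconstructed step; `NA` means
#'   choose automatically from the explicit-reaction stability bound.
#' @export
setClass("DimensionlessParams", representation(
  eps_bar = "numeric", tau_bar = "numeric", delta_bar = "numeric",
  theta = "numeric", RTS = "integer", substeps = "integer"))

setValidity("DimensionlessParams", function(object) {
  if (!(object@eps_bar > 0 && object@eps_bar <= 0.2))
    return("eps_bar must lie in (0, 0.2]")
  if (object@tau_bar <= 0 || object@delta_bar <= 0 || object@theta <= 0)
    return("tau_bar, delta_bar and theta must be strictly positive")
  if (object@RTS < 1L) return("RTS must be a positive integer")
  if (!is.na(object@substeps) && object@substeps < 1L)
    return("substeps must be a positive integer (or NA for automatic)")
  TRUE
})

#' @param eps_bar,tau_bar,delta_bar,theta,RTS,substeps see slot documentation.
#' @rdname DimensionlessParams-class
#' @export
dimensionlessParams <- function(eps_bar, tau_bar, delta_bar = 1.0,
                                theta = 1e-3, RTS = 10L, substeps = NA) {
  new("DimensionlessParams", eps_bar = eps_bar, tau_bar = tau_bar,
      delta_bar = delta_bar, theta = theta, RTS = as.integer(RTS),
      substeps = as.integer(substeps))
}

#' Phase-field snapshot
#'
#' A 2D scalar field on a [GridSpec] whose zero level set is the cell
#' membrane: \eqn{\phi \approx +1} inside the cell, \eqn{-1} outside.
#'
#' @slot values numeric `n x n` matrix.
#' @slot time dimensionless time of the snapshot.
#' @slot grid the [GridSpec] the field lives on.
#' @export
setClass("PhaseField", representation(
  values = "matrix", time = "numeric", grid = "GridSpec"))

setValidity("PhaseField", function(object) {
  n <- object@grid@n
  if (!all(dim(object@values) == c(n, n)))
    return("field dimensions must match the grid")
  if (!all(is.finite(object@values)))
    return("field values must be finite")
  TRUE
})

#' @param values numeric matrix of field values.
#' @param grid a [GridSpec].
#' @param time dimensionless time.
#' @rdname PhaseField-class
#' @export
phaseField <- function(values, grid, time = 0) {
  new("PhaseField", values = values, time = time, grid = grid)
}

#' Membrane forcing control
#'
#' The dimensionless forcing \eqn{\bar\eta}, piecewise constant in time over
#' the reconstructed time steps and supported on a band around the membrane.
#'
#' @slot values list of `n x n` matrices, one per reconstructed step.
#' @slot masks list of logical `n x n` matrices marking the interfacial band;
#'   values are zero wherever the mask is `FALSE`.
#' @slot grid the [GridSpec].
#' @export
setClass("ControlField", representation(
  values = "list", masks = "list", grid = "GridSpec"))

setValidity("ControlField", function(object) {
  if (length(object@values) != length(object@masks))
    return("values and masks must have the same length")
  n <- object@grid@n
  for (k in seq_along(object@values)) {
    if (!all(dim(object@values[[k]]) == c(n, n)))
      return("control field dimensions must match the grid")
    if (any(object@values[[k]][!object@masks[[k]]] != 0))
      return("control values must vanish outside the support mask")
  }
  TRUE
})

#' @param values list of matrices (or a single matrix recycled `nsteps` times).
#' @param grid a [GridSpec].
#' @param masks optional list of logical matrices; default is the whole domain.
#' @param nsteps number of steps when `values` is a single matrix.
#' @rdname ControlField-class
#' @export
controlField <- function(values, grid, masks = NULL, nsteps = NULL) {
  if (is.matrix(values)) {
    nsteps <- if (is.null(nsteps)) 1L else as.integer(nsteps)
    values <- rep(list(values), nsteps)
  }
  if (is.null(masks))
    masks <- lapply(values, function(v) matrix(TRUE, nrow(v), ncol(v)))
  new("ControlField", values = values, masks = masks, grid = grid)
}

#' Zero control over `nsteps` reconstructed steps.
#' @param grid a [GridSpec].
#' @param nsteps number of reconstructed steps.
#' @rdname ControlField-class
#' @export
zeroControl <- function(grid, nsteps) {
  z <- matrix(0, grid@n, grid@n)
  controlField(z, grid, nsteps = nsteps)
}

#' Prescribed mass (cell area) target
#'
#' The prescribed spatial mean of \eqn{\phi} at each solver step.  Tracking a
#' time-dependent mass differs from conservation: the segmented frames may
#' have differing cell area, and the Lagrange multiplier \eqn{\lambda} ties
#' the solution mass to a linear interpolation of the observed masses.
#'
#' @slot values numeric vector, prescribed mean at solver steps `1..N`.
#' @export
setClass("MassTarget", representation(values = "numeric"))

setValidity("MassTarget", function(object) {
  if (any(object@values < -1 | object@values > 1))
    return("mass targets must lie in [-1, 1]")
  TRUE
})

#' @param values numeric vector of prescribed means.
#' @rdname MassTarget-class
#' @export
massTarget <- function(values) new("MassTarget", values = values)

#' Forward solution trajectory
#'
#' States \eqn{\phi^0 \ldots \phi^N} of one forward solve, together with the
#' per-step volume-constraint multipliers \eqn{\lambda^n}.
#'
#' @slot states list of `n x n` matrices (length N+1).
#' @slot times dimensionless times of the states (length N+1, increasing).
#' @slot lambdas numeric vector of multipliers (length N).
#' @slot dt solver step size.
#' @slot grid the [GridSpec].
#' @slot params the [DimensionlessParams] used (with `substeps` resolved).
#' @slot controlIndex integer vector (length N) mapping each solver step to
#'   the reconstructed-step index of the control that drove it.
#' @slot stride storage stride: 1 means every solver step is stored (required
#'   by the adjoint); `k > 1` keeps every k-th state for measurement-only
#'   runs, with `lambdas` and `controlIndex` reported at the stored steps.
#' @export
setClass("StateTrajectory", representation(
  states = "list", times = "numeric", lambdas = "numeric", dt = "numeric",
  grid = "GridSpec", params = "DimensionlessParams", controlIndex = "integer",
  stride = "integer"))

setValidity("StateTrajectory", function(object) {
  if (length(object@lambdas) != length(object@states) - 1L)
    return("lambdas must have one entry per solver step")
  if (length(object@times) != length(object@states))
    return("times must have one entry per state")
  if (any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (length(object@controlIndex) != length(object@lambdas))
    return("controlIndex must have one entry per solver step")
  TRUE
})

#' Segmented observation sequence
#'
#' Phase-field representations of the frames the model is fitted to, with
#' their dimensionless observation times and masses.
#'
#' @slot observations list of `n x n` matrices \eqn{\phi_{obs,i}}.
#' @slot times dimensionless observation times, strictly increasing in (0,1].
#' @slot masses spatial means of the observations.
#' @slot grid the [GridSpec].
#' @export
setClass("TargetSequence", representation(
  observations = "list", times = "numeric", masses = "numeric",
  grid = "GridSpec"))

setValidity("TargetSequence", function(object) {
  if (length(object@observations) != length(object@times) ||
      length(object@times) != length(object@masses))
    return("observations, times and masses must align")
  if (any(diff(object@times) <= 0))
    return("observation times must be strictly increasing")
  if (any(object@times <= 0 | object@times > 1 + 1e-12))
    return("observation times must lie in (0, 1]")
  TRUE
})

#' @param observations list of matrices or [PhaseField] objects.
#' @param times dimensionless observation times.
#' @param grid a [GridSpec].
#' @rdname TargetSequence-class
#' @export
targetSequence <- function(observations, times, grid) {
  observations <- lapply(observations, function(o)
    if (is(o, "PhaseField")) o@values else o)
  masses <- vapply(observations, function(o) quadMean(o, grid), numeric(1))
  new("TargetSequence", observations = observations, times = times,
      masses = masses, grid = grid)
}

#' Adjoint trajectory
#'
#' The adjoint variable of the discrete forward scheme, aggregated per
#' reconstructed step and scaled so that the first-order optimality gradient
#' is `theta * eta + p` on the interfacial band.
#'
#' @slot states list of `n x n` matrices, one per reconstructed step.
#' @slot grid the [GridSpec].
#' @export
setClass("AdjointTrajectory", representation(states = "list", grid = "GridSpec"))

#' Result of fitting one frame pair
#'
#' @slot control the fitted [ControlField].
#' @slot trajectory the [StateTrajectory] driven by the fitted control.
#' @slot objectiveHistory objective value per accepted outer iteration.
#' @slot converged logical convergence flag.
#' @slot misfit final data-misfit term of the objective.
#' @slot regularisation final regularisation term of the objective.
#' @slot label frame-pair label such as `"3-4"`.
#' @export
setClass("PairResult", representation(
  control = "ControlField", trajectory = "StateTrajectory",
  objectiveHistory = "numeric", converged = "logical", misfit = "numeric",
  regularisation = "numeric", label = "character"))

#' A single microscopy frame
#'
#' @slot pixels numeric matrix of grayscale intensities in raster order
#'   (row 1 = top of the image).
#' @slot pixelSize physical pixel size, um/pixel.
#' @slot index frame number.
#' @slot timestamp acquisition time, s.
#' @export
setClass("ImageFrame", representation(
  pixels = "matrix", pixelSize = "numeric", index = "integer",
  timestamp = "numeric"))

setValidity("ImageFrame", function(object) {
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  if (!all(is.finite(object@pixels))) return("pixel intensities must be finite")
  TRUE
})

#' @param pixels numeric matrix of intensities.
#' @param pixelSize um per pixel.
#' @param index frame number.
#' @param timestamp acquisition time in seconds.
#' @rdname ImageFrame-class
#' @export
imageFrame <- function(pixels, pixelSize, index = 1L, timestamp = 0) {
  new("ImageFrame", pixels = pixels, pixelSize = pixelSize,
      index = as.integer(index), timestamp = timestamp)
}

#' Binary segmentation mask
#'
#' @slot values logical matrix in raster order (row 1 = top).
#' @slot components integer matrix labelling connected components.
#' @slot areas integer vector of component areas in pixels.
#' @export
setClass("CellMask", representation(
  values = "matrix", components = "matrix", areas = "integer"))

#' Synthetic time-lapse movie with ground truth
#'
#' @slot frames list of [ImageFrame] objects.
#' @slot masks list of logical ground-truth masks (raster order).
#' @slot meta list with generator name, parameters and seed.
#' @export
setClass("SyntheticMovie", representation(
  frames = "list", masks = "list", meta = "list"))

setValidity("SyntheticMovie", function(object) {
  if (length(object@frames) != length(object@masks))
    return("frames and masks must align")
  TRUE
})
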
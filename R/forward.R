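# Forward solver for the dimensionless forced, volume-constrained Allen-Cahn
# equation on the unit square with homogeneous Neumann boundary:
#
#   eps_bar tau_bar d(phi)/dt = delta_bar eps_bar Lap(phi)
#                               - (delta_bar/eps_bar) G'(phi)
#                               + eta_bar + lambda(t)
#
# Discretisation: semi-implicit IMEX on a uniform vertex-centred grid; the
# Laplacian is implicit (sparse Cholesky, cached per grid/dt), G' and the
# forcing explicit.  The volume constraint is a post-step projection: lambda
# is the spatial constant that sets the quadrature mean of phi to the
# prescribed mass exactly.

# Explicit treatment of G' is stable for dt <~ eps_bar^2 tau_bar/delta_bar;
# when `substeps` is NA each reconstructed step is subdivided to satisfy a
# quarter of that bound.
resolveSubsteps <- function(params, dt_rts) {
  if (!is.na(params@substeps)) return(params@substeps)
  bound <- 0.25 * params@eps_bar^2 * params@tau_bar / params@delta_bar
  max(1L, as.integer(ceiling(dt_rts / bound)))
}

#' One IMEX step of the forced, volume-constrained Allen-Cahn scheme
#'
#' Advances the phase field by one solver step of size `dt`: implicit
#' Laplacian, explicit double-well derivative and forcing, then (if
#' `mass_next` is given) addition of the spatially constant Lagrange
#' multiplier \eqn{\lambda^n} that makes the quadrature mean of the new state
#' equal `mass_next` exactly.
#'
#' @param phi a [PhaseField].
#' @param eta numeric matrix of dimensionless forcing for this step.
#' @param mass_next prescribed mean of the new state, or `NULL` to disable
#'   the volume constraint (`lambda = 0`).
#' @param params a [DimensionlessParams].
#' @param dt solver step size (dimensionless).
#' @return list with elements `phi` (the new [PhaseField]) and `lambda`.
#' @export
phaseFieldStep <- function(phi, eta, mass_next, params, dt) {
  stopifnot(is(phi, "PhaseField"), dt > 0)
  grid <- phi@grid
  if (!all(dim(eta) == dim(phi@values)))
    stop("forcing field shape does not match the state")
  cdt <- dt / (params@eps_bar * params@tau_bar)
  alpha <- dt * params@delta_bar / params@tau_bar
  op <- implicitOperator(grid, alpha)
  rhs <- phi@values +
    cdt * (-(params@delta_bar / params@eps_bar) * doubleWellDeriv(phi@values) +
             eta)
  tilde <- applyAinv(rhs, op)
  if (!all(is.finite(tilde)))
    stop(sprintf("non-finite state after implicit solve at t = %.6g", phi@time))
  if (is.null(mass_next)) {
    lambda <- 0
    newv <- tilde
  } else {
    shift <- mass_next - quadMean(tilde, grid)
    lambda <- params@eps_bar * params@tau_bar * shift / dt
    newv <- tilde + shift
  }
  list(phi = phaseField(newv, grid, time = phi@time + dt), lambda = lambda)
}

#' Solve the forward model over a stretch of dimensionless time
#'
#' Time-steps the forced, volume-constrained Allen-Cahn equation from `phi0`
#' over `duration`, using one control field per reconstructed step (each
#' internally subdivided into `substeps` solver steps).
#'
#' @param phi0 initial [PhaseField].
#' @param eta a [ControlField] with one field per reconstructed step, or
#'   `NULL` for zero forcing over `params@RTS` steps.
#' @param params a [DimensionlessParams].
#' @param mass the prescribed mass: `NULL` disables the constraint;
#'   a single number holds the mass constant; a pair `c(m0, m1)` is
#'   interpolated linearly over the solver steps; a [MassTarget] prescribes
#'   every step.
#' @param duration length of the solved time stretch (dimensionless);
#'   defaults to 1.
#' @param keep storage stride: 1 (default) stores every solver step (needed
#'   by the adjoint); larger values store every `keep`-th state plus the
#'   final one, for long measurement runs where memory matters.
#' @return a [StateTrajectory]; `mean(phi^n)` equals the prescribed mass at
#'   every step by construction of the projection.
#' @export
solveForward <- function(phi0, eta = NULL, params, mass = NULL, duration = 1,
                         keep = 1L) {
  stopifnot(is(phi0, "PhaseField"), duration > 0, keep >= 1L)
  keep <- as.integer(keep)
  grid <- phi0@grid
  if (is.null(eta)) eta <- zeroControl(grid, params@RTS)
  nrts <- length(eta@values)
  dt_rts <- duration / nrts
  sub <- resolveSubsteps(params, dt_rts)
  nsteps <- nrts * sub
  dt <- duration / nsteps
  massVec <- expandMass(mass, phi0, grid, nsteps)

  storeAt <- unique(c(seq(0L, nsteps, by = keep), nsteps))
  states <- vector("list", length(storeAt))
  states[[1L]] <- phi0@values
  lams <- numeric(length(storeAt) - 1L)
  ctrlStore <- integer(length(storeAt) - 1L)
  ctrlIndex <- rep(seq_len(nrts), each = sub)
  cur <- phi0
  si <- 1L
  for (k in seq_len(nsteps)) {
    res <- phaseFieldStep(cur, eta@values[[ctrlIndex[k]]],
                          if (is.null(massVec)) NULL else massVec[k],
                          params, dt)
    cur <- res$phi
    if (k == storeAt[si + 1L]) {
      si <- si + 1L
      states[[si]] <- cur@values
      lams[si - 1L] <- res$lambda
      ctrlStore[si - 1L] <- ctrlIndex[k]
    }
  }
  pr <- params
  pr@substeps <- as.integer(sub)
  new("StateTrajectory", states = states,
      times = phi0@time + dt * storeAt, lambdas = lams,
      dt = dt, grid = grid, params = pr, controlIndex = ctrlStore,
      stride = keep)
}

# Normalise the `mass` argument to a per-step vector (or NULL).
expandMass <- function(mass, phi0, grid, nsteps) {
  if (is.null(mass)) return(NULL)
  if (is(mass, "MassTarget")) {
    if (length(mass@values) != nsteps)
      stop("MassTarget length must equal the number of solver steps")
    return(mass@values)
  }
  if (length(mass) == 1L) return(rep(mass, nsteps))
  if (length(mass) == 2L) {
    t <- seq_len(nsteps) / nsteps
    return(mass[1] * (1 - t) + mass[2] * t)
  }
  if (length(mass) == nsteps) return(as.numeric(mass))
  stop("mass must be NULL, a scalar, a pair of endpoints, or one value per step")
}

#' Ginzburg-Landau interfacial energy
#'
#' \eqn{E(\phi) = \int \frac{\bar\delta\bar\epsilon}{2}|\nabla\phi|^2 +
#' \frac{\bar\delta}{\bar\epsilon} G(\phi)}, the Lyapunov functional of the
#' unforced, unconstrained flow.
#'
#' @param phi a [PhaseField].
#' @param params a [DimensionlessParams].
#' @return numeric scalar.
#' @export
ginzburgLandauEnergy <- function(phi, params) {
  g <- gradientCentral(phi@values, phi@grid)
  dens <- 0.5 * params@delta_bar * params@eps_bar * (g$gx^2 + g$gy^2) +
    (params@delta_bar / params@eps_bar) * doubleWell(phi@values)
  quadIntegral(dens, phi@grid)
}

# Central differences with mirror ghosts (consistent with the Neumann BC).
gradientCentral <- function(f, grid) {
  n <- grid@n
  im <- c(2L, seq_len(n - 1L)); ip <- c(seq(2L, n), n - 1L)
  list(gx = (f[ip, ] - f[im, ]) / (2 * grid@spacing),
       gy = (f[, ip] - f[, im]) / (2 * grid@spacing))
}

#' Export a trajectory as a multi-page TIFF plus a step table
#'
#' Writes one 32-bit page per stored state, with phi mapped affinely from
#' `[-1.2, 1.2]` to `[0, 1]` (stored = (phi + 1.2) / 2.4), and a CSV with
#' columns `step`, `time`, `lambda`, `mass`.
#'
#' @param traj a [StateTrajectory].
#' @param tiff_path output TIFF path.
#' @param csv_path output CSV path.
#' @return invisibly, the step table as a data.frame.
#' @export
writeTrajectory <- function(traj, tiff_path, csv_path) {
  pages <- lapply(traj@states, function(s) {
    # TIFF pages are written in raster order (row 1 = top)
    r <- t(s)[rev(seq_len(ncol(s))), , drop = FALSE]
    pmin(pmax((r + 1.2) / 2.4, 0), 1)
  })
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L,
                  reduce = FALSE)
  masses <- vapply(traj@states, function(s) quadMean(s, traj@grid), numeric(1))
  tab <- data.frame(step = seq_along(traj@states) - 1L, time = traj@times,
                    lambda = c(NA, traj@lambdas), mass = masses)
  utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(tab)
}
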
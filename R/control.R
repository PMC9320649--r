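# Optimal-control fitting of the forward model to segmented observations.
#
# The objective is
#   J(eta; phi) = theta/2 * int_t int_Omega eta^2  +
#                 1/2 * sum_i int_Omega (phi(t_i) - phi_obs,i)^2
# minimised by projected gradient descent with Armijo backtracking.  The
# gradient comes from the exact adjoint of the discrete IMEX scheme
# (discretise-then-optimise), including the transposed mean-projection of the
# volume constraint, so it matches finite differences of the discrete J to
# near machine precision.

#' Objective functional of the tracking problem
#'
#' Evaluates \eqn{J(\eta;\phi)} with trapezoidal quadrature in space and a
#' step sum times `dt` in time, returning the exact decomposition into the
#' regularisation and misfit terms.
#'
#' @param eta a [ControlField] (piecewise constant per reconstructed step).
#' @param traj the [StateTrajectory] driven by `eta`.
#' @param targets a [TargetSequence] whose times lie on the trajectory's step
#'   grid.
#' @param theta regularisation weight.
#' @return list with `total`, `regularisation_term`, `misfit_term`.
#' @export
objectiveValue <- function(eta, traj, targets, theta) {
  grid <- traj@grid
  wq <- quadWeights(grid)
  sub <- traj@params@substeps
  dt_ctrl <- traj@dt * sub
  reg <- 0.5 * theta * dt_ctrl *
    sum(vapply(eta@values, function(v) sum(wq * v^2), numeric(1)))
  idx <- matchObservationSteps(traj, targets)
  mis <- 0
  for (i in seq_along(idx)) {
    d <- traj@states[[idx[i] + 1L]] - targets@observations[[i]]
    mis <- mis + 0.5 * sum(wq * d^2)
  }
  list(total = reg + mis, regularisation_term = reg, misfit_term = mis)
}

# Map observation times onto solver step indices (0-based); error if an
# observation time is not on the step grid.
matchObservationSteps <- function(traj, targets) {
  idx <- integer(length(targets@times))
  for (i in seq_along(targets@times)) {
    k <- which(abs(traj@times - targets@times[i]) < 1e-9 * max(1, traj@times))
    if (length(k) != 1L)
      stop(sprintf("observation time %.6g is not on the trajectory step grid",
                   targets@times[i]))
    idx[i] <- k - 1L
  }
  idx
}

#' Backward adjoint sweep of the discrete forward scheme
#'
#' Solves the adjoint of the linearised IMEX scheme backward in time, with
#' source injections \eqn{\phi(t_i) - \phi_{obs,i}} at the observation steps
#' and the mean-projection of the volume constraint transposed.  The returned
#' states are aggregated per reconstructed step and scaled so that the
#' first-order optimality condition reads `theta * eta + p = 0` on the band;
#' when every target is met exactly the adjoint vanishes identically.
#'
#' @param traj a [StateTrajectory] with stored states.
#' @param targets a [TargetSequence].
#' @param params a [DimensionlessParams] (uses `eps_bar`, `tau_bar`,
#'   `delta_bar`).
#' @return an [AdjointTrajectory] with one field per reconstructed step.
#' @export
solveAdjoint <- function(traj, targets, params) {
  if (traj@stride != 1L)
    stop("the adjoint needs every solver step stored (keep = 1)")
  grid <- traj@grid
  n <- grid@n
  wq <- quadWeights(grid)
  dt <- traj@dt
  cdt <- dt / (params@eps_bar * params@tau_bar)
  alpha <- dt * params@delta_bar / params@tau_bar
  op <- implicitOperator(grid, alpha)
  constrained <- any(traj@lambdas != 0)
  obsIdx <- matchObservationSteps(traj, targets)

  N <- length(traj@lambdas)
  nrts <- max(traj@controlIndex)
  sub <- traj@params@substeps
  dt_ctrl <- dt * sub
  acc <- rep(list(matrix(0, n, n)), nrts)

  p <- matrix(0, n, n)
  for (k in N:1) {
    oi <- which(obsIdx == k)
    if (length(oi))
      p <- p + wq * (traj@states[[k + 1L]] - targets@observations[[oi]])
    q <- if (constrained) p - wq * sum(p) else p
    r <- applyAinvT(q, op)
    j <- traj@controlIndex[k]
    acc[[j]] <- acc[[j]] + cdt * r
    p <- r - cdt * (params@delta_bar / params@eps_bar) *
      doubleWellDeriv2(traj@states[[k]]) * r
  }
  # scale so that discrete grad(eta_j) = dt_ctrl * wq * (theta*eta_j + p_j)
  states <- lapply(acc, function(a) a / (dt_ctrl * wq))
  new("AdjointTrajectory", states = states, grid = grid)
}

#' First-order optimality gradient of the control
#'
#' Assembles \eqn{g = \theta\bar\eta + p} per reconstructed step and zeroes
#' it outside the interfacial band, yielding a valid [ControlField] descent
#' direction.
#'
#' @param eta current [ControlField].
#' @param adjoint an [AdjointTrajectory] from [solveAdjoint()].
#' @param theta regularisation weight.
#' @param band list of logical band masks (one per reconstructed step).
#' @return a [ControlField] holding the gradient.
#' @export
controlGradient <- function(eta, adjoint, theta, band) {
  vals <- vector("list", length(eta@values))
  for (j in seq_along(vals)) {
    g <- theta * eta@values[[j]] + adjoint@states[[j]]
    g[!band[[j]]] <- 0
    vals[[j]] <- g
  }
  new("ControlField", values = vals, masks = band, grid = eta@grid)
}

# Discrete inner product of two ControlFields: sum_j dt_ctrl sum wq a_j b_j.
controlInner <- function(a, b, grid, dt_ctrl) {
  wq <- quadWeights(grid)
  s <- 0
  for (j in seq_along(a@values)) s <- s + sum(wq * a@values[[j]] * b@values[[j]])
  dt_ctrl * s
}

# Interfacial band masks {|phi| < level} sampled at the start of each
# reconstructed step of a trajectory.
bandMasks <- function(traj, level = 0.95) {
  sub <- traj@params@substeps
  nrts <- max(traj@controlIndex)
  lapply(seq_len(nrts), function(j)
    abs(traj@states[[(j - 1L) * sub + 1L]]) < level)
}

#' Fit the membrane force over one frame pair
#'
#' Minimises the tracking objective for a single frame pair by projected
#' gradient descent with Armijo backtracking, starting from \eqn{\bar\eta=0}.
#' The control is piecewise constant over the `params@RTS` reconstructed
#' steps and restricted to the evolving interfacial band
#' \eqn{\{|\phi| < 0.95\}}; the volume constraint interpolates the masses of
#' the two frames linearly.
#'
#' @param phi_init initial [PhaseField] (chained from the previous pair).
#' @param target target [PhaseField] (the segmented next frame).
#' @param params a [DimensionlessParams].
#' @param duration dimensionless length of the frame interval (defaults
#'   to 1, i.e. a single-pair problem).
#' @param max_iter maximum outer iterations.
#' @param tol relative decrease of `J` that stops the iteration.
#' @param armijo_c sufficient-decrease constant.
#' @param shrink backtracking shrink factor.
#' @param step0 initial line-search step.
#' @param max_backtracks line-search failure threshold.
#' @param band_level half-width of the interfacial band in phi units.
#' @param label frame-pair label carried into the result.
#' @return a [PairResult]; `objectiveHistory` is non-increasing.
#' @export
optimizePair <- function(phi_init, target, params, duration = 1,
                         max_iter = 200L, tol = 1e-6, armijo_c = 1e-4,
                         shrink = 0.5, step0 = 1.0, max_backtracks = 40L,
                         band_level = 0.95, label = "1-2") {
  stopifnot(is(phi_init, "PhaseField"), is(target, "PhaseField"))
  grid <- phi_init@grid
  if (grid@n != target@grid@n) stop("fields must share one grid")
  theta <- params@theta
  m0 <- quadMean(phi_init@values, grid)
  m1 <- quadMean(target@values, grid)
  targets <- new("TargetSequence",
                 observations = list(target@values),
                 times = phi_init@time + duration, masses = m1, grid = grid)

  eta <- zeroControl(grid, params@RTS)
  traj <- solveForward(phi_init, eta, params, mass = c(m0, m1),
                       duration = duration)
  dt_ctrl <- traj@dt * traj@params@substeps
  ob <- objectiveValue(eta, traj, targets, theta)
  history <- ob$total
  converged <- FALSE
  step <- step0

  for (it in seq_len(max_iter)) {
    band <- bandMasks(traj, band_level)
    adj <- solveAdjoint(traj, targets, params)
    g <- controlGradient(eta, adj, theta, band)
    gnorm2 <- controlInner(g, g, grid, dt_ctrl)
    if (gnorm2 == 0) { converged <- TRUE; break }

    accepted <- FALSE
    s <- step
    for (bt in seq_len(max_backtracks)) {
      cand <- eta
      for (j in seq_along(cand@values)) {
        v <- eta@values[[j]] - s * g@values[[j]]
        v[!band[[j]]] <- 0
        cand@values[[j]] <- v
      }
      cand@masks <- band
      ctraj <- solveForward(phi_init, cand, params, mass = c(m0, m1),
                            duration = duration)
      cob <- objectiveValue(cand, ctraj, targets, theta)
      if (cob$total <= ob$total - armijo_c * s * gnorm2) {
        accepted <- TRUE
        break
      }
      s <- s * shrink
    }
    if (!accepted) break   # line search failure: return best iterate
    relDecrease <- (ob$total - cob$total) / max(ob$total, .Machine$double.eps)
    eta <- cand; traj <- ctraj; ob <- cob
    history <- c(history, ob$total)
    step <- min(s / shrink, step0 * 4)   # gentle step recovery
    if (relDecrease < tol) { converged <- TRUE; break }
  }

  new("PairResult", control = eta, trajectory = traj,
      objectiveHistory = history, converged = converged,
      misfit = ob$misfit_term, regularisation = ob$regularisation_term,
      label = label)
}

#' Track a full observation sequence frame pair by frame pair
#'
#' Chains [optimizePair()] across the sequence: the fitted final state of
#' pair `i` is the initial state of pair `i+1`, mirroring how the
#' reconstruction proceeds successively through a video.  `N` observed
#' frames (one initial condition plus `N-1` targets) yield `N-1` pair
#' results.
#'
#' @param targets a [TargetSequence] (frames 2..N of the video).
#' @param phi0 initial [PhaseField] (from frame 1).
#' @param params a [DimensionlessParams].
#' @param ... options passed to [optimizePair()].
#' @return list of [PairResult] objects.
#' @export
trackSequence <- function(targets, phi0, params, ...) {
  nObs <- length(targets@observations)
  if (nObs < 1L)
    stop("tracking needs at least one target frame besides the initial one")
  results <- vector("list", nObs)
  cur <- phi0
  prevTime <- phi0@time
  for (i in seq_len(nObs)) {
    tgt <- phaseField(targets@observations[[i]], targets@grid,
                      time = targets@times[i])
    res <- optimizePair(cur, tgt, params,
                        duration = targets@times[i] - prevTime,
                        label = sprintf("%d-%d", i, i + 1L), ...)
    results[[i]] <- res
    nst <- length(res@trajectory@states)
    cur <- phaseField(res@trajectory@states[[nst]], targets@grid,
                      time = targets@times[i])
    prevTime <- targets@times[i]
  }
  results
}
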
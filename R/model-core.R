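#' Double-well potential and its derivative
#'
#' `doubleWell()` evaluates the quartic potential
#' \eqn{G(\phi) = \frac{1}{4}(1-\phi^2)^2}, which has minima at \eqn{\pm 1}
#' (the two bulk phases: cell interior and exterior).  `doubleWellDeriv()`
#' evaluates \eqn{G'(\phi) = \phi^3 - \phi}.
#'
#' @param phi numeric scalar, vector or matrix.
#' @return numeric of the same shape as `phi`.
#' @examples
#' doubleWell(c(-1, 0, 1))   # 0, 0.25, 0
#' doubleWellDeriv(0.5)      # -0.375
#' @export
doubleWell <- function(phi) 0.25 * (1 - phi^2)^2

#' @rdname doubleWell
#' @export
doubleWellDeriv <- function(phi) phi^3 - phi

# G''(phi), needed by the linearised (adjoint) dynamics.
doubleWellDeriv2 <- function(phi) 3 * phi^2 - 1

#' Nondimensionalize the physical model parameters
#'
#' Maps the dimensional parameters onto the unit square / unit interval model:
#' \eqn{\bar\epsilon = \epsilon/L}, \eqn{\bar\delta = \delta/F},
#' \eqn{\bar\tau = \tau L^2 / (F T)}.  Per-dataset configurations typically
#' prescribe a *numerical* interfacial width that overrides the physical
#' ratio \eqn{\epsilon/L}; pass it as `eps_bar`.
#'
#' @param p a [PhysicalParams] object.
#' @param eps_bar optional numerical interfacial width overriding
#'   `p@eps / p@L`.
#' @param theta control regularisation weight.
#' @param RTS reconstructed time steps per frame pair.
#' @param substeps solver steps per reconstructed step (`NA` = automatic).
#' @return a [DimensionlessParams] object.
#' @examples
#' # MDCK-like configuration: tau_bar = 2.62 * 220^2 / (10 * 1800) = 7.04
#' p <- physicalParams(L = 220, T_total = 1800, TI = 300)
#' nondimensionalize(p, eps_bar = 0.05, RTS = 5)
#' @export
nondimensionalize <- function(p, eps_bar = NULL, theta = 1e-3, RTS = 10L,
                              substeps = NA) {
  stopifnot(is(p, "PhysicalParams"))
  validObject(p)
  tau_bar <- p@tau * p@L^2 / (p@F_char * p@T_total)
  delta_bar <- p@delta / p@F_char
  if (is.null(eps_bar)) eps_bar <- p@eps / p@L
  dimensionlessParams(eps_bar = eps_bar, tau_bar = tau_bar,
                      delta_bar = delta_bar, theta = theta, RTS = RTS,
                      substeps = substeps)
}

#' Restore physical units of a dimensionless membrane force
#'
#' The dimensionless forcing scales as \eqn{\bar\eta = \eta / (F/L)}; the
#' physical force line-density on the membrane is therefore
#' \eqn{\eta = \bar\eta F / L} in pN/um.
#'
#' @param eta_bar numeric scalar, vector or matrix of dimensionless forcing.
#' @param p a [PhysicalParams] object.
#' @return the force density in pN/um, same shape as `eta_bar`.
#' @export
redimensionalizeForce <- function(eta_bar, p) {
  stopifnot(is(p, "PhysicalParams"))
  validObject(p)
  eta_bar * p@F_char / p@L
}

#' Equilibrium tanh interface profile
#'
#' Builds a phase field from a signed-distance field via the equilibrium
#' profile of the quartic double well,
#' \eqn{\phi = \tanh(d / (\sqrt{2}\,\bar\epsilon))}.  The zero level set
#' coincides with the zero of the signed distance.
#'
#' @param signed_distance numeric matrix (or [PhaseField]); positive inside
#'   the cell, negative outside, in dimensionless length units.
#' @param eps_bar interfacial width (> 0).
#' @param grid optional [GridSpec]; if supplied a [PhaseField] is returned.
#' @param time dimensionless time attached to the returned field.
#' @return matrix, or [PhaseField] when `grid` is given.
#' @export
tanhProfile <- function(signed_distance, eps_bar, grid = NULL, time = 0) {
  if (eps_bar <= 0) stop("eps_bar must be positive")
  v <- tanh(signed_distance / (sqrt(2) * eps_bar))
  if (is.null(grid)) v else phaseField(v, grid, time = time)
}
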
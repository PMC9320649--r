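# Shared fixtures and independent oracles, built in code at test time.

# Pixel-labelling Euler characteristic oracle: connected components of
# {phi > 0} minus holes (background components not touching the boundary).
# Independent of the diffuse band integral it checks.
labellingEuler <- function(values) {
  m <- values > 0
  comp <- max(EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1))))
  hl <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((!m) * 1)))
  edge <- unique(c(hl[1, ], hl[nrow(hl), ], hl[, 1], hl[, ncol(hl)]))
  holes <- length(setdiff(unique(hl[hl > 0]), edge))
  comp - holes
}

# Random field of disjoint tanh blobs (disks, occasionally annuli) with a
# known Euler characteristic; rejection sampling keeps shapes separated.
randomBlobField <- function(seed, grid, eps_bar = 0.015, max_shapes = 3L) {
  set.seed(seed)
  shapes <- list(); tries <- 0L
  while (length(shapes) < max_shapes && tries < 200L) {
    tries <- tries + 1L
    ce <- runif(2, 0.18, 0.82); R <- runif(1, 0.08, 0.14)
    ok <- ce[1] - R > 0.05 && ce[1] + R < 0.95 &&
      ce[2] - R > 0.05 && ce[2] + R < 0.95
    for (sh in shapes)
      ok <- ok && sqrt(sum((ce - sh$ce)^2)) > R + sh$R + 6 * eps_bar
    if (ok) shapes <- c(shapes, list(list(ce = ce, R = R,
                                          ann = runif(1) < 0.3)))
  }
  co <- gridCoords(grid)
  f <- matrix(-1, nNodes(grid), nNodes(grid))
  for (sh in shapes) {
    r <- sqrt(outer((co - sh$ce[1])^2, (co - sh$ce[2])^2, `+`))
    # annuli only when the inner circle stays well resolved (>= 4 eps_bar)
    d <- if (sh$ann && sh$R >= 0.12) pmin(sh$R - r, r - 0.5 * sh$R)
         else sh$R - r
    f <- pmax(f, tanh(d / (sqrt(2) * eps_bar)))
  }
  f
}

# Two disjoint tanh disks on one grid.
twoDiskField <- function(grid, eps_bar = 0.015, r = 0.15) {
  phaseField(pmax(
    fieldValues(makeDiskField(c(0.3, 0.3), r, eps_bar, grid)),
    fieldValues(makeDiskField(c(0.7, 0.7), r, eps_bar, grid))), grid)
}

# Tanh annulus (outer radius ro, inner ri) centred in the domain.
annulusField <- function(grid, eps_bar = 0.015, ro = 0.35, ri = 0.2) {
  co <- gridCoords(grid)
  r <- sqrt(outer((co - 0.5)^2, (co - 0.5)^2, `+`))
  tanhProfile(pmin(ro - r, r - ri), eps_bar, grid = grid)
}

# Zero-level radius of a roughly circular field, via the contour arclength.
contourRadius <- function(values, grid) {
  sum(membraneContour(values, grid = grid)@lengths) / (2 * pi)
}

# Minimal hand-built PairResult with a static state and a prescribed
# constant control on one reconstructed step (white-box fixture for the
# force-summary line integral).
staticPair <- function(phi, eta_value, grid, params) {
  n <- nNodes(grid)
  eta <- controlField(matrix(eta_value, n, n), grid)
  pr <- params; pr@substeps <- 1L
  traj <- new("StateTrajectory", states = list(fieldValues(phi),
                                               fieldValues(phi)),
              times = c(0, 1), lambdas = 0, dt = 1, grid = grid,
              params = pr, controlIndex = 1L, stride = 1L)
  new("PairResult", control = eta, trajectory = traj,
      objectiveHistory = c(1, 0.5), converged = TRUE, misfit = 0.5,
      regularisation = 0, label = "1-2")
}

# Standard small parameter set used across solver tests.
testParams <- function(eps_bar = 0.05, tau_bar = 5, delta_bar = 1,
                       theta = 1e-3, RTS = 10L, substeps = NA) {
  dimensionlessParams(eps_bar = eps_bar, tau_bar = tau_bar,
                      delta_bar = delta_bar, theta = theta, RTS = RTS,
                      substeps = substeps)
}
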
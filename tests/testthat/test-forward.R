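test_that("Neumann Laplacian is exact on constants, linears and quadratics", {
  g <- gridSpec(32)
  co <- gridCoords(g)
  expect_true(all(laplacianNeumann(matrix(7, 32, 32), g) == 0))
  fx <- outer(co, rep(1, 32))
  expect_lt(max(abs(laplacianNeumann(fx, g)[2:31, 2:31])), 1e-10)
  fx2 <- outer(co^2, rep(1, 32))
  expect_lt(max(abs(laplacianNeumann(fx2, g)[2:31, 2:31] - 2)), 1e-9)
  expect_error(laplacianNeumann(matrix(0, 16, 16), g), "shape")
})

test_that("uniform bulk states are fixed points and lambda has its closed form", {
  g <- gridSpec(32)
  pr <- testParams(substeps = 1L)
  z <- matrix(0, 32, 32)
  s1 <- phaseFieldStep(phaseField(matrix(1, 32, 32), g), z, 1, pr, 0.01)
  expect_equal(max(abs(fieldValues(s1$phi) - 1)), 0, tolerance = 1e-12)
  expect_equal(s1$lambda, 0, tolerance = 1e-10)
  s0 <- phaseFieldStep(phaseField(z, g), z, 0, pr, 0.01)
  expect_equal(max(abs(fieldValues(s0$phi))), 0, tolerance = 1e-12)
  # constrained uniform update: lambda = eps_bar * tau_bar * dm / dt
  dm <- 0.03
  s2 <- phaseFieldStep(phaseField(matrix(1, 32, 32), g), z, 1 + dm, pr, 0.01)
  expect_equal(s2$lambda, pr@eps_bar * pr@tau_bar * dm / 0.01)
  # all-(-1): no cell, stationary under zero forcing
  sm <- phaseFieldStep(phaseField(matrix(-1, 32, 32), g), z, -1, pr, 0.01)
  expect_equal(max(abs(fieldValues(sm$phi) + 1)), 0, tolerance = 1e-12)
})

test_that("the volume constraint tracks the prescribed mass exactly", {
  g <- gridSpec(48)
  pr <- testParams()
  phi0 <- makeDiskField(c(0.5, 0.5), 0.25, pr@eps_bar, g)
  m0 <- quadMean(fieldValues(phi0), g)
  tr <- solveForward(phi0, zeroControl(g, 10L), pr, mass = c(m0, m0 + 0.05),
                     duration = 0.2)
  want <- m0 + 0.05 * seq_len(nSolverSteps(tr)) / nSolverSteps(tr)
  got <- vapply(tr@states[-1], function(s) quadMean(s, g), numeric(1))
  expect_lt(max(abs(got - want)), 1e-10)
  expect_equal(length(lambdas(tr)), nSolverSteps(tr))
})

test_that("unforced unconstrained flow decreases the interfacial energy", {
  g <- gridSpec(64)
  pr <- testParams(eps_bar = 0.06, tau_bar = 1, substeps = 1L)
  phi0 <- makeDiskField(c(0.5, 0.5), 0.3, pr@eps_bar, g)
  # quarter of the explicit-reaction stability bound eps_bar^2*tau/delta
  dt <- 0.25 * pr@eps_bar^2 * pr@tau_bar / pr@delta_bar
  tr <- solveForward(phi0, zeroControl(g, 50L), pr, mass = NULL,
                     duration = 50 * dt)
  E <- vapply(seq_along(tr@states), function(k)
    ginzburgLandauEnergy(phaseField(tr@states[[k]], g), pr), numeric(1))
  expect_true(all(diff(E) <= 1e-9 * max(1, E[1])))
})

test_that("symmetric data stay symmetric along the trajectory", {
  g <- gridSpec(48)
  pr <- testParams()
  phi0 <- makeDiskField(c(0.5, 0.5), 0.25, pr@eps_bar, g)
  eta <- controlField(
    tanhProfile(0.25 - sqrt(outer((gridCoords(g) - 0.5)^2,
                                  (gridCoords(g) - 0.5)^2, `+`)),
                pr@eps_bar),
    g, nsteps = 5L)
  m0 <- quadMean(fieldValues(phi0), g)
  tr <- solveForward(phi0, eta, pr, mass = m0, duration = 0.1)
  last <- tr@states[[length(tr@states)]]
  mirrored <- last[rev(seq_len(48)), ]
  expect_lt(max(abs(last - mirrored)), 1e-12)
  expect_lt(max(abs(last - t(last))), 1e-12)
})

test_that("the shrinking-circle radius follows mean curvature flow on refinement", {
  # short run at two resolutions: radius error small and grid-consistent
  radiusAt <- function(n) {
    g <- gridSpec(n)
    eb <- 0.03
    pr <- testParams(eps_bar = eb, tau_bar = 1, substeps = 1L)
    phi <- makeDiskField(c(0.5, 0.5), 0.3, eb, g)
    dt <- eb^2 / 16
    nst <- 90L
    tr <- solveForward(phi, zeroControl(g, nst), pr, mass = NULL,
                       duration = nst * dt, keep = nst)
    contourRadius(tr@states[[length(tr@states)]], g)
  }
  r128 <- radiusAt(128)
  r256 <- radiusAt(256)
  rex <- sqrt(0.09 - 2 * 90 * 0.03^2 / 16)
  expect_lt(abs(r128 - rex) / rex, 0.02)
  expect_lt(abs(r256 - r128) / r128, 0.01)
})

test_that("strided storage subsamples states without changing the solution", {
  g <- gridSpec(32)
  pr <- testParams(substeps = 2L)
  phi0 <- makeDiskField(c(0.5, 0.5), 0.25, pr@eps_bar, g)
  m0 <- quadMean(fieldValues(phi0), g)
  full <- solveForward(phi0, zeroControl(g, 4L), pr, mass = m0, duration = 0.1)
  thin <- solveForward(phi0, zeroControl(g, 4L), pr, mass = m0, duration = 0.1,
                       keep = 4L)
  expect_identical(thin@states[[length(thin@states)]],
                   full@states[[length(full@states)]])
  expect_equal(length(thin@states), 3L)
  expect_error(solveAdjoint(thin, targetSequence(list(full@states[[9]]),
                                                 0.1, g), pr), "keep")
})

test_that("trajectory export writes a readable TIFF and step table", {
  g <- gridSpec(32)
  pr <- testParams(substeps = 1L)
  phi0 <- makeDiskField(c(0.5, 0.5), 0.25, pr@eps_bar, g)
  tr <- solveForward(phi0, zeroControl(g, 3L), pr,
                     mass = quadMean(fieldValues(phi0), g), duration = 0.03)
  tdir <- withr::local_tempdir()
  tp <- file.path(tdir, "traj.tif"); cp <- file.path(tdir, "traj.csv")
  tab <- writeTrajectory(tr, tp, cp)
  pages <- tiff::readTIFF(tp, all = TRUE)
  expect_equal(length(pages), 4L)
  back <- read.csv(cp)
  expect_equal(nrow(back), 4L)
  expect_equal(back$mass, tab$mass, tolerance = 1e-12)
  # page 1 decodes back to phi0 through the affine map
  dec <- pages[[1]] * 2.4 - 1.2
  expect_equal(max(abs(cellforce:::rasterToField(dec) - fieldValues(phi0))),
               0, tolerance = 1e-6)
})
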
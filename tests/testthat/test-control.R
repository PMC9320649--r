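test_that("objective decomposes exactly into misfit and regularisation", {
  g <- gridSpec(32)
  pr <- testParams(substeps = 1L, RTS = 4L)
  phi0 <- makeDiskField(c(0.5, 0.5), 0.25, pr@eps_bar, g)
  m0 <- quadMean(fieldValues(phi0), g)
  eta <- zeroControl(g, 4L)
  tr <- solveForward(phi0, eta, pr, mass = m0, duration = 1)

  # trajectory equal to its own target, zero control -> J = 0
  tgt <- targetSequence(list(tr@states[[5]]), 1, g)
  ob <- objectiveValue(eta, tr, tgt, pr@theta)
  expect_equal(ob$total, 0)
  expect_equal(ob$misfit_term + ob$regularisation_term, ob$total)

  # unit offset target on the unit square -> misfit = 1/2
  tgt1 <- targetSequence(list(tr@states[[5]] - 1), 1, g)
  ob1 <- objectiveValue(eta, tr, tgt1, pr@theta)
  expect_equal(ob1$misfit_term, 0.5, tolerance = 1e-12)

  # doubling theta doubles the regularisation term only
  etaC <- controlField(matrix(0.3, 32, 32), g, nsteps = 4L)
  trC <- solveForward(phi0, etaC, pr, mass = m0, duration = 1)
  obA <- objectiveValue(etaC, trC, tgt1, pr@theta)
  obB <- objectiveValue(etaC, trC, tgt1, 2 * pr@theta)
  expect_equal(obB$regularisation_term, 2 * obA$regularisation_term)
  expect_equal(obB$misfit_term, obA$misfit_term)

  # observation time off the step grid is an error
  expect_error(objectiveValue(eta, tr, targetSequence(list(tr@states[[5]]),
                                                      0.876, g), pr@theta),
               "step grid")
})

test_that("adjoint vanishes for met targets and scales linearly in the misfit", {
  g <- gridSpec(24)
  pr <- testParams(eps_bar = 0.1, tau_bar = 2, RTS = 3L, substeps = 1L)
  phi0 <- makeDiskField(c(0.5, 0.5), 0.25, 0.1, g)
  m0 <- quadMean(fieldValues(phi0), g)
  eta <- zeroControl(g, 3L)
  tr <- solveForward(phi0, eta, pr, mass = m0, duration = 1)
  tgtMet <- targetSequence(list(tr@states[[4]]), 1, g)
  adj0 <- solveAdjoint(tr, tgtMet, pr)
  expect_true(all(vapply(adj0@states, function(s) max(abs(s)), numeric(1)) == 0))

  off <- matrix(0.01 * seq_len(24^2), 24, 24)
  adj1 <- solveAdjoint(tr, targetSequence(list(tr@states[[4]] - off), 1, g), pr)
  adj2 <- solveAdjoint(tr, targetSequence(list(tr@states[[4]] - 3 * off), 1, g),
                       pr)
  for (j in 1:3)
    expect_equal(adj2@states[[j]], 3 * adj1@states[[j]], tolerance = 1e-12)
})

test_that("adjoint gradient matches finite differences of the objective", {
  set.seed(0)
  g <- gridSpec(24)
  n <- nNodes(g)
  pr <- testParams(eps_bar = 0.1, tau_bar = 2, RTS = 4L, substeps = 1L)
  phi0 <- makeDiskField(c(0.45, 0.5), 0.25, 0.1, g)
  tgt <- fieldValues(makeDiskField(c(0.55, 0.5), 0.25, 0.1, g))
  targets <- targetSequence(list(tgt), 1, g)
  m <- c(quadMean(fieldValues(phi0), g), quadMean(tgt, g))
  etaV <- lapply(1:4, function(j) matrix(rnorm(n^2, sd = 0.1), n, n))
  eta <- controlField(etaV[[1]], g); eta@values <- etaV
  eta@masks <- lapply(1:4, function(j) matrix(TRUE, n, n))

  Jof <- function(ev) {
    e <- eta; e@values <- ev
    trc <- solveForward(phi0, e, pr, mass = m, duration = 1)
    objectiveValue(e, trc, targets, pr@theta)$total
  }
  tr <- solveForward(phi0, eta, pr, mass = m, duration = 1)
  gr <- controlGradient(eta, solveAdjoint(tr, targets, pr), pr@theta,
                        lapply(1:4, function(j) matrix(TRUE, n, n)))
  wq <- cellforce:::quadWeights(g)
  dt_ctrl <- tr@dt * tr@params@substeps
  for (k in 1:3) {
    dir <- lapply(1:4, function(j) matrix(rnorm(n^2), n, n))
    h <- 1e-5
    fd <- (Jof(Map(`+`, etaV, lapply(dir, `*`, h))) -
             Jof(Map(`+`, etaV, lapply(dir, `*`, -h)))) / (2 * h)
    an <- dt_ctrl * sum(mapply(function(gj, dj) sum(wq * gj * dj),
                               gr@values, dir))
    expect_lt(abs(fd - an) / abs(fd), 1e-5)
  }
})

test_that("gradient restriction to the band is a projection", {
  g <- gridSpec(16)
  band <- list(matrix(c(TRUE, FALSE), 16, 16))
  eta <- controlField(matrix(0.5, 16, 16), g)
  adjC <- new("AdjointTrajectory", states = list(matrix(2, 16, 16)), grid = g)
  gr <- controlGradient(eta, adjC, theta = 0.1, band = band)
  expect_true(all(gr@values[[1]][!band[[1]]] == 0))
  expect_true(all(gr@values[[1]][band[[1]]] == 0.1 * 0.5 + 2))
  # p = 0 -> g = theta * eta on the band
  adj0 <- new("AdjointTrajectory", states = list(matrix(0, 16, 16)), grid = g)
  g0 <- controlGradient(eta, adj0, theta = 0.1, band = band)
  expect_true(all(g0@values[[1]][band[[1]]] == 0.05))
})

test_that("an already-optimal pair returns a near-zero control", {
  g <- gridSpec(48)
  pr <- testParams(RTS = 5L)
  # relax the disk to a stationary state of the constrained flow first, so
  # that the identity target really is attainable with zero forcing
  phi0 <- makeDiskField(c(0.5, 0.5), 0.25, pr@eps_bar, g)
  m0 <- quadMean(fieldValues(phi0), g)
  for (i in 1:4) {
    tr0 <- solveForward(phi0, zeroControl(g, 5L), pr, mass = m0, duration = 2)
    phi0 <- phaseField(tr0@states[[length(tr0@states)]], g, time = 0)
  }
  res <- optimizePair(phi0, phi0, pr, max_iter = 10L)
  expect_true(isConverged(res))
  expect_lt(res@misfit, 1e-8)
  expect_lt(max(vapply(controlValues(fittedControl(res)),
                       function(v) max(abs(v)), numeric(1))), 1e-4)
  expect_true(all(diff(objectiveHistory(res)) <= 0))
})

test_that("stronger regularisation shrinks the fitted control", {
  g <- gridSpec(48)
  phi0 <- makeDiskField(c(0.45, 0.5), 0.22, 0.05, g)
  tgt <- makeDiskField(c(0.52, 0.5), 0.22, 0.05, g, time = 1)
  runTheta <- function(theta) {
    pr <- testParams(theta = theta, RTS = 5L)
    res <- optimizePair(phi0, tgt, pr, max_iter = 25L)
    tr <- fittedTrajectory(res)
    sum(vapply(controlValues(fittedControl(res)),
               function(v) sum(cellforce:::quadWeights(g) * v^2),
               numeric(1))) * tr@dt * tr@params@substeps
  }
  expect_gt(runTheta(1e-3), runTheta(1e3))
})

test_that("sequence tracking chains pairs bit-for-bit", {
  g <- gridSpec(48)
  pr <- testParams(RTS = 3L)
  eb <- pr@eps_bar
  obs <- lapply(1:4, function(i)
    fieldValues(makeDiskField(c(0.35 + 0.05 * i, 0.5), 0.2, eb, g)))
  targets <- targetSequence(obs, times = (1:4) / 4, grid = g)
  phi0 <- makeDiskField(c(0.35, 0.5), 0.2, eb, g)
  res <- trackSequence(targets, phi0, pr, max_iter = 5L)
  expect_length(res, 4L)
  for (i in 2:4) {
    prev <- res[[i - 1]]@trajectory
    expect_identical(res[[i]]@trajectory@states[[1]],
                     prev@states[[length(prev@states)]])
  }
  expect_equal(max(res[[1]]@trajectory@controlIndex), 3L)
  expect_error(trackSequence(targetSequence(list(), numeric(0), g), phi0, pr),
               "at least one")
})
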
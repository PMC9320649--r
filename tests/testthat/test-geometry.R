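test_that("membrane contours are extracted with correct topology and length", {
  g <- gridSpec(256)
  d1 <- makeDiskField(c(0.5, 0.5), 0.25, 0.015, g)
  ct <- membraneContour(d1)
  expect_length(ct@polylines, 1L)
  expect_true(all(ct@closed))
  expect_lt(abs(sum(ct@lengths) - 2 * pi * 0.25) / (2 * pi * 0.25), 0.01)

  two <- twoDiskField(g)
  expect_length(membraneContour(two)@polylines, 2L)

  # single-sign field: empty contour, zero length
  ones <- phaseField(matrix(1, 16, 16), gridSpec(16))
  expect_length(membraneContour(ones)@polylines, 0L)
  expect_equal(membraneLength(membraneContour(ones), 100), 0)
})

test_that("membrane length converges at first order under refinement", {
  err <- vapply(c(64, 128, 256), function(n) {
    g <- gridSpec(n)
    ct <- membraneContour(makeDiskField(c(0.5, 0.5), 0.25, 4 / (n - 1), g))
    abs(sum(ct@lengths) - 2 * pi * 0.25)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3] / err[1], 0.5)
  # physical rescaling
  g <- gridSpec(256)
  ct <- membraneContour(makeDiskField(c(0.5, 0.5), 0.25, 0.015, g))
  expect_equal(membraneLength(ct, 81.5), 2 * pi * 0.25 * 81.5, tolerance = 0.01)
  # hand-built unit square polyline: perimeter 4 x L
  sq <- new("MembraneContour",
            polylines = list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))),
            lengths = 4, closed = TRUE)
  expect_equal(membraneLength(sq, 100), 400)
})

test_that("centroid is symmetric, translation-equivariant and guarded", {
  g <- gridSpec(128)
  expect_equal(unname(cellCentroid(makeDiskField(c(0.5, 0.5), 0.2, 0.03, g))),
               c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(unname(cellCentroid(makeDiskField(c(0.3, 0.7), 0.15, 0.03, g))),
               c(0.3, 0.7), tolerance = gridSpacing(g) / 2)
  expect_equal(unname(cellCentroid(phaseField(matrix(1, 128, 128), g))),
               c(0.5, 0.5), tolerance = 1e-12)
  expect_error(cellCentroid(phaseField(matrix(-1, 128, 128), g)), "undefined")
})

test_that("the diffuse Euler number counts components minus holes", {
  g <- gridSpec(256)
  expect_equal(eulerNumber(makeDiskField(c(0.5, 0.5), 0.25, 0.015, g), 0.8),
               1, tolerance = 0.05)
  expect_equal(eulerNumber(twoDiskField(g), 0.8), 2, tolerance = 0.05)
  expect_equal(eulerNumber(annulusField(g), 0.8), 0, tolerance = 0.05)
  expect_error(eulerNumber(annulusField(g), 1.5), "band level")
})

test_that("cell-count trace flags the division step", {
  mv <- makeDivisionMovie(seed = 3)
  g <- gridSpec(256)
  fields <- lapply(seq_along(mv@masks), function(i)
    maskToPhaseField(mv@masks[[i]], g, eps_bar = 0.015,
                     time = (i - 1) / (length(mv@masks) - 1)))
  tr <- cellCountTrace(fields, c = 0.8)
  div <- mv@meta$division_frame
  expect_equal(tr$count[seq_len(div - 1)], rep(1, div - 1))
  expect_equal(tr$count[div:nrow(tr)], rep(2, nrow(tr) - div + 1))
  # component-labelling oracle brackets the recorded division index
  comps <- vapply(mv@masks, function(m)
    max(EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))),
    numeric(1))
  expect_equal(unname(which(comps == 2)[1]), div)
})

test_that("a static single-cell trajectory keeps a constant unit count", {
  g <- gridSpec(64)
  pr <- testParams(RTS = 4L)
  phi0 <- makeDiskField(c(0.5, 0.5), 0.25, pr@eps_bar, g)
  tr <- solveForward(phi0, zeroControl(g, 4L), pr,
                     mass = quadMean(fieldValues(phi0), g), duration = 0.05)
  trace <- cellCountTrace(tr, c = 0.8)
  expect_equal(nrow(trace), 5L)
  expect_true(all(trace$count == 1))
  expect_length(attr(trace, "events"), 0L)
})

test_that("force summary integrates the control along the membrane", {
  g <- gridSpec(128)
  pr <- testParams(substeps = 1L)
  phys <- physicalParams(L = 100, T_total = 300, TI = 60)
  phi <- makeDiskField(c(0.5, 0.5), 0.25, 0.03, g)
  ell <- sum(membraneContour(phi)@lengths)

  a <- 0.7
  pair <- staticPair(phi, a, g, pr)
  row <- forceSummary(pair, phys)
  expect_equal(row$total_protrusion_pN, a * phys@F_char * ell,
               tolerance = 0.01 * a * phys@F_char * ell)
  expect_equal(row$total_retraction_pN, 0)
  expect_equal(row$protrusion_pct, 100)
  expect_equal(row$protrusion_pct + row$retraction_pct, 100)
  expect_equal(row$avg_membrane_length_um, ell * 100, tolerance = 1e-9)

  # homogeneity in eta and F
  row2 <- forceSummary(staticPair(phi, 2 * a, g, pr), phys)
  expect_equal(row2$total_protrusion_pN, 2 * row$total_protrusion_pN)
  phys2 <- physicalParams(L = 100, T_total = 300, TI = 60, F_char = 20,
                          delta = 20)
  row3 <- forceSummary(staticPair(phi, a, g, pr), phys2)
  expect_equal(row3$total_protrusion_pN, 2 * row$total_protrusion_pN)

  # retraction-only control
  rowN <- forceSummary(staticPair(phi, -a, g, pr), phys)
  expect_equal(rowN$total_protrusion_pN, 0)
  expect_equal(rowN$retraction_pct, 100)
})

test_that("force totals are invariant under a quarter rotation", {
  g <- gridSpec(96)
  pr <- testParams(substeps = 1L)
  phys <- physicalParams(L = 100, T_total = 300, TI = 60)
  phi <- makeDiskField(c(0.42, 0.55), 0.2, 0.04, g)
  co <- gridCoords(g)
  eta <- outer(co - 0.42, co - 0.55, function(x, y) 0.5 * x / 0.2) *
    exp(-(sqrt(outer((co - 0.42)^2, (co - 0.55)^2, `+`)) - 0.2)^2 / 0.004)

  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  mkPair <- function(phiV, etaV) {
    pairT <- staticPair(phaseField(phiV, g), 0, g, pr)
    pairT@control@values[[1]] <- etaV
    pairT@control@masks[[1]] <- matrix(TRUE, 96, 96)
    pairT
  }
  r1 <- forceSummary(mkPair(fieldValues(phi), eta), phys)
  r2 <- forceSummary(mkPair(rot90(fieldValues(phi)), rot90(eta)), phys)
  expect_equal(r2$total_protrusion_pN, r1$total_protrusion_pN,
               tolerance = 1e-6 * max(1, r1$total_protrusion_pN))
  expect_equal(r2$total_retraction_pN, r1$total_retraction_pN,
               tolerance = 1e-6 * max(1, r1$total_retraction_pN))
  expect_equal(r2$protrusion_pct, r1$protrusion_pct, tolerance = 1e-6)
})
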
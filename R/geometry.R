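# Geometric post-processing: membrane contours and length, centroid,
# diffuse-interface Euler number (cell counting), and per-pair force
# summaries in physical units.

#' Membrane contour of a phase field
#'
#' Extracts the zero level set (the cell membrane) as polylines by
#' marching-squares contouring of the bilinear interpolant.  Curves whose
#' endpoints coincide, or that do not touch the domain boundary, are treated
#' as closed.
#'
#' @slot polylines list of two-column matrices of dimensionless vertices.
#' @slot lengths per-polyline arclength (dimensionless).
#' @slot closed logical vector.
#' @export
setClass("MembraneContour", representation(
  polylines = "list", lengths = "numeric", closed = "logical"))

setMethod("show", "MembraneContour", function(object) {
  cat(sprintf("MembraneContour: %d polyline(s), total length %.4g\n",
              length(object@polylines), sum(object@lengths)))
})

#' @param phi a [PhaseField] (or a plain matrix with `grid` supplied).
#' @param grid a [GridSpec] when `phi` is a matrix.
#' @param level contour level (default 0, the membrane).
#' @rdname MembraneContour-class
#' @export
membraneContour <- function(phi, grid = NULL, level = 0) {
  if (is(phi, "PhaseField")) { grid <- phi@grid; phi <- phi@values }
  co <- gridCoords(grid)
  if (min(phi) >= level || max(phi) <= level)
    return(new("MembraneContour", polylines = list(), lengths = numeric(0),
               closed = logical(0)))
  cl <- grDevices::contourLines(co, co, phi, levels = level)
  polylines <- list(); lens <- numeric(0); closed <- logical(0)
  tol <- 1e-9
  for (cc in cl) {
    pts <- cbind(cc$x, cc$y)
    if (nrow(pts) < 2L) next
    endsMatch <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < tol
    onBoundary <- function(p) any(abs(p) < tol) || any(abs(p - 1) < tol)
    isClosed <- endsMatch || (!onBoundary(pts[1, ]) &&
                                !onBoundary(pts[nrow(pts), ]))
    if (endsMatch) pts <- pts[-nrow(pts), , drop = FALSE]
    seg <- segmentLengths(pts, isClosed)
    polylines <- c(polylines, list(pts))
    lens <- c(lens, sum(seg))
    closed <- c(closed, isClosed)
  }
  new("MembraneContour", polylines = polylines, lengths = lens,
      closed = closed)
}

segmentLengths <- function(pts, closed) {
  nxt <- if (closed) c(seq(2L, nrow(pts)), 1L) else seq(2L, nrow(pts))
  cur <- if (closed) seq_len(nrow(pts)) else seq_len(nrow(pts) - 1L)
  sqrt(rowSums((pts[nxt, , drop = FALSE] - pts[cur, , drop = FALSE])^2))
}

#' Physical membrane length
#'
#' Sum of the contour arclengths rescaled by the domain length `L`.
#'
#' @param contour a [MembraneContour].
#' @param L domain side length in um.
#' @return length in um (0 for an empty contour).
#' @export
membraneLength <- function(contour, L) sum(contour@lengths) * L

#' Cell centroid
#'
#' Mass-weighted mean position with weight \eqn{(1+\phi)/2} (the volume
#' fraction of the cell phase).
#'
#' @param phi a [PhaseField].
#' @return numeric length-2 vector (dimensionless coordinates).
#' @export
cellCentroid <- function(phi) {
  grid <- phi@grid
  w <- quadWeights(grid) * (1 + phi@values) / 2
  tot <- sum(w)
  if (tot <= 0) stop("centroid undefined: field contains no cell phase")
  co <- gridCoords(grid)
  c(x = sum(w * co) / tot, y = sum(t(w) * co) / tot)
}

#' Diffuse-interface Euler number
#'
#' Evaluates the band integral of the interfacial curvature density
#' \deqn{N = \frac{1}{4\pi c} \int_{\{|\phi|<c\}} -\Delta\phi +
#'   \frac{\nabla|\nabla\phi|^2 \cdot \nabla\phi}{2|\nabla\phi|^2}\, d\bar x,}
#' which approximates the Euler characteristic of the region
#' \eqn{\{\phi > 0\}} — in effect the number of cells (components minus
#' holes).  Derivatives are central differences with mirror ghosts; nodes
#' where \eqn{|\nabla\phi|^2} falls below a floor of
#' \eqn{10^{-12}\max|\nabla\phi|^2} are excluded.
#'
#' @param phi a [PhaseField] (or matrix with `grid`).
#' @param c band half-width in phi units, in (0, 1); the integral runs over
#'   \eqn{\{|\phi| < c\}}.
#' @param grid a [GridSpec] when `phi` is a matrix.
#' @return numeric; near-integer for well-resolved fields.
#' @export
eulerNumber <- function(phi, c = 0.8, grid = NULL) {
  if (c <= 0 || c >= 1) stop("the band level c must lie in (0, 1)")
  if (is(phi, "PhaseField")) { grid <- phi@grid; phi <- phi@values }
  g <- gradientCentral(phi, grid)
  gg <- g$gx^2 + g$gy^2
  lap <- laplacianNeumann(phi, grid)
  dgg <- gradientCentral(gg, grid)
  floorv <- 1e-12 * max(gg)
  band <- abs(phi) < c & gg > floorv
  integrand <- -lap + (dgg$gx * g$gx + dgg$gy * g$gy) / (2 * pmax(gg, floorv))
  wq <- quadWeights(grid)
  sum(wq[band] * integrand[band]) / (4 * pi * c)
}

#' Euler-number trace along a trajectory (cell counting)
#'
#' Computes the diffuse Euler number at each stored reconstructed step (or
#' each supplied field) and reports where the rounded value changes —
#' candidate division or fusion events.
#'
#' @param x a [StateTrajectory], or a list of [PhaseField]s / matrices.
#' @param c band half-width for [eulerNumber()].
#' @param grid a [GridSpec], required when `x` is a list of plain matrices.
#' @param every for trajectories, evaluate every `every`-th reconstructed
#'   step (default 1 = all).
#' @return data.frame with columns `step`, `time`, `euler`, `count` plus an
#'   attribute `"events"` listing the steps where `count` changes.
#' @export
cellCountTrace <- function(x, c = 0.8, grid = NULL, every = 1L) {
  if (is(x, "StateTrajectory")) {
    if (x@stride != 1L)
      stop("cell counting along a trajectory needs keep = 1")
    sub <- x@params@substeps
    nrts <- max(x@controlIndex)
    ks <- seq(0L, nrts, by = every) * sub
    fields <- x@states[ks + 1L]
    times <- x@times[ks + 1L]
    grid <- x@grid
    steps <- ks / sub
  } else {
    fields <- lapply(x, function(f) if (is(f, "PhaseField")) f@values else f)
    if (is.null(grid)) {
      if (!is(x[[1]], "PhaseField"))
        stop("grid must be supplied for plain matrices")
      grid <- x[[1]]@grid
    }
    times <- vapply(seq_along(x), function(i)
      if (is(x[[i]], "PhaseField")) x[[i]]@time else as.numeric(i - 1L),
      numeric(1))
    steps <- seq_along(fields) - 1L
  }
  eu <- vapply(fields, eulerNumber, numeric(1), c = c, grid = grid)
  cnt <- round(eu)
  out <- data.frame(step = steps, time = times, euler = eu, count = cnt)
  attr(out, "events") <- steps[which(diff(cnt) != 0) + 1L]
  out
}

#' Per-pair membrane force summary
#'
#' Condenses a fitted frame pair into the standard reporting row: average
#' membrane length, accumulated protrusion and retraction force in pN, and
#' the average percentage of the membrane under each.  At each reconstructed
#' step the membrane contour of the state is extracted, the dimensionless
#' forcing is sampled at segment midpoints by bilinear interpolation, and the
#' positive (negative) part is integrated along the contour; the line
#' integral \eqn{\bar\eta (F/L) \cdot \ell L = \bar\eta F \ell} is in pN.
#' Totals are summed over the pair's reconstructed steps; percentages are
#' arclength fractions averaged over steps.  The volume-constraint
#' multiplier \eqn{\lambda} is a global constant force and is not included.
#'
#' @param pair a [PairResult].
#' @param p a [PhysicalParams] (supplies `F_char` and `L`).
#' @return one-row data.frame with columns `frame_pair`,
#'   `avg_membrane_length_um`, `total_protrusion_pN`, `protrusion_pct`,
#'   `total_retraction_pN`, `retraction_pct`.  Steps with an empty contour
#'   make the row `NA` with a warning.
#' @export
forceSummary <- function(pair, p) {
  stopifnot(is(pair, "PairResult"), is(p, "PhysicalParams"))
  traj <- pair@trajectory
  if (traj@stride != 1L)
    stop("force summaries need every solver step stored (keep = 1)")
  grid <- traj@grid
  sub <- traj@params@substeps
  nrts <- max(traj@controlIndex)
  Fc <- p@F_char

  lens <- numeric(nrts)
  protr <- 0; retr <- 0
  protrFrac <- numeric(nrts); retrFrac <- numeric(nrts)
  for (j in seq_len(nrts)) {
    state <- traj@states[[j * sub + 1L]]
    contour <- membraneContour(state, grid = grid)
    if (length(contour@polylines) == 0L) {
      warning(sprintf("pair %s: empty membrane contour at step %d", pair@label, j))
      out <- data.frame(frame_pair = pair@label,
                        avg_membrane_length_um = NA_real_,
                        total_protrusion_pN = NA_real_,
                        protrusion_pct = NA_real_,
                        total_retraction_pN = NA_real_,
                        retraction_pct = NA_real_)
      return(out)
    }
    lens[j] <- sum(contour@lengths)
    etaj <- pair@control@values[[j]]
    lpos <- 0; lneg <- 0; fpos <- 0; fneg <- 0
    for (k in seq_along(contour@polylines)) {
      pts <- contour@polylines[[k]]
      closedk <- contour@closed[k]
      nxt <- if (closedk) c(seq(2L, nrow(pts)), 1L) else seq(2L, nrow(pts))
      cur <- if (closedk) seq_len(nrow(pts)) else seq_len(nrow(pts) - 1L)
      mid <- (pts[cur, , drop = FALSE] + pts[nxt, , drop = FALSE]) / 2
      seg <- segmentLengths(pts, closedk)
      ev <- sampleField(etaj, grid, mid[, 1], mid[, 2])
      pos <- ev > 0
      fpos <- fpos + sum(pmax(ev, 0) * seg)
      fneg <- fneg + sum(-pmin(ev, 0) * seg)
      lpos <- lpos + sum(seg[pos])
      lneg <- lneg + sum(seg[!pos])
    }
    protr <- protr + Fc * fpos
    retr <- retr + Fc * fneg
    protrFrac[j] <- lpos / (lpos + lneg)
    retrFrac[j] <- lneg / (lpos + lneg)
  }
  data.frame(frame_pair = pair@label,
             avg_membrane_length_um = mean(lens) * p@L,
             total_protrusion_pN = protr,
             protrusion_pct = 100 * mean(protrFrac),
             total_retraction_pN = retr,
             retraction_pct = 100 * mean(retrFrac))
}
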
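# Imaging front end: segmentation (Otsu + edge detection), mask cleanup,
# signed-distance construction, tanh profile and resampling onto the solver
# grid.  Raster convention: image row 1 is the top; fields use [i = x,
# j = y increasing upward]; ingestion flips rows exactly once.

#' Default segmentation configuration
#'
#' @param cells_bright are cells brighter than the background?
#' @param min_area minimum connected-component area in pixels.
#' @param sigma Gaussian presmoothing sigma in pixels.
#' @param edge_quantile quantile of the Sobel gradient magnitude used as the
#'   edge threshold.
#' @param close_size diameter (px) of the disc brush closing the edge map.
#' @return named list of options.
#' @export
segmentationConfig <- function(cells_bright = TRUE, min_area = 50L,
                               sigma = 1, edge_quantile = 0.9,
                               close_size = 3L) {
  list(cells_bright = cells_bright, min_area = as.integer(min_area),
       sigma = sigma, edge_quantile = edge_quantile,
       close_size = as.integer(close_size))
}

#' Segment a cell from a grayscale frame
#'
#' Deterministic pipeline: Gaussian presmooth, Otsu threshold (polarity per
#' configuration), union with a morphologically closed Sobel edge map, hole
#' filling, then removal of components below `min_area` pixels.
#'
#' @param frame an [ImageFrame] (or a plain intensity matrix).
#' @param cfg options from [segmentationConfig()].
#' @param crop optional integer vector `c(row0, row1, col0, col1)`
#'   restricting the field of view before segmentation (pixels outside are
#'   treated as background).
#' @return a [CellMask].
#' @export
segmentFrame <- function(frame, cfg = segmentationConfig(), crop = NULL) {
  pix <- if (is(frame, "ImageFrame")) frame@pixels else frame
  rng <- range(pix)
  if (diff(rng) == 0)
    stop("no cell found: frame has constant intensity (threshold undefined)")
  x <- (pix - rng[1]) / diff(rng)
  if (!is.null(crop)) {
    keep <- matrix(FALSE, nrow(x), ncol(x))
    keep[crop[1]:crop[2], crop[3]:crop[4]] <- TRUE
  }
  img <- EBImage::Image(x)
  sm <- EBImage::imageData(EBImage::gblur(img, sigma = cfg$sigma))
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  mask <- if (cfg$cells_bright) sm > th else sm < th

  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::imageData(EBImage::filter2(EBImage::Image(sm), kx))
  gy <- EBImage::imageData(EBImage::filter2(EBImage::Image(sm), t(kx)))
  mag <- sqrt(gx^2 + gy^2)
  em <- mag > stats::quantile(mag, cfg$edge_quantile)
  brush <- EBImage::makeBrush(cfg$close_size, shape = "disc")
  em <- EBImage::imageData(EBImage::closing(EBImage::Image(em * 1), brush)) > 0

  # The closed edge map closes boundary gaps before hole filling; keeping
  # only its interior (not the band itself) avoids inflating the Otsu
  # boundary by the edge-band width.
  filled <- EBImage::imageData(
    EBImage::fillHull(EBImage::Image((mask | em) * 1))) > 0
  m <- mask | (filled & !em)
  m <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m * 1))) > 0
  if (!is.null(crop)) m <- m & keep
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
  if (max(lab) == 0)
    stop("no cell found: segmentation produced an empty mask")
  areas <- tabulate(lab[lab > 0])
  keepLab <- which(areas >= cfg$min_area)
  if (length(keepLab) == 0L)
    stop("no cell found: all components smaller than min_area")
  m <- matrix(lab %in% keepLab, nrow(lab), ncol(lab))
  lab[!m] <- 0
  new("CellMask", values = m, components = lab,
      areas = as.integer(areas[keepLab]))
}

# Convert a raster matrix (row 1 = top) to field orientation [x, y-up].
rasterToField <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

# Inverse of rasterToField.
fieldToRaster <- function(f) {
  m <- t(f)
  m[rev(seq_len(nrow(m))), , drop = FALSE]
}

#' Phase-field representation of a segmentation mask
#'
#' Builds the signed Euclidean distance to the mask boundary (positive
#' inside), rescales it to dimensionless units, resamples it onto the solver
#' grid by bilinear interpolation and applies the equilibrium tanh profile.
#'
#' @param mask a [CellMask] or logical raster matrix.
#' @param grid a [GridSpec].
#' @param eps_bar interfacial width of the profile.
#' @param pixel_size physical pixel size in um; defaults to `L / npix`.
#' @param L physical domain length in um mapped onto the unit square;
#'   defaults to the image extent.
#' @param time dimensionless time of the returned field.
#' @return a [PhaseField]; for an empty mask the field is approximately -1
#'   everywhere and carries the attribute `empty = TRUE`.
#' @export
maskToPhaseField <- function(mask, grid, eps_bar, pixel_size = NULL, L = NULL,
                             time = 0) {
  m <- if (is(mask, "CellMask")) mask@values else mask
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(pixel_size) && is.null(L)) { pixel_size <- 1 / nc; L <- 1 }
  if (is.null(L)) L <- nc * pixel_size
  if (is.null(pixel_size)) pixel_size <- L / nc
  scale <- pixel_size / L

  if (!any(m)) {
    phi <- phaseField(matrix(-1, grid@n, grid@n), grid, time = time)
    attr(phi, "empty") <- TRUE
    return(phi)
  }
  dmax <- nr + nc   # cap: distmap is infinite when a phase fills the image
  dIn <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1)))
  dOut <- EBImage::imageData(EBImage::distmap(EBImage::Image((!m) * 1)))
  dIn[!is.finite(dIn)] <- dmax
  dOut[!is.finite(dOut)] <- dmax
  sd_px <- ifelse(m, pmin(dIn - 0.5, dmax), -pmin(dOut - 0.5, dmax))
  sdField <- rasterToField(sd_px) * scale

  xs <- (seq_len(nc) - 0.5) * scale          # field x coords of pixel centres
  ys <- (seq_len(nr) - 0.5) * scale
  co <- gridCoords(grid)
  qx <- rep(co, times = grid@n)
  qy <- rep(co, each = grid@n)
  dq <- interpBilinear(xs, ys, sdField, qx, qy)
  tanhProfile(matrix(dq, grid@n, grid@n), eps_bar, grid = grid, time = time)
}

#' Convert a frame sequence into tracking inputs
#'
#' Segments every frame, converts masks to phase fields on the solver grid,
#' and splits the result into the initial condition (frame 1) and the target
#' sequence (frames 2..N at dimensionless times `(i-1) * TI / T_total`).
#'
#' @param frames list of [ImageFrame]s, or a [SyntheticMovie].
#' @param grid a [GridSpec].
#' @param eps_bar interfacial width.
#' @param TI frame interval, s.
#' @param T_total experiment duration, s; defaults to
#'   `(length(frames) - 1) * TI` so the last frame sits at time 1.
#' @param L physical domain length, um.
#' @param cfg segmentation options, see [segmentationConfig()].
#' @param crop optional crop box passed to [segmentFrame()].
#' @return list with `phi0` (a [PhaseField]) and `targets`
#'   (a [TargetSequence]).
#' @export
framesToTargets <- function(frames, grid, eps_bar, TI = NULL, T_total = NULL,
                            L = NULL, cfg = segmentationConfig(),
                            crop = NULL) {
  if (is(frames, "SyntheticMovie")) frames <- frames@frames
  nF <- length(frames)
  if (nF < 2L) stop("need at least two frames (initial condition + target)")
  if (is.null(TI)) {
    ts <- vapply(frames, function(f) f@timestamp, numeric(1))
    TI <- if (nF > 1 && diff(ts)[1] > 0) diff(ts)[1] else 1
  }
  if (is.null(T_total)) T_total <- (nF - 1L) * TI
  fields <- vector("list", nF)
  for (i in seq_len(nF)) {
    mask <- tryCatch(segmentFrame(frames[[i]], cfg, crop = crop),
                     error = function(e)
                       stop(sprintf("frame %d: %s", i, conditionMessage(e))))
    ps <- frames[[i]]@pixelSize
    fields[[i]] <- maskToPhaseField(mask, grid, eps_bar, pixel_size = ps,
                                    L = L, time = (i - 1L) * TI / T_total)
  }
  targets <- targetSequence(fields[-1L],
                            times = seq_len(nF - 1L) * TI / T_total, grid)
  list(phi0 = fields[[1L]], targets = targets)
}

#' Read image frames from TIFF or PNG files
#'
#' Accepts a multi-page TIFF path or a vector of single-image paths; color
#' images are averaged to grayscale.
#'
#' @param paths character vector of file paths.
#' @param pixel_size um per pixel.
#' @param TI frame interval in seconds.
#' @return list of [ImageFrame]s.
#' @export
readImageFrames <- function(paths, pixel_size, TI = 1) {
  toGray <- function(a) {
    if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                           drop = FALSE], c(1, 2), mean)
    a
  }
  imgs <- list()
  for (p in paths) {
    if (grepl("\\.tiff?$", p, ignore.case = TRUE)) {
      pages <- tiff::readTIFF(p, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      imgs <- c(imgs, lapply(pages, toGray))
    } else if (grepl("\\.png$", p, ignore.case = TRUE)) {
      imgs <- c(imgs, list(toGray(png::readPNG(p))))
    } else stop("unsupported image format: ", p)
  }
  lapply(seq_along(imgs), function(i)
    imageFrame(imgs[[i]], pixelSize = pixel_size, index = i,
               timestamp = (i - 1) * TI))
}

#' Write a mask as a PNG image
#' @param mask a [CellMask] or logical matrix (raster order).
#' @param path output path.
#' @export
writeMaskPNG <- function(mask, path) {
  m <- if (is(mask, "CellMask")) mask@values else mask
  png::writePNG(m * 1, path)
  invisible(path)
}
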
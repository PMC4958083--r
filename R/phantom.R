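# Synthetic coregistered CT/PET vertebra phantom. Vertebral bodies are
# cylinders (cortical shell + trabecular interior) so every mask has a
# closed-form volume to test against.

# physical layout shared by CT, PET and truth rasterization
phantomLayout <- function(spec) {
  inMarginMM <- 25
  zMarginMM <- 16
  half <- spec@bodyRadiusMM + inMarginMM
  zExtent <- spec@nVertebrae * spec@bodyHeightMM +
    (spec@nVertebrae - 1) * spec@gapMM + 2 * zMarginMM
  zStarts <- zMarginMM +
    (seq_len(spec@nVertebrae) - 1) * (spec@bodyHeightMM + spec@gapMM)
  ctSpacing <- c(1.17, 1.17, 5.0)
  extent <- c(2 * half, 2 * half, zExtent)
  ctDim <- pmax(1L, as.integer(ceiling(extent / ctSpacing)))
  list(centerXY = c(half, half), extent = extent, zStarts = zStarts,
       ctSpacing = ctSpacing, ctDim = ctDim,
       # the grid rebinTrilinear() produces from the native CT, so that
       # CT-derived masks lie voxel-for-voxel on PET
       petDim = pmax(1L, as.integer(ceiling(ctDim * ctSpacing / 4))))
}

#' Physical bounding box of the phantom's vertebral column
#'
#' @param spec a [PhantomSpec-class].
#' @return numeric(6) `(x0, x1, y0, y1, z0, z1)` in mm, suitable as the
#'   `lvBox` of [makeInitialRegion()].
#' @export
phantomBox <- function(spec) {
  lay <- phantomLayout(spec)
  c(lay$centerXY[1] - spec@bodyRadiusMM, lay$centerXY[1] + spec@bodyRadiusMM,
    lay$centerXY[2] - spec@bodyRadiusMM, lay$centerXY[2] + spec@bodyRadiusMM,
    lay$zStarts[1], lay$zStarts[length(lay$zStarts)] + spec@bodyHeightMM)
}

#' Ground-truth vertebra masks on an arbitrary grid
#'
#' Rasterizes the phantom's analytic geometry (voxel-center inclusion) on
#' the given grid: the whole-vertebra mask (cortical shell plus interior)
#' and the intraosseous mask (interior only, the shell stripped radially).
#' The cortical shell is radial: real endplates are thin relative to the
#' 5 mm slice thickness, and modelling axial caps at voxel scale would put
#' whole all-cortical slices into the stack that no in-plane erosion could
#' remove.
#'
#' @param spec a [PhantomSpec-class].
#' @param geometry an [ImageVolume-class] or [BinaryMask-class] grid.
#' @return list with [BinaryMask-class] elements `wholeVertebra` and
#'   `intraosseous`.
#' @export
truthMasks <- function(spec, geometry) {
  lay <- phantomLayout(spec)
  d <- if (is(geometry, "ImageVolume")) dim(geometry@voxels)
       else dim(geometry@support)
  sp <- geometry@spacing; o <- geometry@origin
  x <- o[1] + (seq_len(d[1]) - 1) * sp[1] - lay$centerXY[1]
  y <- o[2] + (seq_len(d[2]) - 1) * sp[2] - lay$centerXY[2]
  z <- o[3] + (seq_len(d[3]) - 1) * sp[3]
  r2 <- outer(x^2, y^2, "+")
  inR <- r2 <= spec@bodyRadiusMM^2
  inRi <- r2 <= (spec@bodyRadiusMM - spec@shellThicknessMM)^2
  whole <- array(FALSE, d); intra <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    zz <- z[k]
    for (z0 in lay$zStarts) {
      if (zz >= z0 && zz <= z0 + spec@bodyHeightMM) {
        whole[, , k] <- whole[, , k] | inR
        intra[, , k] <- intra[, , k] | inRi
      }
    }
  }
  list(wholeVertebra = binaryMask(whole, spacing = sp, origin = o,
                                  label = "truth_whole_vertebra"),
       intraosseous = binaryMask(intra, spacing = sp, origin = o,
                                 label = "truth_intraosseous"))
}

#' Generate the phantom low-dose CT and its ground-truth masks
#'
#' The CT lives on the native low-dose grid (1.17 x 1.17 x 5 mm): cortical
#' shell at `huCortical`, trabecular interior at `huTrabecular`, soft-tissue
#' background at `huBackground`, plus seeded additive Gaussian noise of sd
#' `ctNoiseHU`.
#'
#' @param spec a [PhantomSpec-class].
#' @return list: `ct` (an [ImageVolume-class]) and `truth` (the
#'   [truthMasks()] list on the native grid).
#' @export
generateCT <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  lay <- phantomLayout(spec)
  sp <- lay$ctSpacing
  d <- lay$ctDim
  geom <- imageVolume(array(0, d), spacing = sp, origin = c(0, 0, 0))
  truth <- truthMasks(spec, geom)
  v <- array(spec@huBackground, d)
  v[truth$wholeVertebra@support] <- spec@huCortical
  v[truth$intraosseous@support] <- spec@huTrabecular
  if (spec@ctNoiseHU > 0) {
    set.seed(spec@seed)
    v <- v + stats::rnorm(length(v), sd = spec@ctNoiseHU)
  }
  list(ct = imageVolume(v, spacing = sp, origin = c(0, 0, 0),
                        modality = "CT"),
       truth = truth)
}

# separable Gaussian blur of a 3D array, sigma in voxels per axis,
# replicate-padded borders
gaussBlur3D <- function(a, sigmaVox) {
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- stats::dnorm(-r:r, sd = s); k <- k / sum(k)
    d <- dim(a)
    n <- d[ax]
    idx <- pmin(pmax(outer(seq_len(n), -r:r, "+"), 1L), n)
    ap <- aperm(a, c(ax, setdiff(1:3, ax)))
    m <- matrix(ap, nrow = n)
    acc <- matrix(0, nrow = n, ncol = ncol(m))
    for (j in seq_len(2 * r + 1))
      acc <- acc + k[j] * m[idx[, j], , drop = FALSE]
    ap <- array(acc, dim(ap))
    a <- aperm(ap, order(c(ax, setdiff(1:3, ax))))
  }
  a
}

#' Generate the matched serial PET acquisition
#'
#' On a 4 mm isotropic grid covering the CT extent (the grid
#' [rebinTrilinear()] produces, so CT-derived masks lie voxel-for-voxel on
#' PET): marrow voxels take `C(t) = marrowC0 * 2^(-t / effectiveHalfLifeH)`
#' at each scan time, background takes 5 percent of `C(t)`, then the volume
#' is blurred by the PET point-spread (`psfFwhmMM`) and degraded with
#' seeded multiplicative Gaussian noise (`petNoiseFrac`).
#'
#' @param spec a [PhantomSpec-class].
#' @param marrow optional marrow [BinaryMask-class] on the PET grid;
#'   defaults to the analytic intraosseous truth.
#' @param backgroundFrac background uptake as a fraction of marrow uptake.
#' @return list of PET [ImageVolume-class] objects, one per scan time.
#' @export
generatePETSeries <- function(spec, marrow = NULL, backgroundFrac = 0.05) {
  stopifnot(is(spec, "PhantomSpec"))
  lay <- phantomLayout(spec)
  sp <- c(4, 4, 4)
  d <- lay$petDim
  geom <- imageVolume(array(0, d), spacing = sp, origin = c(0, 0, 0))
  if (is.null(marrow)) marrow <- truthMasks(spec, geom)$intraosseous
  if (!any(marrow@support)) stop("marrow truth mask is empty")
  sigmaVox <- rep(spec@psfFwhmMM / 2.3548, 3) / sp
  set.seed(spec@seed + 1L)
  lapply(spec@scanTimesH, function(t) {
    ct <- spec@marrowC0 * 2^(-t / spec@effectiveHalfLifeH)
    v <- array(backgroundFrac * ct, d)
    v[marrow@support] <- ct
    if (spec@psfFwhmMM > 0) v <- gaussBlur3D(v, sigmaVox)
    if (spec@petNoiseFrac > 0)
      v <- pmax(v * (1 + stats::rnorm(length(v), sd = spec@petNoiseFrac)), 0)
    imageVolume(array(v, d), spacing = sp, origin = c(0, 0, 0),
                modality = "PET", timeH = t)
  })
}
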
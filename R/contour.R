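# Automatic lumbar-vertebra delineation: per-slice regularized Chan-Vese
# level-set evolution on the rebinned low-dose CT, followed by in-plane
# morphological erosion to strip the cortical shell.

# ---- small matrix helpers ---------------------------------------------------

# shift a matrix by (dx, dy), padding with `fill`
shiftMat <- function(m, dx, dy, fill) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(fill, n1, n2)
  xs <- seq_len(n1) - dx; ys <- seq_len(n2) - dy
  okx <- xs >= 1 & xs <= n1; oky <- ys >= 1 & ys <= n2
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

# central differences with replicated edges (Neumann boundary)
gradX <- function(m) {
  up <- rbind(m[1, , drop = FALSE], m[-nrow(m), , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE])
  (dn - up) / 2
}
gradY <- function(m) {
  lf <- cbind(m[, 1, drop = FALSE], m[, -ncol(m), drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], m[, ncol(m), drop = FALSE])
  (rt - lf) / 2
}
laplacian <- function(m) {
  up <- rbind(m[1, , drop = FALSE], m[-nrow(m), , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE])
  lf <- cbind(m[, 1, drop = FALSE], m[, -ncol(m), drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], m[, ncol(m), drop = FALSE])
  up + dn + lf + rt - 4 * m
}

# signed distance to the region boundary, positive inside (voxel units)
signedDistance <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  din <- as.matrix(EBImage::distmap(m))
  dout <- as.matrix(EBImage::distmap(1 - m))
  din - dout
}

# ---- operations -------------------------------------------------------------

#' Build the loose initialization region c1 around the lumbar vertebrae
#'
#' Rasterizes a physical-space box on the volume grid (voxel-center
#' inclusion) and dilates it by `marginMM` in every direction — the loose
#' region, drawn with about a 1 cm margin around the five vertebral
#' segments, that seeds the active contour. The margin is applied in whole
#' voxels, rounded outward (10 mm on a 4 mm grid is 3 voxels).
#'
#' @param vol the (rebinned) CT [ImageVolume-class].
#' @param lvBox numeric(6): physical box `(x0, x1, y0, y1, z0, z1)` in mm.
#' @param marginMM margin added on all sides (default 10 mm).
#' @return A [BinaryMask-class] c1 on `vol`'s grid.
#' @export
makeInitialRegion <- function(vol, lvBox, marginMM = 10) {
  stopifnot(is(vol, "ImageVolume"), length(lvBox) == 6L)
  d <- dim(vol@voxels)
  lo <- lvBox[c(1, 3, 5)]; hi <- lvBox[c(2, 4, 6)]
  if (any(hi < lo)) stop("lvBox must have min <= max on each axis")
  # voxel-center inclusion of the box itself
  i0 <- ceiling((lo - vol@origin) / vol@spacing - 1e-9)
  i1 <- floor((hi - vol@origin) / vol@spacing + 1e-9)
  # whole-voxel outward margin
  mv <- ceiling(marginMM / vol@spacing - 1e-9)
  i0 <- pmax(i0 - mv, 0)
  i1 <- pmin(i1 + mv, d - 1)
  if (any(i1 < i0))
    stop("empty region: box does not intersect the volume")
  sup <- array(FALSE, d)
  sup[(i0[1]:i1[1]) + 1, (i0[2]:i1[2]) + 1, (i0[3]:i1[3]) + 1] <- TRUE
  binaryMask(sup, geometry = vol, label = "c1")
}

#' Evolve the regularized Chan-Vese contour on one CT slice
#'
#' Gradient descent on the two-region piecewise-constant segmentation energy
#' with a distance-regularization term (see [ContourParams-class]). Slice
#' intensities are rescaled to `[0, 1]` before evolution so the region-fit
#' weights need no retuning per image; region means are recomputed each
#' iteration with the smoothed Heaviside weighting, and `phi` starts as the
#' signed distance to the boundary of `init` (positive inside). The returned
#' region is `{phi > 0}`. If the converged inside mean falls below the
#' outside mean (a polarity flip on unusual seeds) the complement is
#' returned with a warning; a constant slice returns an empty region with a
#' degenerate-convergence warning.
#'
#' @param sliceImg numeric matrix of HU values.
#' @param init logical matrix seeding the contour; must be non-empty and not
#'   the whole slice.
#' @param params a [ContourParams-class].
#' @return Logical matrix of the inside region, with attribute
#'   `"diagnostics"`: a one-row data.frame with iterations, final region
#'   means in HU, and a degenerate flag.
#' @export
evolveSlice <- function(sliceImg, init, params = contourParams()) {
  stopifnot(is.matrix(sliceImg), is.matrix(init))
  if (!all(is.finite(sliceImg))) stop("slice intensities must be finite")
  if (!any(init)) stop("initialization region is empty")
  if (all(init)) stop("initialization region covers the whole slice")
  rng <- range(sliceImg)
  diag1 <- function(cin, cout, degen) data.frame(
    iterations = params@nIter, c_in_HU = cin, c_out_HU = cout,
    degenerate = degen)
  if (diff(rng) == 0) {
    warning("degenerate slice: constant intensity, no data-term gradient")
    out <- matrix(FALSE, nrow(sliceImg), ncol(sliceImg))
    attr(out, "diagnostics") <- diag1(rng[1], rng[1], TRUE)
    return(out)
  }
  I <- (sliceImg - rng[1]) / diff(rng)
  phi <- signedDistance(init)
  eps <- params@epsilon
  cin <- cout <- NA_real_
  for (it in seq_len(params@nIter)) {
    H <- 0.5 * (1 + 2 / pi * atan(phi / eps))
    delta <- eps / (pi * (eps^2 + phi^2))
    sH <- sum(H); sHc <- sum(1 - H)
    cin <- if (sH > 0) sum(I * H) / sH else mean(I)
    cout <- if (sHc > 0) sum(I * (1 - H)) / sHc else mean(I)
    gx <- gradX(phi); gy <- gradY(phi)
    ng <- sqrt(gx^2 + gy^2 + 1e-10)
    curv <- gradX(gx / ng) + gradY(gy / ng)
    # double-well distance regularization: diffusion rate p'(s)/s stays
    # bounded, avoiding the backward diffusion of the naive (|grad|-1)^2 form
    dpOverS <- ifelse(ng <= 1,
                      ifelse(ng < 1e-6, 1, sin(2 * pi * ng) / (2 * pi * ng)),
                      1 - 1 / ng)
    distreg <- gradX((dpOverS - 1) * gx) + gradY((dpOverS - 1) * gy) +
      laplacian(phi)
    force <- -params@lambdaIn * (I - cin)^2 + params@lambdaOut * (I - cout)^2
    # CFL cap: the zero level set advances at most one voxel per iteration
    step <- params@dt * delta * (params@muLength * curv + force)
    step <- pmin(pmax(step, -1), 1)
    phi <- phi + params@muReg * distreg + step
  }
  out <- phi > 0
  toHU <- function(v) v * diff(rng) + rng[1]
  if (any(out) && !all(out)) {
    mi <- mean(sliceImg[out]); mo <- mean(sliceImg[!out])
    if (mi < mo) {
      warning("contour polarity flipped: returning complement region")
      out <- !out
      tmp <- cin; cin <- cout; cout <- tmp
    }
  }
  attr(out, "diagnostics") <- diag1(toHU(cin), toHU(cout), FALSE)
  out
}

#' Find the outer bone contour c2 of the lumbar vertebrae
#'
#' Applies [evolveSlice()] independently to every axial slice intersecting
#' the loose region c1, restricted to c1 (voxels outside c1 are never
#' included), and stacks the slice results into the 3D outer-bone mask c2 —
#' the region enclosing compact bone and bone marrow. Because c2 is defined
#' by its *outer* contour, interior holes in a slice result are filled.
#' Connected slice components whose mean CT value falls below
#' `params@minBoneHU` are discarded: calibrated HU separates bone from soft
#' tissue, and intervertebral slices inside c1 contain no bone to delineate.
#'
#' @param vol the rebinned CT [ImageVolume-class] (PET grid).
#' @param c1 the loose-region [BinaryMask-class] from [makeInitialRegion()].
#' @param params a [ContourParams-class].
#' @return A [BinaryMask-class] c2, with attribute `"diagnostics"`: one row
#'   per processed slice (slice index, iterations, region means, kept voxel
#'   count).
#' @export
findOuterBone <- function(vol, c1, params = contourParams()) {
  stopifnot(is(vol, "ImageVolume"), is(c1, "BinaryMask"))
  if (!sameGeometry(vol, c1)) stop("c1 geometry does not match the volume")
  if (!any(c1@support)) stop("empty region: c1 contains no voxels")
  d <- dim(vol@voxels)
  out <- array(FALSE, d)
  rows <- vector("list", d[3])
  for (z in seq_len(d[3])) {
    initSlice <- c1@support[, , z]
    if (!any(initSlice)) next
    res <- withCallingHandlers(
      evolveSlice(vol@voxels[, , z], initSlice, params),
      warning = function(w) invokeRestart("muffleWarning"))
    dg <- attr(res, "diagnostics")
    keep <- res & initSlice
    if (any(keep) && !dg$degenerate) {
      # fill interior holes: c2 is the region enclosed by the outer contour
      keep <- as.matrix(EBImage::fillHull(matrix(as.integer(keep),
                                                 d[1], d[2]))) > 0
      keep <- keep & initSlice
      # HU gate per connected component
      lab <- EBImage::bwlabel(matrix(as.integer(keep), d[1], d[2]))
      img <- vol@voxels[, , z]
      for (cc in seq_len(max(lab))) {
        sel <- lab == cc
        if (mean(img[sel]) < params@minBoneHU) keep[sel] <- FALSE
      }
    } else {
      keep <- matrix(FALSE, d[1], d[2])
    }
    out[, , z] <- keep
    rows[[z]] <- cbind(slice = z, dg, kept_voxels = sum(keep))
  }
  mask <- binaryMask(out, geometry = vol, label = "c2")
  attr(mask, "diagnostics") <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  mask
}

#' Erode the outer bone contour to the intraosseous volume c3
#'
#' Per-slice (in-plane) binary erosion of c2 by a cross-shaped structuring
#' element spanning `kernelPx` voxels vertically and horizontally — removing
#' the cortical-bone layer so only the intraosseous (marrow) volume remains.
#' The three kernel sizes correspond to the large (3), medium (2) and small
#' (1) erosion kernels.
#'
#' @param c2 the outer-bone [BinaryMask-class].
#' @param kernelPx erosion radius in voxels (0 = identity; 3 is the default
#'   large kernel).
#' @param element `"cross"` (default: vertical + horizontal arms) or
#'   `"square"` (full `(2k+1)^2` neighborhood).
#' @return A [BinaryMask-class] c3; an empty result is valid.
#' @export
erodeToIntraosseous <- function(c2, kernelPx = 3,
                                element = c("cross", "square")) {
  stopifnot(is(c2, "BinaryMask"), kernelPx >= 0)
  element <- match.arg(element)
  kernelPx <- as.integer(kernelPx)
  d <- dim(c2@support)
  out <- c2@support
  if (kernelPx > 0) {
    offsets <- if (element == "cross") {
      k <- setdiff(-kernelPx:kernelPx, 0)
      rbind(cbind(k, 0), cbind(0, k))
    } else {
      as.matrix(expand.grid(dx = -kernelPx:kernelPx, dy = -kernelPx:kernelPx))
    }
    for (z in seq_len(d[3])) {
      sl <- c2@support[, , z]
      if (!any(sl)) { out[, , z] <- FALSE; next }
      acc <- sl
      for (r in seq_len(nrow(offsets)))
        acc <- acc & shiftMat(sl, offsets[r, 1], offsets[r, 2], FALSE)
      out[, , z] <- acc
    }
  }
  binaryMask(out, geometry = c2, label = sprintf("c3_k%d", kernelPx))
}

#' Run the full delineation pipeline c1 -> c2 -> c3
#'
#' @param vol the rebinned CT [ImageVolume-class].
#' @param lvBox physical box around the vertebral segments (mm), see
#'   [makeInitialRegion()].
#' @param params a [ContourParams-class].
#' @param kernels erosion kernel sizes to produce (default 1, 2, 3).
#' @param marginMM c1 margin in mm.
#' @return A [DelineationResult-class].
#' @export
delineate <- function(vol, lvBox, params = contourParams(), kernels = 1:3,
                      marginMM = 10) {
  c1 <- makeInitialRegion(vol, lvBox, marginMM = marginMM)
  c2 <- findOuterBone(vol, c1, params)
  dg <- attr(c2, "diagnostics")
  c3 <- lapply(kernels, function(k) erodeToIntraosseous(c2, k))
  names(c3) <- as.character(kernels)
  new("DelineationResult", c1 = c1, c2 = c2, c3 = c3,
      diagnostics = if (is.null(dg)) data.frame() else dg)
}
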
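# Manual cylindrical VOIs, PET value extraction and Dice overlap.

#' Rasterize a cylindrical VOI on an image grid
#'
#' A voxel is included iff its center lies inside the cylinder: in-plane
#' distance to the axis at most `diameter/2` and axial distance at most
#' `height/2`. With the default 1.9 cm x 2 cm cylinder on a 4 mm grid with
#' the center on a voxel center, the mask spans exactly five axial slices —
#' the circular regions drawn in five slices per vertebral segment.
#'
#' @param spec a [CylinderSpec-class].
#' @param geometry an [ImageVolume-class] or [BinaryMask-class] supplying the
#'   grid.
#' @return A [BinaryMask-class] on `geometry`'s grid.
#' @export
makeCylinderVOI <- function(spec, geometry) {
  stopifnot(is(spec, "CylinderSpec"))
  d <- if (is(geometry, "ImageVolume")) dim(geometry@voxels)
       else dim(geometry@support)
  sp <- geometry@spacing; o <- geometry@origin
  x <- o[1] + (seq_len(d[1]) - 1) * sp[1] - spec@center[1]
  y <- o[2] + (seq_len(d[2]) - 1) * sp[2] - spec@center[2]
  z <- o[3] + (seq_len(d[3]) - 1) * sp[3] - spec@center[3]
  r2 <- (spec@diameterMM / 2)^2
  inplane <- outer(x^2, y^2, "+") <= r2
  inz <- abs(z) <= spec@heightMM / 2
  sup <- array(FALSE, d)
  for (k in which(inz)) sup[, , k] <- inplane
  # outside the grid's physical extent entirely -> error; inside but too
  # small to catch a voxel center -> legitimate empty mask
  lo <- o - sp / 2; hi <- o + (d - 0.5) * sp
  cLo <- spec@center - c(spec@diameterMM / 2, spec@diameterMM / 2,
                         spec@heightMM / 2)
  cHi <- spec@center + c(spec@diameterMM / 2, spec@diameterMM / 2,
                         spec@heightMM / 2)
  if (any(cHi < lo) || any(cLo > hi))
    stop("empty region: cylinder does not intersect the grid")
  binaryMask(sup, spacing = sp, origin = o, label = "manual_VOI")
}

#' Mean PET activity concentration under a mask
#'
#' Maps a CT-derived VOI onto the coregistered PET volume and returns the
#' arithmetic mean of the PET voxel values under the mask, in Bq/mL.
#'
#' @param mask a [BinaryMask-class].
#' @param pet a PET [ImageVolume-class] on the same grid.
#' @return Mean concentration, Bq/mL.
#' @export
meanConcentration <- function(mask, pet) {
  stopifnot(is(mask, "BinaryMask"), is(pet, "ImageVolume"))
  if (!sameGeometry(mask, pet))
    stop("grid mismatch between mask and PET volume")
  if (!any(mask@support)) stop("empty region: mask contains no voxels")
  mean(pet@voxels[mask@support])
}

#' Dice similarity coefficient between two masks
#'
#' `DSC = 2 |A intersect M| / (|A| + |M|)` by voxel counts; the volume
#' overlap between the automatic (A) and manual (M) VOI.
#'
#' @param a,m [BinaryMask-class] objects on the same grid.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, m) {
  stopifnot(is(a, "BinaryMask"), is(m, "BinaryMask"))
  if (!sameGeometry(a, m)) stop("grid mismatch between masks")
  na <- sum(a@support); nm <- sum(m@support)
  if (na + nm == 0) stop("DSC undefined: both masks are empty")
  2 * sum(a@support & m@support) / (na + nm)
}

#' Extract a region time-activity curve from a serial PET acquisition
#'
#' @param mask the region [BinaryMask-class] on the PET grid.
#' @param petSeries list of PET [ImageVolume-class] objects with ascending
#'   `timeH`.
#' @param region region label (defaults to the mask label).
#' @param volumeML region volume to attach (defaults to the mask volume).
#' @return A [TimeActivityCurve-class].
#' @export
extractTAC <- function(mask, petSeries, region = NULL, volumeML = NULL) {
  stopifnot(is.list(petSeries), length(petSeries) >= 1)
  times <- vapply(petSeries, function(p) p@timeH, numeric(1))
  if (any(is.na(times)))
    stop("every PET volume needs an acquisition time (timeH)")
  ord <- order(times)
  conc <- vapply(petSeries[ord], function(p) meanConcentration(mask, p),
                 numeric(1))
  timeActivityCurve(
    region = if (is.null(region)) {
      if (nzchar(mask@label)) mask@label else "region"
    } else region,
    timesH = times[ord], concBqPerML = pmax(conc, 0),
    volumeML = if (is.null(volumeML)) maskVolumeML(mask) else volumeML)
}
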
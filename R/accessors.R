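#' @name accessors
#' @title Accessors for image-grid objects
#' @description `voxels()` returns the raw array, `voxelSpacing()` and
#'   `voxelOrigin()` the grid geometry in mm, `maskSupport()` the logical
#'   array of a mask, and `maskVolumeML()` the mask volume in mL
#'   (voxel count times voxel volume).
#' @param x an [ImageVolume-class] or [BinaryMask-class].
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "ImageVolume", function(x) x@voxels)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "BinaryMask", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "ImageVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "BinaryMask", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("maskSupport", function(x) standardGeneric("maskSupport"))
#' @rdname accessors
#' @export
setMethod("maskSupport", "BinaryMask", function(x) x@support)

#' @rdname accessors
#' @export
setGeneric("maskVolumeML", function(x) standardGeneric("maskVolumeML"))
#' @rdname accessors
#' @export
setMethod("maskVolumeML", "BinaryMask", function(x)
  sum(x@support) * prod(x@spacing) / 1000)

#' Do two grid objects share the same geometry?
#'
#' @param a,b [ImageVolume-class] or [BinaryMask-class] objects.
#' @param tol relative tolerance on spacing/origin comparison.
#' @return `TRUE` if dimensions, spacing and origin agree.
#' @export
sameGeometry <- function(a, b, tol = 1e-6) {
  da <- if (is(a, "ImageVolume")) dim(a@voxels) else dim(a@support)
  db <- if (is(b, "ImageVolume")) dim(b@voxels) else dim(b@support)
  identical(da, db) &&
    all(abs(a@spacing - b@spacing) <= tol * pmax(1, abs(a@spacing))) &&
    all(abs(a@origin - b@origin) <= tol * pmax(1, abs(a@origin)))
}

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume [%s] %d x %d x %d, spacing (%.2f, %.2f, %.2f) mm\n",
              object@modality, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  if (!is.na(object@timeH))
    cat(sprintf("  acquired %.1f h post injection\n", object@timeH))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@support)
  cat(sprintf("BinaryMask%s %d x %d x %d, %d voxels, %.2f mL\n",
              if (nzchar(object@label)) sprintf(" '%s'", object@label) else "",
              d[1], d[2], d[3], sum(object@support), maskVolumeML(object)))
})

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve '%s' (%d samples, volume %.1f mL)\n",
              object@region, length(object@timesH), object@volumeML))
  print(data.frame(time_h = object@timesH,
                   conc_Bq_per_mL = object@concBqPerML))
})

setMethod("show", "ResidenceTimeSet", function(object) {
  cat("ResidenceTimeSet (hours):\n")
  for (nm in names(object@tauH))
    cat(sprintf("  %-12s %8.3f\n", nm, object@tauH[[nm]]))
  cat(sprintf("  %-12s %8.3f\n", "remainder", object@tauRemainderH))
})

setMethod("show", "DoseReport", function(object) {
  cat(sprintf("DoseReport: self RM dose %.4g mGy/MBq, total RM dose %.4g mGy/MBq\n",
              object@selfDose, object@totalDose))
})

setMethod("show", "DelineationResult", function(object) {
  cat("DelineationResult:\n  c1:", sum(object@c1@support), "voxels\n",
      " c2:", sum(object@c2@support), "voxels\n")
  for (k in names(object@c3))
    cat(sprintf("  c3[kernel %s]: %d voxels\n", k, sum(object@c3[[k]]@support)))
})

#' Convert a time-activity curve to a data.frame
#'
#' @param x a [TimeActivityCurve-class].
#' @param ... ignored.
#' @return data.frame with columns region, time_h, conc_Bq_per_mL, volume_mL.
#' @export
as.data.frame.TimeActivityCurve <- function(x, ...) {
  data.frame(region = x@region, time_h = x@timesH,
             conc_Bq_per_mL = x@concBqPerML, volume_mL = x@volumeML)
}
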
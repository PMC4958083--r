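# NIfTI I/O and resampling. Grid convention throughout the package:
# voxel (i,j,k) (0-based) sits at physical position origin + c(i,j,k)*spacing,
# and the grid's physical extent is dim*spacing (half a voxel beyond the
# first/last centers on each side).

#' Read a 3D volume from NIfTI, with an optional JSON sidecar
#'
#' Spacing is taken from the NIfTI `pixdim` and the origin from the qform
#' offset. The sidecar, if given, supplies study metadata the NIfTI header
#' has no home for: `modality`, `time_post_injection_h`,
#' `injected_activity_MBq`, `patient_weight_kg`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param sidecar optional path to the JSON sidecar.
#' @return An [ImageVolume-class]; when a sidecar with study fields is
#'   present, attribute `"meta"` carries the parsed list.
#' @export
readVolume <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions")
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI header has missing or non-positive voxel spacing")
  hdr <- RNifti::niftiHeader(img)
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  modality <- "CT"
  timeH <- NA_real_
  meta <- NULL
  if (!is.null(sidecar)) {
    if (!file.exists(sidecar)) stop("cannot read sidecar: ", sidecar)
    meta <- jsonlite::fromJSON(sidecar)
    if (!is.null(meta$modality)) modality <- meta$modality
    if (!is.null(meta$time_post_injection_h))
      timeH <- as.numeric(meta$time_post_injection_h)
  }
  vol <- imageVolume(array(as.numeric(img), d), spacing = spacing,
                     origin = origin, modality = modality, timeH = timeH)
  attr(vol, "meta") <- meta
  vol
}

#' Write a volume as NIfTI, with an optional JSON sidecar
#'
#' Voxels are stored as float32; geometry round-trips through [readVolume()]
#' at that precision.
#'
#' @param vol an [ImageVolume-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @param sidecar optional path for the JSON sidecar; written when either
#'   `sidecar` is non-`NULL` and the volume has a time or `meta` is given.
#' @param meta optional [StudyMeta-class] merged into the sidecar.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path, sidecar = NULL, meta = NULL) {
  stopifnot(is(vol, "ImageVolume"))
  img <- RNifti::asNifti(vol@voxels,
                         reference = list(qoffset_x = vol@origin[1],
                                          qoffset_y = vol@origin[2],
                                          qoffset_z = vol@origin[3],
                                          qform_code = 1))
  RNifti::pixdim(img) <- vol@spacing
  ok <- try(RNifti::writeNifti(img, path, datatype = "float"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write NIfTI file: ", path)
  if (!is.null(sidecar)) {
    sc <- list(modality = vol@modality)
    if (!is.na(vol@timeH)) sc$time_post_injection_h <- vol@timeH
    if (!is.null(meta)) {
      sc$injected_activity_MBq <- meta@injectedMBq
      sc$patient_weight_kg <- meta@weightKg
    }
    jsonlite::write_json(sc, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a JSON sidecar into a StudyMeta
#'
#' @param path sidecar path.
#' @return A [StudyMeta-class]; scan times default to the single
#'   `time_post_injection_h` if no list is present.
#' @export
readStudyMeta <- function(path) {
  m <- jsonlite::fromJSON(path)
  times <- if (!is.null(m$scan_times_h)) m$scan_times_h
           else if (!is.null(m$time_post_injection_h)) m$time_post_injection_h
           else numeric()
  studyMeta(injectedMBq = as.numeric(m$injected_activity_MBq),
            weightKg = as.numeric(m$patient_weight_kg),
            scanTimesH = times)
}

# Trilinear sample of a 3D array at continuous 0-based indices (matrix n x 3).
# Queries outside the grid clamp to the edge value.
trilinearSample <- function(a, idx) {
  d <- dim(a)
  ix <- pmin(pmax(idx[, 1], 0), d[1] - 1)
  iy <- pmin(pmax(idx[, 2], 0), d[2] - 1)
  iz <- pmin(pmax(idx[, 3], 0), d[3] - 1)
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  x1 <- pmin(x0 + 1, d[1] - 1)
  y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  g <- function(x, y, z) a[cbind(x + 1, y + 1, z + 1)]
  g(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
  g(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
  g(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
  g(x1, y1, z0) * fx       * fy       * (1 - fz) +
  g(x0, y0, z1) * (1 - fx) * (1 - fy) * fz       +
  g(x1, y0, z1) * fx       * (1 - fy) * fz       +
  g(x0, y1, z1) * (1 - fx) * fy       * fz       +
  g(x1, y1, z1) * fx       * fy       * fz
}

#' Rebin a volume onto a coarser/finer grid by trilinear interpolation
#'
#' Used to resample the native low-dose CT (1.17 x 1.17 x 5 mm) onto the
#' 4 mm isotropic PET grid so that masks drawn on the rebinned CT lie
#' voxel-for-voxel on PET. The output grid is anchored at the input origin
#' with `ceil(extent / target)` voxels per axis, covering the same physical
#' extent to within one target voxel per border; each output value is the
#' trilinear interpolant of the input at the output voxel center, with
#' out-of-support queries clamped to edge values.
#'
#' @param vol an [ImageVolume-class].
#' @param targetSpacing numeric(3) desired spacing in mm (default 4 mm
#'   isotropic, the PET grid).
#' @return A resampled [ImageVolume-class].
#' @export
rebinTrilinear <- function(vol, targetSpacing = c(4, 4, 4)) {
  stopifnot(is(vol, "ImageVolume"))
  targetSpacing <- as.numeric(targetSpacing)
  if (length(targetSpacing) == 1L) targetSpacing <- rep(targetSpacing, 3)
  if (any(targetSpacing <= 0)) stop("target spacing must be > 0")
  d <- dim(vol@voxels)
  extent <- d * vol@spacing
  if (any(targetSpacing > extent))
    stop("degenerate grid: target spacing coarser than the volume extent")
  dOut <- pmax(1L, as.integer(ceiling(extent / targetSpacing)))
  # output voxel centers in continuous input-index units
  cx <- (seq_len(dOut[1]) - 1) * targetSpacing[1] / vol@spacing[1]
  cy <- (seq_len(dOut[2]) - 1) * targetSpacing[2] / vol@spacing[2]
  cz <- (seq_len(dOut[3]) - 1) * targetSpacing[3] / vol@spacing[3]
  idx <- cbind(rep(cx, times = dOut[2] * dOut[3]),
               rep(rep(cy, each = dOut[1]), times = dOut[3]),
               rep(cz, each = dOut[1] * dOut[2]))
  out <- array(trilinearSample(vol@voxels, idx), dOut)
  imageVolume(out, spacing = targetSpacing, origin = vol@origin,
              modality = vol@modality, timeH = vol@timeH)
}
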
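#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ImageVolume: a 3D scalar image on a regular grid
#'
#' Container for a CT (Hounsfield units) or PET (Bq/mL) volume. Voxel `(i,j,k)`
#' (0-based) sits at physical position `origin + c(i,j,k) * spacing`, in mm.
#'
#' @slot voxels 3D numeric array of voxel values.
#' @slot spacing numeric(3), voxel spacing (dx, dy, dz) in mm, all > 0.
#' @slot origin numeric(3), physical position (mm) of voxel (0,0,0).
#' @slot modality `"CT"` or `"PET"`.
#' @slot timeH acquisition time in hours post injection (PET), or `NA`.
#'
#' @seealso [imageVolume()], [readVolume()], [writeVolume()]
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 modality = "character", timeH = "numeric"),
  prototype(modality = "CT", timeH = NA_real_))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (!all(is.finite(object@voxels)))
    msg <- c(msg, "all voxel values must be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers (mm)")
  if (!object@modality %in% c("CT", "PET"))
    msg <- c(msg, "modality must be 'CT' or 'PET'")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) physical origin in mm.
#' @param modality `"CT"` or `"PET"`.
#' @param timeH hours post injection (PET only).
#' @return An [ImageVolume-class] object.
#' @examples
#' vol <- imageVolume(array(0, c(4, 4, 4)), spacing = c(4, 4, 4))
#' @export
imageVolume <- function(voxels, spacing, origin = c(0, 0, 0),
                        modality = "CT", timeH = NA_real_) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality,
      timeH = as.numeric(timeH))
}

#' BinaryMask: a boolean region on an image grid
#'
#' Shares the geometry (dimensions, spacing, origin) of a reference
#' [ImageVolume-class]; used for the loose initialization region (c1), the
#' outer bone contour (c2) and the intraosseous volume (c3), as well as for
#' manual cylindrical VOIs.
#'
#' @slot support 3D logical array.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot origin numeric(3) physical origin in mm.
#' @slot label free-text region label.
#' @export
setClass("BinaryMask",
  representation(support = "array", spacing = "numeric", origin = "numeric",
                 label = "character"),
  prototype(label = ""))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (length(dim(object@support)) != 3L || !is.logical(object@support))
    msg <- c(msg, "support must be a 3D logical array")
  if (any(is.na(object@support)))
    msg <- c(msg, "support must not contain NA")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryMask
#'
#' @param support 3D logical array.
#' @param geometry an [ImageVolume-class] or [BinaryMask-class] providing
#'   spacing and origin, or `NULL` if `spacing`/`origin` are given.
#' @param spacing,origin geometry, used when `geometry` is `NULL`.
#' @param label region label.
#' @return A [BinaryMask-class].
#' @export
binaryMask <- function(support, geometry = NULL, spacing = NULL,
                       origin = NULL, label = "") {
  if (!is.null(geometry)) {
    spacing <- geometry@spacing
    origin <- geometry@origin
  }
  new("BinaryMask", support = array(as.logical(support), dim(support)),
      spacing = as.numeric(spacing), origin = as.numeric(origin),
      label = label)
}

#' Study metadata carried by the JSON sidecar
#'
#' @slot injectedMBq injected activity in MBq.
#' @slot weightKg patient weight in kg.
#' @slot scanTimesH strictly increasing scan times, hours post injection.
#' @export
setClass("StudyMeta",
  representation(injectedMBq = "numeric", weightKg = "numeric",
                 scanTimesH = "numeric"))

setValidity("StudyMeta", function(object) {
  msg <- character()
  if (length(object@injectedMBq) != 1L || object@injectedMBq <= 0)
    msg <- c(msg, "injectedMBq must be a single positive number")
  if (length(object@weightKg) != 1L || object@weightKg <= 0)
    msg <- c(msg, "weightKg must be a single positive number")
  if (length(object@scanTimesH) &&
      (any(object@scanTimesH < 0) || is.unsorted(object@scanTimesH, strictly = TRUE)))
    msg <- c(msg, "scanTimesH must be strictly increasing and non-negative")
  if (length(msg)) msg else TRUE
})

#' @param injectedMBq injected activity (MBq).
#' @param weightKg patient weight (kg).
#' @param scanTimesH scan times in hours post injection.
#' @rdname StudyMeta-class
#' @export
studyMeta <- function(injectedMBq, weightKg,
                      scanTimesH = c(1, 24, 48, 96, 144)) {
  new("StudyMeta", injectedMBq = injectedMBq, weightKg = weightKg,
      scanTimesH = as.numeric(scanTimesH))
}

#' Parameters of the regularized Chan-Vese slice evolution
#'
#' The contour minimizes, per axial slice,
#' `E(phi) = muReg * R(phi) + muLength * L(phi) +
#'  lambdaIn * int_inside (I - cIn)^2 + lambdaOut * int_outside (I - cOut)^2`
#' where `R(phi) = int 0.5 * (|grad phi| - 1)^2` keeps `phi` close to a signed
#' distance function, `L` is the smoothed contour length, and `cIn`/`cOut`
#' are the region means recomputed every iteration. Slice intensities are
#' rescaled to `[0, 1]` before evolution, so the region-fit weights are
#' intensity-scale free.
#'
#' Numerically, each iteration takes one explicit step on the
#' distance-regularization term (a double-well variant whose diffusion rate
#' stays bounded, step size `muReg`, stable below 0.25) plus one step on the
#' Dirac-weighted data and length terms, scaled by `dt` and capped at one
#' voxel so the zero level set obeys a CFL-type bound regardless of image
#' contrast. With the cap in place, `dt` sets how strongly weak region
#' contrast still moves the contour; the default is large enough that the
#' loose initial region (about 1 cm away from the bone) converges within the
#' 30 iterations.
#'
#' @slot nIter number of gradient-descent iterations (default 30).
#' @slot muLength contour-length weight (>= 0).
#' @slot lambdaIn,lambdaOut region-fit weights (> 0).
#' @slot muReg distance-regularization step per iteration (>= 0, < 0.25).
#' @slot dt data-term step scale, in voxel units (> 0).
#' @slot epsilon Heaviside/Dirac smoothing width, in voxels (> 0).
#' @slot minBoneHU minimum mean HU for a slice component to be kept as
#'   bone (default 120: midway between soft tissue and a typical vertebral
#'   cross-section, so a kept slice is majority bone).
#' @export
setClass("ContourParams",
  representation(nIter = "numeric", muLength = "numeric", lambdaIn = "numeric",
                 lambdaOut = "numeric", muReg = "numeric", dt = "numeric",
                 epsilon = "numeric", minBoneHU = "numeric"))

setValidity("ContourParams", function(object) {
  msg <- character()
  if (object@nIter < 1) msg <- c(msg, "nIter must be >= 1")
  if (object@muLength < 0 || object@muReg < 0)
    msg <- c(msg, "muLength and muReg must be >= 0")
  if (object@lambdaIn <= 0 || object@lambdaOut <= 0)
    msg <- c(msg, "lambdaIn and lambdaOut must be > 0")
  if (object@dt <= 0 || object@epsilon <= 0)
    msg <- c(msg, "dt and epsilon must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param nIter,muLength,lambdaIn,lambdaOut,muReg,dt,epsilon,minBoneHU see
#'   slot documentation in [ContourParams-class].
#' @rdname ContourParams-class
#' @export
contourParams <- function(nIter = 30, muLength = 0.05, lambdaIn = 1,
                          lambdaOut = 1, muReg = 0.2, dt = 300,
                          epsilon = 1.5, minBoneHU = 120) {
  new("ContourParams", nIter = nIter, muLength = muLength,
      lambdaIn = lambdaIn, lambdaOut = lambdaOut, muReg = muReg,
      dt = dt, epsilon = epsilon, minBoneHU = minBoneHU)
}

#' Result of the automatic delineation pipeline
#'
#' @slot c1 loose initialization region (the coarse CT region).
#' @slot c2 outer bone contour region: compact bone plus marrow.
#' @slot c3 named list of intraosseous masks keyed by erosion kernel size
#'   (`"1"`, `"2"`, `"3"`).
#' @slot diagnostics per-slice data.frame: slice index, iterations, region
#'   means in HU, voxel counts.
#' @export
setClass("DelineationResult",
  representation(c1 = "BinaryMask", c2 = "BinaryMask", c3 = "list",
                 diagnostics = "data.frame"))

setValidity("DelineationResult", function(object) {
  msg <- character()
  in2 <- object@c2@support
  if (any(in2 & !object@c1@support))
    msg <- c(msg, "c2 must be contained in c1")
  for (k in names(object@c3)) {
    if (any(object@c3[[k]]@support & !in2))
      msg <- c(msg, sprintf("c3[%s] must be contained in c2", k))
  }
  if (length(msg)) msg else TRUE
})

#' Cylindrical VOI specification
#'
#' Defaults match a 1.9 cm diameter, 2 cm tall marrow cylinder, the manual
#' VOI placed in each lumbar vertebral body; on a 4 mm grid the 2 cm height
#' covers five axial slices.
#'
#' @slot center physical (x, y, z) center in mm.
#' @slot diameterMM cylinder diameter in mm (default 19).
#' @slot heightMM cylinder height in mm (default 20); axis is the grid z-axis.
#' @export
setClass("CylinderSpec",
  representation(center = "numeric", diameterMM = "numeric",
                 heightMM = "numeric"))

setValidity("CylinderSpec", function(object) {
  msg <- character()
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be 3 finite numbers (mm)")
  if (object@diameterMM <= 0 || object@heightMM <= 0)
    msg <- c(msg, "diameter and height must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param center physical (x, y, z) center in mm.
#' @param diameterMM,heightMM cylinder dimensions in mm.
#' @rdname CylinderSpec-class
#' @export
cylinderSpec <- function(center, diameterMM = 19, heightMM = 20) {
  new("CylinderSpec", center = as.numeric(center), diameterMM = diameterMM,
      heightMM = heightMM)
}

#' Radionuclide decay constants
#'
#' @slot halfLifeH physical half-life in hours.
#' @slot lambdaPerH decay constant, `log(2) / halfLifeH`, per hour.
#' @export
setClass("Radionuclide",
  representation(halfLifeH = "numeric", lambdaPerH = "numeric"))

setValidity("Radionuclide", function(object) {
  msg <- character()
  if (object@halfLifeH <= 0) msg <- c(msg, "halfLifeH must be > 0")
  if (abs(object@lambdaPerH * object@halfLifeH - log(2)) >
      1e-12 * log(2))
    msg <- c(msg, "lambdaPerH must equal log(2)/halfLifeH")
  if (length(msg)) msg else TRUE
})

#' @param halfLifeH physical half-life in hours.
#' @rdname Radionuclide-class
#' @export
radionuclide <- function(halfLifeH) {
  new("Radionuclide", halfLifeH = halfLifeH, lambdaPerH = log(2) / halfLifeH)
}

#' Zirconium-89 physical constants
#'
#' @return A [Radionuclide-class] with the Zr-89 physical half-life of
#'   78.41 h.
#' @examples
#' zirconium89()@halfLifeH
#' @export
zirconium89 <- function() radionuclide(78.41)

#' Time-activity curve of one source region
#'
#' @slot region region label.
#' @slot timesH strictly increasing sample times, hours post injection.
#' @slot concBqPerML activity concentration at each time, Bq/mL, >= 0.
#' @slot volumeML region volume in mL.
#' @export
setClass("TimeActivityCurve",
  representation(region = "character", timesH = "numeric",
                 concBqPerML = "numeric", volumeML = "numeric"))

setValidity("TimeActivityCurve", function(object) {
  msg <- character()
  if (length(object@timesH) != length(object@concBqPerML))
    msg <- c(msg, "timesH and concBqPerML must have equal length")
  if (length(object@timesH) > 1 && is.unsorted(object@timesH, strictly = TRUE))
    msg <- c(msg, "timesH must be strictly increasing")
  if (any(object@timesH < 0)) msg <- c(msg, "timesH must be >= 0")
  if (any(object@concBqPerML < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (object@volumeML <= 0) msg <- c(msg, "volumeML must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param region region label.
#' @param timesH sample times (h).
#' @param concBqPerML concentrations (Bq/mL).
#' @param volumeML region volume (mL).
#' @rdname TimeActivityCurve-class
#' @export
timeActivityCurve <- function(region, timesH, concBqPerML, volumeML = 1) {
  new("TimeActivityCurve", region = region, timesH = as.numeric(timesH),
      concBqPerML = as.numeric(concBqPerML), volumeML = volumeML)
}

#' Residence times of the source regions plus the remainder of body
#'
#' @slot tauH named numeric: residence time (h) per source region.
#' @slot tauRemainderH remainder-of-body residence time (h).
#' @slot injectedMBq injected activity (MBq), or `NA`.
#' @export
setClass("ResidenceTimeSet",
  representation(tauH = "numeric", tauRemainderH = "numeric",
                 injectedMBq = "numeric"),
  prototype(injectedMBq = NA_real_))

setValidity("ResidenceTimeSet", function(object) {
  msg <- character()
  if (length(object@tauH) && is.null(names(object@tauH)))
    msg <- c(msg, "tauH must be named by source region")
  if (any(object@tauH < 0) || object@tauRemainderH < 0)
    msg <- c(msg, "residence times must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param tauH named numeric of per-source residence times (h).
#' @param tauRemainderH remainder-of-body residence time (h).
#' @param injectedMBq injected activity (MBq).
#' @rdname ResidenceTimeSet-class
#' @export
residenceTimeSet <- function(tauH, tauRemainderH, injectedMBq = NA_real_) {
  new("ResidenceTimeSet", tauH = tauH, tauRemainderH = tauRemainderH,
      injectedMBq = injectedMBq)
}

#' S-value table and reference anatomy
#'
#' Dose conversion factors S(target <- source) in mGy per MBq h, as tabulated
#' by MIRD-schema software; they are user-supplied configuration, not computed
#' here. Must contain the red-marrow self term `RM <- RM` and the
#' remainder-of-body term `RM <- RB`.
#'
#' @slot s named numeric, names of the form `"TARGET<-SOURCE"`.
#' @slot refRMVolumeML reference-anatomy red-marrow volume, mL.
#' @slot refBodyWeightKg reference-anatomy body weight, kg.
#' @export
setClass("SValueTable",
  representation(s = "numeric", refRMVolumeML = "numeric",
                 refBodyWeightKg = "numeric"))

setValidity("SValueTable", function(object) {
  msg <- character()
  if (is.null(names(object@s)) || any(!grepl("<-", names(object@s), fixed = TRUE)))
    msg <- c(msg, "s must be named 'TARGET<-SOURCE'")
  if (!all(c("RM<-RM", "RM<-RB") %in% names(object@s)))
    msg <- c(msg, "s must contain entries 'RM<-RM' and 'RM<-RB'")
  if (any(object@s < 0)) msg <- c(msg, "S values must be >= 0")
  if (object@refRMVolumeML <= 0 || object@refBodyWeightKg <= 0)
    msg <- c(msg, "reference volume and weight must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param s named numeric of S values, names `"TARGET<-SOURCE"`.
#' @param refRMVolumeML reference red-marrow volume (mL).
#' @param refBodyWeightKg reference body weight (kg).
#' @rdname SValueTable-class
#' @export
sValueTable <- function(s, refRMVolumeML, refBodyWeightKg) {
  new("SValueTable", s = s, refRMVolumeML = refRMVolumeML,
      refBodyWeightKg = refBodyWeightKg)
}

#' Red-marrow dose report
#'
#' @slot selfDose self red-marrow dose, mGy/MBq (marrow-to-marrow term only).
#' @slot totalDose total red-marrow dose, mGy/MBq (all sources plus remainder).
#' @slot contributions named numeric of per-source dose contributions,
#'   mGy/MBq, including `"RB"` for the remainder of body.
#' @export
setClass("DoseReport",
  representation(selfDose = "numeric", totalDose = "numeric",
                 contributions = "numeric"))

setValidity("DoseReport", function(object) {
  if (object@totalDose < object@selfDose - 1e-12 * max(1, abs(object@selfDose)))
    "totalDose must be >= selfDose for non-negative S values and taus"
  else TRUE
})

#' Synthetic CT/PET vertebra phantom specification
#'
#' Emulates the study imaging: a stack of vertebral bodies (cylinders with a
#' cortical shell and trabecular interior) in soft-tissue background on the
#' native low-dose CT grid (1.17 x 1.17 x 5 mm), plus a matched serial PET
#' acquisition on a 4 mm grid in which marrow activity clears
#' mono-exponentially.
#'
#' @slot nVertebrae number of vertebral bodies (default 5).
#' @slot bodyRadiusMM vertebral-body radius, mm.
#' @slot bodyHeightMM vertebral-body height, mm.
#' @slot gapMM intervertebral gap, mm.
#' @slot huBackground,huCortical,huTrabecular CT levels in HU
#'   (defaults 40, 400, 120); must satisfy cortical > trabecular > background.
#' @slot shellThicknessMM cortical shell thickness, mm.
#' @slot ctNoiseHU additive Gaussian CT noise sd, HU.
#' @slot petNoiseFrac multiplicative Gaussian PET noise fraction.
#' @slot marrowC0 marrow activity concentration at t = 0, Bq/mL.
#' @slot effectiveHalfLifeH marrow effective (physical + biological)
#'   half-life, h.
#' @slot scanTimesH PET acquisition times, h post injection.
#' @slot psfFwhmMM PET point-spread FWHM, mm.
#' @slot seed RNG seed; identical seeds give bit-identical phantoms.
#' @export
setClass("PhantomSpec",
  representation(nVertebrae = "numeric", bodyRadiusMM = "numeric",
                 bodyHeightMM = "numeric", gapMM = "numeric",
                 huBackground = "numeric", huCortical = "numeric",
                 huTrabecular = "numeric", shellThicknessMM = "numeric",
                 ctNoiseHU = "numeric", petNoiseFrac = "numeric",
                 marrowC0 = "numeric", effectiveHalfLifeH = "numeric",
                 scanTimesH = "numeric", psfFwhmMM = "numeric",
                 seed = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!(object@huCortical > object@huTrabecular &&
        object@huTrabecular > object@huBackground))
    msg <- c(msg, "need huCortical > huTrabecular > huBackground for segmentable contrast")
  if (object@nVertebrae < 1) msg <- c(msg, "nVertebrae must be >= 1")
  if (object@bodyRadiusMM <= object@shellThicknessMM)
    msg <- c(msg, "bodyRadiusMM must exceed shellThicknessMM")
  if (any(c(object@bodyHeightMM, object@gapMM, object@marrowC0,
            object@effectiveHalfLifeH, object@shellThicknessMM) <= 0))
    msg <- c(msg, "geometry, C0 and half-life must be > 0")
  if (is.unsorted(object@scanTimesH, strictly = TRUE) ||
      any(object@scanTimesH < 0))
    msg <- c(msg, "scanTimesH must be strictly increasing and >= 0")
  if (object@ctNoiseHU < 0 || object@petNoiseFrac < 0 || object@psfFwhmMM < 0)
    msg <- c(msg, "noise and blur parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param nVertebrae,bodyRadiusMM,bodyHeightMM,gapMM,huBackground,huCortical,huTrabecular,shellThicknessMM,ctNoiseHU,petNoiseFrac,marrowC0,effectiveHalfLifeH,scanTimesH,psfFwhmMM,seed
#'   see slot documentation in [PhantomSpec-class].
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(nVertebrae = 5, bodyRadiusMM = 20, bodyHeightMM = 28,
                        gapMM = 10, huBackground = 40, huCortical = 400,
                        huTrabecular = 120, shellThicknessMM = 3,
                        ctNoiseHU = 20, petNoiseFrac = 0.05,
                        marrowC0 = 2000, effectiveHalfLifeH = 73,
                        scanTimesH = c(1, 24, 48, 96, 144),
                        psfFwhmMM = 7, seed = 1) {
  new("PhantomSpec", nVertebrae = nVertebrae, bodyRadiusMM = bodyRadiusMM,
      bodyHeightMM = bodyHeightMM, gapMM = gapMM, huBackground = huBackground,
      huCortical = huCortical, huTrabecular = huTrabecular,
      shellThicknessMM = shellThicknessMM, ctNoiseHU = ctNoiseHU,
      petNoiseFrac = petNoiseFrac, marrowC0 = marrowC0,
      effectiveHalfLifeH = effectiveHalfLifeH,
      scanTimesH = as.numeric(scanTimesH), psfFwhmMM = psfFwhmMM, seed = seed)
}
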
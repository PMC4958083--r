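# MIRD dosimetry chain: cumulated activity by the trapezoidal rule with a
# physical-decay tail, residence times with remainder-of-body closure and
# weight scaling, S-value dose, plus the plasma-factor comparator and the
# effective-half-life fit.

#' Cumulated activity concentration of a time-activity curve
#'
#' Integrates the curve by the trapezoidal rule over the sampled interval,
#' adds the unmeasured leading interval `[0, t1]`, and assumes physical
#' decay after the last measurement, which contributes the analytic tail
#' `C(t_last) / lambda`. The leading interval defaults to constant
#' back-extrapolation (a trapezoid between `(0, C(t1))` and `(t1, C(t1))`);
#' with a first scan at 1 h this contributes well under 1 percent of the
#' total for Zr-89 kinetics.
#'
#' @param tac a [TimeActivityCurve-class] with at least 2 samples.
#' @param rc a [Radionuclide-class] (default [zirconium89()]).
#' @param leading one of `"constant"`, `"linear-from-zero"`, `"exclude"`:
#'   treatment of `[0, t1]` when `t1 > 0`.
#' @param tail include the physical-decay tail after the last sample?
#' @return Cumulated concentration, Bq h/mL.
#' @export
cumulatedConcentration <- function(tac, rc = zirconium89(),
                                   leading = c("constant",
                                               "linear-from-zero",
                                               "exclude"),
                                   tail = TRUE) {
  stopifnot(is(tac, "TimeActivityCurve"), is(rc, "Radionuclide"))
  leading <- match.arg(leading)
  t <- tac@timesH; cc <- tac@concBqPerML
  if (length(t) < 2) stop("need at least 2 samples to integrate")
  trap <- sum(diff(t) * (cc[-length(cc)] + cc[-1]) / 2)
  lead <- if (t[1] > 0) {
    switch(leading,
           "constant" = t[1] * cc[1],
           "linear-from-zero" = t[1] * cc[1] / 2,
           "exclude" = 0)
  } else 0
  tl <- if (tail) cc[length(cc)] / rc@lambdaPerH else 0
  trap + lead + tl
}

#' Residence time of a region
#'
#' `tau = cumulated concentration (Bq h/mL) x region volume (mL) /
#' injected activity`, with the Bq-to-MBq conversion applied, returned in
#' hours. For red marrow the volume is the reference-anatomy marrow volume
#' from the S-value configuration.
#'
#' @param cumcBqHPerML cumulated concentration, Bq h/mL.
#' @param regionVolumeML region volume, mL.
#' @param injectedMBq injected activity, MBq.
#' @return Residence time, hours.
#' @export
residenceTime <- function(cumcBqHPerML, regionVolumeML, injectedMBq) {
  if (any(c(cumcBqHPerML, regionVolumeML, injectedMBq) <= 0))
    stop("cumulated concentration, volume and injected activity must be > 0")
  cumcBqHPerML * regionVolumeML * 1e-6 / injectedMBq
}

#' Remainder-of-body residence time
#'
#' The maximum possible residence time assuming physical decay only (no
#' biological clearance) is `T_half / ln 2`; the remainder of body receives
#' that maximum minus the residence times already assigned to source organs.
#'
#' @param taus numeric (optionally named) of source-organ residence times, h.
#' @param rc a [Radionuclide-class].
#' @return Remainder-of-body residence time, h.
#' @export
remainderResidence <- function(taus = numeric(), rc = zirconium89()) {
  stopifnot(is(rc, "Radionuclide"))
  maxTau <- rc@halfLifeH / log(2)
  s <- sum(taus)
  if (s > maxTau * (1 + 1e-12))
    stop(sprintf(
      "inconsistent residence times: sum %.4f h exceeds the physical-decay maximum %.4f h by %.4g h",
      s, maxTau, s - maxTau))
  maxTau - s
}

#' Scale a residence time by patient weight
#'
#' Organ residence times are scaled to the reference anatomy as
#' `tau x reference weight / patient weight`.
#'
#' @param tauH residence time, h.
#' @param patientWeightKg patient weight, kg.
#' @param referenceWeightKg reference-anatomy weight, kg.
#' @return Scaled residence time, h.
#' @export
scaleByWeight <- function(tauH, patientWeightKg, referenceWeightKg) {
  if (patientWeightKg <= 0 || referenceWeightKg <= 0)
    stop("weights must be > 0")
  tauH * referenceWeightKg / patientWeightKg
}

# look up S(target <- source), failing loudly with the missing pair
sValue <- function(s, target, source) {
  key <- paste0(target, "<-", source)
  if (!key %in% names(s@s))
    stop("missing S value for pair ", key)
  s@s[[key]]
}

#' Red-marrow absorbed dose from residence times and S values
#'
#' `self = S(RM <- RM) x tau_RM`;
#' `total = sum_sources S(RM <- source) x tau_source +
#'  S(RM <- RB) x tau_remainder`, both in mGy/MBq.
#'
#' @param taus a [ResidenceTimeSet-class]; must contain an `"RM"` entry.
#' @param s an [SValueTable-class] with an entry for every source in `taus`.
#' @return A [DoseReport-class].
#' @export
rmDose <- function(taus, s) {
  stopifnot(is(taus, "ResidenceTimeSet"), is(s, "SValueTable"))
  if (!"RM" %in% names(taus@tauH))
    stop("residence-time set must contain an 'RM' entry")
  contrib <- vapply(names(taus@tauH), function(src)
    sValue(s, "RM", src) * taus@tauH[[src]], numeric(1))
  rb <- sValue(s, "RM", "RB") * taus@tauRemainderH
  contributions <- c(contrib, RB = rb)
  new("DoseReport",
      selfDose = unname(contrib[["RM"]]),
      totalDose = sum(contributions),
      contributions = contributions)
}

#' Plasma-based red-marrow time-activity curve
#'
#' The conventional comparator: the plasma curve multiplied by a fixed
#' red-marrow-to-plasma concentration ratio (0.19).
#'
#' @param plasma a plasma [TimeActivityCurve-class].
#' @param factor the fixed ratio (default 0.19).
#' @return A [TimeActivityCurve-class] labelled `"RM-plasma-method"`.
#' @export
plasmaRmTac <- function(plasma, factor = 0.19) {
  stopifnot(is(plasma, "TimeActivityCurve"))
  if (factor <= 0) stop("factor must be > 0")
  timeActivityCurve("RM-plasma-method", plasma@timesH,
                    plasma@concBqPerML * factor, plasma@volumeML)
}

#' Fit the effective half-life of a time-activity curve
#'
#' Ordinary least squares on `ln C(t) = ln C0 - lambda_eff t` over all
#' samples; returns `ln 2 / lambda_eff` in hours. The effective half-life
#' combines physical decay and biological clearance, so it is shorter than
#' the physical half-life whenever clearance is nonzero. A non-decreasing
#' curve yields a non-positive rate: the (infinite or negative) value is
#' returned with a warning.
#'
#' @param tac a [TimeActivityCurve-class] with at least 2 samples, all
#'   concentrations > 0.
#' @return Effective half-life, hours.
#' @export
fitEffectiveHalfLife <- function(tac) {
  stopifnot(is(tac, "TimeActivityCurve"))
  if (length(tac@timesH) < 2) stop("need at least 2 samples")
  if (any(tac@concBqPerML <= 0))
    stop("all concentrations must be > 0 for a log-linear fit")
  fit <- stats::lm(log(tac@concBqPerML) ~ tac@timesH)
  lambda <- -unname(stats::coef(fit)[2])
  if (abs(lambda) < 1e-12) lambda <- 0  # flat curve up to rounding
  if (lambda <= 0) {
    warning("non-decreasing curve: effective half-life is not finite/positive")
    return(if (lambda == 0) Inf else log(2) / lambda)
  }
  log(2) / lambda
}

#' Assemble a residence-time set with remainder-of-body closure
#'
#' Integrates each curve, converts to residence times, applies weight
#' scaling, and closes the balance with the remainder of body, so that
#' `tau_remainder + sum(tau) = T_half / ln 2` by construction.
#'
#' @param tacs named list of [TimeActivityCurve-class] objects; the red
#'   marrow entry must be named `"RM"`.
#' @param injectedMBq injected activity, MBq.
#' @param rc a [Radionuclide-class].
#' @param patientWeightKg,referenceWeightKg optional weight scaling; both
#'   `NULL` skips it.
#' @param rmVolumeML optional override of the `"RM"` curve volume with the
#'   reference-anatomy marrow volume.
#' @return A [ResidenceTimeSet-class].
#' @export
residenceTimesFromTACs <- function(tacs, injectedMBq, rc = zirconium89(),
                                   patientWeightKg = NULL,
                                   referenceWeightKg = NULL,
                                   rmVolumeML = NULL) {
  stopifnot(is.list(tacs), !is.null(names(tacs)))
  taus <- vapply(names(tacs), function(nm) {
    tac <- tacs[[nm]]
    vol <- if (nm == "RM" && !is.null(rmVolumeML)) rmVolumeML else tac@volumeML
    residenceTime(cumulatedConcentration(tac, rc), vol, injectedMBq)
  }, numeric(1))
  if (!is.null(patientWeightKg) && !is.null(referenceWeightKg))
    taus <- scaleByWeight(taus, patientWeightKg, referenceWeightKg)
  residenceTimeSet(taus, remainderResidence(taus, rc), injectedMBq)
}

#' Read an S-value table from JSON configuration
#'
#' Expected layout:
#' \preformatted{
#' {
#'   "s_mGy_per_MBq_h": {"RM<-RM": ..., "RM<-RB": ...},
#'   "reference_rm_volume_mL": ...,
#'   "reference_body_weight_kg": ...
#' }
#' }
#' A template with placeholder values ships in
#' `system.file("extdata", "svalues_template.json", package = "marrowDose")`;
#' real analyses must substitute S values from MIRD-schema software for the
#' radionuclide and reference anatomy at hand.
#'
#' @param path JSON file path.
#' @return An [SValueTable-class].
#' @export
readSValueTable <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  sValueTable(unlist(cfg$s_mGy_per_MBq_h),
              refRMVolumeML = as.numeric(cfg$reference_rm_volume_mL),
              refBodyWeightKg = as.numeric(cfg$reference_body_weight_kg))
}
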
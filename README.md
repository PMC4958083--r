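# marrowDose

Image-based red bone marrow (RM) dosimetry for Zr-89 immunoPET/CT.

Red marrow is the dose-limiting organ in radio-immunotherapy. The
conventional estimate scales a plasma time-activity curve by a fixed
marrow-to-plasma ratio (0.19), which is known to drift over time and can
understate the marrow dose. `marrowDose` implements the image-based
alternative for hybrid PET/CT studies, for medical physicists and
image-analysis researchers working on internal dosimetry:

1. **Automatic delineation** of the lumbar vertebrae on the low-dose CT of
   each acquisition. The CT is rebinned to the 4 mm PET grid by trilinear
   interpolation; inside a loose region c1 (a box around the vertebral
   column with a ~1 cm margin) a regularized Chan–Vese active contour is
   evolved per axial slice for a fixed 30 iterations, minimizing

   `E(φ) = μ_reg R(φ) + μ_len L(φ) + λ_in ∫_{φ>0}(I−c_in)² + λ_out ∫_{φ<0}(I−c_out)²`

   to find the outer bone contour c2. In-plane erosion by a cross-shaped
   kernel of radius k ∈ {1,2,3} voxels then strips the cortical shell,
   leaving the intraosseous volume c3.
2. **VOI evaluation**: manual-style cylindrical VOIs (1.9 cm diameter,
   2 cm height, five slices on the 4 mm grid) and the Dice similarity
   coefficient `DSC = 2|A∩M|/(|A|+|M|)`.
3. **MIRD dosimetry**: region time-activity curves from the serial PET
   scans; cumulated activity by the trapezoidal rule with a physical-decay
   tail `C(t_last)/λ` (Zr-89, T½ = 78.41 h); residence times
   `τ = Ã/A_inj` with remainder-of-body closure
   `τ_RB = T½/ln 2 − Στ`; weight scaling; and
   `D_self = S(RM←RM)·τ_RM`,
   `D_total = Σ S(RM←src)·τ_src + S(RM←RB)·τ_RB`
   from a user-supplied S-value table. Plasma-factor comparator and
   mono-exponential effective-half-life fit included.
4. **Synthetic phantom**: a five-vertebra CT stack (cortical shell,
   trabecular interior, soft-tissue background) with a matched PET series
   whose marrow clears mono-exponentially — analytic ground truth for
   every stage.

## Worked example

Delineate a synthetic study and carry it to dose (placeholder S values from
the shipped template — substitute MIRD-schema values for real work):

```r
library(marrowDose)

spec <- phantomSpec(seed = 1)          # 5 vertebrae, noisy CT + PET
gen  <- generateCT(spec)
ct4  <- rebinTrilinear(gen$ct)         # native 1.17x1.17x5 -> 4 mm PET grid
seg  <- delineate(ct4, phantomBox(spec))
seg
#> DelineationResult:
#>   c1: 13312 voxels
#>   c2: 2928 voxels
#>   c3[kernel 1]: 1956 voxels
#>   c3[kernel 2]: 1188 voxels
#>   c3[kernel 3]: 576 voxels

dice(seg@c2, truthMasks(spec, ct4)$wholeVertebra)
#> [1] 0.9325464

pets <- generatePETSeries(spec)
tac  <- extractTAC(seg@c3[["3"]], pets, region = "RM")
tac
#> TimeActivityCurve 'RM' (5 samples, volume 36.9 mL)
#>   time_h conc_Bq_per_mL
#> 1      1      1854.4060
#> 2     24      1484.8587
#> 3     48      1183.7082
#> 4     96       749.9202
#> 5    144       475.3398

fitEffectiveHalfLife(tac)              # < 78.41 h: biological clearance
#> [1] 72.88023

sv  <- readSValueTable(system.file("extdata", "svalues_template.json",
                                   package = "marrowDose"))
rts <- residenceTimesFromTACs(list(RM = tac), injectedMBq = 37.1,
                              patientWeightKg = 75,
                              referenceWeightKg = sv@refBodyWeightKg,
                              rmVolumeML = sv@refRMVolumeML)
rts
#> ResidenceTimeSet (hours):
#>   RM              5.988
#>   remainder     107.133
rmDose(rts, sv)
#> DoseReport: self RM dose 0.01797 mGy/MBq, total RM dose 0.07153 mGy/MBq
```

The marrow concentration at 1 h (1854 Bq/mL) sits just under the generating
2000 Bq/mL at t = 0; the fitted 72.9 h effective half-life recovers the
generator's 73 h; and the residence-time set closes exactly to
T½/ln 2 = 113.12 h. A shell workflow over NIfTI files (phantom /
delineate / dose subcommands) is available via `inst/cli/marrowdose`.

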
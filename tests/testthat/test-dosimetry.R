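test_that("radionuclide constants are internally consistent", {
  rc <- radionuclide(50)
  expect_equal(rc@lambdaPerH * rc@halfLifeH, log(2))
  expect_error(radionuclide(-1), "halfLifeH")
})

test_that("cumulated concentration combines trapezoid, lead-in and tail", {
  rc <- zirconium89()
  unitSeg <- timeActivityCurve("x", c(0, 1), c(1, 1))
  expect_equal(cumulatedConcentration(unitSeg, rc, tail = FALSE), 1.0)
  # tail alone for a unit endpoint is T_half / ln 2
  expect_equal(cumulatedConcentration(unitSeg, rc) - 1,
               rc@halfLifeH / log(2))
  # constant back-extrapolation of [0, t1]
  lateStart <- timeActivityCurve("x", c(2, 3), c(4, 4))
  expect_equal(cumulatedConcentration(lateStart, rc, tail = FALSE), 4 + 8)
  expect_equal(cumulatedConcentration(lateStart, rc,
                                      leading = "linear-from-zero",
                                      tail = FALSE), 4 + 4)
  expect_equal(cumulatedConcentration(lateStart, rc, leading = "exclude",
                                      tail = FALSE), 4)
})

test_that("densely sampled exponential integral approaches C0 / lambda", {
  rc <- zirconium89()
  C0 <- 1234
  closed <- C0 / rc@lambdaPerH
  errAt <- function(dt) {
    t <- seq(0, 600, by = dt)
    tac <- timeActivityCurve("x", t, C0 * exp(-rc@lambdaPerH * t))
    abs(cumulatedConcentration(tac, rc) / closed - 1)
  }
  expect_lt(errAt(1), 0.005)
  # refinement strictly reduces the error
  errs <- vapply(c(10, 1, 0.1), errAt, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("cumulated concentration is linear in the curve", {
  rc <- zirconium89()
  set.seed(5)
  t <- sort(runif(6, 0, 200))
  cc <- runif(6, 10, 100)
  tac <- timeActivityCurve("x", t, cc)
  scaled <- timeActivityCurve("x", t, 3.5 * cc)
  expect_equal(cumulatedConcentration(scaled, rc),
               3.5 * cumulatedConcentration(tac, rc))
})

test_that("residence time follows the MIRD definition", {
  # cumulated activity equal to injected x 1 h gives tau = 1 h
  inj <- 37.1
  vol <- 100
  cumc <- inj * 1e6 / vol
  expect_equal(residenceTime(cumc, vol, inj), 1)
  expect_equal(residenceTime(cumc, 2 * vol, inj),
               2 * residenceTime(cumc, vol, inj))
  expect_error(residenceTime(-1, vol, inj), "> 0")
  expect_error(residenceTime(cumc, vol, 0), "> 0")
})

test_that("remainder of body closes the residence-time balance", {
  rc <- zirconium89()
  maxTau <- rc@halfLifeH / log(2)
  expect_equal(remainderResidence(numeric(), rc), maxTau)
  expect_equal(remainderResidence(maxTau, rc), 0)
  expect_error(remainderResidence(120, rc), "exceeds")
  set.seed(3)
  for (i in 1:50) {
    taus <- runif(sample(1:6, 1), 0, maxTau / 6)
    expect_equal(remainderResidence(taus, rc) + sum(taus), maxTau)
  }
})

test_that("weight scaling is the reference-to-patient ratio", {
  expect_equal(scaleByWeight(10, 73.7, 73.7), 10)
  expect_equal(scaleByWeight(10, 2 * 73.7, 73.7), 5)
  expect_error(scaleByWeight(10, 0, 73.7), "> 0")
})

test_that("red-marrow dose assembles S-weighted residence times", {
  s0 <- sValueTable(c("RM<-RM" = 0.5, "RM<-RB" = 0), 1120, 73.7)
  d <- rmDose(residenceTimeSet(c(RM = 2), 0), s0)
  expect_equal(d@selfDose, 1.0)
  expect_equal(d@totalDose, 1.0)
  expect_equal(rmDose(residenceTimeSet(c(RM = 0), 0), s0)@totalDose, 0)
  s2 <- sValueTable(c("RM<-RM" = 0.003, "RM<-Liver" = 0.0011,
                      "RM<-RB" = 0.0005), 1120, 73.7)
  taus <- residenceTimeSet(c(RM = 5, Liver = 12), 60)
  d2 <- rmDose(taus, s2)
  expect_equal(d2@selfDose, 0.003 * 5)
  expect_equal(d2@totalDose, 0.003 * 5 + 0.0011 * 12 + 0.0005 * 60)
  expect_error(rmDose(residenceTimeSet(c(RM = 1, Spleen = 1), 0), s2),
               "RM<-Spleen")
})

test_that("plasma comparator scales the curve by the fixed ratio", {
  pl <- timeActivityCurve("plasma", c(1, 24, 48), c(1000, 800, 600))
  rm <- plasmaRmTac(pl)
  expect_equal(rm@concBqPerML, c(190, 152, 114))
  expect_identical(rm@region, "RM-plasma-method")
  expect_equal(plasmaRmTac(pl, 1)@concBqPerML, pl@concBqPerML)
  expect_error(plasmaRmTac(pl, -0.1), "> 0")
})

test_that("effective half-life fit recovers exponentials", {
  t <- c(1, 24, 48, 96, 144)
  tac <- timeActivityCurve("x", t, exp(-log(2) * t / 50))
  expect_equal(fitEffectiveHalfLife(tac), 50)
  flat <- timeActivityCurve("x", t, rep(2, 5))
  expect_warning(hl <- fitEffectiveHalfLife(flat), "non-decreasing")
  expect_identical(hl, Inf)
  expect_error(fitEffectiveHalfLife(timeActivityCurve("x", c(0, 1), c(1, 0))),
               "> 0")
})

test_that("residence-time assembly closes and weight-scales", {
  rc <- zirconium89()
  t <- c(1, 24, 48, 96, 144)
  tac <- timeActivityCurve("RM", t, 1000 * exp(-log(2) * t / 73),
                           volumeML = 50)
  rts <- residenceTimesFromTACs(list(RM = tac), injectedMBq = 37.1, rc = rc,
                                patientWeightKg = 75,
                                referenceWeightKg = 73.7,
                                rmVolumeML = 1120)
  expect_equal(unname(rts@tauH[["RM"]] + 0) * 75 / 73.7,
               residenceTime(cumulatedConcentration(tac, rc), 1120, 37.1))
  expect_equal(sum(rts@tauH) + rts@tauRemainderH, rc@halfLifeH / log(2))
})

test_that("S-value tables load from JSON and enforce required entries", {
  path <- system.file("extdata", "svalues_template.json",
                      package = "marrowDose")
  sv <- readSValueTable(path)
  expect_true(all(c("RM<-RM", "RM<-RB") %in% names(sv@s)))
  expect_gt(sv@refRMVolumeML, 0)
  expect_error(sValueTable(c("RM<-RM" = 1), 1000, 70), "RM<-RB")
})
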
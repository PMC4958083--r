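# Shared fixtures, built once per test run. The clean/noisy phantoms and
# their delineations are reused across contour, voi and acceptance tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

cleanSpec <- function() phantomSpec(ctNoiseHU = 0, petNoiseFrac = 0,
                                    psfFwhmMM = 0)
noisySpec <- function() phantomSpec(ctNoiseHU = 20, petNoiseFrac = 0,
                                    psfFwhmMM = 0, seed = 1)

cleanPhantom <- function() fixture("cleanPhantom", function() {
  gen <- generateCT(cleanSpec())
  reb <- rebinTrilinear(gen$ct)
  list(gen = gen, reb = reb, truth4 = truthMasks(cleanSpec(), reb))
})

cleanDelineation <- function() fixture("cleanDelineation", function()
  delineate(cleanPhantom()$reb, phantomBox(cleanSpec())))

noisyDelineation <- function() fixture("noisyDelineation", function() {
  reb <- rebinTrilinear(generateCT(noisySpec())$ct)
  delineate(reb, phantomBox(noisySpec()))
})

cleanPET <- function() fixture("cleanPET", function()
  generatePETSeries(cleanSpec()))

# brute-force in-plane erosion oracle: a voxel survives iff every voxel in
# the cross (or square) of radius k around it is inside
bruteErode2D <- function(m, k, element = "cross") {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(FALSE, n1, n2)
  offs <- if (element == "cross") {
    s <- setdiff(-k:k, 0); rbind(c(0, 0), cbind(s, 0), cbind(0, s))
  } else as.matrix(expand.grid(-k:k, -k:k))
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (!m[i, j]) next
    ok <- TRUE
    for (r in seq_len(nrow(offs))) {
      ii <- i + offs[r, 1]; jj <- j + offs[r, 2]
      if (ii < 1 || ii > n1 || jj < 1 || jj > n2 || !m[ii, jj]) {
        ok <- FALSE; break
      }
    }
    out[i, j] <- ok
  }
  out
}

randomMask3D <- function(d, p = 0.5) {
  binaryMask(array(stats::runif(prod(d)) < p, d),
             spacing = c(4, 4, 4), origin = c(0, 0, 0))
}
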
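test_that("loose region dilates the box by whole outward-rounded voxels", {
  g <- imageVolume(array(0, c(30, 30, 30)), spacing = c(4, 4, 4))
  # box over index range [10..20]^3; 10 mm on a 4 mm grid rounds out to 3
  m <- makeInitialRegion(g, c(40, 80, 40, 80, 40, 80))
  idx <- which(m@support, arr.ind = TRUE) - 1L
  for (a in 1:3) expect_equal(range(idx[, a]), c(7, 23))
  # zero margin reproduces the rasterized box
  m0 <- makeInitialRegion(g, c(40, 80, 40, 80, 40, 80), marginMM = 0)
  idx0 <- which(m0@support, arr.ind = TRUE) - 1L
  for (a in 1:3) expect_equal(range(idx0[, a]), c(10, 20))
  expect_error(makeInitialRegion(g, c(500, 600, 500, 600, 500, 600)),
               "empty region")
})

test_that("slice evolution recovers a high-contrast disk from a loose box", {
  img <- matrix(40, 40, 40)
  xy <- (0:39) * 4 - 78
  disk <- outer(xy^2, xy^2, "+") <= 24^2
  img[disk] <- 300
  init <- matrix(FALSE, 40, 40); init[11:28, 11:28] <- TRUE
  res <- evolveSlice(img, init)
  # area within 5 % of pi * 24^2 mm^2 on the 4 mm grid
  expect_lt(abs(sum(res) * 16 / (pi * 24^2) - 1), 0.05)
  # fully contains the disk eroded by one voxel
  er <- disk
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    er <- er & marrowDose:::shiftMat(disk, s[1], s[2], FALSE)
  expect_true(all(res[er]))
  # boundary within one voxel of the true step (Hausdorff)
  boundary <- function(m) {
    inner <- m
    for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      inner <- inner & marrowDose:::shiftMat(m, s[1], s[2], FALSE)
    m & !inner
  }
  w <- which(boundary(res), arr.ind = TRUE)
  v <- which(boundary(disk), arr.ind = TRUE)
  dm <- sqrt(outer(w[, 1], v[, 1], "-")^2 + outer(w[, 2], v[, 2], "-")^2)
  expect_lte(max(apply(dm, 1, min), apply(dm, 2, min)), 1)
})

test_that("slice evolution is invariant to an intensity offset", {
  img <- matrix(40, 40, 40)
  xy <- (0:39) * 4 - 78
  img[outer(xy^2, xy^2, "+") <= 24^2] <- 300
  init <- matrix(FALSE, 40, 40); init[11:28, 11:28] <- TRUE
  r1 <- evolveSlice(img, init)
  r2 <- evolveSlice(img + 750, init)
  expect_identical(as.vector(r1), as.vector(r2))
})

test_that("degenerate and invalid initializations are handled", {
  flat <- matrix(100, 20, 20)
  init <- matrix(FALSE, 20, 20); init[5:15, 5:15] <- TRUE
  expect_warning(res <- evolveSlice(flat, init), "degenerate")
  expect_false(any(res))
  expect_true(attr(res, "diagnostics")$degenerate)
  expect_error(evolveSlice(flat, matrix(FALSE, 20, 20)), "empty")
  expect_error(evolveSlice(flat, matrix(TRUE, 20, 20)), "whole slice")
  bad <- flat; bad[1, 1] <- NaN
  expect_error(evolveSlice(bad, init), "finite")
  expect_equal(contourParams()@nIter, 30)
})

test_that("outer-bone search stays inside c1 and its slices", {
  ph <- cleanPhantom()
  vol <- ph$reb
  # c1 restricted to a single mid-vertebra slice
  full <- makeInitialRegion(vol, phantomBox(cleanSpec()))
  z <- round(mean(which(apply(ph$truth4$wholeVertebra@support, 3, any))))
  one <- full@support; one[, , setdiff(seq_len(dim(one)[3]), z)] <- FALSE
  c1 <- binaryMask(one, geometry = vol)
  c2 <- findOuterBone(vol, c1)
  expect_true(any(c2@support[, , z]))
  expect_false(any(c2@support[, , -z]))
  expect_false(any(c2@support & !c1@support))
  expect_error(findOuterBone(vol, binaryMask(array(FALSE, dim(one)),
                                             geometry = vol)), "empty")
})

test_that("cross erosion matches hand-computable cases", {
  d <- c(15, 15, 1)
  sq <- array(FALSE, d); sq[3:13, 3:13, 1] <- TRUE
  m <- binaryMask(sq, spacing = c(4, 4, 4), origin = c(0, 0, 0))
  e3 <- erodeToIntraosseous(m, 3)
  expected <- array(FALSE, d); expected[6:10, 6:10, 1] <- TRUE
  expect_identical(e3@support, expected)           # 11x11 -> 5x5
  expect_identical(erodeToIntraosseous(m, 0)@support, sq)  # identity
  small <- array(FALSE, d); small[7:9, 7:9, 1] <- TRUE
  expect_false(any(erodeToIntraosseous(
    binaryMask(small, geometry = m), 3)@support))  # annihilation
})

test_that("erosion agrees with the brute-force oracle on random masks", {
  set.seed(7)
  for (i in 1:100) {
    m <- matrix(runif(32 * 32) < runif(1, 0.3, 0.8), 32, 32)
    k <- sample(1:3, 1)
    mask <- binaryMask(array(m, c(32, 32, 1)), spacing = c(4, 4, 4),
                       origin = c(0, 0, 0))
    expect_identical(erodeToIntraosseous(mask, k)@support[, , 1],
                     bruteErode2D(m, k))
  }
  # square element agrees with its own oracle
  set.seed(8)
  m <- matrix(runif(32 * 32) < 0.6, 32, 32)
  mask <- binaryMask(array(m, c(32, 32, 1)), spacing = c(4, 4, 4),
                     origin = c(0, 0, 0))
  expect_identical(erodeToIntraosseous(mask, 2, element = "square")@support[, , 1],
                   bruteErode2D(m, 2, element = "square"))
})

test_that("erosion is nested and monotone in the kernel size", {
  set.seed(21)
  for (i in 1:20) {
    m <- randomMask3D(c(20, 20, 3), p = runif(1, 0.4, 0.9))
    prev <- m@support
    for (k in 1:3) {
      ek <- erodeToIntraosseous(m, k)@support
      expect_false(any(ek & !prev))
      prev <- ek
    }
  }
})

test_that("delineation result nests c3 within c2 within c1", {
  res <- cleanDelineation()
  expect_false(any(res@c2@support & !res@c1@support))
  prev <- res@c2@support
  for (k in c("1", "2", "3")) {
    ck <- res@c3[[k]]@support
    expect_false(any(ck & !prev))
    prev <- ck
  }
  counts <- vapply(res@c3, function(m) sum(m@support), numeric(1))
  expect_true(counts[["3"]] <= counts[["2"]] &&
              counts[["2"]] <= counts[["1"]])
})
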
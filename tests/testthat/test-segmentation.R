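test_that("mineral thresholding follows the >= boundary convention", {
  v <- VoxelVolume(array(120, c(8, 8, 8)), 10, 8L)
  expect_false(any(thresholdMineral(v, 121)))   # t above max: empty
  expect_true(all(thresholdMineral(v, 120)))    # uniform at t: all mineral
  # conservative threshold recovers truth mineral on a noisy phantom
  p <- generatePhantom(smallPhantomSpec(seed = 12, shape = 64L, nOm = 1L,
                                        noiseSd = 9))
  mm <- thresholdMineral(p$volume, 160)
  truthMineral <- p$truth@labels == phaseCodes()[["mineral"]]
  expect_lt(mean(mm != truthMineral), 0.01)
})

test_that("dual thresholding equals single-threshold components when ranges match", {
  f <- randomBlobField(c(24L, 24L, 24L), sigma = 2, seed = 3)
  vals <- pmin(pmax(round(100 + 40 * f), 0), 255)
  v <- VoxelVolume(array(vals, c(24, 24, 24)), 10, 8L)
  rng <- c(110, 255)
  om1 <- segmentOmDual(v, weak = rng, strong = rng, minSizeVoxels = 1)
  single <- voxelData(v) >= 110
  expect_identical(labelArray(om1) > 0L, single)
})

test_that("weak-only blobs are excluded; strong-cored blobs are kept whole", {
  d <- c(64L, 64L, 64L)
  vals <- array(0, d)
  # blob with strong core and weak rim
  blob <- digitalBall(d, c(20, 20, 20), 8)
  core <- digitalBall(d, c(20, 20, 20), 4)
  vals[blob] <- 80   # weak range
  vals[core] <- 110  # strong range
  # weak-only speck elsewhere
  speck <- digitalBall(d, c(48, 48, 48), 5)
  vals[speck] <- 80
  v <- VoxelVolume(vals, 10, 8L)
  om <- segmentOmDual(v, weak = c(70, 140), strong = c(100, 140),
                      minSizeVoxels = 1)
  got <- labelArray(om) > 0L
  expect_true(all(got[blob]))
  expect_false(any(got[speck]))
  # and the result equals the brute-force flood fill oracle
  weakMask <- vals >= 70 & vals <= 140
  strongMask <- vals >= 100 & vals <= 140
  expect_identical(got, floodFillOracle(weakMask, strongMask))
})

test_that("dual-threshold result is sandwiched and monotone in the ranges", {
  for (s in 1:5) {
    f <- randomBlobField(c(32L, 32L, 32L), sigma = 2, seed = 100 + s)
    v <- VoxelVolume(array(round(128 + 60 * pmax(pmin(f, 2), -2)),
                           c(32, 32, 32)), 10, 8L)
    om <- segmentOmDual(v, weak = c(150, 255), strong = c(180, 255),
                        minSizeVoxels = 1)
    got <- labelArray(om) > 0L
    weakMask <- voxelData(v) >= 150
    strongMask <- voxelData(v) >= 180
    expect_true(all(got[strongMask]))          # strong subset of result
    expect_true(all(weakMask[got]))            # result subset of weak
    # widening the weak range never shrinks the result
    om2 <- segmentOmDual(v, weak = c(140, 255), strong = c(180, 255),
                         minSizeVoxels = 1)
    expect_true(all((labelArray(om2) > 0L)[got]))
    # oracle equivalence, voxel for voxel
    expect_identical(got, floodFillOracle(weakMask, strongMask))
  }
})

test_that("raising the mineral threshold never grows the mineral mask", {
  p <- generatePhantom(smallPhantomSpec(seed = 13, shape = 64L, nOm = 1L,
                                        noiseSd = 9))
  m1 <- thresholdMineral(p$volume, 150)
  m2 <- thresholdMineral(p$volume, 170)
  expect_true(all(m1[m2]))
})

test_that("empty strong set warns and yields no OM", {
  v <- VoxelVolume(array(50, c(8, 8, 8)), 10, 8L)
  expect_warning(om <- segmentOmDual(v, weak = c(70, 140),
                                     strong = c(100, 120),
                                     minSizeVoxels = 1),
                 "empty strong")
  expect_equal(nrow(particleTable(om)), 0L)
})

test_that("pore segmentation subtracts OM and matches truth on clean phantoms", {
  p <- generatePhantom(smallPhantomSpec(seed = 14, shape = 64L, nOm = 2L))
  seg <- segmentDefault(p$volume)
  pore <- labelArray(seg$phase) == phaseCodes()[["pore"]]
  expect_identical(pore, p$truth@labels == phaseCodes()[["pore"]])
  # no OM voxel is ever in the pore mask
  expect_false(any(pore & labelArray(seg$om) > 0L))
  # empty case: threshold below the gray minimum
  expect_false(any(segmentPores(p$volume, -1)))
})

test_that("noise-free phantoms segment to ground truth for any in-between thresholds", {
  p <- generatePhantom(smallPhantomSpec(seed = 15, shape = 64L, nOm = 2L))
  for (t in list(c(150, 70, 100, 145), c(180, 60, 90, 160))) {
    seg <- segmentCore(p$volume, tMineral = t[1], weak = c(t[2], t[4]),
                       strong = c(t[3], 130), tPoreOm = t[4],
                       minSizeVoxels = 100)
    expect_identical(labelArray(seg$phase), p$truth@labels)
  }
})

test_that("CT-visible porosity is the pore share of the ROI", {
  d <- c(10L, 10L, 10L)
  allPore <- array(TRUE, d)
  expect_equal(ctVisiblePorosity(allPore), 100)
  expect_equal(ctVisiblePorosity(array(FALSE, d)), 0)
  expect_error(ctVisiblePorosity(allPore, roi = array(FALSE, d)), "empty ROI")
  p <- generatePhantom(smallPhantomSpec(seed = 16, shape = 64L, nOm = 0L))
  expect_equal(ctVisiblePorosity(p$truth), 100 * p$truth@truePorosity)
})

test_that("valley helper finds the gap between two gray modes", {
  set.seed(9)
  vals <- c(round(rnorm(4000, 60, 8)), round(rnorm(4000, 190, 8)))
  v <- VoxelVolume(array(vals, c(20, 20, 20)), 10, 8L)
  t <- autoThresholdValley(v)
  expect_true(t > 90 && t < 160)
})
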
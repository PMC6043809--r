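test_that("distance map matches the brute-force all-pairs oracle", {
  set.seed(2)
  for (s in 1:3) {
    f <- randomBlobField(c(14L, 14L, 14L), sigma = 1.5, seed = 40 + s)
    pore <- f > quantile(f, 0.6)
    dm <- distanceMap(pore, pitchUm = 10)
    expect_equal(voxelData(dm), bruteDistanceMap(pore) * 10,
                 tolerance = 1e-12)
  }
})

test_that("distance map limit cases", {
  d <- c(9L, 9L, 9L)
  # single isolated pore voxel: nearest solid is a face neighbor
  pore <- array(FALSE, d); pore[5, 5, 5] <- TRUE
  expect_equal(max(voxelData(distanceMap(pore, 10))), 10)
  # all solid: empty (zero) map
  expect_true(all(voxelData(distanceMap(array(FALSE, d), 10)) == 0))
  # digital sphere of radius 5: max distance 5 pitch +/- one pitch
  ball <- digitalBall(c(21L, 21L, 21L), c(11, 11, 11), 5)
  expect_lt(abs(max(voxelData(distanceMap(ball, 10))) - 50), 10 + 1e-9)
  # boundary is solid: a pore slab touching a face is bounded there
  slab <- array(TRUE, d)
  expect_equal(max(voxelData(distanceMap(slab, 1))),
               bruteDistanceMap(slab)[5, 5, 5])
})

test_that("watershed labels match the brute-force priority flood, voxel for voxel", {
  for (s in 1:4) {
    f <- randomBlobField(c(20L, 20L, 20L), sigma = 2, seed = 60 + s)
    pore <- f > quantile(f, 0.55)
    dm <- distanceMap(pore, pitchUm = 10)
    net <- watershedSeparate(dm, pore, hMinUm = 10)
    dv <- voxelData(dm); dv[!pore] <- 0
    dims <- dim(pore)
    rec <- soilhabitat:::cpp_reconstruct(pmax(as.vector(dv) - 10, 0),
                                         as.vector(dv), dims, 26L)
    mk <- soilhabitat:::cpp_regional_maxima(rec, as.vector(pore), dims, 26L)
    oracle <- bruteWatershed(array(dv, dims), array(mk, dims), pore)
    expect_identical(as.vector(labelArray(net)), as.vector(oracle))
    # labels cover the pore mask exactly
    expect_identical(labelArray(net) > 0L, pore)
    # volume conservation
    expect_equal(sum(regionTable(net)$voxels), sum(pore))
  }
})

test_that("single spherical pore gives one region; neck phantom gives two", {
  ball <- digitalBall(c(21L, 21L, 21L), c(11, 11, 11), 6)
  net1 <- poreNetwork(ball, pitchUm = 10)
  expect_equal(nrow(regionTable(net1)), 1L)
  expect_equal(nrow(neckTable(net1)), 0L)  # isolated region: no necks

  np <- makeNeckPhantom(120, 60, 120, pitchUm = 10)
  net2 <- poreNetwork(np$truth)
  expect_equal(nrow(regionTable(net2)), 2L)
  # watershed boundary crosses the channel near the analytic midplane
  lab <- labelArray(net2)
  bz <- integer(0)
  for (k in seq_len(dim(lab)[3] - 1)) {
    a <- lab[, , k]; b <- lab[, , k + 1]
    if (any(a > 0L & b > 0L & a != b)) bz <- c(bz, k)
  }
  mid <- mean(np$truth@info$centers_z) + 1  # 1-based
  expect_true(all(abs(bz - mid) <= 2))
})

test_that("watershed is deterministic and h-min is monotone in region count", {
  f <- randomBlobField(c(24L, 24L, 24L), sigma = 2, seed = 71)
  pore <- f > quantile(f, 0.6)
  dm <- distanceMap(pore, pitchUm = 10)
  n1 <- watershedSeparate(dm, pore, hMinUm = 5)
  n1b <- watershedSeparate(dm, pore, hMinUm = 5)
  expect_identical(labelArray(n1), labelArray(n1b))
  counts <- vapply(c(0, 5, 10, 20, 40),
                   function(h) nrow(regionTable(watershedSeparate(dm, pore, h))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("neck diameters match construction and respect the insphere bound", {
  np <- makeNeckPhantom(150, 40, 100, pitchUm = 10)
  net <- poreNetwork(np$truth)
  nt <- neckTable(net)
  expect_equal(nrow(nt), 1L)
  expect_lt(abs(nt$neck_um - 40), 2 * 10 + 1e-9)
  reg <- regionTable(net)
  expect_true(all(nt$neck_um <=
                    pmin(reg$max_insphere_um[match(nt$id_a, reg$id)],
                         reg$max_insphere_um[match(nt$id_b, reg$id)]) + 1e-9))
})

test_that("PND assigns classes by governing neck and conserves volume", {
  # empty network: all-zero table
  empty <- poreNetworkFromLabels(array(0L, c(8L, 8L, 8L)), 10)
  expect_true(all(pnd(empty)$volume_um3 == 0))

  # one region whose inscribed sphere is ~70 um: all volume in 60-90
  ball <- digitalBall(c(21L, 21L, 21L), c(11, 11, 11), 3.5)
  net1 <- poreNetwork(ball, pitchUm = 10)
  t1 <- pnd(net1)
  expect_equal(t1$volume_um3[t1$class == "60-90"], sum(ball) * 1000)

  # neck phantom: smaller lobe classed by the 40 um neck (30-60),
  # largest lobe by its own inscribed sphere (250-350 for R = 150)
  np <- makeNeckPhantom(150, 40, 100, pitchUm = 10)
  net <- poreNetwork(np$truth)
  tt <- pnd(net)
  reg <- regionTable(net)
  expect_equal(tt$volume_um3[tt$class == "30-60"], min(reg$volume_um3))
  expect_equal(tt$volume_um3[tt$class == "250-350"], max(reg$volume_um3))
  # conservation: class volumes sum to the pore volume exactly
  expect_equal(sum(tt$volume_um3), sum(reg$volume_um3))
  expect_equal(sum(tt$volume_um3),
               sum(np$truth@labels == phaseCodes()[["pore"]]) * 1000)
  expect_equal(sum(tt$pct), 100, tolerance = 0.01)
})

test_that("equivalent sphere diameter: closed form, scaling, digital sphere", {
  expect_equal(equivalentSphereDiameter(1, 10), (6000 / pi)^(1 / 3))
  expect_equal(equivalentSphereDiameter(16, 10) /
                 equivalentSphereDiameter(8, 10), 2^(1 / 3))
  ball <- digitalBall(c(25L, 25L, 25L), c(13, 13, 13), 10)
  expect_lt(abs(equivalentSphereDiameter(sum(ball), 10) / 200 - 1), 0.03)
})

test_that("invisible porosity completes the bulk-density budget", {
  expect_equal(invisiblePorosity(1.26, 30), 100 * (1 - 1.26 / 2.65) - 30)
})
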
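test_that("phantom generation is deterministic for a fixed seed", {
  spec <- smallPhantomSpec(seed = 11, shape = 64L, nOm = 1L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_identical(a$truth@labels, b$truth@labels)
  expect_identical(a$truth@omIds, b$truth@omIds)
})

test_that("truth porosity hits the target and phases partition the grid", {
  for (s in 1:4) {
    spec <- smallPhantomSpec(seed = s, shape = 64L, nOm = 2L,
                             targetPorosity = runif(1, 0.3, 0.5))
    p <- generatePhantom(spec)
    expect_lt(abs(p$truth@truePorosity - spec@targetPorosity), 0.02)
    # every voxel carries exactly one of mineral/pore/om
    expect_true(all(p$truth@labels %in% phaseCodes()[c("mineral", "pore", "om")]))
    # direct voxel count is the oracle for the recorded porosity
    nonOm <- sum(p$truth@labels != phaseCodes()[["om"]])
    expect_equal(p$truth@truePorosity,
                 sum(p$truth@labels == phaseCodes()[["pore"]]) / nonOm)
  }
})

test_that("porosity example: target 0.40 on a larger grid lands in [0.38, 0.42]", {
  spec <- smallPhantomSpec(seed = 21, shape = 96L, nOm = 0L,
                           targetPorosity = 0.40)
  p <- generateGrainPack(spec)
  expect_true(p$truth@truePorosity >= 0.38 && p$truth@truePorosity <= 0.42)
})

test_that("degenerate targets: porosity 0 gives an all-mineral pack", {
  spec <- smallPhantomSpec(seed = 3, shape = 64L, nOm = 0L,
                           targetPorosity = 0)
  spec@grainSizeFractions$fraction <-
    spec@grainSizeFractions$fraction / sum(spec@grainSizeFractions$fraction)
  p <- generateGrainPack(spec)
  expect_equal(p$truth@truePorosity, 0)
  expect_true(all(p$truth@labels == phaseCodes()[["mineral"]]))
})

test_that("unreachable porosity without a matrix fraction fails loudly", {
  spec <- smallPhantomSpec(seed = 4, shape = 64L, nOm = 0L,
                           targetPorosity = 0.2)
  # only large spheres, no sub-resolution fraction: 0.8 solid is beyond
  # random-sequential-addition jamming
  spec@grainSizeFractions <- data.frame(d_min_um = 200, d_max_um = 400,
                                        fraction = 0.8)
  expect_error(generateGrainPack(spec), "unreachable")
})

test_that("OM embedding: count, disjointness, and bounding-box span", {
  spec <- smallPhantomSpec(seed = 5, shape = 64L, nOm = 0L)
  pack <- generateGrainPack(spec)

  # zero particles leaves the pack untouched
  out0 <- embedOmParticles(pack$volume, pack$truth, spec)
  expect_identical(out0$truth@labels, pack$truth@labels)

  spec2 <- phantomSpec(shape = 160L, pitchUm = 10, nOmParticles = 3L,
                       omSizeRangeUm = c(500, 1000), seed = 6)
  p <- generatePhantom(spec2)
  pt <- particleTable(p$truth)
  expect_equal(nrow(pt), 3L)
  # ids partition the OM voxels (disjoint by construction)
  expect_equal(sum(pt$voxels), sum(p$truth@omIds > 0L))
  # diameters drawn in [500, 1000] um at 10 um pitch: bbox spans
  # 50-100 voxels per axis (plus/minus one voxel of discretization)
  spans <- cbind(pt$bbox_y1 - pt$bbox_y0, pt$bbox_x1 - pt$bbox_x0,
                 pt$bbox_z1 - pt$bbox_z0) + 1L
  expect_true(all(spans >= 49 & spans <= 101))
  # OM gray level sits strictly between pore and mineral means
  gl <- spec2@grayLevels
  expect_true(gl$pore < gl$om && gl$om < gl$mineral)
})

test_that("OM placement failure names the achieved count", {
  spec <- smallPhantomSpec(seed = 7, shape = 64L, nOm = 500L)
  expect_error(generatePhantom(spec), "of 500 placed")
})

test_that("neck phantom records its analytic geometry and guards limits", {
  np <- makeNeckPhantom(150, 40, 100, pitchUm = 10)
  expect_equal(np$truth@info$neck_diameter_um, 40)
  # 40 um at 10 um pitch falls in the 30-60 um class by construction
  expect_true(np$truth@info$neck_diameter_um >= 30 &&
                np$truth@info$neck_diameter_um < 60)
  expect_error(makeNeckPhantom(150, 350, 100, 10), "smaller than")
  expect_error(makeNeckPhantom(150, 15, 100, 10), "not representable")

  # tangent spheres at zero neck length still form one connected pore
  np0 <- makeNeckPhantom(100, 40, 0, pitchUm = 10)
  pore <- np0$truth@labels == phaseCodes()[["pore"]]
  lab <- soilhabitat:::.label3d(pore, 26L)
  expect_equal(max(lab), 1L)

  # max inscribed sphere in each lobe recovers the sphere radius
  np2 <- makeNeckPhantom(100, 40, 100, pitchUm = 10)
  dm <- distanceMap(np2$truth)
  expect_lt(abs(max(voxelData(dm)) - 100), 10 + 1e-9)
})

test_that("synthetic incubation series: zero flux, determinism, truth bookkeeping", {
  rec0 <- generateIncubationSeries(rateUgPerGPerH = 0, noiseSd = 0)
  expect_equal(rec0$sample_ppm, rec0$blank_ppm)
  a <- generateIncubationSeries(noiseSd = 2, seed = 9)
  b <- generateIncubationSeries(noiseSd = 2, seed = 9)
  expect_identical(a, b)
  tr <- attr(a, "truth")
  expect_equal(length(tr$cumulative_ug_per_g), nrow(a))
  expect_true(all(diff(tr$cumulative_ug_per_g) >= 0))
})

test_that("synthetic PLFA tables reproduce group totals and flag the trace acid", {
  gt <- c(gram_positive = 12, gram_negative = 6, actinobacteria = 4,
          c17 = 2, fungi = 5)
  tab <- generatePlfaTable(gt, noiseSd = 0, traceFraction = 0.005)
  g <- plfaMarkerGroups()
  for (grp in c("gram_positive", "gram_negative", "actinobacteria"))
    expect_equal(sum(unlist(tab[1, g[[grp]]])), unname(gt[[grp]]))
  expect_equal(tab[1, "C17:0"], unname(gt[["c17"]]))
  expect_equal(tab[1, g$fungi], unname(gt[["fungi"]]))
  # recompute the trace acid's share from the generated table itself
  acids <- setdiff(names(tab), "sample_id")
  conc <- unlist(tab[1, acids])
  share <- 100 * conc[["C15:0"]] / sum(conc)
  expect_lt(share, 1)
  expect_equal(share, 0.5, tolerance = 1e-10)
})
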
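# helper: OmParticleSet around an id array
omFromIds <- function(ids, pitchUm = 10) {
  storage.mode(ids) <- "integer"
  new("OmParticleSet", ids = ids,
      particles = soilhabitat:::.om_particle_table(ids, pitchUm),
      pitchUm = pitchUm, connectivity = 26L)
}

test_that("shell geometry: dilation minus particle, within radius, exclusions", {
  d <- c(40L, 40L, 40L)
  ids <- array(0L, d)
  ids[digitalBall(d, c(15, 20, 20), 4)] <- 1L
  ids[digitalBall(d, c(29, 20, 20), 4)] <- 2L  # neighbor 140 um away
  om <- omFromIds(ids)
  sh <- buildShell(om, 1L, radiusUm = 60)
  # shell excludes both particles
  expect_false(any(ids[sh@voxels] > 0L))
  # every shell voxel within the radius of some particle voxel
  dist <- soilhabitat:::.edt_vox(ids != 1L) * 10
  expect_true(all(dist[sh@voxels] <= 60 + 1e-9))
  expect_true(all(dist[sh@voxels] > 0))
  # minimal radius: shell is the immediate Euclidean neighborhood
  shMin <- buildShell(om, 1L, radiusUm = 10)
  expect_true(all(dist[shMin@voxels] <= 10 + 1e-9))
  expect_gt(length(shMin@voxels), 0)
})

test_that("sphere-particle shell volume matches the analytic annulus within 3%", {
  d <- c(128L, 128L, 128L)
  ids <- array(0L, d)
  ids[digitalBall(d, c(64, 64, 64), 25)] <- 1L
  om <- omFromIds(ids)
  sh <- buildShell(om, 1L, radiusUm = 350)
  analytic <- 4 / 3 * pi * (60^3 - 25^3)
  expect_lt(abs(length(sh@voxels) / analytic - 1), 0.03)
  expect_false(sh@clipped)
})

test_that("shells clipped by the grid or ROI are flagged", {
  d <- c(40L, 40L, 40L)
  ids <- array(0L, d)
  ids[digitalBall(d, c(6, 20, 20), 4)] <- 1L
  om <- omFromIds(ids)
  expect_true(buildShell(om, 1L, radiusUm = 100)@clipped)
  roi <- array(FALSE, d); roi[, , 1:30] <- TRUE
  ids2 <- array(0L, d)
  ids2[digitalBall(d, c(20, 20, 25), 4)] <- 1L
  sh2 <- buildShell(omFromIds(ids2), 1L, radiusUm = 80, roi = roi)
  expect_true(sh2@clipped)
  expect_true(all(roi[sh2@voxels]))
})

test_that("local porosity counts pore voxels over shell voxels", {
  d <- c(30L, 30L, 30L)
  ids <- array(0L, d)
  ids[digitalBall(d, c(15, 15, 15), 4)] <- 1L
  om <- omFromIds(ids)
  sh <- buildShell(om, 1L, radiusUm = 50)
  expect_equal(localPorosity(sh, array(TRUE, d)), 100)
  expect_equal(localPorosity(sh, array(FALSE, d)), 0)
  # against a known truth: pore share computed directly from labels
  p <- generatePhantom(smallPhantomSpec(seed = 31, shape = 64L, nOm = 2L))
  shp <- buildShell(p$truth, 1L, radiusUm = 200)
  pore <- p$truth@labels == phaseCodes()[["pore"]]
  expect_equal(localPorosity(shp, p$truth),
               100 * sum(pore[shp@voxels]) / length(shp@voxels))
  # internal consistency: equals CT-visible porosity with ROI = shell
  roi <- array(FALSE, dim(pore)); roi[shp@voxels] <- TRUE
  expect_equal(localPorosity(shp, p$truth),
               ctVisiblePorosity(pore, roi = roi))
})

test_that("connectivity fraction follows the region-adjacency reachability rule", {
  d <- c(60L, 60L, 60L)
  lab <- array(0L, d)
  shellBox <- array(FALSE, d); shellBox[20:39, 20:39, 20:29] <- TRUE
  lab[25:29, 25:30, 28:29] <- 1L  # A: 60 voxels in shell, touches C
  lab[34:35, 22:26, 22:23] <- 2L  # B: 20 voxels in shell, isolated
  lab[23:47, 23:47, 30:54] <- 3L  # C: large external region
  net <- poreNetworkFromLabels(lab, 10)
  shell <- new("HabitatShell", particleId = 1L,
               voxels = as.integer(which(shellBox)), dim = d,
               radiusUm = 350, pitchUm = 10, clipped = FALSE)
  # C has ESD 310 um and lies outside the shell; A:B volumes are 3:1
  expect_equal(regionTable(net)$esd_um[3],
               equivalentSphereDiameter(25^3, 10))
  expect_equal(connectivityFraction(shell, net, 300), 0.75)
  # count share alternative: one of two local pores connected
  expect_equal(connectivityFraction(shell, net, 300, share = "count"), 0.5)
  # no region above the cutoff: zero
  expect_equal(connectivityFraction(shell, net, 400), 0)
  # monotone non-increasing under a cutoff sweep
  sweep <- vapply(seq(100, 500, by = 50),
                  function(ct) connectivityFraction(shell, net, ct),
                  numeric(1))
  expect_true(all(diff(sweep) <= 1e-12))
  # undefined when the shell holds no pore voxels
  emptyShell <- new("HabitatShell", particleId = 2L,
                    voxels = as.integer(which(array(c(TRUE, rep(FALSE, 59)),
                                                    c(60, 1, 1))[, 1, 1])),
                    dim = d, radiusUm = 350, pitchUm = 10, clipped = FALSE)
  expect_true(is.na(connectivityFraction(emptyShell, net, 300)))
})

test_that("a shell pore continuing into a single large region scores 1", {
  d <- c(40L, 40L, 60L)
  lab <- array(0L, d)
  lab[18:22, 18:22, 5:55] <- 1L  # one column through and beyond the shell
  net <- poreNetworkFromLabels(lab, 10)
  shellBox <- array(FALSE, d); shellBox[10:30, 10:30, 20:30] <- TRUE
  shell <- new("HabitatShell", particleId = 1L,
               voxels = as.integer(which(shellBox)), dim = d,
               radiusUm = 350, pitchUm = 10, clipped = FALSE)
  expect_gt(regionTable(net)$esd_um, 300 * 0 + 100)  # sanity: sizable
  cutoff <- regionTable(net)$esd_um - 1
  expect_equal(connectivityFraction(shell, net, cutoff), 1)
})

test_that("habitat summary reproduces hand arithmetic", {
  shells <- data.frame(id = 1:2, shell_voxels = c(10, 10),
                       local_porosity_pct = c(20, 40),
                       connectivity_fraction = c(0.5, 1),
                       connectivity_count_share = c(0.5, 1),
                       clipped = FALSE)
  s <- habitatSummary(shells)
  expect_equal(s$mean_local_porosity, 30)
  expect_equal(s$sd_local_porosity, sqrt(200), tolerance = 1e-12)
  expect_equal(s$n_particles, 2L)
  one <- habitatSummary(shells[1, ])
  expect_equal(one$sd_local_porosity, 0)
})

test_that("habitatShells evaluates every particle and the radius sweep runs", {
  p <- generatePhantom(smallPhantomSpec(seed = 32, shape = 64L, nOm = 3L))
  net <- poreNetwork(p$truth)
  sh <- habitatShells(p$truth, p$truth, net = net, radiusUm = 150,
                      esdCutoffUm = 100)
  expect_equal(nrow(sh), nrow(particleTable(p$truth)))
  expect_true(all(sh$local_porosity_pct >= 0 & sh$local_porosity_pct <= 100))
  expect_true(all(is.na(sh$connectivity_fraction) |
                    (sh$connectivity_fraction >= 0 &
                       sh$connectivity_fraction <= 1)))
  sweep <- shellRadiusSweep(p$truth, p$truth, radiiUm = c(100, 200, 300))
  expect_equal(sweep$radius_um, c(100, 200, 300))
  expect_true(all(is.finite(sweep$var_local_porosity)))
})
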
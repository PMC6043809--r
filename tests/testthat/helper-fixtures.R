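# fixture builders and independent oracles used across tests

# logical 3D ball mask: voxel centers within radius (voxels) of center
digitalBall <- function(dim, center, radius) {
  g <- arrayInd(seq_len(prod(dim)), dim)
  d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 +
    (g[, 3] - center[3])^2
  array(d2 <= radius^2, dim)
}

# neighbor offsets for a connectivity
neighborOffsets <- function(connectivity = 26L) {
  g <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  g <- g[rowSums(abs(g)) > 0, ]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, ]
  if (connectivity == 18L) g <- g[rowSums(abs(g)) <= 2, ]
  g
}

# brute-force all-pairs Euclidean distance map oracle (voxel units,
# borders solid), for tiny fixtures only
bruteDistanceMap <- function(pore) {
  d <- dim(pore)
  sol <- which(!pore)
  out <- array(0, d)
  pidx <- which(pore)
  if (!length(pidx)) return(out)
  pc <- arrayInd(pidx, d)
  sc <- arrayInd(sol, d)
  for (r in seq_along(pidx)) {
    dmin <- if (nrow(sc)) sqrt(min((sc[, 1] - pc[r, 1])^2 +
                                     (sc[, 2] - pc[r, 2])^2 +
                                     (sc[, 3] - pc[r, 3])^2)) else Inf
    dborder <- min(pc[r, ], d - pc[r, ] + 1)
    out[pidx[r]] <- min(dmin, dborder)
  }
  out
}

# brute-force priority-flood watershed oracle: highest distance first,
# FIFO among ties; independent of the compiled path
bruteWatershed <- function(dist, markers, mask, connectivity = 26L) {
  d <- dim(dist)
  offs <- neighborOffsets(connectivity)
  lab <- array(0L, d)
  sel <- markers > 0L & mask
  lab[sel] <- markers[sel]
  fr_i <- which(lab > 0L)
  fr_d <- dist[fr_i]
  fr_s <- seq_along(fr_i)
  nextseq <- length(fr_i) + 1L
  while (length(fr_i)) {
    best <- which(fr_d == max(fr_d))
    best <- best[which.min(fr_s[best])]
    p <- fr_i[best]
    lp <- lab[p]
    fr_i <- fr_i[-best]; fr_d <- fr_d[-best]; fr_s <- fr_s[-best]
    pc <- arrayInd(p, d)
    for (t in seq_len(nrow(offs))) {
      ii <- pc[1] + offs$a[t]; jj <- pc[2] + offs$b[t]; kk <- pc[3] + offs$c[t]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      q <- ii + d[1] * ((jj - 1) + d[2] * (kk - 1))
      if (mask[q] && lab[q] == 0L) {
        lab[q] <- lp
        fr_i <- c(fr_i, q); fr_d <- c(fr_d, dist[q]); fr_s <- c(fr_s, nextseq)
        nextseq <- nextseq + 1L
      }
    }
  }
  lab
}

# flood-fill-from-strong-seeds oracle for dual thresholding, built on
# igraph connected components over the weak-voxel adjacency graph
floodFillOracle <- function(weak, strong, connectivity = 26L) {
  d <- dim(weak)
  wi <- which(weak)
  out <- array(FALSE, d)
  if (!length(wi) || !any(strong & weak)) return(out)
  inw <- array(0L, d)
  inw[wi] <- seq_along(wi)
  offs <- neighborOffsets(connectivity)
  offs <- offs[offs$a > 0 | (offs$a == 0 & offs$b > 0) |
                 (offs$a == 0 & offs$b == 0 & offs$c > 0), ]
  coords <- arrayInd(wi, d)
  edges <- NULL
  for (t in seq_len(nrow(offs))) {
    ii <- coords[, 1] + offs$a[t]
    jj <- coords[, 2] + offs$b[t]
    kk <- coords[, 3] + offs$c[t]
    v <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    qi <- inw[cbind(ii[v], jj[v], kk[v])]
    keep <- qi > 0L
    if (any(keep))
      edges <- rbind(edges, cbind(which(v)[keep], qi[keep]))
  }
  g <- igraph::make_empty_graph(n = length(wi), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  strongComp <- unique(comp[inw[which(strong & weak)]])
  out[wi[comp %in% strongComp]] <- TRUE
  out
}

# random smooth gray field fixture for dual-threshold tests
randomBlobField <- function(dim, sigma = 2, seed = 1) {
  set.seed(seed)
  f <- soilhabitat:::cpp_gauss3d(rnorm(prod(dim)), as.integer(dim), sigma)
  array(f / sd(f), dim) # unit variance so gray thresholds bite
}

# small OM-bearing phantom spec used by several tests (grain sizes
# scaled to the grid so packing stays fast)
smallPhantomSpec <- function(seed, shape = 96L, nOm = 3L,
                             noiseSd = 0, targetPorosity = 0.40) {
  sizes <- rbind(coarse = c(250, 500), fine = c(80, 250),
                 silt = c(0, 53))
  gf <- grainFractions(c(10, 40, 50), targetPorosity, sizes)
  phantomSpec(shape = shape, pitchUm = 10, grainSizeFractions = gf,
              targetPorosity = targetPorosity, nOmParticles = nOm,
              omSizeRangeUm = c(150, 300),
              grayLevels = list(pore = 40, om = 110, mineral = 200,
                                noiseSd = noiseSd),
              seed = seed)
}

# paired "dense" (10:40:50, fines-rich) vs "loose" (20:60:20,
# fines-poor) core specs at equal bulk porosity, desk scale: grain and
# OM sizes scaled to a 128^3 grid at 10 um pitch, 40 OM particles
structurePairSpec <- function(structure, seed) {
  sizes <- rbind(coarse = c(250, 500), fine = c(53, 250),
                 silt = c(0, 53))
  ratio <- if (structure == "dense") c(10, 40, 50) else c(20, 60, 20)
  gf <- grainFractions(ratio, 0.45, sizes)
  phantomSpec(shape = 128L, pitchUm = 10, grainSizeFractions = gf,
              targetPorosity = 0.45, nOmParticles = 40L,
              omSizeRangeUm = c(200, 350), seed = seed)
}

# standard thresholds for phantoms rendered at the default gray levels
segmentDefault <- function(volume, minSizeVoxels = 100) {
  segmentCore(volume, tMineral = 160, weak = c(75, 145),
              strong = c(100, 120), tPoreOm = 150,
              minSizeVoxels = minSizeVoxels)
}
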
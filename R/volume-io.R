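#' Write a volume as a multi-page TIFF stack with a sidecar metadata file
#'
#' One TIFF page per z-slice; the sidecar JSON records the voxel pitch,
#' axis order and bit depth so that linear measures survive the round
#' trip. Gray values are stored losslessly at the volume's bit depth.
#'
#' @param v A [VoxelVolume-class].
#' @param path Output TIFF path.
#' @param metaPath Sidecar JSON path (default: `path` with `.json`).
#' @return Invisibly, the metadata list.
#' @export
writeVolume <- function(v, path, metaPath = paste0(path, ".json")) {
  stopifnot(is(v, "VoxelVolume"))
  maxval <- 2^v@bitDepth - 1
  d <- dim(v@values)
  pages <- lapply(seq_len(d[3]), function(k) v@values[, , k] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = v@bitDepth,
                  compression = "none")
  meta <- list(pitch_um = v@pitchUm, axis_order = "z,y,x",
               bit_depth = v@bitDepth, dim_zyx = c(d[3], d[1], d[2]))
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

#' Read a volume from a multi-page TIFF stack
#'
#' Fails loudly if the sidecar metadata (and hence the voxel pitch) is
#' missing, or if slice dimensions are inconsistent.
#'
#' @param path TIFF path.
#' @param metaPath Sidecar JSON path (default: `path` with `.json`).
#' @return A [VoxelVolume-class].
#' @export
readVolume <- function(path, metaPath = paste0(path, ".json")) {
  if (!file.exists(path)) stop("no such TIFF stack: ", path)
  if (!file.exists(metaPath))
    stop("missing sidecar metadata (voxel pitch unknown): ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (is.null(meta$pitch_um) || !is.finite(meta$pitch_um) ||
      meta$pitch_um <= 0)
    stop("metadata does not define a positive pitch_um")
  bit <- as.integer(meta$bit_depth)
  if (!(bit %in% c(8L, 16L))) stop("unsupported bit depth: ", bit)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- lapply(pages, dim)
  if (length(unique(vapply(shp, paste, "", collapse = "x"))) != 1L)
    stop("inconsistent slice dimensions in TIFF stack")
  maxval <- 2^bit - 1
  d <- c(shp[[1]], length(pages))
  vals <- array(0, d)
  for (k in seq_along(pages)) vals[, , k] <- round(pages[[k]] * maxval)
  VoxelVolume(vals, pitchUm = meta$pitch_um, bitDepth = bit)
}

#' Linear contrast enhancement between two gray percentiles
#'
#' Maps the `[lowPct, highPct]` percentile gray range linearly onto the
#' full bit range, clipping outside; the mapping is monotone
#' non-decreasing. Defaults (0.5 / 99.5) are robust to hot pixels and
#' near-identity on clean phantoms.
#'
#' @param v A [VoxelVolume-class].
#' @param lowPct,highPct Percentiles in `[0, 100]`, `lowPct < highPct`.
#' @return A contrast-stretched [VoxelVolume-class].
#' @export
enhanceContrast <- function(v, lowPct = 0.5, highPct = 99.5) {
  stopifnot(is(v, "VoxelVolume"), lowPct >= 0, highPct <= 100,
            lowPct < highPct)
  q <- quantile(v@values, c(lowPct, highPct) / 100, names = FALSE)
  if (q[1] == q[2]) {
    warning("constant-valued volume: contrast enhancement is a no-op")
    return(v)
  }
  maxval <- 2^v@bitDepth - 1
  out <- (v@values - q[1]) / (q[2] - q[1]) * maxval
  out <- round(pmin(pmax(out, 0), maxval))
  VoxelVolume(array(out, dim(v@values)), v@pitchUm, v@bitDepth)
}

#' Convert a 16-bit volume to 8-bit
#'
#' Linear rescale of the full 16-bit range onto 0-255 with
#' round-half-up; order preserving. An 8-bit input is returned
#' unchanged with a warning.
#'
#' @param v A [VoxelVolume-class].
#' @return An 8-bit [VoxelVolume-class].
#' @export
convertTo8bit <- function(v) {
  stopifnot(is(v, "VoxelVolume"))
  if (v@bitDepth == 8L) {
    warning("volume is already 8-bit")
    return(v)
  }
  out <- floor(v@values * 255 / 65535 + 0.5)
  VoxelVolume(array(out, dim(v@values)), v@pitchUm, 8L)
}

#' Select a cylindrical region of interest
#'
#' The ROI is the cylinder inscribed in the lateral (y, x) cross-section
#' shrunk by `marginVoxels`, with the z-range trimmed by the same
#' margin; it keeps analysis away from container border artifacts.
#'
#' @param v A [VoxelVolume-class] (or 3D array).
#' @param marginVoxels Non-negative margin, smaller than half the
#'   smallest lateral extent.
#' @return An [RoiMask-class].
#' @export
selectCylindricalRoi <- function(v, marginVoxels = 0) {
  vals <- if (is(v, "VoxelVolume")) v@values else v
  d <- .as_dim3(vals)
  rmax <- min(d[1], d[2]) / 2
  if (marginVoxels < 0 || marginVoxels >= rmax)
    stop("margin must be in [0, ", rmax, ")")
  r <- rmax - marginVoxels
  cy <- (d[1] - 1) / 2
  cx <- (d[2] - 1) / 2
  yy <- (seq_len(d[1]) - 1) - cy
  xx <- (seq_len(d[2]) - 1) - cx
  disc <- outer(yy^2, xx^2, "+") <= r^2
  zlo <- 1L + as.integer(marginVoxels)
  zhi <- d[3] - as.integer(marginVoxels)
  if (zlo > zhi) stop("margin exhausts the z extent")
  mask <- array(FALSE, d)
  mask[, , zlo:zhi] <- disc
  new("RoiMask", mask = mask,
      geometry = list(type = "cylinder", center_yx = c(cy, cx),
                      radius_vox = r, z_range = c(zlo, zhi)))
}

#' Gaussian denoising filter
#'
#' Separable Gaussian smoothing with `strength` = standard deviation in
#' voxels and reflecting boundaries, standing in for the (unpublished)
#' recursive smoothing step of commercial CT suites. Strength 0 is the
#' identity; the gray-value mean is conserved up to rounding.
#'
#' @param v A [VoxelVolume-class].
#' @param strength Gaussian s.d. in voxels (>= 0).
#' @return A smoothed [VoxelVolume-class] at the same bit depth.
#' @export
denoise <- function(v, strength = 1) {
  stopifnot(is(v, "VoxelVolume"), strength >= 0)
  if (strength == 0) return(v)
  d <- dim(v@values)
  sm <- cpp_gauss3d(as.vector(v@values), as.integer(d), strength)
  # keep continuous values: integer re-quantization would destroy the
  # low-amplitude tails of the kernel and the mean-preservation contract
  maxval <- 2^v@bitDepth - 1
  out <- pmin(pmax(sm, 0), maxval)
  VoxelVolume(array(out, d), v@pitchUm, v@bitDepth)
}
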
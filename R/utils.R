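# internal helpers

.as_dim3 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  as.integer(d)
}

.check_conn <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  connectivity
}

# resolve a NULL / RoiMask / logical-array ROI argument to a logical array
.roi_array <- function(roi, dim) {
  if (is.null(roi)) return(array(TRUE, dim))
  m <- if (is(roi, "RoiMask")) roi@mask else roi
  if (!identical(dim(m), as.integer(dim)) && !identical(dim(m), dim))
    stop("ROI dimensions do not match the volume")
  m
}

# Euclidean distance map (voxel units) of `fg` to the nearest !fg voxel
.edt_vox <- function(fg, borderSolid = FALSE) {
  d <- .as_dim3(fg)
  sq <- cpp_edt_sq(as.vector(fg), d, borderSolid)
  array(sqrt(sq), d)
}

.label3d <- function(mask, connectivity = 26L) {
  d <- .as_dim3(mask)
  array(cpp_label3d(as.vector(mask), d, .check_conn(connectivity)), d)
}

# sample sd convention used for all summary statistics
.sample_sd <- function(x) if (length(x) < 2L) 0 else sd(x)
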
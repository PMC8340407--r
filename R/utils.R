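#' Construct an ImageVolume
#'
#' @param voxels 3-D array of voxel values.
#' @param spacing numeric(3) mm per axis (all <= 1 mm).
#' @param origin numeric(3) mm, world position of voxel (0,0,0).
#' @return an \linkS4class{ImageVolume}.
#' @export
imageVolume <- function(voxels, spacing = c(0.5, 0.5, 0.5), origin = c(0, 0, 0)) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axisOrder = "xyz")
}

# world (mm) -> nearest 0-based voxel index
worldToIndex <- function(vol, pt) {
  as.integer(round((pt - vol@origin) / vol@spacing))
}

# 0-based voxel index -> world (mm)
indexToWorld <- function(vol, idx) {
  vol@origin + idx * vol@spacing
}

# Shift a 3-D array by k voxels along one axis, replicating the edge.
shiftArray <- function(a, k, axis) {
  if (k == 0) return(a)
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) - k, 1L), d[axis])
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# Separable Gaussian smoothing with sigma given in mm per axis.
gaussSmooth <- function(a, sigmaMm, spacing) {
  for (axis in 1:3) {
    sVox <- sigmaMm / spacing[axis]
    if (sVox <= 1e-9) next
    half <- max(1L, ceiling(3 * sVox))
    w <- exp(-((-half:half)^2) / (2 * sVox^2))
    w <- w / sum(w)
    out <- array(0, dim(a))
    for (m in seq_along(w)) out <- out + w[m] * shiftArray(a, (-half:half)[m], axis)
    a <- out
  }
  a
}

# Sigmoid intensity -> speed map in (0, 1).
sigmoidSpeed <- function(intensity, midpoint, width) {
  1 / (1 + exp(-(intensity - midpoint) / width))
}

# Signed Euclidean distance of a binary mask (negative inside), mm.
signedDistance <- function(mask, spacing) {
  inside <- cpp_edt(mask, dim(mask), spacing)
  outside <- cpp_edt(!mask, dim(mask), spacing)
  outside - inside
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return Dice coefficient 2|A&B|/(|A|+|B|).
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Fan a single global seed out to a stage-specific seed by stable hashing
# of the stage name (kept below 2^31 - 1).
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}
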
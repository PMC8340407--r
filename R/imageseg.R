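#' Fast marching first-arrival map
#'
#' Solves the Eikonal equation |grad T| F = 1 with first-order upwind
#' differences and a min-heap narrow band.  The speed F is either supplied
#' per voxel or derived from image intensity through a sigmoid (the
#' standard choice for contrast-filled lumens: bright voxels fast, dark
#' voxels slow).
#'
#' @param image an \linkS4class{ImageVolume}.
#' @param seeds matrix of 0-based voxel index triples (one seed per row),
#'   or a numeric(3) for a single seed.
#' @param speed optional per-voxel speed array; when NULL it is
#'   \code{1/(1 + exp(-(I - midpoint)/width))}.
#' @param midpoint,width sigmoid parameters (intensity units); defaults
#'   are half and a tenth of the image's robust intensity range.
#' @return an \linkS4class{ArrivalMap}; unreached voxels are +Inf.  When
#'   every non-seed voxel is unreached (all speeds zero) a warning flags it.
#' @export
fastMarching <- function(image, seeds, speed = NULL, midpoint = NULL,
                         width = NULL) {
  v <- voxels(image)
  if (is.null(speed)) {
    rng <- quantile(v, c(0.01, 0.99), names = FALSE)
    if (is.null(midpoint)) midpoint <- mean(rng)
    if (is.null(width)) width <- max(diff(rng) / 10, 1e-9)
    speed <- sigmoidSpeed(v, midpoint, width)
  }
  stopifnot(identical(dim(speed), dim(v)))
  if (is.vector(seeds)) seeds <- matrix(seeds, nrow = 1)
  seeds <- matrix(as.integer(seeds), nrow = nrow(seeds))
  if (nrow(seeds) < 1) stop("at least one seed is required")
  res <- cpp_fast_marching(as.numeric(speed), dim(v), spacing(image), seeds)
  arr <- res$arrival
  if (all(!is.finite(arr[-(seeds[, 1] + 1 + dim(v)[1] * (seeds[, 2] + dim(v)[2] * seeds[, 3]))])))
    warning("no voxel reachable from the seeds (zero speed everywhere)")
  new("ArrivalMap", arrival = arr, spacing = spacing(image),
      origin = origin(image), seeds = seeds, monotone = res$monotone)
}

#' Colliding-fronts vessel initialization
#'
#' Propagates one fast-marching front from each of two seeds and keeps the
#' voxels whose summed arrival \code{T_a + T_b} does not exceed
#' \code{(1 + tol)} times the geodesic time between the seeds - the
#' near-geodesic tube connecting them - restricted to the connected
#' component containing both seeds.
#'
#' @param image an \linkS4class{ImageVolume}.
#' @param seedA,seedB 0-based voxel index triples inside the lumen.
#' @param tol acceptance tolerance on the geodesic sum (default 0.05).
#' @param midpoint,width sigmoid speed parameters (see
#'   \code{\link{fastMarching}}).
#' @param speed optional per-voxel speed array overriding the sigmoid;
#'   exact zeros make regions genuinely unreachable.
#' @return logical mask array.
#' @export
collidingFronts <- function(image, seedA, seedB, tol = 0.05,
                            midpoint = NULL, width = NULL, speed = NULL) {
  fa <- fastMarching(image, seedA, speed = speed, midpoint = midpoint, width = width)
  fb <- fastMarching(image, seedB, speed = speed, midpoint = midpoint, width = width)
  tAB <- fa@arrival[matrix(as.integer(seedB) + 1L, nrow = 1)]
  if (!is.finite(tAB))
    stop("seeds lie in disconnected components: no front collision")
  mask <- (fa@arrival + fb@arrival) <= (1 + tol) * tAB
  mask[!is.finite(fa@arrival) | !is.finite(fb@arrival)] <- FALSE
  dim(mask) <- dim(voxels(image))
  cpp_flood_fill(mask, dim(mask), as.integer(seedA))
}

#' Level-set refinement of a binary initialization
#'
#' Evolves a signed field phi (negative inside) from the signed distance
#' of the initialization under a region-based two-phase force (inside /
#' outside mean intensities, Chan-Vese style) with mean-curvature
#' regularization, upwind advection, and periodic signed-distance
#' reinitialization.  Evolution stops early when the zero level set moves
#' by fewer than 0.1% of voxels over 10 iterations.
#'
#' @param image an \linkS4class{ImageVolume}.
#' @param init non-empty logical mask.
#' @param iterations maximum iterations (0 returns the signed distance of
#'   \code{init} unchanged).
#' @param curvature curvature (smoothing) weight, relative to the unit
#'   region force.
#' @param reinitEvery reinitialize phi to a signed distance every this
#'   many iterations.
#' @param dt pseudo-time step in voxel units (CFL-safe at the default).
#' @return a \linkS4class{LevelSetField}.
#' @export
levelSetRefine <- function(image, init, iterations = 60L, curvature = 0.1,
                           reinitEvery = 20L, dt = 0.45) {
  if (!any(init)) stop("initialization mask is empty")
  v <- voxels(image)
  sp <- spacing(image)
  h <- min(sp)
  phi <- signedDistance(init, sp)
  changed <- rep(NA_integer_, 10)
  lastInside <- init
  it <- 0L
  converged <- FALSE
  while (it < iterations) {
    it <- it + 1L
    inside <- phi < 0
    if (!any(inside))
      stop(sprintf("level set collapsed to the empty set at iteration %d", it))
    c1 <- mean(v[inside]); c2 <- mean(v[!inside])
    # region force scaled by the phase separation (intensity-scale
    # invariant, robust to noise outliers), clamped; positive where the
    # voxel looks like the inside phase, pushing phi negative (growth)
    Fr <- ((v - c2)^2 - (v - c1)^2) / max((c1 - c2)^2, 1e-12)
    Fr <- pmin(pmax(Fr, -2), 2)
    # upwind advection for motion with speed -Fr along the normal
    gpm <- upwindGradients(phi, sp)
    adv <- pmax(Fr, 0) * gpm$gplus + pmin(Fr, 0) * gpm$gminus
    kap <- meanCurvature(phi, sp)
    # outward normal speed Fr moves phi by -Fr|grad phi|; curvature flow
    # shrinks convex (noise) bumps of the inside region
    phi <- phi - dt * h * adv + dt * h * curvature * kap * gpm$gcent
    if (it %% reinitEvery == 0L) phi <- signedDistance(phi < 0, sp)
    nowInside <- phi < 0
    changed <- c(changed[-1], sum(nowInside != lastInside))
    lastInside <- nowInside
    if (!anyNA(changed) && sum(changed) < 0.001 * length(phi) * 1) {
      converged <- TRUE
      break
    }
  }
  phi <- signedDistance(phi < 0, sp)
  new("LevelSetField", phi = phi, spacing = sp, origin = origin(image),
      iterations = it, converged = converged || it == 0L)
}

# Upwind (Godunov) gradient magnitudes for level-set advection, plus a
# central-difference magnitude for the curvature term.  Spacing in mm.
upwindGradients <- function(phi, sp) {
  gp2 <- 0; gm2 <- 0; gc2 <- 0
  for (axis in 1:3) {
    fwd <- (shiftArray(phi, -1, axis) - phi) / sp[axis]
    bwd <- (phi - shiftArray(phi, 1, axis)) / sp[axis]
    gp2 <- gp2 + pmax(bwd, 0)^2 + pmin(fwd, 0)^2
    gm2 <- gm2 + pmin(bwd, 0)^2 + pmax(fwd, 0)^2
    gc2 <- gc2 + ((fwd + bwd) / 2)^2
  }
  list(gplus = sqrt(gp2), gminus = sqrt(gm2), gcent = sqrt(gc2))
}

# Mean curvature of the level sets of phi by central differences,
# clamped to the stable |kappa| <= 1/h range.
meanCurvature <- function(phi, sp) {
  g <- list(); gg <- list()
  for (axis in 1:3) {
    g[[axis]] <- (shiftArray(phi, -1, axis) - shiftArray(phi, 1, axis)) / (2 * sp[axis])
    gg[[axis]] <- (shiftArray(phi, -1, axis) - 2 * phi + shiftArray(phi, 1, axis)) / sp[axis]^2
  }
  gxy <- (shiftArray(shiftArray(phi, -1, 1), -1, 2) - shiftArray(shiftArray(phi, -1, 1), 1, 2) -
          shiftArray(shiftArray(phi, 1, 1), -1, 2) + shiftArray(shiftArray(phi, 1, 1), 1, 2)) /
         (4 * sp[1] * sp[2])
  gxz <- (shiftArray(shiftArray(phi, -1, 1), -1, 3) - shiftArray(shiftArray(phi, -1, 1), 1, 3) -
          shiftArray(shiftArray(phi, 1, 1), -1, 3) + shiftArray(shiftArray(phi, 1, 1), 1, 3)) /
         (4 * sp[1] * sp[3])
  gyz <- (shiftArray(shiftArray(phi, -1, 2), -1, 3) - shiftArray(shiftArray(phi, -1, 2), 1, 3) -
          shiftArray(shiftArray(phi, 1, 2), -1, 3) + shiftArray(shiftArray(phi, 1, 2), 1, 3)) /
         (4 * sp[2] * sp[3])
  g2 <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2
  num <- gg[[1]] * (g[[2]]^2 + g[[3]]^2) + gg[[2]] * (g[[1]]^2 + g[[3]]^2) +
         gg[[3]] * (g[[1]]^2 + g[[2]]^2) -
         2 * (g[[1]] * g[[2]] * gxy + g[[1]] * g[[3]] * gxz + g[[2]] * g[[3]] * gyz)
  kap <- num / (g2^1.5 + 1e-12)
  h <- min(sp)
  pmin(pmax(kap, -1 / h), 1 / h)
}

#' Extract a triangulated iso-surface
#'
#' Marching-tetrahedra surface extraction (six face-consistent tetrahedra
#' per grid cube, linear interpolation along edges) followed by a cleaning
#' pass: vertices are shared through edge-keyed deduplication and
#' degenerate triangles dropped, so closed level sets yield watertight
#' meshes.  A logical mask input is first converted to its signed distance
#' and extracted at iso = 0.
#'
#' @param field a \linkS4class{LevelSetField}, a numeric array, or a
#'   logical mask.
#' @param iso iso-value (default 0); must be crossed by the field.
#' @param spacing,origin grid geometry, required for bare arrays.
#' @return a \linkS4class{TriangleSurface}.
#' @export
extractSurface <- function(field, iso = 0, spacing = NULL, origin = NULL) {
  if (is(field, "LevelSetField")) {
    arr <- field@phi; spacing <- field@spacing; origin <- field@origin
  } else {
    arr <- field
    if (is.null(spacing)) spacing <- c(0.5, 0.5, 0.5)
    if (is.null(origin)) origin <- c(0, 0, 0)
    if (is.logical(arr)) arr <- signedDistance(arr, spacing)
  }
  if (iso <= min(arr) || iso >= max(arr))
    stop(sprintf("iso value %g outside the field range [%g, %g]",
                 iso, min(arr), max(arr)))
  res <- cpp_march_tet(as.numeric(arr), dim(arr), spacing, origin, iso)
  new("TriangleSurface", vertices = res$vertices,
      triangles = res$triangles, iso = iso)
}

#' Surface area of a triangulated surface (mm^2)
#' @param surface a \linkS4class{TriangleSurface}.
#' @export
surfaceArea <- function(surface) {
  V <- surface@vertices; Tr <- surface@triangles
  a <- V[Tr[, 2], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 3], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Volume enclosed by a closed triangulated surface (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedron volumes; the absolute
#' value is returned so triangle orientation does not matter for closed
#' surfaces.
#' @param surface a \linkS4class{TriangleSurface}.
#' @export
enclosedVolume <- function(surface) {
  V <- surface@vertices; Tr <- surface@triangles
  p1 <- V[Tr[, 1], , drop = FALSE]
  p2 <- V[Tr[, 2], , drop = FALSE]
  p3 <- V[Tr[, 3], , drop = FALSE]
  svol <- (p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
           p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
           p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
  abs(sum(svol))
}

#' Edge manifoldness check
#'
#' @param surface a \linkS4class{TriangleSurface}.
#' @return TRUE when every edge is shared by exactly two triangles
#'   (watertight manifold).
#' @export
isWatertight <- function(surface) {
  Tr <- surface@triangles
  e <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Euler characteristic V - E + F
#' @param surface a \linkS4class{TriangleSurface}.
#' @export
eulerCharacteristic <- function(surface) {
  Tr <- surface@triangles
  e <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
  key <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(surface@vertices) - length(key) + nrow(Tr)
}

#' Myocardial mass from a ventricle mask
#'
#' mass = voxel count x voxel volume x tissue density.  The default
#' density 1.05 g/mL is the standard myocardium value converting the
#' segmented volume to the mass that drives the allometric resting-flow
#' relation Q = qc * M^k.
#'
#' @param ventricleMask non-empty logical array.
#' @param spacing voxel spacing, mm.
#' @param density tissue density, g/mL.
#' @return mass in grams.
#' @export
myocardialMass <- function(ventricleMask, spacing, density = 1.05) {
  n <- sum(ventricleMask)
  if (n == 0) stop("empty ventricle mask: the flow model is undefined without mass")
  voxVolMl <- prod(spacing) / 1000  # mm^3 -> mL
  n * voxVolMl * density
}
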
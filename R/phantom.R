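#' Build a TreeSpec by hand
#'
#' Constructor for explicit phantom geometries (e.g. a single straight
#' tube).  Radii are lumen radii in mm; stenoses narrow the diameter by a
#' cosine taper over their length, so the minimal diameter of a stenosis
#' of severity s is exactly (1 - s) times the local reference diameter.
#'
#' @param segments data.frame with columns id, parent (NA for root),
#'   x0, y0, z0, x1, y1, z1 (mm), r0, r1 (mm).
#' @param stenoses data.frame with columns segment, center (arc-length mm),
#'   length (mm), severity in [0, 1); zero rows allowed.
#' @param seed integer provenance seed (NA for hand-built trees).
#' @return a \linkS4class{TreeSpec}.
#' @export
treeSpec <- function(segments, stenoses = NULL, seed = NA_integer_) {
  if (is.null(stenoses))
    stenoses <- data.frame(segment = integer(), center = numeric(),
                           length = numeric(), severity = numeric())
  if (nrow(stenoses) > 0 && any(stenoses$severity >= 1))
    stop("occlusions excluded: stenosis severity must be < 1")
  new("TreeSpec", segments = segments, stenoses = stenoses,
      seed = as.integer(seed))
}

#' Straight-tube phantom specification
#'
#' Convenience single-segment tree along +z, optionally stenosed at
#' mid-length.
#'
#' @param radius lumen radius, mm.
#' @param length tube length, mm.
#' @param severity fractional diameter reduction in [0, 1); 0 for none.
#' @param stenosisLength lesion length, mm.
#' @return a \linkS4class{TreeSpec}.
#' @export
tubePhantom <- function(radius = 2, length = 40, severity = 0,
                        stenosisLength = 8) {
  seg <- data.frame(id = 1L, parent = NA_integer_,
                    x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0, z1 = length,
                    r0 = radius, r1 = radius)
  st <- if (severity > 0)
    data.frame(segment = 1L, center = length / 2, length = stenosisLength,
               severity = severity)
  else NULL
  treeSpec(seg, st)
}

#' Generate a random coronary-tree specification
#'
#' Builds a binary tree of straight tapered segments.  Each bifurcation
#' splits the parent's distal diameter by Murray's law
#' (d0^3 = d1^3 + d2^3) with a random asymmetry fraction, so the cube-law
#' identity holds to machine precision by construction.  Daughters whose
#' radius would fall below the 0.75 mm floor are not created.  Requested
#' stenoses are placed mid-segment on the largest segments.
#'
#' @param depth number of bifurcation generations (>= 1).
#' @param rootRadius root lumen radius, mm (in [0.75, 2.5]).
#' @param rootLength root segment length, mm.
#' @param lengthDecay child length = parent length * lengthDecay.
#' @param taper distal/proximal radius ratio within a segment.
#' @param branchAngle half-angle between daughters, degrees.
#' @param severities numeric vector of stenosis severities in [0, 1);
#'   one lesion per value, placed on the largest segments first.
#' @param stenosisLength lesion length, mm.
#' @param seed integer seed; the same (arguments, seed) give a
#'   byte-identical tree.
#' @return a \linkS4class{TreeSpec}.
#' @export
generateTree <- function(depth = 2L, rootRadius = 1.8, rootLength = 22,
                         lengthDecay = 0.72, taper = 0.94, branchAngle = 32,
                         severities = numeric(), stenosisLength = 8,
                         seed = 1L) {
  stopifnot(depth >= 1L)
  if (rootRadius < 0.75 || rootRadius > 2.5)
    stop("rootRadius must lie within the [0.75, 2.5] mm lumen-radius range")
  if (length(severities) > 0 && any(severities >= 1))
    stop("occlusions excluded: stenosis severity must be < 1")
  set.seed(seed)

  segs <- list()
  nextId <- 1L
  # queue entries: parent id, start point, direction, radius, length, level
  queue <- list(list(parent = NA_integer_, p0 = c(0, 0, 0), dir = c(0, 0, 1),
                     r = rootRadius, len = rootLength, level = 0L))
  while (length(queue) > 0) {
    nd <- queue[[1]]; queue <- queue[-1]
    p1 <- nd$p0 + nd$dir * nd$len
    r1 <- nd$r * taper
    segs[[nextId]] <- data.frame(id = nextId, parent = nd$parent,
                                 x0 = nd$p0[1], y0 = nd$p0[2], z0 = nd$p0[3],
                                 x1 = p1[1], y1 = p1[2], z1 = p1[3],
                                 r0 = nd$r, r1 = r1)
    myId <- nextId; nextId <- nextId + 1L
    if (nd$level < depth) {
      a <- runif(1, 0.40, 0.60)                 # cube-share of daughter 1
      rd <- r1 * c(a, 1 - a)^(1 / 3)            # Murray split, exact
      if (all(rd >= 0.75)) {
        # rotate the parent direction by +/- branchAngle about an axis
        # perpendicular to it, azimuth varied per level
        az <- (nd$level * 90 + runif(1, -15, 15)) * pi / 180
        perp <- normalizePerp(nd$dir, az)
        ang <- branchAngle * pi / 180
        for (kd in 1:2) {
          sgn <- if (kd == 1) 1 else -1
          dird <- cos(ang) * nd$dir + sgn * sin(ang) * perp
          dird <- dird / sqrt(sum(dird^2))
          queue[[length(queue) + 1]] <-
            list(parent = myId, p0 = p1, dir = dird, r = rd[kd],
                 len = nd$len * lengthDecay, level = nd$level + 1L)
        }
      }
    }
  }
  segments <- do.call(rbind, segs)

  stenoses <- NULL
  if (length(severities) > 0) {
    lens <- sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2 +
                 (segments$z1 - segments$z0)^2)
    ord <- order(-segments$r0)
    ord <- ord[lens[ord] > stenosisLength + 2][seq_along(severities)]
    stenoses <- data.frame(segment = segments$id[ord],
                           center = lens[ord] / 2,
                           length = stenosisLength,
                           severity = severities)
    stenoses <- stenoses[stenoses$severity > 0, , drop = FALSE]
  }
  treeSpec(segments, stenoses, seed)
}

# A unit vector perpendicular to dir, at azimuth az about it.
normalizePerp <- function(dir, az) {
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  cos(az) * e1 + sin(az) * e2
}

# Lumen radius at arc length s along a segment, including the cosine
# stenosis taper: multiplier 1 - severity * cos^2(pi (s - c)/L) inside
# the lesion window, so the throat diameter is (1 - severity) * reference.
segmentRadius <- function(seg, stenoses, s, segLen) {
  r <- seg$r0 + (seg$r1 - seg$r0) * s / segLen
  if (nrow(stenoses) > 0) {
    st <- stenoses[stenoses$segment == seg$id, , drop = FALSE]
    for (i in seq_len(nrow(st))) {
      x <- s - st$center[i]
      inL <- abs(x) <= st$length[i] / 2
      mult <- 1 - st$severity[i] * cos(pi * x / st$length[i])^2
      r <- ifelse(inL, r * mult, r)
    }
  }
  r
}

#' Voxelize a tree specification into a CCTA-like volume
#'
#' Renders the tree as a bright tubular foreground (two-level intensity
#' model: background 0, lumen \code{contrast}), applies a Gaussian
#' point-spread blur producing the partial-volume ramp at the lumen
#' boundary, and adds i.i.d. Gaussian noise.  A half-ellipsoid ventricle
#' shell is placed away from the tree as the myocardial mask.
#'
#' @param tree a \linkS4class{TreeSpec}.
#' @param spacing voxel spacing, mm (scalar or length 3; <= 1 mm).
#' @param margin padding around the tree bounding box, mm.
#' @param contrast lumen foreground intensity (background is 0).
#' @param noiseSd additive Gaussian noise SD, intensity units.
#' @param psfSigma Gaussian point-spread sigma, mm (0 disables blur).
#' @param seed integer seed for the noise.
#' @param extent optional list(lower, upper) world bounds, mm; segments
#'   outside raise an error naming the first offending segment.
#' @param ventricle logical, add the ventricle shell (at 25% of contrast
#'   in the image, full in the mask).
#' @return list with \code{image} (\linkS4class{ImageVolume}),
#'   \code{lumenTruth} and \code{ventricleMask} (logical arrays).
#' @export
voxelizeTree <- function(tree, spacing = 0.5, margin = 4, contrast = 400,
                         noiseSd = 0, psfSigma = 0.4, seed = 1L,
                         extent = NULL, ventricle = TRUE) {
  sp <- rep(spacing, length.out = 3)
  if (any(sp > 1)) stop("spacing must be <= 1 mm per axis")
  s <- tree@segments
  rmax <- max(s$r0, s$r1)
  lower <- c(min(s$x0, s$x1), min(s$y0, s$y1), min(s$z0, s$z1)) - rmax - margin
  upper <- c(max(s$x0, s$x1), max(s$y0, s$y1), max(s$z0, s$z1)) + rmax + margin
  if (!is.null(extent)) {
    for (i in seq_len(nrow(s))) {
      pts <- rbind(c(s$x0[i], s$y0[i], s$z0[i]), c(s$x1[i], s$y1[i], s$z1[i]))
      if (any(t(pts) - s$r0[i] < extent$lower) || any(t(pts) + s$r0[i] > extent$upper))
        stop(sprintf("segment %d exceeds the requested grid extent", s$id[i]))
    }
    lower <- extent$lower; upper <- extent$upper
  }
  ventCenter <- NULL
  if (ventricle) {
    ventAx <- c(25, 25, 35)  # outer semi-axes, mm (wall volume ~ 25 mL)
    ventCenter <- c(upper[1] + 4 + ventAx[1],
                    (lower[2] + upper[2]) / 2, (lower[3] + upper[3]) / 2)
    upper[1] <- ventCenter[1] + ventAx[1] + 2
    lower[2] <- min(lower[2], ventCenter[2] - ventAx[2] - 2)
    upper[2] <- max(upper[2], ventCenter[2] + ventAx[2] + 2)
    lower[3] <- min(lower[3], ventCenter[3] - ventAx[3] - 2)
    upper[3] <- max(upper[3], ventCenter[3] + ventAx[3] + 2)
  }
  n <- pmax(ceiling((upper - lower) / sp) + 1L, 8L)
  lumen <- array(FALSE, n)

  ax <- lower[1] + (seq_len(n[1]) - 1) * sp[1]
  ay <- lower[2] + (seq_len(n[2]) - 1) * sp[2]
  az <- lower[3] + (seq_len(n[3]) - 1) * sp[3]

  for (i in seq_len(nrow(s))) {
    p0 <- c(s$x0[i], s$y0[i], s$z0[i]); p1 <- c(s$x1[i], s$y1[i], s$z1[i])
    segLen <- sqrt(sum((p1 - p0)^2))
    u <- (p1 - p0) / segLen
    rm <- max(s$r0[i], s$r1[i])
    # crop to the segment's bounding box
    ix <- which(ax >= min(p0[1], p1[1]) - rm - sp[1] & ax <= max(p0[1], p1[1]) + rm + sp[1])
    iy <- which(ay >= min(p0[2], p1[2]) - rm - sp[2] & ay <= max(p0[2], p1[2]) + rm + sp[2])
    iz <- which(az >= min(p0[3], p1[3]) - rm - sp[3] & az <= max(p0[3], p1[3]) + rm + sp[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    X <- array(ax[ix] - p0[1], c(length(ix), length(iy), length(iz)))
    Y <- aperm(array(ay[iy] - p0[2], c(length(iy), length(ix), length(iz))), c(2, 1, 3))
    Z <- aperm(array(az[iz] - p0[3], c(length(iz), length(ix), length(iy))), c(2, 3, 1))
    tpar <- X * u[1] + Y * u[2] + Z * u[3]
    d2 <- X^2 + Y^2 + Z^2 - tpar^2
    d2[d2 < 0] <- 0
    R <- segmentRadius(s[i, ], tree@stenoses, pmin(pmax(tpar, 0), segLen), segLen)
    inside <- tpar >= 0 & tpar < segLen & sqrt(d2) <= R  # half-open end caps
    lumen[ix, iy, iz] <- lumen[ix, iy, iz] | inside
  }

  vent <- array(FALSE, n)
  if (ventricle) {
    outer3 <- c(25, 25, 35); inner3 <- c(19, 19, 28)
    X <- array(ax - ventCenter[1], n)
    Y <- aperm(array(ay - ventCenter[2], n[c(2, 1, 3)]), c(2, 1, 3))
    Z <- aperm(array(az - ventCenter[3], n[c(3, 1, 2)]), c(2, 3, 1))
    qo <- (X / outer3[1])^2 + (Y / outer3[2])^2 + (Z / outer3[3])^2
    qi <- (X / inner3[1])^2 + (Y / inner3[2])^2 + (Z / inner3[3])^2
    vent <- qo <= 1 & qi > 1 & Z <= 0   # half-ellipsoid shell
  }

  img <- contrast * lumen + 0.25 * contrast * vent
  if (psfSigma > 0) img <- gaussSmooth(img, psfSigma, sp)
  if (noiseSd > 0) {
    set.seed(seed)
    img <- img + array(rnorm(prod(n), 0, noiseSd), n)
  }
  list(image = imageVolume(img, sp, lower),
       lumenTruth = lumen, ventricleMask = vent)
}

#' Simulate a paired index/reference FFR cohort
#'
#' Reference FFR is drawn from a two-component mixture straddling the 0.80
#' ischemia threshold (positives truncated-normal below it, negatives
#' above), emulating a referred chest-pain population.  The index
#' measurement is reference + bias + Gaussian noise, clipped to (0, 1].
#' Vessels are grouped into patients (1-3 vessels each) and the
#' per-patient value is the minimum over the patient's vessels: the worst
#' lesion governs the patient-level call.
#'
#' @param nVessels number of vessel rows (>= 2).
#' @param seed integer seed.
#' @param bias systematic index - reference offset.  The default -0.06
#'   makes the index read lower than the reference, the direction implied
#'   by a 2x2 table with more false positives than false negatives.
#' @param sd measurement noise SD (>= 0).
#' @param prevalence probability a vessel's reference FFR is <= 0.80.
#' @return data.frame with columns unit_id, level ("vessel"/"patient"),
#'   reference_ffr, index_ffr, ccta_ds_percent; attribute "degenerate" is
#'   TRUE when all references fall on one side of 0.80 (the ROC stage
#'   refuses such cohorts).
#' @export
generateCohort <- function(nVessels = 78L, seed = 1L, bias = -0.06,
                           sd = 0.07, prevalence = 22 / 78) {
  stopifnot(nVessels >= 2L, sd >= 0)
  set.seed(seed)
  pos <- runif(nVessels) < prevalence
  ref <- numeric(nVessels)
  ref[pos] <- pmin(pmax(rnorm(sum(pos), 0.68, 0.08), 0.30), 0.80)
  ref[!pos] <- pmin(pmax(rnorm(sum(!pos), 0.89, 0.055), 0.805), 1.0)
  idx <- ref + bias + rnorm(nVessels, 0, sd)
  idx <- pmin(pmax(idx, 1e-6), 1)
  ds <- pmin(pmax(55 + 120 * (0.83 - ref) + rnorm(nVessels, 0, 15), 1), 95)

  # group vessels into patients, 1-3 vessels each
  pat <- integer(nVessels); p <- 0L; i <- 1L
  while (i <= nVessels) {
    p <- p + 1L
    k <- sample(1:3, 1, prob = c(0.65, 0.26, 0.09))
    pat[i:min(i + k - 1L, nVessels)] <- p
    i <- i + k
  }
  vessels <- data.frame(unit_id = sprintf("V%03d", seq_len(nVessels)),
                        level = "vessel", reference_ffr = ref,
                        index_ffr = idx, ccta_ds_percent = ds,
                        patient = pat)
  agg <- function(v) tapply(v, pat, min)
  patients <- data.frame(unit_id = sprintf("P%03d", sort(unique(pat))),
                         level = "patient",
                         reference_ffr = as.numeric(agg(ref)),
                         index_ffr = as.numeric(agg(idx)),
                         ccta_ds_percent = as.numeric(tapply(ds, pat, max)),
                         patient = sort(unique(pat)))
  out <- rbind(vessels, patients)
  rownames(out) <- NULL
  attr(out, "degenerate") <- all(ref <= 0.80) || all(ref > 0.80)
  if (attr(out, "degenerate"))
    warning("cohort is single-class at the 0.80 threshold; ROC analysis will refuse it")
  out
}
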
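#' @import methods
NULL

#' Volumetric scalar image
#'
#' A scalar voxel grid with rectilinear geometry: per-axis spacing (mm),
#' world origin (mm) and a fixed axis-order tag.  World coordinates follow
#' \code{world = origin + index * spacing} with 0-based voxel indices.
#'
#' @slot voxels 3-D numeric (or logical, for masks) array.
#' @slot spacing numeric(3), mm per axis; all positive, at most 1 mm along
#'   the slice axis so sub-millimetre slice thickness is guaranteed.
#' @slot origin numeric(3), mm.
#' @slot axisOrder single string tagging the axis convention ("xyz").
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 axisOrder = "character"),
  prototype(spacing = c(0.5, 0.5, 0.5), origin = c(0, 0, 0), axisOrder = "xyz"))

setValidity("ImageVolume", function(object) {
  msg <- NULL
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (any(object@spacing > 1 + 1e-12))
    msg <- c(msg, "spacing must be <= 1 mm per axis (sub-millimetre slices)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  if (is.numeric(object@voxels) && any(!is.finite(object@voxels)))
    msg <- c(msg, "voxel values must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Synthetic coronary-tree specification
#'
#' Ground-truth geometry of a vessel tree: straight tapered segments with a
#' parent/child topology plus cosine-tapered stenoses.  Radii are lumen
#' radii in mm; daughters attach at the parent's distal point and every
#' bifurcation obeys Murray's law (d0^3 = d1^3 + d2^3) by construction.
#'
#' @slot segments data.frame with columns id, parent (NA for the root),
#'   x0,y0,z0, x1,y1,z1 (mm), r0, r1 (mm).
#' @slot stenoses data.frame with columns segment, center (arc-length mm),
#'   length (mm), severity (fractional diameter reduction in [0,1)).
#' @slot seed integer seed the tree was generated from (NA for hand-built).
#' @export
setClass("TreeSpec",
  representation(segments = "data.frame", stenoses = "data.frame",
                 seed = "integer"))

setValidity("TreeSpec", function(object) {
  s <- object@segments
  msg <- NULL
  need <- c("id", "parent", "x0", "y0", "z0", "x1", "y1", "z1", "r0", "r1")
  if (!all(need %in% names(s))) return("segments missing required columns")
  if (any(s$r0 <= 0) || any(s$r1 <= 0)) msg <- c(msg, "segment radii must be > 0")
  if (sum(is.na(s$parent)) != 1L) msg <- c(msg, "exactly one root segment required")
  if (anyDuplicated(s$id)) msg <- c(msg, "segment ids must be unique")
  # daughters attach at the parent's distal point; acyclic by construction
  for (i in seq_len(nrow(s))) {
    p <- s$parent[i]
    if (is.na(p)) next
    j <- match(p, s$id)
    if (is.na(j)) { msg <- c(msg, "parent id not found"); break }
    if (max(abs(c(s$x0[i] - s$x1[j], s$y0[i] - s$y1[j], s$z0[i] - s$z1[j]))) > 1e-9) {
      msg <- c(msg, sprintf("segment %d does not attach at its parent's distal point", s$id[i]))
      break
    }
  }
  st <- object@stenoses
  if (nrow(st) > 0) {
    if (any(st$severity >= 1)) msg <- c(msg, "occlusions excluded: severity must be < 1")
    if (any(st$severity < 0)) msg <- c(msg, "severity must be >= 0")
    if (!all(st$segment %in% s$id)) msg <- c(msg, "stenosis references unknown segment")
  }
  if (is.null(msg)) TRUE else msg
})

#' First-arrival map from fast marching
#'
#' Per-voxel first arrival time of the Eikonal front; unreached voxels are
#' +Inf.  The freezing order of the upwind sweep is monotone non-decreasing
#' and the sweep records whether that held.
#'
#' @slot arrival 3-D numeric array (s, up to the speed scale).
#' @slot spacing,origin grid geometry inherited from the input volume.
#' @slot seeds integer matrix of 0-based seed voxel indices (one per row).
#' @slot monotone logical, monotonicity of the freezing order.
#' @export
setClass("ArrivalMap",
  representation(arrival = "array", spacing = "numeric", origin = "numeric",
                 seeds = "matrix", monotone = "logical"))

setValidity("ArrivalMap", function(object) {
  a <- object@arrival
  if (any(a[is.finite(a)] < 0)) return("arrival times must be >= 0")
  TRUE
})

#' Signed level-set field
#'
#' Signed scalar field (negative inside the segmented object) on the image
#' grid, produced by level-set refinement.
#'
#' @slot phi 3-D numeric array, negative inside.
#' @slot spacing,origin grid geometry (mm).
#' @slot iterations number of evolution iterations actually run.
#' @slot converged logical.
#' @export
setClass("LevelSetField",
  representation(phi = "array", spacing = "numeric", origin = "numeric",
                 iterations = "integer", converged = "logical"))

setValidity("LevelSetField", function(object) {
  if (any(is.na(object@phi))) return("phi must contain no NaN")
  if (all(object@phi > 0) || all(object@phi < 0))
    return("zero level set is empty")
  TRUE
})

#' Triangulated surface
#'
#' @slot vertices numeric matrix (n x 3), mm.
#' @slot triangles integer matrix (m x 3) of 1-based vertex indices.
#' @slot iso iso-value at which the surface was extracted.
#' @export
setClass("TriangleSurface",
  representation(vertices = "matrix", triangles = "matrix", iso = "numeric"))

setValidity("TriangleSurface", function(object) {
  tr <- object@triangles
  if (nrow(tr) > 0 && (max(tr) > nrow(object@vertices) || min(tr) < 1))
    return("triangle indices out of range")
  if (nrow(tr) > 0 && any(tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]))
    return("degenerate triangles present")
  TRUE
})

#' Centerline tree with radius profile
#'
#' Branch-wise centerline polylines with the maximal-inscribed-sphere
#' radius and cumulative arc length at each point, plus parent/child
#' topology with the attachment arc length on the parent.
#'
#' @slot branches named list of data.frames with columns x, y, z (mm),
#'   radius (mm), arclen (mm, strictly increasing from 0).
#' @slot topology data.frame with columns branch, parent (NA for root),
#'   attach (arc length on parent, mm).
#' @slot root integer id of the root branch.
#' @export
setClass("CenterlineTree",
  representation(branches = "list", topology = "data.frame", root = "integer"))

setValidity("CenterlineTree", function(object) {
  msg <- NULL
  for (b in object@branches) {
    if (any(b$radius <= 0)) { msg <- c(msg, "radii must be > 0"); break }
    if (nrow(b) > 1 && any(diff(b$arclen) <= 0)) {
      msg <- c(msg, "arc length must be strictly increasing"); break
    }
  }
  if (!(object@root %in% object@topology$branch))
    msg <- c(msg, "root branch missing from topology")
  if (is.null(msg)) TRUE else msg
})

#' Axisymmetric structured mesh
#'
#' Finite-volume grid in (axial z, radial r) for a root-to-leaf vessel
#' path.  Cells are the tensor product of axial intervals and global
#' radial intervals; per axial column, cells above the local wall radius
#' R(z) are blocked, so every active cell lies strictly inside r <= R(z).
#' All cell edges respect the mesh-size cap (default 0.3 mm).
#'
#' @slot zFaces numeric, axial face positions (mm, along the path).
#' @slot rFaces numeric, radial face positions (mm), starting at 0.
#' @slot wall numeric, wall radius R(z) per axial cell (mm).
#' @slot wallFace integer, index of the radial face the wall is snapped to,
#'   per axial cell (number of active radial cells in that column).
#' @slot radius numeric, centerline radius samples at axial faces (mm).
#' @slot hMax numeric, mesh size cap (mm).
#' @export
setClass("AxiMesh",
  representation(zFaces = "numeric", rFaces = "numeric", wall = "numeric",
                 wallFace = "integer", radius = "numeric", hMax = "numeric"))

setValidity("AxiMesh", function(object) {
  msg <- NULL
  dz <- diff(object@zFaces); dr <- diff(object@rFaces)
  if (any(dz <= 0) || any(dr <= 0)) msg <- c(msg, "faces must be strictly increasing")
  if (max(c(dz, dr)) > object@hMax + 1e-12)
    msg <- c(msg, "cell edge exceeds hMax")
  if (length(object@wall) != length(object@zFaces) - 1L)
    msg <- c(msg, "wall must have one entry per axial cell")
  if (is.null(msg)) TRUE else msg
})

#' Reduced-order 1-D vessel network
#'
#' @slot nodes data.frame with columns id, x, y, z (mm).
#' @slot elements data.frame with columns node0, node1, length (mm),
#'   r0, r1 (proximal/distal radius, mm), rmin (minimum radius within the
#'   element, mm), branch.
#' @slot inlet integer node id of the inlet.
#' @slot outlets data.frame with columns node, diameter (mm).
#' @export
setClass("Network1D",
  representation(nodes = "data.frame", elements = "data.frame",
                 inlet = "integer", outlets = "data.frame"))

setValidity("Network1D", function(object) {
  msg <- NULL
  if (any(object@elements$length <= 0)) msg <- c(msg, "element length must be > 0")
  if (length(object@inlet) != 1L) msg <- c(msg, "exactly one inlet required")
  if (nrow(object@outlets) < 1L) msg <- c(msg, "at least one outlet required")
  if (is.null(msg)) TRUE else msg
})

#' Physiological boundary conditions
#'
#' Mean aortic pressure, resting and hyperemic flow, the Murray-law outlet
#' split, and the blood constants of the Newtonian model
#' (rho = 1056 kg/m^3, mu = 0.0035 Pa s).
#'
#' @slot mapMmHg mean aortic pressure, mmHg.
#' @slot mapPa mean aortic pressure, Pa.
#' @slot qRest resting flow, mL/s.
#' @slot hyperemiaFactor dimensionless hyperemia multiplier (2-4 expected).
#' @slot qHyp total hyperemic flow, mL/s.
#' @slot outletFlows per-outlet flows, mL/s, summing to qHyp.
#' @slot rho blood density, kg/m^3.
#' @slot mu dynamic viscosity, Pa s.
#' @slot k allometric exponent of the mass-flow relation Q = qc * M^k.
#' @slot qc allometric coefficient, mL s^-1 g^-k.
#' @export
setClass("BoundaryConditions",
  representation(mapMmHg = "numeric", mapPa = "numeric", qRest = "numeric",
                 hyperemiaFactor = "numeric", qHyp = "numeric",
                 outletFlows = "numeric", rho = "numeric", mu = "numeric",
                 k = "numeric", qc = "numeric"))

setValidity("BoundaryConditions", function(object) {
  msg <- NULL
  if (object@rho <= 0 || object@mu <= 0) msg <- c(msg, "rho and mu must be > 0")
  if (any(object@outletFlows <= 0)) msg <- c(msg, "outlet flows must be > 0")
  if (length(object@outletFlows) > 0 &&
      abs(sum(object@outletFlows) - object@qHyp) > 1e-12 * max(object@qHyp, 1))
    msg <- c(msg, "outlet flows must sum to the hyperemic flow")
  if (object@qHyp <= 0 || object@qRest <= 0) msg <- c(msg, "flows must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Solved steady flow field on an axisymmetric mesh
#'
#' @slot mesh the \linkS4class{AxiMesh} solved on.
#' @slot pressure matrix (nz x nr) of cell-centre pressures, Pa (blocked
#'   cells NA).
#' @slot uz matrix ((nz+1) x nr) of axial face velocities, m/s.
#' @slot ur matrix (nz x (nr+1)) of radial face velocities, m/s.
#' @slot planePressure numeric, area-weighted mean pressure per axial
#'   plane (cell centres), Pa.
#' @slot planeZ numeric, axial positions of those planes, mm.
#' @slot residuals data.frame of iteration, momentum and continuity
#'   residuals.
#' @slot converged logical.
#' @slot massErr relative inlet/outlet mass-flux imbalance.
#' @export
setClass("FlowField",
  representation(mesh = "AxiMesh", pressure = "matrix", uz = "matrix",
                 ur = "matrix", planePressure = "numeric", planeZ = "numeric",
                 residuals = "data.frame", converged = "logical",
                 massErr = "numeric"))

#' FFR profile and classification
#'
#' @slot table data.frame with columns arclen (mm), radius (mm), pressure
#'   (Pa) and ffr along the solved path.
#' @slot lesionFFR FFR read at the measurement point.
#' @slot measurementArclen arc length of the measurement point, mm.
#' @slot positive logical, TRUE when lesionFFR <= threshold.
#' @slot threshold classification threshold (0.80).
#' @export
setClass("FFRResult",
  representation(table = "data.frame", lesionFFR = "numeric",
                 measurementArclen = "numeric", positive = "logical",
                 threshold = "numeric"))

setValidity("FFRResult", function(object) {
  msg <- NULL
  if (abs(object@table$ffr[1] - 1) > 1e-12)
    msg <- c(msg, "FFR at the inlet must be exactly 1")
  if (xor(object@positive, object@lesionFFR <= object@threshold))
    msg <- c(msg, "classification inconsistent with the threshold rule")
  if (is.null(msg)) TRUE else msg
})

#' 2x2 confusion counts at a fixed FFR threshold
#'
#' @slot tp,tn,fp,fn non-negative integer counts.
#' @slot level "patient" or "vessel".
#' @slot threshold FFR positivity threshold (reference and index are both
#'   positive when <= threshold).
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", tn = "integer", fp = "integer", fn = "integer",
                 level = "character", threshold = "numeric"))

setValidity("ConfusionCounts", function(object) {
  cts <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(cts < 0)) return("counts must be non-negative")
  if (sum(cts) == 0) return("total count must be > 0")
  TRUE
})

#' ROC curve with trapezoidal AUC
#'
#' Positivity is low-score (ischemia is FFR <= 0.80), so the threshold
#' sweep predicts positive when score <= t.
#'
#' @slot points data.frame with columns threshold, fpr, tpr.
#' @slot auc area under the curve (trapezoid; equals the Mann-Whitney
#'   statistic with half-credit ties).
#' @slot orientation "lower_score_positive".
#' @export
setClass("ROCCurve",
  representation(points = "data.frame", auc = "numeric",
                 orientation = "character"))

setValidity("ROCCurve", function(object) {
  p <- object@points
  if (object@auc < 0 || object@auc > 1) return("AUC must be in [0,1]")
  if (any(diff(p$fpr) < -1e-12) || any(diff(p$tpr) < -1e-12))
    return("ROC curve must be monotone non-decreasing")
  TRUE
})

#' Paired agreement summary (Pearson + Bland-Altman)
#'
#' @slot r Pearson correlation of reference and index values.
#' @slot p two-sided p-value from the t transform with n-2 df.
#' @slot meanDiff mean of differences (index - reference).
#' @slot sdDiff SD of differences.
#' @slot loa 95% limits of agreement, mean +/- 1.96 SD.
#' @slot n number of pairs.
#' @export
setClass("AgreementSummary",
  representation(r = "numeric", p = "numeric", meanDiff = "numeric",
                 sdDiff = "numeric", loa = "numeric", n = "integer"))

setValidity("AgreementSummary", function(object) {
  if (object@r < -1 || object@r > 1) return("r must be in [-1, 1]")
  if (max(abs(object@loa - (object@meanDiff + c(-1.96, 1.96) * object@sdDiff))) > 1e-9)
    return("limits of agreement must equal mean +/- 1.96 SD")
  TRUE
})
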
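#' @rdname ImageVolume-class
#' @param object,x an object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname ImageVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname ImageVolume-class
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname CenterlineTree-class
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))

#' @rdname CenterlineTree-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname ConfusionCounts-class
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname ROCCurve-class
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

setMethod("voxels", "ImageVolume", function(x) x@voxels)
setMethod("spacing", "ImageVolume", function(x) x@spacing)
setMethod("origin", "ImageVolume", function(x) x@origin)
setMethod("branches", "CenterlineTree", function(x) x@branches)
setMethod("topology", "CenterlineTree", function(x) x@topology)
setMethod("counts", "ConfusionCounts",
          function(x) c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn))
setMethod("auc", "ROCCurve", function(x) x@auc)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume: %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              paste(format(object@origin, digits = 3), collapse = ", ")))
})

setMethod("show", "TreeSpec", function(object) {
  cat(sprintf("TreeSpec: %d segment(s), %d stenosis(es), seed %s\n",
              nrow(object@segments), nrow(object@stenoses),
              ifelse(is.na(object@seed), "<none>", object@seed)))
})

setMethod("show", "ArrivalMap", function(object) {
  fin <- is.finite(object@arrival)
  cat(sprintf("ArrivalMap: %d/%d voxels reached, max arrival %.4g, monotone sweep: %s\n",
              sum(fin), length(fin), suppressWarnings(max(object@arrival[fin])),
              object@monotone))
})

setMethod("show", "LevelSetField", function(object) {
  cat(sprintf("LevelSetField: %d voxels inside, %d iterations, converged: %s\n",
              sum(object@phi < 0), object@iterations, object@converged))
})

setMethod("show", "TriangleSurface", function(object) {
  cat(sprintf("TriangleSurface: %d vertices, %d triangles (iso = %g)\n",
              nrow(object@vertices), nrow(object@triangles), object@iso))
})

setMethod("show", "CenterlineTree", function(object) {
  cat(sprintf("CenterlineTree: %d branch(es), total length %.1f mm\n",
              length(object@branches),
              sum(vapply(object@branches, function(b) max(b$arclen), 0))))
})

setMethod("show", "AxiMesh", function(object) {
  cat(sprintf("AxiMesh: %d axial x %d radial cells, hMax %.2f mm, length %.1f mm\n",
              length(object@zFaces) - 1L, length(object@rFaces) - 1L,
              object@hMax, diff(range(object@zFaces))))
})

setMethod("show", "Network1D", function(object) {
  cat(sprintf("Network1D: %d nodes, %d elements, %d outlet(s)\n",
              nrow(object@nodes), nrow(object@elements), nrow(object@outlets)))
})

setMethod("show", "BoundaryConditions", function(object) {
  cat(sprintf(paste0("BoundaryConditions: MAP %.1f mmHg (%.0f Pa), Q_rest %.2f mL/s,",
                     " x%.1f hyperemia -> %.2f mL/s over %d outlet(s)\n"),
              object@mapMmHg, object@mapPa, object@qRest,
              object@hyperemiaFactor, object@qHyp, length(object@outletFlows)))
})

setMethod("show", "FlowField", function(object) {
  cat(sprintf("FlowField: %s, mass imbalance %.2e, plane dP %.2f Pa\n",
              if (object@converged) "converged" else "NOT converged",
              object@massErr,
              object@planePressure[1] - object@planePressure[length(object@planePressure)]))
})

setMethod("show", "FFRResult", function(object) {
  cat(sprintf("FFRResult: lesion FFR %.3f at %.1f mm -> %s (threshold %.2f)\n",
              object@lesionFFR, object@measurementArclen,
              if (object@positive) "POSITIVE (hemodynamically significant)" else "negative",
              object@threshold))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts (%s level, threshold %.2f): TP %d, TN %d, FP %d, FN %d\n",
              object@level, object@threshold, object@tp, object@tn,
              object@fp, object@fn))
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: AUC %.4f over %d thresholds (%s)\n",
              object@auc, nrow(object@points), object@orientation))
})

setMethod("show", "AgreementSummary", function(object) {
  cat(sprintf("Agreement: r %.3f (p %.3g), Bland-Altman %.3f +/- %.3f, LoA [%.3f, %.3f], n %d\n",
              object@r, object@p, object@meanDiff, object@sdDiff,
              object@loa[1], object@loa[2], object@n))
})
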
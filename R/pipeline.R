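#' Default pipeline configuration
#'
#' Returns the full default configuration: stage toggles and every
#' physical/numerical parameter with its documented default.  Ranges are
#' validated by \code{\link{validateConfig}}; unknown keys are rejected
#' with a nearest-key suggestion.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    out_dir = tempfile("ctffr_run_"),
    stages = list(phantom = TRUE, segment = TRUE, geometry = TRUE,
                  hemodynamics = TRUE, ffr = TRUE, concordance = TRUE),
    phantom = list(depth = 1L, root_radius = 1.8, severities = c(0.55),
                   spacing = 0.5, noise_sd = 40, psf_sigma = 0.4,
                   contrast = 400),
    segment = list(iterations = 40L, curvature = 0.2),
    geometry = list(h_max = 0.3, dx = 0.5),
    hemodynamics = list(k = 0.75, q_c = 0.0466, hyperemia_factor = 3,
                        mu = 0.0035, rho = 1056, systolic = 131,
                        diastolic = 76, tol = 1e-6, axisymmetric = FALSE),
    ffr = list(offset = 20, threshold = 0.80),
    concordance = list(cohort_csv = NULL, n_vessels = 78L, bias = -0.06,
                       sd = 0.07, prevalence = 22 / 78)
  )
}

configRanges <- function() {
  list(
    "phantom.root_radius" = c(0.75, 2.5),
    "phantom.spacing" = c(0.05, 1),
    "phantom.noise_sd" = c(0, Inf),
    "phantom.psf_sigma" = c(0, 5),
    "segment.curvature" = c(0, 2),
    "geometry.h_max" = c(0.01, 1),
    "geometry.dx" = c(0.05, 10),
    "hemodynamics.k" = c(0.1, 1.5),
    "hemodynamics.q_c" = c(1e-4, 1),
    "hemodynamics.hyperemia_factor" = c(0.001, 10),
    "hemodynamics.mu" = c(1e-4, 0.1),
    "hemodynamics.rho" = c(500, 2000),
    "ffr.threshold" = c(0, 1),
    "concordance.sd" = c(0, 1),
    "concordance.prevalence" = c(0, 1)
  )
}

#' Validate and complete a pipeline configuration
#'
#' Merges user keys over \code{\link{defaultConfig}}; rejects unknown
#' keys (with the nearest known key as a suggestion) and values outside
#' their documented ranges.
#'
#' @param config partial configuration list (possibly from YAML).
#' @return the completed, validated configuration.
#' @export
validateConfig <- function(config = list()) {
  def <- defaultConfig()
  merged <- def
  flatKeys <- function(x, prefix = "") {
    out <- character()
    for (nm in names(x)) {
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      out <- c(out, key)
      if (is.list(x[[nm]]) && !is.null(names(x[[nm]])))
        out <- c(out, flatKeys(x[[nm]], key))
    }
    out
  }
  known <- flatKeys(def)
  for (top in names(config)) {
    checkKey(top, known)
    if (is.list(config[[top]]) && !is.null(names(config[[top]]))) {
      for (sub in names(config[[top]])) {
        key <- paste0(top, ".", sub)
        checkKey(key, known)
        merged[[top]][[sub]] <- config[[top]][[sub]]
      }
    } else merged[[top]] <- config[[top]]
  }
  rng <- configRanges()
  for (key in names(rng)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- merged[[parts[1]]][[parts[2]]]
    if (!is.null(val) && is.numeric(val) &&
        (any(val < rng[[key]][1]) || any(val > rng[[key]][2])))
      stop(sprintf("config key '%s' = %s outside its documented range [%g, %g]",
                   key, paste(val, collapse = ","), rng[[key]][1], rng[[key]][2]))
  }
  merged
}

checkKey <- function(key, known) {
  if (key %in% known) return(invisible(TRUE))
  d <- utils::adist(key, known)
  stop(sprintf("unknown config key '%s'; did you mean '%s'?",
               key, known[which.min(d)]))
}

#' Run report
#'
#' @slot version package version string.
#' @slot config the validated configuration the run used.
#' @slot stages named list of per-stage artifact paths, md5 hashes and
#'   summaries.
#' @export
setClass("RunReport",
  representation(version = "character", config = "list", stages = "list"))

setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport (ctFFR %s): stages run: %s\n", object@version,
              paste(names(object@stages), collapse = ", ")))
})

#' Run the full pipeline
#'
#' Executes phantom -> segment -> geometry -> hemodynamics -> ffr ->
#' concordance in order, skipping disabled stages; every stage writes its
#' artifacts into the output directory before the next begins, and the
#' report records an md5 hash for each artifact.  All randomness flows
#' from the single global seed, fanned out per stage by stable hashing of
#' the stage name.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @return a \linkS4class{RunReport}.
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  ver <- as.character(utils::packageVersion("ctFFR"))
  art <- function(...) file.path(out, ...)
  hash <- function(paths) vapply(paths, function(p) unname(tools::md5sum(p)), "")

  tree <- NULL; vox <- NULL; mask <- NULL; ctree <- NULL; lesions <- NULL
  net <- NULL; bcObj <- NULL; sol <- NULL; ffrRes <- NULL; massG <- NULL

  runStage <- function(name, body) {
    tryCatch(body(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s (artifacts under %s)",
                   name, conditionMessage(e), out), call. = FALSE))
  }

  if (isTRUE(cfg$stages$phantom)) runStage("phantom", function() {
    ph <- cfg$phantom
    tree <<- generateTree(depth = ph$depth, rootRadius = ph$root_radius,
                          severities = ph$severities,
                          seed = stageSeed(cfg$seed, "phantom"))
    vox <<- voxelizeTree(tree, spacing = ph$spacing, contrast = ph$contrast,
                         noiseSd = ph$noise_sd, psfSigma = ph$psf_sigma,
                         seed = stageSeed(cfg$seed, "phantom-noise"))
    writeTreeSpec(tree, art("tree.json"))
    writeVolume(vox$image, art("image.nii.gz"))
    writeVolume(vox$lumenTruth, art("lumen_truth.nii.gz"),
                spacing(vox$image), origin(vox$image))
    writeVolume(vox$ventricleMask, art("ventricle_mask.nii.gz"),
                spacing(vox$image), origin(vox$image))
    stages$phantom <<- list(
      artifacts = hash(art(c("tree.json", "image.nii.gz", "lumen_truth.nii.gz",
                             "ventricle_mask.nii.gz"))),
      summary = list(segments = nrow(tree@segments),
                     lumen_voxels = sum(vox$lumenTruth)))
  })

  if (isTRUE(cfg$stages$segment)) runStage("segment", function() {
    if (is.null(vox)) stop("segment stage needs the phantom stage outputs")
    seedsIJK <- treeSeedVoxels(tree, vox$image)
    init <- collidingFronts(vox$image, seedsIJK$root, seedsIJK$leaves[1, ])
    ls <- levelSetRefine(vox$image, init,
                         iterations = cfg$segment$iterations,
                         curvature = cfg$segment$curvature)
    mask <<- ls@phi < 0
    massG <<- myocardialMass(vox$ventricleMask, spacing(vox$image))
    surf <- extractSurface(ls)
    writeVolume(mask, art("lumen_mask.nii.gz"), spacing(vox$image),
                origin(vox$image))
    writeSurface(surf, art("lumen_surface.stl"))
    stages$segment <<- list(
      artifacts = hash(art(c("lumen_mask.nii.gz", "lumen_surface.stl"))),
      summary = list(dice_vs_truth = diceCoefficient(mask, vox$lumenTruth),
                     myocardial_mass_g = massG))
  })

  if (isTRUE(cfg$stages$geometry)) runStage("geometry", function() {
    if (is.null(mask)) stop("geometry stage needs the segment stage outputs")
    seedsIJK <- treeSeedVoxels(tree, vox$image, insideMask = mask)
    ctree <<- extractCenterline(mask, seedsIJK$root, seedsIJK$leaves,
                                spacing(vox$image), origin(vox$image))
    lesions <<- quantifyStenosis(ctree)
    net <<- buildNetwork(ctree, dx = cfg$geometry$dx)
    writeCenterline(ctree, art("centerline.json"))
    writeCenterline(ctree, art("centerline.vtk"))
    write.csv(lesions, art("lesions.csv"), row.names = FALSE)
    stages$geometry <<- list(
      artifacts = hash(art(c("centerline.json", "centerline.vtk", "lesions.csv"))),
      summary = list(branches = length(ctree@branches),
                     lesions = nrow(lesions)))
  })

  if (isTRUE(cfg$stages$hemodynamics)) runStage("hemodynamics", function() {
    if (is.null(net)) stop("hemodynamics stage needs the geometry stage outputs")
    hd <- cfg$hemodynamics
    bcObj <<- boundaryConditions(systolic = hd$systolic, diastolic = hd$diastolic,
                                 mass = massG, hyperemiaFactor = hd$hyperemia_factor,
                                 outletDiameters = net@outlets$diameter,
                                 k = hd$k, qc = hd$q_c, rho = hd$rho, mu = hd$mu)
    sol <<- solveNetwork(net, bcObj)
    if (isTRUE(hd$axisymmetric)) {
      meshA <- buildAxiMesh(ctree, hMax = cfg$geometry$h_max)
      fieldA <- solveAxisymmetric(meshA, bcObj,
                                  inflow = mainPathInflow(ctree, bcObj, net),
                                  tol = hd$tol)
      saveRDSless <- NULL # fields are summarized, not serialized binary
      stages$hemodynamics_axisym <<- list(summary = list(
        plane_dp_pa = pressureDrop(fieldA), converged = fieldA@converged))
    }
    presDf <- data.frame(node = seq_along(sol@pressures),
                         pressure_pa = sol@pressures)
    write.csv(presDf, art("node_pressures.csv"), row.names = FALSE)
    stages$hemodynamics <<- list(
      artifacts = hash(art("node_pressures.csv")),
      summary = list(q_rest_ml_s = bcObj@qRest, q_hyp_ml_s = bcObj@qHyp,
                     map_mmhg = bcObj@mapMmHg))
  })

  if (isTRUE(cfg$stages$ffr)) runStage("ffr", function() {
    if (is.null(sol)) stop("ffr stage needs the hemodynamics stage outputs")
    lesionEnd <- if (!is.null(lesions) && nrow(lesions) > 0)
      lesions$end[which.max(lesions$ds_percent)] else NULL
    ffrRes <<- computeFFR(sol, bcObj, lesionEnd = lesionEnd,
                          offset = cfg$ffr$offset,
                          threshold = cfg$ffr$threshold)
    writeFFR(ffrRes, art("ffr_profile.csv"))
    writeFFR(ffrRes, art("ffr_summary.json"))
    stages$ffr <<- list(
      artifacts = hash(art(c("ffr_profile.csv", "ffr_summary.json"))),
      summary = list(lesion_ffr = ffrRes@lesionFFR,
                     positive = ffrRes@positive))
  })

  if (isTRUE(cfg$stages$concordance)) runStage("concordance", function() {
    cc <- cfg$concordance
    cohort <- if (!is.null(cc$cohort_csv)) readCohort(cc$cohort_csv)
              else generateCohort(cc$n_vessels,
                                  seed = stageSeed(cfg$seed, "concordance"),
                                  bias = cc$bias, sd = cc$sd,
                                  prevalence = cc$prevalence)
    lv <- intersect(c("vessel", "patient"), unique(cohort$level))
    rep <- list()
    for (level in lv) {
      cts <- confusionCounts(cohort, level)
      rows <- cohort[cohort$level == level, ]
      rep[[level]] <- list(
        counts = as.list(counts(cts)),
        metrics = diagnosticMetrics(cts),
        auc = tryCatch(auc(rocAuc(rows$index_ffr,
                                  rows$reference_ffr <= 0.80)),
                       error = function(e) NA_real_),
        agreement = {
          ag <- agreementStats(rows$reference_ffr, rows$index_ffr)
          list(r = ag@r, p = ag@p, mean_diff = ag@meanDiff,
               sd_diff = ag@sdDiff, loa = ag@loa)
        })
    }
    jsonlite::write_json(rep, art("concordance.json"), digits = NA,
                         auto_unbox = TRUE, dataframe = "rows")
    stages$concordance <<- list(
      artifacts = hash(art("concordance.json")),
      summary = lapply(rep, function(x) x$counts))
  })

  new("RunReport", version = ver, config = cfg, stages = stages)
}

# Seed voxels safely inside the tree: a point 10% along the root segment
# and one 85% along each leaf segment (nudged inside the given mask when
# supplied).
treeSeedVoxels <- function(tree, image, insideMask = NULL) {
  s <- tree@segments
  pointAt <- function(row, f) {
    p <- c(row$x0, row$y0, row$z0) * (1 - f) + c(row$x1, row$y1, row$z1) * f
    worldToIndex(image, p)
  }
  rootRow <- s[is.na(s$parent), ]
  leaves <- s[!(s$id %in% s$parent[!is.na(s$parent)]), , drop = FALSE]
  rootIJK <- pointAt(rootRow[1, ], 0.1)
  leafIJK <- t(vapply(seq_len(nrow(leaves)),
                      function(i) pointAt(leaves[i, ], 0.85), integer(3)))
  if (!is.null(insideMask)) {
    snap <- function(ijk) {
      if (insideMask[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1]) return(ijk)
      cand <- which(insideMask, arr.ind = TRUE) - 1L
      d2 <- rowSums((t(t(cand) - ijk))^2)
      as.integer(cand[which.min(d2), ])
    }
    rootIJK <- snap(rootIJK)
    leafIJK <- t(apply(leafIJK, 1, snap))
  }
  list(root = rootIJK, leaves = leafIJK)
}

# inflow down the main (largest) path when the axisymmetric solver is run
# on a single root-to-leaf path: the Murray share of its outlet
mainPathInflow <- function(ctree, bc, net) {
  path <- defaultPath(ctree)
  leafBranch <- path[length(path)]
  leaves <- setdiff(ctree@topology$branch,
                    ctree@topology$parent[!is.na(ctree@topology$parent)])
  iOut <- match(leafBranch, leaves)
  if (is.na(iOut) || length(bc@outletFlows) < iOut) bc@qHyp
  else bc@outletFlows[iOut]
}

#' Export a run report
#'
#' JSON (machine-readable) and Markdown (human-readable) renderings of
#' the report; the FFR profile CSV is written by the ffr stage itself.
#'
#' @param report a \linkS4class{RunReport}.
#' @param path output path without extension; writes <path>.json and
#'   <path>.md.
#' @return invisibly, the two paths.
#' @export
exportReport <- function(report, path) {
  obj <- list(version = report@version, config = report@config,
              stages = report@stages)
  jsonPath <- paste0(path, ".json")
  jsonlite::write_json(obj, jsonPath, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  md <- c(sprintf("# ctFFR run report (v%s)", report@version), "")
  for (nm in names(report@stages)) {
    md <- c(md, sprintf("## %s", nm), "")
    sm <- report@stages[[nm]]$summary
    for (k in names(sm))
      md <- c(md, sprintf("- %s: %s", k, paste(format(sm[[k]]), collapse = ", ")))
    md <- c(md, "")
  }
  mdPath <- paste0(path, ".md")
  writeLines(md, mdPath)
  invisible(c(jsonPath, mdPath))
}
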
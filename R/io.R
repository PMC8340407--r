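#' Read a volumetric image
#'
#' NIfTI (.nii/.nii.gz) through RNifti; MetaImage (.mha/.mhd) through the
#' package's own minimal reader (uncompressed MET_UCHAR / MET_SHORT /
#' MET_FLOAT / MET_DOUBLE, local data).
#'
#' @param path file path with extension .nii, .nii.gz, .mha or .mhd.
#' @return an \linkS4class{ImageVolume}.
#' @export
readVolume <- function(path) {
  ext <- volumeExt(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    hdr <- RNifti::niftiHeader(img)
    org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
    return(imageVolume(array(as.numeric(img), dim(img)[1:3]), sp, org))
  }
  if (ext %in% c("mha", "mhd")) return(readMetaImage(path))
  stop("unsupported extension '", ext,
       "': convert to NIfTI/MetaImage first (DICOM is not read directly)")
}

#' Write a volumetric image
#'
#' @param vol an \linkS4class{ImageVolume} or a (logical) mask array with
#'   attributes taken from \code{spacing}/\code{origin}.
#' @param path destination (.nii, .nii.gz, .mha, .mhd); masks are written
#'   as unsigned 8-bit, arrival maps and images as float32.
#' @param spacing,origin used when \code{vol} is a bare array.
#' @export
writeVolume <- function(vol, path, spacing = c(0.5, 0.5, 0.5),
                        origin = c(0, 0, 0)) {
  if (is(vol, "ImageVolume")) {
    arr <- voxels(vol); spacing <- spacing(vol); origin <- origin(vol)
  } else if (is(vol, "ArrivalMap")) {
    arr <- vol@arrival; spacing <- vol@spacing; origin <- vol@origin
    arr[!is.finite(arr)] <- -1  # +Inf has no portable float voxel encoding
  } else arr <- vol
  isMask <- is.logical(arr)
  storage.mode(arr) <- "double"
  ext <- volumeExt(path)
  if (ext %in% c("nii", "nii.gz")) {
    hdr <- RNifti::niftiHeader(RNifti::asNifti(arr))
    hdr$pixdim[2:4] <- spacing
    hdr$qoffset_x <- origin[1]; hdr$qoffset_y <- origin[2]
    hdr$qoffset_z <- origin[3]; hdr$qform_code <- 1L
    img <- RNifti::asNifti(arr, reference = hdr,
                           datatype = if (isMask) "uint8" else "float")
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("mha", "mhd")) {
    writeMetaImage(arr, path, spacing, origin,
                   type = if (isMask) "MET_UCHAR" else "MET_FLOAT")
  } else {
    stop("unsupported extension '", ext, "': use NIfTI or MetaImage")
  }
  invisible(path)
}

volumeExt <- function(path) {
  if (grepl("\\.nii\\.gz$", path)) return("nii.gz")
  tolower(sub(".*\\.", "", path))
}

# --- minimal MetaImage (ITK MHA/MHD) support --------------------------------

writeMetaImage <- function(arr, path, spacing, origin, type = "MET_FLOAT") {
  d <- dim(arr)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(origin, collapse = " ")),
           paste("ElementSpacing =", paste(spacing, collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementType =", type),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  vals <- as.numeric(arr)
  switch(type,
    MET_UCHAR  = writeBin(as.integer(vals), con, size = 1),
    MET_SHORT  = writeBin(as.integer(vals), con, size = 2, endian = "little"),
    MET_FLOAT  = writeBin(vals, con, size = 4, endian = "little"),
    MET_DOUBLE = writeBin(vals, con, size = 8, endian = "little"),
    stop("unsupported ElementType ", type))
  invisible(path)
}

readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readHeaderLine(con)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line: '", line, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  for (need in c("DimSize", "ElementType", "ElementSpacing"))
    if (is.null(hdr[[need]]))
      stop("malformed MetaImage header: missing field ", need)
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL MetaImage data are supported")
  if (identical(hdr[["CompressedData"]], "True"))
    stop("compressed MetaImage data are not supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  n <- prod(d)
  vals <- switch(hdr$ElementType,
    MET_UCHAR  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    MET_SHORT  = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    MET_FLOAT  = readBin(con, "numeric", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported ElementType ", hdr$ElementType))
  imageVolume(array(vals, d), sp, org)
}

readHeaderLine <- function(con) {
  chars <- character()
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("malformed MetaImage header: unexpected EOF")
    if (ch == "\n") break
    chars <- c(chars, ch)
  }
  sub("\r$", "", paste(chars, collapse = ""))
}

# --- surfaces ---------------------------------------------------------------

#' Write a triangulated surface
#'
#' ASCII STL or PLY chosen by extension.
#' @param surface a \linkS4class{TriangleSurface}.
#' @param path destination ending in .stl or .ply.
#' @export
writeSurface <- function(surface, path) {
  ext <- tolower(sub(".*\\.", "", path))
  V <- surface@vertices; Tr <- surface@triangles
  if (ext == "stl") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid surface", con)
    for (i in seq_len(nrow(Tr))) {
      p <- V[Tr[i, ], , drop = FALSE]
      nvec <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) - (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
                (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) - (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
                (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) - (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
      nn <- sqrt(sum(nvec^2)); if (nn > 0) nvec <- nvec / nn
      writeLines(c(sprintf("  facet normal %g %g %g", nvec[1], nvec[2], nvec[3]),
                   "    outer loop",
                   sprintf("      vertex %g %g %g", p[, 1], p[, 2], p[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid surface", con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(Tr)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%g %g %g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", Tr[, 1] - 1L, Tr[, 2] - 1L, Tr[, 3] - 1L), con)
  } else stop("unsupported surface extension .", ext)
  invisible(path)
}

# --- centerlines, meshes, tables --------------------------------------------

#' Write a centerline tree
#'
#' Legacy-VTK polylines (.vtk) or JSON (.json) chosen by extension.
#' @param tree a \linkS4class{CenterlineTree}.
#' @param path destination.
#' @export
writeCenterline <- function(tree, path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "json") {
    obj <- list(root = tree@root, topology = tree@topology,
                branches = tree@branches)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  } else if (ext == "vtk") {
    pts <- do.call(rbind, lapply(tree@branches, function(b) cbind(b$x, b$y, b$z)))
    rads <- unlist(lapply(tree@branches, function(b) b$radius))
    offs <- cumsum(c(0, vapply(tree@branches, nrow, 1L)))
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "centerline", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(pts))), con)
    writeLines(sprintf("%g %g %g", pts[, 1], pts[, 2], pts[, 3]), con)
    nb <- length(tree@branches)
    writeLines(sprintf("LINES %d %d", nb, nb + nrow(pts)), con)
    for (b in seq_len(nb)) {
      n <- offs[b + 1] - offs[b]
      writeLines(paste(c(n, seq(offs[b], offs[b + 1] - 1)), collapse = " "), con)
    }
    writeLines(c(sprintf("POINT_DATA %d", nrow(pts)),
                 "SCALARS radius float 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%g", rads), con)
  } else stop("unsupported centerline extension .", ext)
  invisible(path)
}

#' Write an FFR profile
#'
#' CSV of (arclen, radius, pressure, ffr) or a JSON summary.
#' @param ffr an \linkS4class{FFRResult}.
#' @param path destination (.csv or .json).
#' @export
writeFFR <- function(ffr, path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "csv") {
    write.csv(ffr@table, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(lesion_ffr = ffr@lesionFFR,
                              measurement_arclen_mm = ffr@measurementArclen,
                              positive = ffr@positive,
                              threshold = ffr@threshold),
                         path, digits = NA, auto_unbox = TRUE)
  } else stop("unsupported FFR extension .", ext)
  invisible(path)
}

#' Read/write a paired cohort table
#'
#' CSV schema: unit_id, level, reference_ffr, index_ffr, ccta_ds_percent.
#' @param cohort cohort data.frame.
#' @param path CSV path.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort[, c("unit_id", "level", "reference_ffr", "index_ffr",
                       "ccta_ds_percent")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "level", "reference_ffr", "index_ffr")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("cohort CSV is missing columns: ", paste(miss, collapse = ", "))
  if (any(df$reference_ffr <= 0 | df$reference_ffr > 1) ||
      any(df$index_ffr <= 0 | df$index_ffr > 1))
    stop("FFR values must lie in (0, 1]")
  df
}

#' Write a TreeSpec as JSON
#' @param tree a \linkS4class{TreeSpec}.
#' @param path JSON path.
#' @export
writeTreeSpec <- function(tree, path) {
  jsonlite::write_json(list(segments = tree@segments,
                            stenoses = tree@stenoses, seed = tree@seed),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTreeSpec
#' @export
readTreeSpec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- obj$stenoses
  if (is.null(st) || length(st) == 0) st <- NULL
  seg <- as.data.frame(obj$segments)
  if (is.null(seg$parent)) seg$parent <- NA_integer_
  seg$parent <- as.integer(seg$parent)
  seg <- seg[, c("id", "parent", "x0", "y0", "z0", "x1", "y1", "z1",
                 "r0", "r1")]
  treeSpec(seg, st, if (is.null(obj$seed)) NA_integer_ else obj$seed)
}
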
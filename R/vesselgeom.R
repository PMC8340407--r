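#' Extract a centerline tree from a lumen mask
#'
#' Fast marching is seeded at the root with speed equal to the interior
#' Euclidean distance transform raised to a positive power (so the front
#' runs fastest along the medial axis), and each endpoint is backtracked
#' by steepest descent on the arrival map.  Shared path prefixes are
#' merged into branches; the radius at each centerline point is the
#' distance-transform value less half a voxel (the distance to background
#' voxel centres overestimates the inscribed-sphere radius by about half
#' a voxel).
#'
#' @param mask logical lumen array.
#' @param root 0-based voxel index triple of the tree root (inside mask).
#' @param endpoints matrix of 0-based voxel index triples (rows), inside
#'   the mask.
#' @param spacing voxel spacing, mm.
#' @param origin world origin, mm.
#' @param power exponent on the distance-transform speed (default 2).
#' @param smoothWindow moving-average half-window (points) applied to the
#'   backtracked polylines.
#' @return a \linkS4class{CenterlineTree}.
#' @export
extractCenterline <- function(mask, root, endpoints, spacing = c(0.5, 0.5, 0.5),
                              origin = c(0, 0, 0), power = 2, smoothWindow = 2L) {
  if (is.vector(endpoints)) endpoints <- matrix(endpoints, nrow = 1)
  d <- dim(mask)
  inMask <- function(ix) mask[matrix(as.integer(ix) + 1L, nrow = 1)]
  if (!inMask(root)) stop("root is not inside the mask")
  edt <- cpp_edt(mask, d, spacing)
  speed <- (edt / max(edt))^power
  vol <- imageVolume(array(0, d), spacing, origin)
  am <- fastMarching(vol, root, speed = speed)
  Tm <- am@arrival

  paths <- vector("list", nrow(endpoints))
  for (e in seq_len(nrow(endpoints))) {
    cur <- as.integer(endpoints[e, ])
    if (!inMask(cur))
      stop(sprintf("endpoint %d is not inside the mask", e))
    if (!is.finite(Tm[matrix(cur + 1L, nrow = 1)]))
      stop(sprintf("endpoint %d is unreachable from the root", e))
    path <- list(cur)
    repeat {
      tCur <- Tm[cur[1] + 1, cur[2] + 1, cur[3] + 1]
      if (tCur <= 0) break
      # best 26-neighbour strictly downhill in arrival time
      best <- NULL; bestT <- tCur
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nb <- cur + c(dx, dy, dz)
        if (any(nb < 0) || any(nb >= d)) next
        tn <- Tm[nb[1] + 1, nb[2] + 1, nb[3] + 1]
        if (is.finite(tn) && tn < bestT) { bestT <- tn; best <- nb }
      }
      if (is.null(best))
        stop(sprintf("steepest descent stalled backtracking endpoint %d", e))
      cur <- best
      path[[length(path) + 1]] <- cur
      if (length(path) > prod(d)) stop("backtracking failed to terminate")
    }
    paths[[e]] <- do.call(rbind, rev(path))  # root -> endpoint
  }

  tree <- mergePaths(paths)
  # convert voxel paths to world polylines with radius and arc length
  halfVox <- mean(spacing) / 2
  branches <- lapply(tree$branches, function(pm) {
    pts <- sweep(pm * rep(spacing, each = nrow(pm)), 2, origin, "+")
    r <- edt[pm + 1L]
    if (smoothWindow > 0 && nrow(pts) > 2 * smoothWindow + 1) {
      pts <- apply(pts, 2, movingAverage, k = smoothWindow)
      r <- movingAverage(r, smoothWindow)
    }
    keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-9)
    pts <- pts[keep, , drop = FALSE]; r <- r[keep]
    arclen <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
               radius = pmax(r - halfVox, 0.05), arclen = arclen)
  })
  topo <- tree$topology
  topo$attach <- vapply(seq_len(nrow(topo)), function(i) {
    p <- topo$parent[i]
    if (is.na(p)) return(0)
    max(branches[[p]]$arclen)
  }, 0)
  new("CenterlineTree", branches = branches, topology = topo, root = 1L)
}

movingAverage <- function(x, k) {
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1, i - k); hi <- min(n, i + k)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Merge root->endpoint voxel paths into branches by splitting at the
# first voxel where a new path leaves the existing tree.
mergePaths <- function(paths) {
  keyOf <- function(v) paste(v, collapse = ",")
  branches <- list(paths[[1]])
  topo <- data.frame(branch = 1L, parent = NA_integer_)
  loc <- new.env(hash = TRUE)
  for (r in seq_len(nrow(paths[[1]])))
    assign(keyOf(paths[[1]][r, ]), c(1L, r), envir = loc)
  if (length(paths) > 1) for (e in 2:length(paths)) {
    pm <- paths[[e]]
    j <- 1L
    while (j <= nrow(pm) && !is.null(loc[[keyOf(pm[j, ])]])) j <- j + 1L
    split <- j - 1L           # last shared row
    at <- loc[[keyOf(pm[split, ])]]
    b <- at[1]; pos <- at[2]
    if (pos < nrow(branches[[b]])) {
      # split branch b at pos: tail becomes a new branch
      tailPart <- branches[[b]][pos:nrow(branches[[b]]), , drop = FALSE]
      branches[[b]] <- branches[[b]][1:pos, , drop = FALSE]
      nb <- length(branches) + 1L
      branches[[nb]] <- tailPart
      for (r in 2:nrow(tailPart))
        assign(keyOf(tailPart[r, ]), c(nb, r), envir = loc)
      # children previously hanging off the tail follow the new branch
      topo$parent[topo$parent == b &
                  vapply(topo$branch, function(bb) {
                    !is.null(loc[[keyOf(branches[[bb]][1, ])]]) &&
                      loc[[keyOf(branches[[bb]][1, ])]][1] == nb
                  }, TRUE)] <- nb
      topo <- rbind(topo, data.frame(branch = nb, parent = b))
    }
    # new branch for the divergent tail (attachment voxel included first)
    newPath <- pm[split:nrow(pm), , drop = FALSE]
    nb2 <- length(branches) + 1L
    branches[[nb2]] <- newPath
    for (r in 2:nrow(newPath))
      assign(keyOf(newPath[r, ]), c(nb2, r), envir = loc)
    topo <- rbind(topo, data.frame(branch = nb2, parent = b))
  }
  list(branches = branches, topology = topo)
}

#' Quantify stenoses along a centerline tree
#'
#' The diameter profile of each branch is compared against a reference
#' obtained by linear interpolation between healthy shoulders (the 90th
#' percentile of the diameter over windows proximal and distal of the
#' lesion, the QCA-style convention).  Lesions are maximal runs where the
#' diameter falls below 0.9 x reference; percent diameter stenosis is
#' 100 (1 - minimal/reference) and the CCTA positivity call uses the 50%
#' threshold.
#'
#' @param tree a \linkS4class{CenterlineTree}.
#' @param minPoints branches with fewer centerline points are skipped
#'   with a warning (default 10).
#' @param shoulderWindow number of points in each shoulder window.
#' @param minDs lesions narrower than this percent diameter stenosis are
#'   discarded as centerline-noise dips (default 10).
#' @return data.frame with one row per lesion: branch, start, end (arc
#'   length mm), mld (minimal lumen diameter mm), reference (mm),
#'   ds_percent, ccta_positive.
#' @export
quantifyStenosis <- function(tree, minPoints = 10L, shoulderWindow = 10L,
                             minDs = 10) {
  out <- list()
  for (b in seq_along(tree@branches)) {
    br <- tree@branches[[b]]
    if (nrow(br) < minPoints) {
      warning(sprintf("branch %d shorter than the lesion-detection window; skipped", b))
      next
    }
    D <- 2 * br$radius
    n <- length(D)
    k <- min(shoulderWindow, max(3L, n %/% 5))
    refProx <- quantile(D[seq_len(k)], 0.9, names = FALSE)
    refDist <- quantile(D[(n - k + 1):n], 0.9, names = FALSE)
    ref0 <- approx(c(br$arclen[ (k+1)/2 ], br$arclen[n - (k-1)/2]),
                   c(refProx, refDist), xout = br$arclen, rule = 2)$y
    low <- D < 0.9 * ref0
    if (!any(low)) next
    runs <- rle(low)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (ri in which(runs$values)) {
      i0 <- starts[ri]; i1 <- ends[ri]
      pw <- max(1L, i0 - k):max(1L, i0 - 1L)
      dw <- min(n, i1 + 1L):min(n, i1 + k)
      shoulders <- c(quantile(D[pw], 0.9, names = FALSE),
                     quantile(D[dw], 0.9, names = FALSE))
      sPos <- c(mean(br$arclen[pw]), mean(br$arclen[dw]))
      imin <- i0 + which.min(D[i0:i1]) - 1L
      refAt <- approx(sPos, shoulders, xout = br$arclen[imin], rule = 2)$y
      mld <- min(D[i0:i1], refAt)
      ds <- 100 * (1 - mld / refAt)
      if (ds < minDs) next
      out[[length(out) + 1]] <- data.frame(
        branch = b, start = br$arclen[i0], end = br$arclen[i1],
        mld = mld, reference = refAt, ds_percent = ds,
        ccta_positive = ds >= 50)
    }
  }
  if (length(out) == 0)
    return(data.frame(branch = integer(), start = numeric(), end = numeric(),
                      mld = numeric(), reference = numeric(),
                      ds_percent = numeric(), ccta_positive = logical()))
  do.call(rbind, out)
}

# Concatenated (arclen, radius) profile along a root-to-leaf branch path.
pathProfile <- function(tree, path) {
  s0 <- 0
  segs <- list()
  for (b in path) {
    br <- tree@branches[[b]]
    segs[[length(segs) + 1]] <- data.frame(arclen = s0 + br$arclen,
                                           radius = br$radius)
    s0 <- s0 + max(br$arclen)
  }
  pr <- do.call(rbind, segs)
  pr[!duplicated(pr$arclen), , drop = FALSE]
}

# Default root-to-leaf path: follow the largest-radius child.
defaultPath <- function(tree) {
  path <- tree@root
  repeat {
    kids <- tree@topology$branch[!is.na(tree@topology$parent) &
                                 tree@topology$parent == path[length(path)]]
    if (length(kids) == 0) break
    r0 <- vapply(kids, function(k) tree@branches[[k]]$radius[1], 0)
    path <- c(path, kids[which.max(r0)])
  }
  path
}

#' Build the axisymmetric finite-volume mesh for a vessel path
#'
#' Structured cells in (axial z, radial r) along a root-to-leaf path of
#' the centerline tree.  The axial grid is uniform with spacing <= hMax;
#' global radial faces are spaced at most hMax (optionally graded toward
#' the wall) and each axial column is capped by a partial cell ending
#' exactly at the local wall radius R(z), so the meridional cell area sums
#' to the analytic integral of R(z) dz.
#'
#' @param tree a \linkS4class{CenterlineTree} (or NULL when \code{profile}
#'   is given).
#' @param path branch ids from root to leaf; default follows the
#'   largest-radius child.
#' @param hMax mesh size cap, mm (default 0.3, the precision/cost balance
#'   for coronary work).
#' @param grading wall-ward grading ratio of radial face spacing (1 =
#'   uniform); spacing still never exceeds hMax.
#' @param profile optional data.frame(arclen, radius) overriding the tree.
#' @return an \linkS4class{AxiMesh}.
#' @export
buildAxiMesh <- function(tree = NULL, path = NULL, hMax = 0.3, grading = 1,
                         profile = NULL) {
  if (hMax <= 0) stop("hMax must be > 0")
  if (is.null(profile)) {
    if (is.null(path)) path <- defaultPath(tree)
    profile <- pathProfile(tree, path)
  }
  if (any(profile$radius <= 0)) stop("radius profile must be positive")
  L <- max(profile$arclen)
  nz <- max(2L, ceiling(L / hMax))
  zFaces <- seq(0, L, length.out = nz + 1)
  rAtFace <- approx(profile$arclen, profile$radius, xout = zFaces, rule = 2)$y
  wall <- (rAtFace[-1] + rAtFace[-(nz + 1)]) / 2
  rmax <- max(wall)
  # radial faces: widths <= hMax / 1.5 so a merged partial top cell stays
  # under hMax; optional geometric grading, finer toward the wall
  base <- hMax / 1.5
  nr <- max(3L, ceiling(rmax / base))
  if (grading == 1) {
    rFaces <- seq(0, rmax, length.out = nr + 1)
  } else {
    w <- grading^(-(seq_len(nr) - 1))        # widths shrink toward the wall
    w <- w / sum(w) * rmax
    while (max(w) > base) {
      nr <- nr + 1L
      w <- grading^(-(seq_len(nr) - 1)); w <- w / sum(w) * rmax
    }
    rFaces <- c(0, cumsum(w))
  }
  dr <- diff(rFaces)
  # active cells per column: last global face strictly below the wall,
  # merging slivers thinner than 30% of the local spacing into the cell
  # below
  wallFace <- vapply(wall, function(R) {
    m <- findInterval(R - 1e-12, rFaces)      # rFaces[m] <= R
    m <- min(m, as.integer(nr))
    if (m > 1 && (R - rFaces[m]) < 0.3 * dr[m - 1]) m <- m - 1L
    max(as.integer(m), 2L)
  }, 1L)
  new("AxiMesh", zFaces = zFaces, rFaces = rFaces, wall = wall,
      wallFace = as.integer(wallFace), radius = rAtFace, hMax = hMax)
}

#' Total active cell count of an AxiMesh
#' @param mesh an \linkS4class{AxiMesh}.
#' @export
cellCount <- function(mesh) sum(mesh@wallFace)

#' Meridional area of the mesh (sum over active cells, mm^2)
#' @param mesh an \linkS4class{AxiMesh}.
#' @export
meshMeridionalArea <- function(mesh) {
  dz <- diff(mesh@zFaces)
  sum(dz * mesh@wall)   # columns end exactly at the wall radius
}

#' Build a reduced-order 1-D network from a centerline tree
#'
#' Each branch is chopped into elements of length at most dx; junction
#' nodes are shared between parent and daughters, and every leaf end is
#' tagged as an outlet carrying its local diameter for the Murray-law
#' flow split.
#'
#' @param tree a \linkS4class{CenterlineTree}.
#' @param dx maximum element length, mm.
#' @return a \linkS4class{Network1D}.
#' @export
buildNetwork <- function(tree, dx = 1) {
  if (dx <= 0) stop("dx must be > 0")
  nodes <- list(); elements <- list()
  nodeId <- 0L
  branchStartNode <- integer(length(tree@branches))
  branchEndNode <- integer(length(tree@branches))
  topo <- tree@topology
  order <- topoOrder(topo, tree@root)
  for (b in order) {
    br <- tree@branches[[b]]
    L <- max(br$arclen)
    ne <- max(1L, ceiling(L / dx - 1e-9))
    sNodes <- seq(0, L, length.out = ne + 1)
    rNodes <- approx(br$arclen, br$radius, xout = sNodes, rule = 2)$y
    xyz <- cbind(approx(br$arclen, br$x, xout = sNodes, rule = 2)$y,
                 approx(br$arclen, br$y, xout = sNodes, rule = 2)$y,
                 approx(br$arclen, br$z, xout = sNodes, rule = 2)$y)
    parent <- topo$parent[topo$branch == b]
    ids <- integer(ne + 1)
    for (i in seq_len(ne + 1)) {
      if (i == 1 && !is.na(parent)) {
        ids[i] <- branchEndNode[parent]      # shared junction node
      } else {
        nodeId <- nodeId + 1L
        ids[i] <- nodeId
        nodes[[nodeId]] <- data.frame(id = nodeId, x = xyz[i, 1],
                                      y = xyz[i, 2], z = xyz[i, 3],
                                      radius = rNodes[i])
      }
    }
    for (i in seq_len(ne)) {
      # minimum radius within the element from the original samples
      inEl <- br$radius[br$arclen >= sNodes[i] - 1e-9 & br$arclen <= sNodes[i + 1] + 1e-9]
      elements[[length(elements) + 1]] <- data.frame(
        node0 = ids[i], node1 = ids[i + 1],
        length = sNodes[i + 1] - sNodes[i],
        r0 = rNodes[i], r1 = rNodes[i + 1],
        rmin = min(c(rNodes[i], rNodes[i + 1], inEl)), branch = b)
    }
    branchStartNode[b] <- ids[1]
    branchEndNode[b] <- ids[ne + 1]
  }
  leaves <- setdiff(topo$branch, topo$parent[!is.na(topo$parent)])
  outlets <- data.frame(node = branchEndNode[leaves],
                        diameter = vapply(leaves, function(b) {
                          br <- tree@branches[[b]]
                          2 * br$radius[nrow(br)]
                        }, 0))
  new("Network1D", nodes = do.call(rbind, nodes),
      elements = do.call(rbind, elements),
      inlet = branchStartNode[tree@root], outlets = outlets)
}

# branches ordered parent-before-child
topoOrder <- function(topo, root) {
  out <- root
  repeat {
    kids <- topo$branch[!is.na(topo$parent) & topo$parent %in% out &
                        !(topo$branch %in% out)]
    if (length(kids) == 0) break
    out <- c(out, kids)
  }
  out
}
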
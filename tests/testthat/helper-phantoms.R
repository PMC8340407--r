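# Shared fixtures, built in code at test time.

# cosine-tapered stenosis radius profile of a straight vessel
stenosisProfile <- function(severity, R = 1.5, L = 30, center = 15,
                            lesionLength = 8, n = 301) {
  s <- seq(0, L, length.out = n)
  r <- rep(R, n)
  x <- s - center
  inl <- abs(x) <= lesionLength / 2
  r[inl] <- R * (1 - severity * cos(pi * x[inl] / lesionLength)^2)
  data.frame(arclen = s, radius = r)
}

# single-branch CenterlineTree from an (arclen, radius) profile
profileTree <- function(profile) {
  br <- data.frame(x = 0, y = 0, z = profile$arclen,
                   radius = profile$radius, arclen = profile$arclen)
  new("CenterlineTree", branches = list(br),
      topology = data.frame(branch = 1L, parent = NA_integer_, attach = 0),
      root = 1L)
}

# boundary conditions carrying a prescribed total hyperemic flow (mL/s)
bcWithFlow <- function(qHyp, outletDiameters = 3, ...) {
  boundaryConditions(qRest = qHyp / 3, hyperemiaFactor = 3,
                     outletDiameters = outletDiameters, ...)
}

# analytic signed-distance sphere field
sphereField <- function(r = 10, sp = 0.5, pad = 2) {
  ax <- seq(-(r + pad), r + pad, by = sp)
  n <- length(ax)
  X <- array(ax, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  list(phi = sqrt(X^2 + Y^2 + Z^2) - r, spacing = rep(sp, 3),
       origin = rep(-(r + pad), 3))
}

# brute-force pairwise Mann-Whitney AUC with half-credit ties
# (low score = positive class)
mannWhitneyAUC <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  (sum(outer(pos, neg, "<")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}
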
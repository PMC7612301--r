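# Stimulation depth: distance of the anode-cathode midpoint from the brain
# surface, signed negative when the midpoint falls outside the surface's
# convex hull. The inside/outside test minimises the distance from the
# midpoint to the convex hull of the surface point set with a pairwise
# Frank-Wolfe solver (linearly convergent; exact enough at mm scale).

# squared distance from point p to conv(rows of V)
hull_sqdist <- function(p, V, max_iter = 4000L, tol = 1e-10) {
  nv <- nrow(V)
  d2 <- colSums((t(V) - p)^2)
  w <- numeric(nv)
  i0 <- which.min(d2)
  w[i0] <- 1
  x <- V[i0, ]
  scale2 <- max(d2, 1)
  for (it in seq_len(max_iter)) {
    g <- x - p
    scores <- as.numeric(V %*% g)
    s <- which.min(scores)                  # toward vertex
    active <- which(w > 1e-15)
    a <- active[which.max(scores[active])]  # away vertex
    gap <- sum((x - V[s, ]) * g)
    if (gap < tol * scale2) break
    dirv <- V[s, ] - V[a, ]
    denom <- sum(dirv^2)
    if (denom <= 0) break
    gam <- min(max(-sum(dirv * g) / denom, 0), w[a])
    if (gam <= 0) break
    w[s] <- w[s] + gam
    w[a] <- w[a] - gam
    x <- x + gam * dirv
  }
  sum((x - p)^2)
}

#' Stimulation depth relative to the brain surface
#'
#' The depth of a stimulation site is the minimum Euclidean distance from
#' the anode-cathode midpoint to the brain-surface point set; the sign is
#' negative when the midpoint lies outside the convex hull of the surface
#' points (i.e. outside the brain).
#'
#' @param anode_xyz,cathode_xyz Length-3 electrode coordinates (mm).
#' @param surface_points m x 3 matrix of surface points (mm), at least 4
#'   and not all coplanar.
#' @param tol Distance (mm) below which the midpoint counts as inside the
#'   hull.
#' @return Signed depth in mm.
#' @examples
#' sphere <- 50 * stimconsist:::random_directions(400)
#' stimulation_depth(c(0, 0, 0), c(0, 0, 0), sphere)   # ~ +50
#' @export
stimulation_depth <- function(anode_xyz, cathode_xyz, surface_points,
                              tol = 1e-3) {
  surface_points <- as.matrix(surface_points)
  if (nrow(surface_points) < 4L) stopf("degenerate surface: need >= 4 points")
  centred <- sweep(surface_points, 2L, colMeans(surface_points))
  if (qr(centred)$rank < 3L) stopf("degenerate surface: points are coplanar")
  mid <- (as.numeric(anode_xyz) + as.numeric(cathode_xyz)) / 2
  dmin <- sqrt(min(colSums((t(surface_points) - mid)^2)))
  outside <- sqrt(hull_sqdist(mid, surface_points)) > tol
  if (outside) -dmin else dmin
}
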
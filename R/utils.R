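# Internal geometry and RNG helpers shared across modules.

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Tight 0-based half-open bbox (row0, col0, row1, col1) of a logical mask.
maskBBox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box", call. = FALSE)
  as.integer(c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
               max(idx[, 1]), max(idx[, 2])))
}

maskIoU <- function(a, b) {
  inter <- sum(a & b)
  if (inter == 0L) return(0)
  inter / sum(a | b)
}

# Pixel-centre coordinates (x = col - 0.5, y = row - 0.5) of mask pixels.
maskPoints <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2] - 0.5, y = idx[, 1] - 0.5)
}

# Minimum-area rotated rectangle of a point set by rotating calipers over
# the convex hull. Returns extents of the point set along the rectangle
# sides (no pixel-footprint correction) and the angle of the long side.
minAreaRect <- function(pts) {
  if (nrow(pts) == 0L) stop("no points", call. = FALSE)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n == 1L) return(list(major = 0, minor = 0, angleDeg = 0))
  if (n == 2L) {
    d <- hp[2, ] - hp[1, ]
    return(list(major = sqrt(sum(d^2)), minor = 0,
                angleDeg = (atan2(d["y"], d["x"]) * 180 / pi) %% 180))
  }
  cand <- vector("list", n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len                      # edge direction
    v <- c(-u[2], u[1])               # normal
    p1 <- hp %*% u
    p2 <- hp %*% v
    e1 <- max(p1) - min(p1)
    e2 <- max(p2) - min(p2)
    ang <- if (e1 >= e2) atan2(u[2], u[1]) else atan2(v[2], v[1])
    cand[[i]] <- list(area = e1 * e2, major = max(e1, e2),
                      minor = min(e1, e2),
                      angleDeg = (ang * 180 / pi) %% 180)
  }
  cand <- Filter(Negate(is.null), cand)
  areas <- vapply(cand, `[[`, numeric(1), "area")
  # Among rectangles within 0.5% of the minimal area, prefer the most
  # elongated: pixel discretization perturbs hull edges enough that the
  # strict minimizer can tilt off a symmetric body's axis, padding the
  # minor extent by a pixel while shaving the major.
  near <- which(areas <= min(areas) * 1.005)
  minors <- vapply(cand[near], `[[`, numeric(1), "minor")
  best <- cand[[near[which.min(minors)]]]
  best[c("major", "minor", "angleDeg")]
}

# Convex-hull perimeter of the mask pixel centres, corrected by pi for the
# half-pixel footprint (dilating a convex hull by r adds 2*pi*r).
maskHullPerimeter <- function(mask) {
  pts <- maskPoints(mask)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 2L) return(pi)
  d <- hp[c(seq(2, n), 1L), , drop = FALSE] - hp
  sum(sqrt(rowSums(d^2))) + pi
}

# Circularity (4*pi*A/P^2) and elongation (major/minor of the min-area
# rectangle, with +1 px footprint correction per side) of a mask.
maskShapeScores <- function(mask) {
  a <- sum(mask)
  pts <- maskPoints(mask)
  p <- maskHullPerimeter(mask)
  r <- minAreaRect(pts)
  major <- r$major + 1
  minor <- r$minor + 1
  list(area = a,
       circularity = 4 * pi * a / p^2,
       elongation = major / minor,
       majorPx = major, minorPx = minor,
       angleDeg = r$angleDeg)
}

# Expected extent deficit of grid-sampled pixel centres against the true
# support of a smooth convex boundary. Near a support point with curvature
# radius R the region within depth d of the tangent holds ~ (2/3)sqrt(8R)
# d^(3/2) pixel centres; the depth at which the first centre is expected is
# d* = (1.5 / sqrt(8R))^(2/3) per side, capped at the half-pixel average
# that applies when the tangent is grid-aligned. Curvature radii at the
# rectangle's side and tip are estimated from the rectangle itself as for
# an ellipse (a^2/b and b^2/a).
extentCorrections <- function(majorPx, minorPx) {
  a <- max(majorPx, 1e-6) / 2
  b <- max(minorPx, 1e-6) / 2
  dstar <- function(R) min(0.5, (1.5 / sqrt(8 * R))^(2 / 3))
  c(major = 2 * dstar(b^2 / a), minor = 2 * dstar(a^2 / b))
}

maskTouchesBorder <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Condition constructors: calibration failure and skipped measurements are
# typed so callers (pipeline, CLI) can react to them specifically.
calibrationError <- function(message) {
  stop(structure(class = c("calibrationError", "error", "condition"),
                 list(message = message, call = NULL)))
}

measurementSkipped <- function(message) {
  stop(structure(class = c("measurementSkipped", "error", "condition"),
                 list(message = message, call = NULL)))
}

degenerateMaskError <- function(message) {
  stop(structure(class = c("degenerateMask", "error", "condition"),
                 list(message = message, call = NULL)))
}
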
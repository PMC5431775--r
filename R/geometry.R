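#' Sample points uniformly (by area) on a disk
#'
#' Draws `n` points with uniform areal density on the disk of radius `R`
#' centred at the origin, by inverse-CDF sampling of the radial coordinate
#' (`r = R * sqrt(u)` with `u` uniform) followed by a uniform angle. Two
#' uniform deviates are consumed per point, radius first, so a fixed seed
#' reproduces the same sequence exactly.
#'
#' @param n number of points to draw.
#' @param R disk radius (must be positive unless `n == 0`).
#' @return an `n x 2` numeric matrix with columns `x` and `y`.
#' @examples
#' set.seed(1)
#' p <- sample_uniform_disk(1000, R = 50)
#' mean(sqrt(rowSums(p^2)))  # close to 2R/3
#' @export
sample_uniform_disk <- function(n, R) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("'n' must be a single non-negative integer")
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("'R' must be a single positive number")
  if (n == 0L)
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("x", "y"))))
  r <- R * sqrt(stats::runif(n))
  th <- 2 * pi * stats::runif(n)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Area of intersection of an offset T-disk with the R-disk
#'
#' Computes the area of the intersection of a disk of radius `T` centred at
#' radial distance `r` from the origin with the disk of radius `R` centred at
#' the origin. Three regimes apply:
#' \itemize{
#'   \item full containment of the T-disk, `r <= R - T`: area is `pi * T^2`;
#'   \item full containment of the R-disk, `T >= r + R`: area is `pi * R^2`;
#'   \item partial overlap otherwise: the circular-lens formula
#'     `alpha R^2 + gamma T^2 - 2 sqrt(s (s - R) (s - T) (s - r))`, where
#'     `alpha` and `gamma` are the half-angles subtended at the two centres
#'     and `s = (R + T + r) / 2` is the semiperimeter of the centre-centre
#'     triangle.
#' }
#' The `acos` arguments are clamped to `[-1, 1]` and the Heron radicand
#' floored at 0 to absorb floating-point overshoot near tangency.
#'
#' @param r distance of the T-disk centre from the origin; vectorized.
#'   Must satisfy `0 <= r <= R`.
#' @param T radius of the offset disk, `>= 0`.
#' @param R radius of the reference disk, `> 0`.
#' @return intersection areas, same length as `r`.
#' @seealso [coverage_fraction()]
#' @export
disk_intersection_area <- function(r, T, R) {
  if (!is.numeric(r) || !is.numeric(T) || !is.numeric(R))
    stop("'r', 'T' and 'R' must be numeric")
  if (length(T) != 1L || length(R) != 1L)
    stop("'T' and 'R' must be scalars")
  if (R <= 0) stop("'R' must be positive")
  if (T < 0) stop("'T' must be non-negative")
  if (any(r < 0)) stop("'r' must be non-negative")
  if (any(r > R + 1e-9 * R)) stop("'r' must not exceed 'R'")
  r <- pmin(r, R)

  area <- numeric(length(r))
  inside <- r <= R - T           # T-disk entirely inside the R-disk
  covers <- T >= r + R           # T-disk covers the whole R-disk
  lens <- !inside & !covers
  area[inside] <- pi * T^2
  area[covers] <- pi * R^2
  if (any(lens)) {
    rl <- r[lens]
    alpha <- acos(pmin(1, pmax(-1, (R^2 + rl^2 - T^2) / (2 * rl * R))))
    gam   <- acos(pmin(1, pmax(-1, (rl^2 + T^2 - R^2) / (2 * rl * T))))
    s <- (R + T + rl) / 2
    heron <- pmax(0, s * (s - R) * (s - T) * (s - rl))
    area[lens] <- alpha * R^2 + gam * T^2 - 2 * sqrt(heron)
  }
  area
}

#' Fraction of the R-disk reachable within radius T from an offset centre
#'
#' The intersection area of [disk_intersection_area()] divided by the area of
#' the R-disk; this is the probability that a point placed uniformly on the
#' R-disk falls within distance `T` of a point at radial distance `r`.
#'
#' @inheritParams disk_intersection_area
#' @return values in `[0, 1]`, same length as `r`.
#' @export
coverage_fraction <- function(r, T, R) {
  p <- disk_intersection_area(r, T, R) / (pi * R^2)
  pmin(1, pmax(0, p))
}

#' Degree-normalized effective distance
#'
#' The attachment rule of the growing model ranks candidate neighbours by
#' their Euclidean distance divided by the square root of their current
#' degree, so that hubs appear closer than their geometric position. The
#' degree is floored at 1: a square-root of zero would make isolated or
#' newborn nodes infinitely attractive (or undefined), whereas the floor
#' leaves raw Euclidean distance for degree-0 and degree-1 candidates.
#'
#' @param p,q points as length-2 numeric vectors `(x, y)`, or matrices with
#'   two columns for vectorized evaluation (recycled against each other).
#' @param degree candidate degree(s) of `q`, non-negative integers.
#' @return effective distances `d_euclidean / sqrt(max(degree, 1))`.
#' @examples
#' effective_distance(c(0, 0), c(10, 0), 4)  # 5
#' @export
effective_distance <- function(p, q, degree) {
  p <- .as_points(p)
  q <- .as_points(q)
  if (any(degree < 0)) stop("'degree' must be non-negative")
  d <- sqrt((p[, 1L] - q[, 1L])^2 + (p[, 2L] - q[, 2L])^2)
  d / sqrt(pmax(degree, 1))
}

# coerce a length-2 vector or 2-column matrix to a 2-column matrix
.as_points <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 2L) stop("point matrices must have exactly 2 columns")
    return(p)
  }
  if (is.numeric(p) && length(p) == 2L) return(matrix(p, ncol = 2L))
  stop("a point must be a length-2 numeric vector or a 2-column matrix")
}
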
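# The search space: a genotype is (translation, quaternion orientation,
# torsion angles). Internally the evolvers operate on the raw real vector
# c(tx, ty, tz, qw, qx, qy, qz, tor_1..tor_T); repair_genotype() keeps such
# vectors valid (clamp to box, renormalise quaternion, wrap torsions).

#' Define the docking search box
#'
#' @param center Numeric length-3, box center (Angstrom).
#' @param half_extent Numeric length-3 (or scalar), strictly positive half
#'   widths of the box along x, y, z.
#' @return An object of class `search_box`.
#' @export
search_box <- function(center = c(0, 0, 0), half_extent = c(10, 10, 10)) {
  center <- as.numeric(center)
  half_extent <- rep_len(as.numeric(half_extent), 3L)
  stopifnot(length(center) == 3L, all(is.finite(center)),
            all(is.finite(half_extent)))
  if (any(half_extent <= 0)) stop("half_extent must be strictly positive")
  structure(list(center = center, half_extent = half_extent),
            class = "search_box")
}

#' Construct a genotype
#'
#' @param translation Length-3 displacement of the ligand's rigid-root
#'   centroid relative to the box center, Angstrom.
#' @param orientation Length-4 quaternion `(w, x, y, z)`; normalised on use.
#' @param torsions `T` torsion angles, radians, wrapped to `(-pi, pi]`.
#' @return An object of class `genotype`.
#' @export
genotype <- function(translation = c(0, 0, 0), orientation = c(1, 0, 0, 0),
                     torsions = numeric(0)) {
  stopifnot(length(translation) == 3L, length(orientation) == 4L)
  structure(list(translation = as.numeric(translation),
                 orientation = as.numeric(orientation),
                 torsions = as.numeric(torsions)),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype> translation", sprintf("%.3f", x$translation),
      "| quaternion", sprintf("%.3f", x$orientation))
  if (length(x$torsions)) {
    cat(" |", length(x$torsions), "torsions (deg):",
        sprintf("%.1f", x$torsions * 180 / pi))
  }
  cat("\n")
  invisible(x)
}

genotype_to_vec <- function(g) c(g$translation, g$orientation, g$torsions)

vec_to_genotype <- function(v) {
  genotype(v[1:3], v[4:7], if (length(v) > 7L) v[-(1:7)] else numeric(0))
}

as_gvec <- function(g, n_torsions) {
  v <- if (inherits(g, "genotype")) genotype_to_vec(g) else as.numeric(g)
  if (length(v) != 7L + n_torsions) {
    stop("genotype has ", length(v) - 7L, " torsions, ligand needs ",
         n_torsions)
  }
  v
}

#' Normalise a genotype's orientation quaternion
#'
#' @param g A `genotype`.
#' @return The genotype with a unit-norm quaternion, direction preserved.
#' @export
normalize_orientation <- function(g) {
  n <- sqrt(sum(g$orientation^2))
  if (n == 0 || !is.finite(n)) stop("degenerate orientation: zero quaternion")
  g$orientation <- g$orientation / n
  g
}

# raw-vector repair: clamp translation, renormalise quaternion, wrap torsions
repair_vec <- function(v, half_extent, n_torsions) {
  v[1:3] <- clamp(v[1:3], -half_extent, half_extent)
  q <- v[4:7]
  n <- sqrt(sum(q * q))
  v[4:7] <- if (n > 1e-12) q / n else c(1, 0, 0, 0)
  if (n_torsions > 0L) {
    k <- 7L + seq_len(n_torsions)
    v[k] <- wrap_angle(v[k])
  }
  v
}

#' Repair a genotype after evolutionary arithmetic
#'
#' Evolver arithmetic on raw gene vectors can leave the box or denormalise
#' the quaternion; this clamps the translation componentwise to the box,
#' renormalises the quaternion and wraps torsions into `(-pi, pi]` (boundary
#' mapped to `+pi`). Idempotent.
#'
#' @param g A `genotype` (or raw gene vector).
#' @param box A [search_box()].
#' @return A valid `genotype`.
#' @export
repair_genotype <- function(g, box) {
  nt <- if (inherits(g, "genotype")) length(g$torsions) else length(g) - 7L
  v <- repair_vec(as_gvec(g, nt), box$half_extent, nt)
  vec_to_genotype(v)
}

# random gene vector: uniform translation in the box, uniform orientation on
# the unit 3-sphere (4 normal deviates, normalised), uniform torsions
random_gvec <- function(n_torsions, half_extent) {
  q <- rnorm(4)
  n <- sqrt(sum(q * q))
  while (n < 1e-8) {
    q <- rnorm(4)
    n <- sqrt(sum(q * q))
  }
  c(runif(3, -half_extent, half_extent), q / n,
    if (n_torsions > 0L) runif(n_torsions, -pi, pi) else numeric(0))
}

#' Draw a uniform random genotype
#'
#' Translation uniform within the box, orientation uniform on the unit
#' 3-sphere, torsions uniform in `(-pi, pi]`. Uses R's global RNG stream.
#'
#' @param ligand A `ligand` (or an integer torsion count).
#' @param box A [search_box()].
#' @return A `genotype`.
#' @export
random_genotype <- function(ligand, box) {
  nt <- if (inherits(ligand, "ligand")) ligand$n_torsions else as.integer(ligand)
  vec_to_genotype(random_gvec(nt, box$half_extent))
}

# rotation matrix of a unit quaternion (w, x, y, z)
quat_rotation_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)),
         nrow = 3, byrow = TRUE)
}

# Rodrigues rotation of points about the axis through `a` along unit `u`
# (column arithmetic; this sits on the pose-building hot path)
rotate_about_axis <- function(pts, a, u, theta) {
  px <- pts[, 1] - a[1]; py <- pts[, 2] - a[2]; pz <- pts[, 3] - a[3]
  ct <- cos(theta); st <- sin(theta)
  dotc <- (px * u[1] + py * u[2] + pz * u[3]) * (1 - ct)
  cbind(a[1] + px * ct + (u[2] * pz - u[3] * py) * st + dotc * u[1],
        a[2] + py * ct + (u[3] * px - u[1] * pz) * st + dotc * u[2],
        a[3] + pz * ct + (u[1] * py - u[2] * px) * st + dotc * u[3],
        deparse.level = 0)
}
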
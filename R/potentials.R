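#' Force-field constants (reduced units)
#'
#' All interaction constants of the model, in reduced units: the monomer
#' diameter sigma is the unit of length, the physiological thermal energy
#' k_B*T_eq the unit of energy, and the drag coefficient the unit of
#' friction.
#'
#' Defaults are chosen for numerical stability of the explicit Euler update
#' at the standard time step dt = 0.01 tau: a spring of constant k relaxes
#' stably only if `dt * 2k / zeta < 2`, which bounds the loop springs
#' (`loop_k_multiplier * k_bond`) and hence the backbone constant.
#'
#' @param k_bond backbone spring constant (energy/length^2); default 5, the
#'   entropic-spring scale (~3-5 thermal energies per sigma^2) of a 1 Mb
#'   domain.
#' @param r0 bond rest length (the equilibrium domain separation).
#' @param V0 Gaussian-core amplitude: the inter-monomer pair energy at zero
#'   separation, of order the thermal energy.
#' @param sigma Gaussian-core width, equal to the monomer diameter.
#' @param k_wall confinement stiffness (energy/length^2): harmonic in the
#'   outside distance to the nuclear boundary.
#' @param loop_k_multiplier loop springs are this factor stiffer than
#'   backbone springs (default 10).
#' @param eps_ne depth of the selective nuclear-envelope attraction felt by
#'   active monomers (energy).
#' @param lambda_ne range of the NE attraction (length).
#' @param r_cut pair-interaction cutoff (>= 3 sigma).
#' @return A `force_field` list.
#' @export
force_field <- function(k_bond = 5, r0 = 1, V0 = 2, sigma = 1,
                        k_wall = 50, loop_k_multiplier = 10,
                        eps_ne = 50, lambda_ne = 1, r_cut = 3) {
  ff <- list(k_bond = k_bond, r0 = r0, V0 = V0, sigma = sigma,
             k_wall = k_wall, loop_k_multiplier = loop_k_multiplier,
             eps_ne = eps_ne, lambda_ne = lambda_ne, r_cut = r_cut)
  if (any(unlist(ff) <= 0)) stop("all force-field constants must be positive")
  if (loop_k_multiplier < 1) stop("loop_k_multiplier must be >= 1")
  if (r_cut < 3 * sigma) stop("r_cut must be >= 3*sigma")
  class(ff) <- "force_field"
  ff
}

#' @export
print.force_field <- function(x, ...) {
  cat("Force field (reduced units):\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Semi-axes of a volume-preserving ellipsoid of revolution
#'
#' Returns semi-axes (a, b, c) with a = b and c = aspect * a, scaled so the
#' ellipsoid volume equals that of the sphere of radius `R0`
#' (a^2 c = R0^3). `aspect > 1` gives a prolate, `aspect < 1` an oblate
#' spheroid.
#'
#' @param aspect ratio c/a of the distinct to the repeated semi-axis.
#' @param R0 radius of the reference sphere.
#' @return Numeric vector `c(a, b, c)`.
#' @export
ellipsoid_axes <- function(aspect, R0) {
  if (aspect <= 0) stop("aspect must be positive")
  a <- R0 * aspect^(-1 / 3)
  c(a = a, b = a, c = aspect * a)
}

#' Confinement geometry
#'
#' Construct the nuclear confinement: a sphere of radius `R0`, or a
#' volume-matched ellipsoid of revolution given either its `aspect` ratio
#' (see [ellipsoid_axes()]) or explicit semi-axes with two equal axes.
#'
#' @param kind "sphere" or "ellipsoid".
#' @param R0 sphere radius (and volume reference for ellipsoids).
#' @param aspect ellipsoid aspect ratio c/a (ignored for spheres).
#' @param axes optional explicit semi-axes (a, b, c) with a == b; overrides
#'   `aspect`, and `R0` is then derived from the volume.
#' @return A `geometry` list with fields `kind`, `R0`, `axes`.
#' @export
geometry <- function(kind = c("sphere", "ellipsoid"), R0 = 10, aspect = 1,
                     axes = NULL) {
  kind <- match.arg(kind)
  if (kind == "sphere") {
    if (R0 <= 0) stop("R0 must be positive")
    g <- list(kind = "sphere", R0 = R0, axes = c(a = R0, b = R0, c = R0))
  } else {
    if (is.null(axes)) {
      axes <- ellipsoid_axes(aspect, R0)
    } else {
      if (length(axes) != 3 || any(axes <= 0)) stop("axes must be 3 positive numbers")
      if (abs(axes[1] - axes[2]) > 1e-12 * axes[1]) {
        stop("only ellipsoids of revolution (a == b) are supported")
      }
      names(axes) <- c("a", "b", "c")
      R0 <- prod(axes)^(1 / 3)
    }
    g <- list(kind = "ellipsoid", R0 = R0, axes = axes)
  }
  class(g) <- "geometry"
  g
}

#' @export
print.geometry <- function(x, ...) {
  if (x$kind == "sphere") {
    cat(sprintf("Spherical confinement, R0 = %g\n", x$R0))
  } else {
    cat(sprintf("Ellipsoidal confinement, semi-axes (%g, %g, %g), volume-equivalent R0 = %g\n",
                x$axes[1], x$axes[2], x$axes[3], x$R0))
  }
  invisible(x)
}

# Nearest point on the quarter ellipse x^2/A^2 + y^2/C^2 = 1 (A, C > 0) to
# the query (u, v) with u, v >= 0. Returns c(xu, xv). Robust for interior,
# exterior and on-axis queries, including the degenerate near-axis cases
# where the nearest point leaves the axis.
ellipse_nearest_point <- function(u, v, A, C, tol = 1e-13) {
  eps <- 1e-14 * max(A, C)
  if (u < eps && v < eps) {           # centre: nearest point on shortest axis
    return(if (A <= C) c(A, 0) else c(0, C))
  }
  if (u < eps) {                      # on the v-axis
    best <- c(0, C); bd <- abs(v - C)
    if (C > A && v < (C^2 - A^2) / C) {
      xv <- C^2 * v / (C^2 - A^2)
      xu <- A * sqrt(max(0, 1 - (xv / C)^2))
      d <- sqrt(xu^2 + (v - xv)^2)
      if (d < bd) best <- c(xu, xv)
    }
    return(best)
  }
  if (v < eps) {                      # on the u-axis
    best <- c(A, 0); bd <- abs(u - A)
    if (A > C && u < (A^2 - C^2) / A) {
      xu <- A^2 * u / (A^2 - C^2)
      xv <- C * sqrt(max(0, 1 - (xu / A)^2))
      d <- sqrt((u - xu)^2 + xv^2)
      if (d < bd) best <- c(xu, xv)
    }
    return(best)
  }
  # general case: root of G(t) = (Au/(A^2+t))^2 + (Cv/(C^2+t))^2 - 1 on
  # t in (-min(A,C)^2, inf); G is strictly decreasing there.
  g <- function(t) (A * u / (A^2 + t))^2 + (C * v / (C^2 + t))^2 - 1
  lo <- -min(A, C)^2
  lo <- lo + 1e-300 + abs(lo) * 1e-15
  while (g(lo) <= 0) lo <- lo - (lo + min(A, C)^2)  # nudge (paranoia)
  hi <- max(A, C) * sqrt(u^2 + v^2) + max(A, C)^2
  while (g(hi) > 0) hi <- 2 * hi + 1
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, abs(hi))) break
  }
  t <- 0.5 * (lo + hi)
  c(A^2 * u / (A^2 + t), C^2 * v / (C^2 + t))
}

# Signed surface distance plus nearest surface point for an n x 3 matrix of
# query points. Negative inside.
surface_query <- function(points, geom) {
  points <- as_points(points)
  if (geom$kind == "sphere") {
    r <- sqrt(rowSums(points^2))
    d <- r - geom$R0
    scale <- ifelse(r > 0, geom$R0 / r, 0)
    nearest <- points * scale
    nearest[r == 0, ] <- rep(c(geom$R0, 0, 0), each = sum(r == 0))
    return(list(distance = d, nearest = nearest))
  }
  A <- geom$axes[[1]]; C <- geom$axes[[3]]
  u <- sqrt(points[, 1]^2 + points[, 2]^2)
  v <- abs(points[, 3])
  inside <- (u / A)^2 + (v / C)^2 < 1
  near <- t(vapply(seq_along(u), function(i) {
    ellipse_nearest_point(u[i], v[i], A, C)
  }, numeric(2)))
  d <- sqrt((u - near[, 1])^2 + (v - near[, 2])^2)
  d[inside] <- -d[inside]
  cosx <- ifelse(u > 0, points[, 1] / u, 1)
  sinx <- ifelse(u > 0, points[, 2] / u, 0)
  nearest <- cbind(near[, 1] * cosx, near[, 1] * sinx,
                   sign(points[, 3] + (points[, 3] == 0)) * near[, 2])
  list(distance = d, nearest = nearest)
}

#' Signed distance to the confining surface
#'
#' Euclidean distance from each point to the nearest point on the bounding
#' surface, negative inside the geometry. For spheres this is `|r| - R0`
#' exactly; for ellipsoids the nearest surface point is found by a bisection
#' solve of the ellipse nearest-point equation, converged well below 1e-10.
#' By construction, points at equal surface distance experience equal
#' confinement energy ("equipotential at equal surface distance").
#'
#' @param points a length-3 vector or an n x 3 matrix of coordinates.
#' @param geom a `geometry`.
#' @return Numeric vector of signed distances.
#' @export
surface_distance <- function(points, geom) {
  surface_query(points, geom)$distance
}

#' Bond (backbone spring) energy and force
#'
#' Harmonic spring between neighbouring monomers along a chain:
#' `E(d) = k/2 (d - r0)^2`. The scalar force is `-dE/dd`; positive values
#' push the pair apart, negative pull it together, always restoring the rest
#' length.
#'
#' @param d separation distance (>= 0).
#' @param ff a `force_field`.
#' @param k spring constant override (used for loop springs).
#' @return Energy (or scalar radial force), vectorized over `d`.
#' @export
bond_energy <- function(d, ff, k = ff$k_bond) {
  0.5 * k * (d - ff$r0)^2
}

#' @rdname bond_energy
#' @export
bond_force <- function(d, ff, k = ff$k_bond) {
  -k * (d - ff$r0)
}

#' Gaussian-core pair energy and force
#'
#' Soft repulsion between any two monomers,
#' `U(d) = V0 exp(-d^2 / (2 sigma^2))`, truncated at `r_cut`. With
#' `shifted = TRUE` the truncated tail value is subtracted so the energy is
#' continuous at the cutoff (the form used inside the integrator); the force
#' is unaffected by the shift.
#'
#' @param d separation distance.
#' @param ff a `force_field`.
#' @param shifted subtract the cutoff energy inside the cutoff?
#' @return Energy (or scalar radial force, positive = repulsive),
#'   vectorized over `d`.
#' @export
gaussian_core_energy <- function(d, ff, shifted = FALSE) {
  e <- ff$V0 * exp(-d^2 / (2 * ff$sigma^2))
  if (shifted) e <- e - ff$V0 * exp(-ff$r_cut^2 / (2 * ff$sigma^2))
  ifelse(d <= ff$r_cut, e, 0)
}

#' @rdname gaussian_core_energy
#' @export
gaussian_core_force <- function(d, ff) {
  ifelse(d <= ff$r_cut,
         ff$V0 * d / ff$sigma^2 * exp(-d^2 / (2 * ff$sigma^2)), 0)
}

#' Confinement (wall) energy and force
#'
#' Zero inside the geometry; harmonic in the outside distance to the
#' bounding surface, `E = k_wall/2 d_out^2`, hence continuous (with
#' continuous force) at the surface.
#'
#' @param points a length-3 vector or n x 3 matrix.
#' @param geom a `geometry`.
#' @param ff a `force_field`.
#' @return `wall_energy`: numeric vector; `wall_force`: n x 3 matrix of
#'   force vectors.
#' @export
wall_energy <- function(points, geom, ff) {
  d <- surface_distance(points, geom)
  ifelse(d > 0, 0.5 * ff$k_wall * d^2, 0)
}

#' @rdname wall_energy
#' @export
wall_force <- function(points, geom, ff) {
  points <- as_points(points)
  q <- surface_query(points, geom)
  f <- matrix(0, nrow(points), 3)
  out <- q$distance > 0
  if (any(out)) {
    # grad(d) = (p - nearest)/d; F = -k_wall * d * grad(d)
    f[out, ] <- -ff$k_wall * (points[out, , drop = FALSE] -
                                q$nearest[out, , drop = FALSE])
  }
  f
}

#' Selective nuclear-envelope interaction
#'
#' Inactive monomers feel only the repulsive confinement. Active monomers
#' additionally feel a short-ranged attraction with its minimum at the
#' nuclear boundary: `E_NE = -eps_ne exp(-d^2 / (2 lambda_ne^2))` with `d`
#' the unsigned distance to the surface.
#'
#' @param points a length-3 vector or n x 3 matrix.
#' @param is_active logical (recycled): does each point belong to an active
#'   monomer?
#' @param geom a `geometry`.
#' @param ff a `force_field`.
#' @return `ne_energy`: numeric vector (confinement + attraction);
#'   `ne_force`: n x 3 matrix.
#' @export
ne_energy <- function(points, is_active, geom, ff) {
  points <- as_points(points)
  is_active <- rep_len(is_active, nrow(points))
  d <- surface_distance(points, geom)
  e <- ifelse(d > 0, 0.5 * ff$k_wall * d^2, 0)
  e - ifelse(is_active, ff$eps_ne * exp(-d^2 / (2 * ff$lambda_ne^2)), 0)
}

#' @rdname ne_energy
#' @export
ne_force <- function(points, is_active, geom, ff) {
  points <- as_points(points)
  is_active <- rep_len(is_active, nrow(points))
  q <- surface_query(points, geom)
  f <- wall_force(points, geom, ff)
  act <- which(is_active)
  for (i in act) {
    s <- q$distance[i]
    if (s == 0) next
    grad_s <- (points[i, ] - q$nearest[i, ]) / s
    # E = -eps exp(-s^2/(2 l^2)); F = -dE/dp = -eps s/l^2 exp(.) grad_s
    f[i, ] <- f[i, ] - ff$eps_ne * s / ff$lambda_ne^2 *
      exp(-s^2 / (2 * ff$lambda_ne^2)) * grad_s
  }
  f
}

#' Total deterministic forces on every monomer
#'
#' Sum of backbone springs, loop springs, Gaussian-core pair repulsion
#' (cell-list accelerated, truncated at `r_cut`), confinement, and -- when
#' `ne_on` -- the selective NE attraction on active monomers. Pairwise terms
#' obey action-reaction exactly.
#'
#' @param positions n x 3 coordinate matrix (or a `sim_state`).
#' @param table the `monomer_table` (row order defines monomer ids).
#' @param loops a `loop_set` (or NULL for none).
#' @param geom a `geometry`.
#' @param ff a `force_field`.
#' @param ne_on enable the selective NE attraction?
#' @param walls set FALSE to disable confinement (isolated-system checks).
#' @return n x 3 matrix of force vectors.
#' @export
total_forces <- function(positions, table, loops = NULL, geom, ff,
                         ne_on = FALSE, walls = TRUE) {
  if (inherits(positions, "sim_state")) positions <- positions$positions
  if (!all(is.finite(positions))) {
    bad <- which(!is.finite(rowSums(positions)))[1]
    stop(sprintf("non-finite coordinate for monomer id %d", bad - 1L))
  }
  bonds <- chain_bonds(table, ff, loops)
  forces_cpp(positions, bonds$i, bonds$j, bonds$k,
             geom_code(geom), geom$R0, geom$axes[[1]], geom$axes[[3]],
             ff_vector(ff), table$activity_class == "active",
             isTRUE(ne_on), isTRUE(walls))
}

# Backbone bonds (consecutive chain_index within each chromosome copy) plus
# loop springs, as 0-based index vectors with per-bond spring constants.
chain_bonds <- function(table, ff, loops = NULL) {
  chain <- paste(table$chrom, table$copy, sep = "\r")
  n <- nrow(table)
  same <- chain[-1] == chain[-n]
  i <- which(same) - 1L           # 0-based id of first bond partner
  j <- i + 1L
  k <- rep(ff$k_bond, length(i))
  if (!is.null(loops) && nrow(loops)) {
    i <- c(i, loops$i)
    j <- c(j, loops$j)
    k <- c(k, loops$k_spring)
  }
  list(i = as.integer(i), j = as.integer(j), k = as.numeric(k))
}

geom_code <- function(geom) if (geom$kind == "sphere") 0L else 1L

#' Total potential energy of a configuration
#'
#' Companion to [total_forces()]: bonds + loop springs + shifted-truncated
#' Gaussian core + confinement (+ NE attraction when enabled).
#'
#' @inheritParams total_forces
#' @return Scalar energy.
#' @export
total_energy <- function(positions, table, loops = NULL, geom, ff,
                         ne_on = FALSE, walls = TRUE) {
  if (inherits(positions, "sim_state")) positions <- positions$positions
  bonds <- chain_bonds(table, ff, loops)
  energy_cpp(positions, bonds$i, bonds$j, bonds$k,
             geom_code(geom), geom$R0, geom$axes[[1]], geom$axes[[3]],
             ff_vector(ff), table$activity_class == "active",
             isTRUE(ne_on), isTRUE(walls))
}

# Coerce a length-3 vector or n x 3 matrix to an unnamed coordinate matrix.
as_points <- function(p) {
  p <- rbind(p)
  dimnames(p) <- NULL
  p
}
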
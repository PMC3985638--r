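# Observables computed from trajectories: radial chromosome distributions
# S(R), shell activity averages, total/gene density profiles, the effective
# radial coordinate in ellipsoids, and the territory index N_c.

# Normalize the (frames, table, geom) triple: accepts an actseg_run, a
# single n x 3 matrix, or an n x 3 x F array.
resolve_frames <- function(x, table = NULL, geom = NULL) {
  if (inherits(x, "actseg_run")) {
    return(list(frames = x$frames, table = x$table, geom = x$geom))
  }
  if (inherits(x, "sim_state")) x <- x$positions
  if (is.matrix(x)) x <- array(x, c(nrow(x), 3, 1))
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[2] == 3,
            !is.null(table), !is.null(geom))
  list(frames = x, table = table, geom = geom)
}

#' Effective radial coordinate
#'
#' For spheres this is the ordinary radius `|r|`. For ellipsoids, points at
#' equal distance from the boundary are mapped to equal effective radius:
#' `r_eff = R0 (1 - d_in / d_in_max)` where `d_in` is the inside depth
#' (unsigned surface distance) and `d_in_max = min(a, c)` its maximum, so
#' `r_eff` runs from 0 at the deepest interior point to `R0` at the surface.
#'
#' @param points length-3 vector or n x 3 matrix (inside the geometry up to
#'   a tolerance of `tol`).
#' @param geom a `geometry`.
#' @param tol allowed overshoot outside the surface (monomer diameters);
#'   points further out are an error, points within it clamp to `R0`.
#' @return Numeric vector of effective radii in `[0, R0]`.
#' @export
effective_radius <- function(points, geom, tol = 1) {
  points <- as_points(points)
  if (geom$kind == "sphere") {
    r <- sqrt(rowSums(points^2))
    if (any(r > geom$R0 + tol)) stop("point(s) far outside the geometry")
    return(pmin(r, geom$R0))
  }
  d <- surface_distance_cpp(points, 1L, geom$R0, geom$axes[[1]],
                            geom$axes[[3]])
  if (any(d > tol)) stop("point(s) far outside the geometry")
  d_in <- pmax(-d, 0)
  geom$R0 * (1 - d_in / min(geom$axes))
}

radial_profile <- function(edges, value, stderr, kind) {
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    value = value, stderr = stderr)
  attr(out, "kind") <- kind
  class(out) <- c("radial_profile", "data.frame")
  out
}

# Sum x by bin index, keeping empty bins as zeros.
sum_by_bin <- function(x, idx, nbins) {
  unname(vapply(split(x, factor(idx, levels = seq_len(nbins))), sum,
                numeric(1)))
}

# Histogram of r values (optionally weighted), normalized to integrate to 1.
norm_hist <- function(r, edges, w = NULL) {
  dr <- diff(edges)
  idx <- findInterval(r, edges, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- if (is.null(w)) {
    tabulate(idx, nbins = length(edges) - 1)
  } else {
    sum_by_bin(w, idx, length(edges) - 1)
  }
  tot <- sum(cnt)
  if (tot == 0) return(rep(0, length(dr)))
  cnt / (tot * dr)
}

# Split frame indices into blocks for standard errors.
frame_blocks <- function(n_frames, n_blocks) {
  n_blocks <- max(1L, min(n_blocks, n_frames))
  if (n_blocks == 1L) return(list(seq_len(n_frames)))
  split(seq_len(n_frames), cut(seq_len(n_frames), n_blocks, labels = FALSE))
}

#' Radial distribution S(R) of selected chromosomes
#'
#' Probability density of finding a monomer of the selected chromosome(s)
#' at (effective) radial coordinate R, pooled over both homologous copies
#' and all frames and normalized so that the integral over R is 1. For a
#' spatially uniform distribution S(R) grows quadratically with R. Standard
#' errors come from block averaging over frames.
#'
#' @param x an `actseg_run`, or an n x 3 x F array / n x 3 matrix of
#'   coordinates (then `table` and `geom` are required).
#' @param chromosomes chromosome label(s) to select (default: all monomers).
#' @param n_bins number of radial bins over `[0, R0]`.
#' @param table,geom required when `x` is raw coordinates.
#' @param n_blocks blocks for the standard error.
#' @return A `radial_profile` of kind "S".
#' @export
radial_S <- function(x, chromosomes = NULL, n_bins = 50, table = NULL,
                     geom = NULL, n_blocks = 10) {
  inp <- resolve_frames(x, table, geom)
  sel <- if (is.null(chromosomes)) {
    rep(TRUE, nrow(inp$table))
  } else {
    inp$table$chrom %in% chromosomes
  }
  if (!any(sel)) stop("empty chromosome selection")
  edges <- seq(0, inp$geom$R0, length.out = n_bins + 1)
  nf <- dim(inp$frames)[3]
  r_by_frame <- lapply(seq_len(nf), function(f) {
    effective_radius(inp$frames[sel, , f, drop = FALSE][, , 1], inp$geom,
                     tol = Inf)
  })
  value <- norm_hist(unlist(r_by_frame), edges)
  blocks <- frame_blocks(nf, n_blocks)
  if (length(blocks) > 1) {
    bv <- vapply(blocks, function(b) norm_hist(unlist(r_by_frame[b]), edges),
                 numeric(n_bins))
    stderr <- apply(bv, 1, stats::sd) / sqrt(length(blocks))
  } else {
    stderr <- rep(NA_real_, n_bins)
  }
  radial_profile(edges, value, stderr, "S")
}

#' Radial activity profile
#'
#' Mean effective temperature of the monomers in successive radial shells
#' (a configurational average over frames). With `rescale = TRUE` the
#' profile is mapped to (0:1): 0 at the physiological temperature, 1 at
#' `T_a`. Shells that never contain a monomer are NA.
#'
#' @inheritParams radial_S
#' @param rescale rescale to the (0:1) range?
#' @param T_a active temperature used for rescaling (default: the largest
#'   `T_eff` in the table).
#' @return A `radial_profile` of kind "activity".
#' @export
activity_profile <- function(x, n_bins = 50, rescale = FALSE, T_a = NULL,
                             table = NULL, geom = NULL, n_blocks = 10) {
  inp <- resolve_frames(x, table, geom)
  edges <- seq(0, inp$geom$R0, length.out = n_bins + 1)
  nf <- dim(inp$frames)[3]
  Teff <- inp$table$T_eff
  sums <- numeric(n_bins)
  cnts <- numeric(n_bins)
  per_frame <- matrix(NA_real_, n_bins, nf)
  for (f in seq_len(nf)) {
    r <- effective_radius(inp$frames[, , f], inp$geom, tol = Inf)
    idx <- findInterval(r, edges, rightmost.closed = TRUE, all.inside = TRUE)
    s <- sum_by_bin(Teff, idx, n_bins)
    k <- tabulate(idx, nbins = n_bins)
    sums <- sums + s
    cnts <- cnts + k
    per_frame[, f] <- ifelse(k > 0, s / k, NA_real_)
  }
  value <- ifelse(cnts > 0, sums / cnts, NA_real_)
  blocks <- frame_blocks(nf, n_blocks)
  stderr <- if (length(blocks) > 1) {
    bm <- vapply(blocks, function(b) rowMeans(per_frame[, b, drop = FALSE],
                                              na.rm = TRUE),
                 numeric(n_bins))
    apply(bm, 1, stats::sd) / sqrt(length(blocks))
  } else {
    rep(NA_real_, n_bins)
  }
  if (rescale) {
    if (is.null(T_a)) T_a <- max(Teff)
    denom <- max(T_a - 1, .Machine$double.eps)
    value <- (value - 1) / denom
    stderr <- stderr / denom
  }
  radial_profile(edges, value, stderr, "activity")
}

#' Radial total-density and gene-density profiles
#'
#' The total density is the (normalized) radial histogram of all monomers;
#' the gene density weights each monomer by its gene content. Both are
#' normalized to integrate to 1 over R and rise quadratically near the
#' origin for spatially uniform configurations.
#'
#' @inheritParams radial_S
#' @return List with elements `total` and `gene`, both `radial_profile`s.
#' @export
density_profiles <- function(x, n_bins = 50, table = NULL, geom = NULL,
                             n_blocks = 10) {
  inp <- resolve_frames(x, table, geom)
  edges <- seq(0, inp$geom$R0, length.out = n_bins + 1)
  nf <- dim(inp$frames)[3]
  w <- inp$table$gene_content
  r_by_frame <- lapply(seq_len(nf), function(f) {
    effective_radius(inp$frames[, , f], inp$geom, tol = Inf)
  })
  r_all <- unlist(r_by_frame)
  w_all <- rep(w, nf)
  blocks <- frame_blocks(nf, n_blocks)
  make <- function(weights, kind) {
    value <- norm_hist(r_all, edges, weights)
    stderr <- if (length(blocks) > 1) {
      bv <- vapply(blocks, function(b) {
        norm_hist(unlist(r_by_frame[b]), edges,
                  if (is.null(weights)) NULL else rep(w, length(b)))
      }, numeric(n_bins))
      apply(bv, 1, stats::sd) / sqrt(length(blocks))
    } else {
      rep(NA_real_, n_bins)
    }
    radial_profile(edges, value, stderr, kind)
  }
  list(total = make(NULL, "density"), gene = make(w_all, "gene_density"))
}

#' Territory index N_c
#'
#' Around each monomer a sphere of radius `R_sphere` is drawn; every other
#' monomer whose centre lies strictly inside contributes +1 if it belongs
#' to the same chain and -1 otherwise, and the sum is averaged over all
#' monomers. Positive values indicate territorial demixing. By default
#' "same chain" means the same chromosome copy (homologs count -1, as
#' separate territories); set `homologs = "chromosome"` to pool copies.
#'
#' @param positions n x 3 matrix (or `sim_state`) of coordinates.
#' @param table a `monomer_table`.
#' @param R_sphere probe radius (> 0).
#' @param method "grid" (cell-list accelerated) or "direct" (exhaustive
#'   double loop; reference implementation).
#' @param homologs "copy" (per-homolog territories) or "chromosome".
#' @return Scalar N_c.
#' @export
territory_index <- function(positions, table, R_sphere,
                            method = c("grid", "direct"),
                            homologs = c("copy", "chromosome")) {
  method <- match.arg(method)
  homologs <- match.arg(homologs)
  if (R_sphere <= 0) stop("R_sphere must be positive")
  if (inherits(positions, "sim_state")) positions <- positions$positions
  chain <- if (homologs == "copy") {
    paste(table$chrom, table$copy, sep = "\r")
  } else {
    table$chrom
  }
  chain_id <- as.integer(factor(chain, levels = unique(chain)))
  if (method == "grid") {
    return(territory_index_cpp(positions, chain_id, R_sphere))
  }
  n <- nrow(positions)
  d <- as.matrix(stats::dist(positions))
  same <- outer(chain_id, chain_id, "==")
  inside <- d < R_sphere
  diag(inside) <- FALSE
  mean(rowSums(inside * ifelse(same, 1, -1)))
}

#' Territory-index curve N_c(R_sphere)
#'
#' [territory_index()] averaged over frames, for a grid of probe radii.
#' Looped (compact) chromosomes under inhomogeneous activity show a
#' positive peak at intermediate radii; without loops the curve stays
#' negative.
#'
#' @inheritParams radial_S
#' @param R_grid vector of probe radii.
#' @param homologs see [territory_index()].
#' @return Data frame with columns `R_sphere`, `N_c`, `stderr` (over
#'   frames).
#' @export
territory_curve <- function(x, R_grid, table = NULL, geom = NULL,
                            homologs = c("copy", "chromosome")) {
  homologs <- match.arg(homologs)
  inp <- resolve_frames(x, table, geom)
  nf <- dim(inp$frames)[3]
  vals <- vapply(R_grid, function(R) {
    per <- vapply(seq_len(nf), function(f) {
      territory_index(inp$frames[, , f], inp$table, R, homologs = homologs)
    }, numeric(1))
    c(mean(per), if (nf > 1) stats::sd(per) / sqrt(nf) else NA_real_)
  }, numeric(2))
  data.frame(R_sphere = R_grid, N_c = vals[1, ], stderr = vals[2, ])
}

#' Mean (effective) radial position by group
#'
#' Convenience summary used to quantify segregation: the mean effective
#' radius of each group of monomers, pooled over frames.
#'
#' @inheritParams radial_S
#' @param by grouping column of the table, e.g. "activity_class" or
#'   "chrom".
#' @return Named numeric vector of mean radii.
#' @export
mean_radius_by <- function(x, by = "activity_class", table = NULL,
                           geom = NULL) {
  inp <- resolve_frames(x, table, geom)
  nf <- dim(inp$frames)[3]
  g <- inp$table[[by]]
  acc <- NULL
  for (f in seq_len(nf)) {
    r <- effective_radius(inp$frames[, , f], inp$geom, tol = Inf)
    s <- tapply(r, g, sum)
    acc <- if (is.null(acc)) s else acc + s
  }
  cnt <- tapply(rep(1, length(g)), g, sum) * nf
  out <- acc / cnt
  out[!is.na(out)]
}

#' Fit the low-R power of a radial profile
#'
#' Least-squares fit of log(value) against log(R) over a radial window,
#' used to check the quadratic rise of S(R) for uniform configurations.
#'
#' @param profile a `radial_profile`.
#' @param window fractions of the maximum radius delimiting the fit window.
#' @return List with `slope` and `se` (standard error of the slope).
#' @export
fit_radial_power <- function(profile, window = c(0.2, 0.8)) {
  mid <- 0.5 * (profile$bin_lo + profile$bin_hi)
  R_max <- max(profile$bin_hi)
  keep <- mid >= window[1] * R_max & mid <= window[2] * R_max &
    is.finite(profile$value) & profile$value > 0
  fit <- stats::lm(log(profile$value[keep]) ~ log(mid[keep]))
  list(slope = unname(stats::coef(fit)[2]),
       se = unname(sqrt(diag(stats::vcov(fit)))[2]))
}

#' Plot a radial profile
#'
#' Line plot with block-averaged error bars. An external reference curve
#' (e.g. a digitized experimental radial distribution) can be overlaid as
#' open symbols for visual comparison via `overlay`, a two-column object
#' of (radius, value).
#'
#' @param x a `radial_profile`.
#' @param overlay optional two-column matrix or data frame to overlay.
#' @param xlab,ylab,type usual plot parameters.
#' @param ... passed to [graphics::plot()].
#' @export
plot.radial_profile <- function(x, ..., overlay = NULL,
                                xlab = "R (effective radial coordinate)",
                                ylab = attr(x, "kind"), type = "l") {
  mid <- 0.5 * (x$bin_lo + x$bin_hi)
  graphics::plot(mid, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  ok <- is.finite(x$stderr)
  if (any(ok)) {
    graphics::arrows(mid[ok], x$value[ok] - x$stderr[ok], mid[ok],
                     x$value[ok] + x$stderr[ok], angle = 90, code = 3,
                     length = 0.02)
  }
  if (!is.null(overlay)) {
    graphics::points(overlay[[1]], overlay[[2]], pch = 1)
  }
  invisible(x)
}
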
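#' Per-component noise displacement scale
#'
#' Standard deviation of the stochastic displacement of one Cartesian
#' component in one Euler step: `sqrt(2 k_B T_i dt / zeta)`. Out of
#' equilibrium the effective temperature `T_i` differs between monomers and
#' the Einstein relation across monomers is violated; for a single free
#' monomer the mean-square displacement still grows as `6 (k_B T_i/zeta) t`.
#'
#' @param T_i effective temperature (units of the physiological
#'   temperature, k_B = 1).
#' @param zeta drag coefficient (same for all monomers).
#' @param dt time step (tau units).
#' @return Displacement standard deviation (length units), vectorized.
#' @export
noise_scale <- function(T_i, zeta = 1, dt = 0.01) {
  stopifnot(all(T_i >= 0), zeta > 0, dt > 0)
  sqrt(2 * T_i * dt / zeta)
}

#' Simulation schedule
#'
#' @param dt time step in tau units (default 0.01).
#' @param n_steps total number of steps.
#' @param n_burnin steps discarded before sampling begins (default 10% of
#'   `n_steps`).
#' @param sample_every steps between stored frames.
#' @param seed top-level seed; sub-streams for initialization and dynamics
#'   noise are fanned out from it.
#' @return A `schedule` list.
#' @export
schedule <- function(dt = 0.01, n_steps = 100000L,
                     n_burnin = floor(n_steps / 10), sample_every = 1000L,
                     seed = 1L) {
  if (dt <= 0) stop("dt must be positive")
  if (n_burnin >= n_steps) stop("n_burnin must be < n_steps")
  if (sample_every < 1) stop("sample_every must be >= 1")
  out <- list(dt = dt, n_steps = as.integer(n_steps),
              n_burnin = as.integer(n_burnin),
              sample_every = as.integer(sample_every),
              seed = as.integer(seed))
  class(out) <- "schedule"
  out
}

#' Simulation state
#'
#' Monomer coordinates plus elapsed simulation time.
#'
#' @param positions n x 3 coordinate matrix.
#' @param time elapsed time in tau units.
#' @return A `sim_state`.
#' @export
sim_state <- function(positions, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  structure(list(positions = positions, time = time), class = "sim_state")
}

is_inside <- function(points, geom, margin = 0) {
  points <- as_points(points)
  if (geom$kind == "sphere") {
    sqrt(rowSums(points^2)) < geom$R0 - margin
  } else {
    A <- geom$axes[[1]] - margin
    C <- geom$axes[[3]] - margin
    (points[, 1] / A)^2 + (points[, 2] / A)^2 + (points[, 3] / C)^2 < 1
  }
}

#' Random initial configuration
#'
#' Lays each chain down as a compact random walk with exact bond length
#' `r0`: the chain start is uniform inside the geometry and each subsequent
#' monomer is placed at distance `r0` in a random direction, re-drawn until
#' it falls inside the confinement (stepping toward the centre as a
#' fallback). All monomers start strictly inside the geometry. The same
#' seed reproduces the same state.
#'
#' @param geom a `geometry`.
#' @param table a `monomer_table`.
#' @param seed integer seed.
#' @param r0 bond length used for the walk.
#' @return A `sim_state` at time 0.
#' @export
initialize_random <- function(geom, table, seed = 1L, r0 = 1) {
  margin <- min(0.5 * r0, 0.1 * min(geom$axes))
  n <- nrow(table)
  chain <- paste(table$chrom, table$copy, sep = "\r")
  pos <- matrix(NA_real_, n, 3)
  withr_seed(seed, {
    starts <- which(!duplicated(chain))
    bb <- c(geom$axes[[1]], geom$axes[[2]], geom$axes[[3]])
    for (s in seq_along(starts)) {
      first <- starts[s]
      last <- if (s < length(starts)) starts[s + 1] - 1L else n
      repeat {
        p <- stats::runif(3, -bb, bb)
        if (is_inside(p, geom, margin)) break
      }
      pos[first, ] <- p
      if (last > first) for (i in seq(first + 1L, last)) {
        prev <- pos[i - 1L, ]
        placed <- FALSE
        for (try in 1:50) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- prev + r0 * u
          if (is_inside(cand, geom, margin)) {
            pos[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) {  # step toward the centre
          d <- sqrt(sum(prev^2))
          pos[i, ] <- prev * (1 - r0 / max(d, r0))
        }
      }
    }
  })
  sim_state(pos, time = 0)
}

#' One Euler step of the overdamped Langevin dynamics
#'
#' Advances the state by `r_i <- r_i + (dt/zeta) F_i + xi_i` where `xi_i`
#' has independent components of standard deviation
#' [noise_scale()]`(T_i, zeta, dt)`. Noise is drawn from the current R RNG
#' stream in monomer order; seed it with `set.seed()` for reproducibility.
#' Aborts if the deterministic drift of any monomer exceeds `guard_sigma`
#' monomer diameters in a single step.
#'
#' @param state a `sim_state`.
#' @param table a `monomer_table` (supplies `T_eff` and activity classes).
#' @param loops a `loop_set` or NULL.
#' @param geom a `geometry`.
#' @param ff a `force_field`.
#' @param dt time step.
#' @param zeta drag coefficient.
#' @param ne_on enable the selective NE attraction?
#' @param walls enable confinement?
#' @param guard_sigma abort threshold for the deterministic drift, in
#'   monomer diameters per step.
#' @return The advanced `sim_state`.
#' @export
euler_step <- function(state, table, loops = NULL, geom, ff, dt = 0.01,
                       zeta = 1, ne_on = FALSE, walls = TRUE,
                       guard_sigma = 5) {
  bonds <- chain_bonds(table, ff, loops)
  res <- bd_run_cpp(state$positions, table$T_eff, bonds$i, bonds$j, bonds$k,
                    geom_code(geom), geom$R0, geom$axes[[1]], geom$axes[[3]],
                    ff_vector(ff), table$activity_class == "active",
                    isTRUE(ne_on), isTRUE(walls), dt, zeta, 1L, 0L, 1L,
                    state$time, FALSE, guard_sigma)
  sim_state(res$final, time = state$time + dt)
}

ff_vector <- function(ff) {
  as.numeric(unlist(ff[c("k_bond", "r0", "V0", "sigma", "k_wall", "eps_ne",
                         "lambda_ne", "r_cut")]))
}

#' Run the Brownian dynamics simulation
#'
#' Evolves the system for `sch$n_steps` Euler steps, storing a frame every
#' `sch$sample_every` steps after the first `sch$n_burnin` steps, together
#' with a potential-energy trace at the sampled frames. All randomness
#' derives from `sch$seed` through named sub-streams (initial placement,
#' dynamics noise), so identical inputs reproduce identical trajectories.
#'
#' @param table a `monomer_table` with activity assigned.
#' @param ff a `force_field`.
#' @param geom a `geometry`.
#' @param sch a `schedule`.
#' @param loops a `loop_set` or NULL.
#' @param ne_on enable the selective NE attraction?
#' @param init optional starting `sim_state`; by default a random compact
#'   configuration from the init sub-stream of `sch$seed`.
#' @param zeta drag coefficient.
#' @param record_energy store the potential energy at each sampled frame?
#' @param walls enable confinement?
#' @param guard_sigma abort threshold for the deterministic drift, in
#'   monomer diameters per step (stochastic displacements are unbounded by
#'   construction and not guarded).
#' @return An `actseg_run` with elements `frames` (N x 3 x n_frames array),
#'   `times`, `energy`, `final` (a `sim_state`), `table`, `loops`, `geom`,
#'   `ff`, `schedule`, `ne_on`, `max_drift`, and `containment` (mean
#'   fraction of monomers inside the geometry over the sampled frames).
#' @export
simulate_chromosomes <- function(table, ff = force_field(), geom, sch,
                                 loops = NULL, ne_on = FALSE, init = NULL,
                                 zeta = 1, record_energy = TRUE,
                                 walls = TRUE, guard_sigma = 5) {
  if (is.null(init)) {
    init <- initialize_random(geom, table, seed = sub_seed(sch$seed, "init"),
                              r0 = ff$r0)
  }
  stopifnot(nrow(init$positions) == nrow(table))
  bonds <- chain_bonds(table, ff, loops)
  res <- withr_seed(sub_seed(sch$seed, "dynamics"), {
    bd_run_cpp(init$positions, table$T_eff, bonds$i, bonds$j, bonds$k,
               geom_code(geom), geom$R0, geom$axes[[1]], geom$axes[[3]],
               ff_vector(ff), table$activity_class == "active",
               isTRUE(ne_on), isTRUE(walls), sch$dt, zeta,
               sch$n_steps, sch$n_burnin, sch$sample_every, init$time,
               record_energy, guard_sigma)
  })
  nf <- dim(res$frames)[3]
  containment <- if (nf > 0) {
    mean(vapply(seq_len(nf), function(f) {
      mean(is_inside(res$frames[, , f], geom))
    }, numeric(1)))
  } else {
    NA_real_
  }
  out <- list(frames = res$frames, times = res$times, energy = res$energy,
              final = sim_state(res$final,
                                time = init$time + sch$n_steps * sch$dt),
              table = table, loops = loops, geom = geom, ff = ff,
              schedule = sch, ne_on = isTRUE(ne_on), zeta = zeta,
              max_drift = res$max_drift, containment = containment)
  class(out) <- "actseg_run"
  out
}

#' @export
print.actseg_run <- function(x, ...) {
  cat(sprintf("Brownian dynamics run: %d monomers, %d frames (dt = %g, %d steps, burn-in %d)\n",
              dim(x$frames)[1], dim(x$frames)[3], x$schedule$dt,
              x$schedule$n_steps, x$schedule$n_burnin))
  cat(sprintf("  geometry: %s; NE attraction: %s; loops: %s\n",
              x$geom$kind, if (x$ne_on) "on" else "off",
              if (is.null(x$loops)) "none" else nrow(x$loops)))
  if (length(x$energy)) {
    cat(sprintf("  potential energy (first -> last frame): %.4g -> %.4g\n",
                x$energy[1], x$energy[length(x$energy)]))
  }
  cat(sprintf("  max deterministic drift per step: %.3g sigma; containment %.1f%%; seed %d\n",
              x$max_drift, 100 * x$containment, x$schedule$seed))
  invisible(x)
}

#' NE switch-on protocol
#'
#' Starting from an ensemble of passive-confinement steady states, the
#' selective NE attraction is switched on at t = 0 and the positional
#' statistics are recorded at a grid of times, averaged over the ensemble.
#' This tracks how the radial distribution of chromosomes evolves between
#' the conventional (active-inside) and inverted (active-peripheral) steady
#' states.
#'
#' @param table,ff,geom as in [simulate_chromosomes()].
#' @param loops a `loop_set` or NULL.
#' @param ensemble list of `sim_state`s drawn from the passive steady state.
#' @param times_steps increasing integer step counts at which snapshots are
#'   taken (0 = the moment of switch-on).
#' @param dt,zeta integrator parameters.
#' @param n_init number of ensemble members required (defaults to all);
#'   an ensemble smaller than this is an error.
#' @param seed seed for the dynamics noise.
#' @return An `actseg_switch`: list with `times_steps`, `snapshots` (one
#'   n x 3 x n_init array per time) and the inputs needed to compute
#'   profiles.
#' @export
ne_switch_protocol <- function(table, ff, geom, loops = NULL, ensemble,
                               times_steps, dt = 0.01, zeta = 1,
                               n_init = length(ensemble), seed = 1L) {
  if (length(ensemble) < n_init) {
    stop(sprintf("ensemble of %d states is smaller than the %d requested",
                 length(ensemble), n_init))
  }
  ensemble <- ensemble[seq_len(n_init)]
  times_steps <- as.integer(times_steps)
  stopifnot(!is.unsorted(times_steps), all(times_steps >= 0))
  n <- nrow(table)
  bonds <- chain_bonds(table, ff, loops)
  snaps <- lapply(times_steps, function(t) array(NA_real_, c(n, 3, n_init)))
  names(snaps) <- as.character(times_steps)
  withr_seed(seed, {
    for (m in seq_len(n_init)) {
      pos <- ensemble[[m]]$positions
      prev_t <- 0L
      for (k in seq_along(times_steps)) {
        nst <- times_steps[k] - prev_t
        if (nst > 0) {
          res <- bd_run_cpp(pos, table$T_eff, bonds$i, bonds$j, bonds$k,
                            geom_code(geom), geom$R0, geom$axes[[1]],
                            geom$axes[[3]], ff_vector(ff),
                            table$activity_class == "active", TRUE, TRUE,
                            dt, zeta, nst, nst, 1L, 0, FALSE, 5)
          pos <- res$final
          prev_t <- times_steps[k]
        }
        snaps[[k]][, , m] <- pos
      }
    }
  })
  structure(list(times_steps = times_steps, snapshots = snaps,
                 table = table, geom = geom, ff = ff),
            class = "actseg_switch")
}
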
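# Shared fixtures and independent oracles for the test suite. Expensive
# simulations are memoised so several test blocks can interrogate the same
# study-condition runs.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# --- small building blocks -------------------------------------------------

tiny_karyotype <- function(n = 2, len = 5, copies = 1) {
  karyotype(sprintf("chrT%d", seq_len(n)), rep(len, n), copies)
}

tiny_table <- function(n = 2, len = 5, copies = 1, seed = 42) {
  kar <- tiny_karyotype(n, len, copies)
  build_monomer_table(kar, synthesize_gene_track(kar, seed = seed))
}

# The scaled study system: 8 chains x 100 monomers at the same volume
# fraction as the full 6098-monomer nucleus, 10% active at T_a = 20.
scaled_radius <- function(n = 800) 10 * (n / 6098)^(1 / 3)

scaled_system <- function(mode = "inhomogeneous", active_fraction = 0.10,
                          T_a = 20) {
  kar <- tutorial_karyotype()
  trk <- cached("scaled_track", synthesize_gene_track(kar, seed = 101))
  tab <- assign_activity(build_monomer_table(kar, trk), mode,
                         active_fraction, T_a)
  list(table = tab, geom = geometry("sphere", R0 = scaled_radius()),
       ff = force_field())
}

# --- memoised study-condition runs ----------------------------------------

# Five independent passive runs of the scaled inhomogeneous system,
# 2e5 steps each (the segregation study condition).
passive_runs <- function() cached("passive_runs", {
  sys <- scaled_system()
  lapply(1:5, function(seed) {
    sch <- schedule(dt = 0.01, n_steps = 200000L, n_burnin = 100000L,
                    sample_every = 2000L, seed = seed)
    simulate_chromosomes(sys$table, sys$ff, sys$geom, sch,
                         record_energy = FALSE)
  })
})

# NE switch-on continuations of the passive runs (selective attraction of
# active monomers to the envelope), 6e4 further steps each.
ne_runs <- function() cached("ne_runs", {
  sys <- scaled_system()
  pr <- passive_runs()
  lapply(1:5, function(seed) {
    sch <- schedule(dt = 0.01, n_steps = 60000L, n_burnin = 30000L,
                    sample_every = 1000L, seed = seed + 500L)
    simulate_chromosomes(sys$table, sys$ff, sys$geom, sch, ne_on = TRUE,
                         init = pr[[seed]]$final, record_energy = FALSE)
  })
})

# Scaled equilibrium run (all monomers at the physiological temperature).
equilibrium_run <- function() cached("equilibrium_run", {
  sys <- scaled_system(mode = "equilibrium")
  sch <- schedule(dt = 0.01, n_steps = 80000L, n_burnin = 16000L,
                  sample_every = 800L, seed = 7L)
  simulate_chromosomes(sys$table, sys$ff, sys$geom, sch,
                       record_energy = FALSE)
})

# Scaled inhomogeneous run with high-preset random loops (territory study).
looped_run <- function() cached("looped_run", {
  sys <- scaled_system()
  loops <- generate_loops(sys$table, "high", sys$ff, seed = 13L)
  sch <- schedule(dt = 0.01, n_steps = 100000L, n_burnin = 50000L,
                  sample_every = 2000L, seed = 13L)
  simulate_chromosomes(sys$table, sys$ff, sys$geom, sch, loops = loops,
                       record_energy = FALSE)
})

segregation_gap <- function(run) {
  m <- mean_radius_by(run)
  (m[["inactive"]] - m[["active"]]) / m[["inactive"]]
}

# --- independent oracles ---------------------------------------------------

# Exhaustive O(N^2) force evaluation in plain R, written independently of
# the cell-list engine: harmonic bonds along each chain, loop springs,
# truncated Gaussian core, harmonic wall, optional NE attraction.
direct_forces <- function(positions, table, loops = NULL, geom, ff,
                          ne_on = FALSE, walls = TRUE) {
  n <- nrow(positions)
  f <- matrix(0, n, 3)
  # pairs
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dv <- positions[i, ] - positions[j, ]
      d2 <- sum(dv^2)
      if (d2 < ff$r_cut^2) {
        g <- ff$V0 / ff$sigma^2 * exp(-d2 / (2 * ff$sigma^2))
        f[i, ] <- f[i, ] + g * dv
        f[j, ] <- f[j, ] - g * dv
      }
    }
  }
  # chain bonds
  chain <- paste(table$chrom, table$copy)
  for (i in seq_len(n - 1)) {
    if (chain[i] == chain[i + 1]) {
      dv <- positions[i, ] - positions[i + 1, ]
      d <- sqrt(sum(dv^2))
      if (d > 0) {
        fac <- -ff$k_bond * (d - ff$r0) / d
        f[i, ] <- f[i, ] + fac * dv
        f[i + 1, ] <- f[i + 1, ] - fac * dv
      }
    }
  }
  # loop springs
  if (!is.null(loops) && nrow(loops)) {
    for (b in seq_len(nrow(loops))) {
      i <- loops$i[b] + 1L
      j <- loops$j[b] + 1L
      dv <- positions[i, ] - positions[j, ]
      d <- sqrt(sum(dv^2))
      if (d > 0) {
        fac <- -loops$k_spring[b] * (d - ff$r0) / d
        f[i, ] <- f[i, ] + fac * dv
        f[j, ] <- f[j, ] - fac * dv
      }
    }
  }
  # wall and NE
  for (i in seq_len(n)) {
    q <- actseg:::surface_query(positions[i, , drop = FALSE], geom)
    s <- q$distance
    if (walls && s > 0) {
      f[i, ] <- f[i, ] - ff$k_wall * (positions[i, ] - q$nearest[1, ])
    }
    if (ne_on && table$activity_class[i] == "active" && s != 0) {
      w <- ff$eps_ne / ff$lambda_ne^2 * exp(-s^2 / (2 * ff$lambda_ne^2))
      f[i, ] <- f[i, ] - w * (positions[i, ] - q$nearest[1, ])
    }
  }
  f
}

# Brute-force distance to a spheroid surface: dense sampling of the
# generating ellipse followed by local parabolic refinement.
brute_surface_distance <- function(p, axes, n_grid = 20001) {
  A <- axes[[1]]; C <- axes[[3]]
  u <- sqrt(p[1]^2 + p[2]^2)
  v <- abs(p[3])
  th <- seq(0, pi / 2, length.out = n_grid)
  d2 <- (A * cos(th) - u)^2 + (C * sin(th) - v)^2
  k <- which.min(d2)
  lo <- th[max(1, k - 2)]; hi <- th[min(n_grid, k + 2)]
  opt <- stats::optimize(function(t) (A * cos(t) - u)^2 + (C * sin(t) - v)^2,
                         c(lo, hi), tol = 1e-14)
  d <- sqrt(opt$objective)
  inside <- (u / A)^2 + (v / C)^2 < 1
  if (inside) -d else d
}

# Exhaustive territory index: the defining double loop.
brute_territory_index <- function(positions, table, R_sphere,
                                  homologs = "copy") {
  n <- nrow(positions)
  chain <- if (homologs == "copy") paste(table$chrom, table$copy) else
    table$chrom
  total <- 0
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      if (sum((positions[i, ] - positions[j, ])^2) < R_sphere^2) {
        s <- s + if (chain[i] == chain[j]) 1 else -1
      }
    }
    total <- total + s
  }
  total / n
}

random_positions_in_sphere <- function(n, R0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, n, 3)
  k <- 0
  while (k < n) {
    p <- matrix(runif(3 * (n - k), -R0, R0), ncol = 3)
    keep <- rowSums(p^2) < R0^2
    if (any(keep)) {
      p <- p[keep, , drop = FALSE]
      out[(k + 1):(k + nrow(p)), ] <- p
      k <- k + nrow(p)
    }
  }
  out
}
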
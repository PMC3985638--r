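test_that("noise scale follows sqrt(2 k_B T dt / zeta)", {
  expect_equal(noise_scale(0), 0)
  expect_equal(noise_scale(1, zeta = 1, dt = 0.01), sqrt(0.02))
  expect_equal(noise_scale(20) / noise_scale(1), sqrt(20))
  expect_error(noise_scale(1, zeta = 0), "zeta")
})

test_that("schedules validate their fields and fix the frame arithmetic", {
  sch <- schedule()
  expect_equal(sch$dt, 0.01)
  expect_error(schedule(dt = -1), "positive")
  expect_error(schedule(n_steps = 100, n_burnin = 100), "n_burnin")
  expect_error(schedule(sample_every = 0), "sample_every")

  # 1000 steps, 200 burn-in, sample every 100 -> 8 stored frames
  tab <- tiny_table(n = 1, len = 4)
  run <- simulate_chromosomes(tab, force_field(), geometry("sphere", 5),
                              schedule(n_steps = 1000, n_burnin = 200,
                                       sample_every = 100, seed = 1))
  expect_equal(dim(run$frames)[3], 8)
  expect_equal(run$times, 0.01 * seq(300, 1000, by = 100))
})

test_that("random initialization is contained, bonded and seed-deterministic", {
  tab <- tiny_table(n = 4, len = 60)
  for (geo in list(geometry("sphere", R0 = 6),
                   geometry("ellipsoid", R0 = 6, aspect = 0.3))) {
    st <- initialize_random(geo, tab, seed = 5)
    expect_true(all(surface_distance(st$positions, geo) < 0))
    # consecutive bonded monomers sit at the rest length
    chain <- paste(tab$chrom, tab$copy)
    d <- sqrt(rowSums((st$positions[-1, ] - st$positions[-nrow(tab), ])^2))
    same <- chain[-1] == chain[-nrow(tab)]
    expect_true(all(abs(d[same] - 1) < 1e-9))
  }
  st1 <- initialize_random(geometry("sphere", 6), tab, seed = 5)
  st2 <- initialize_random(geometry("sphere", 6), tab, seed = 5)
  st3 <- initialize_random(geometry("sphere", 6), tab, seed = 6)
  expect_identical(st1, st2)
  expect_false(identical(st1$positions, st3$positions))
})

test_that("the Euler update is exact drift plus seeded Gaussian noise", {
  # single monomer, T_eff = 0: pure drift, Delta x = dt * F / zeta
  tab <- tiny_table(n = 1, len = 1)
  tab$T_eff <- 0
  geo <- geometry("sphere", R0 = 2)
  ff <- force_field()
  st <- sim_state(matrix(c(2.5, 0, 0), 1))      # outside: constant wall force
  f <- total_forces(st$positions, tab, NULL, geo, ff)
  st2 <- euler_step(st, tab, NULL, geo, ff, dt = 0.01)
  expect_equal(st2$positions[1, ], st$positions[1, ] + 0.01 * f[1, ],
               tolerance = 1e-12)
  expect_equal(st2$time, 0.01)

  # zero force, T = 0: nothing moves
  st0 <- sim_state(matrix(0, 1, 3))
  expect_equal(euler_step(st0, tab, NULL, geo, ff)$positions, st0$positions)

  # with temperature the step reproduces drift + noise_scale * N(0,1)
  tab$T_eff <- 4
  set.seed(99)
  st3 <- euler_step(st0, tab, NULL, geo, ff, dt = 0.01)
  set.seed(99)
  eta <- rnorm(3)
  expect_equal(st3$positions[1, ], noise_scale(4, 1, 0.01) * eta,
               tolerance = 1e-12)
})

test_that("identical (config, seed) reproduces trajectories bitwise", {
  tab <- assign_activity(tiny_table(n = 2, len = 40), "inhomogeneous",
                         0.1, 20)
  geo <- geometry("sphere", R0 = 4)
  sch <- schedule(n_steps = 500, n_burnin = 100, sample_every = 50, seed = 3)
  r1 <- simulate_chromosomes(tab, force_field(), geo, sch)
  r2 <- simulate_chromosomes(tab, force_field(), geo, sch)
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$energy, r2$energy)
  r3 <- simulate_chromosomes(tab, force_field(), geo,
                             schedule(n_steps = 500, n_burnin = 100,
                                      sample_every = 50, seed = 4))
  expect_false(identical(r1$frames, r3$frames))
})

test_that("a harmonically tethered monomer equilibrates to k_B T / k", {
  # two bonded monomers with a near-zero rest length form a harmonic dimer;
  # each relative coordinate component is an OU process with stationary
  # variance T/k_bond. k is kept soft so the Euler discretization bias
  # (~ dt k / zeta) is well below the tolerance.
  kar <- karyotype("c", 2L, 1L)
  tab <- build_monomer_table(kar, synthesize_gene_track(kar, seed = 1))
  ff <- force_field(k_bond = 2, r0 = 1e-9, V0 = 1e-12)
  geo <- geometry("sphere", R0 = 1000)
  sch <- schedule(n_steps = 200000, n_burnin = 20000, sample_every = 20,
                  seed = 8)
  run <- simulate_chromosomes(tab, ff, geo, sch, walls = FALSE,
                              record_energy = FALSE)
  rel <- run$frames[1, , ] - run$frames[2, , ]     # 3 x n_frames
  v <- mean(apply(rel, 1, var))
  expect_equal(v, 1 / 2, tolerance = 0.05)
})

test_that("free-monomer diffusion obeys the Einstein relation per temperature", {
  # many non-interacting monomers diffusing without confinement: the MSD
  # slope matches 6 k_B T / zeta within 3 standard errors
  n <- 400
  kar <- karyotype(sprintf("m%03d", 1:n), rep(1L, n), 1L)
  tab <- build_monomer_table(kar, synthesize_gene_track(kar, seed = 1))
  for (Temp in c(1, 20)) {
    tab$T_eff <- Temp
    side <- ceiling(n^(1 / 3))
    g <- as.matrix(expand.grid(x = 1:side, y = 1:side, z = 1:side))[1:n, ]
    init <- sim_state(g * 50)
    sch <- schedule(n_steps = 2000, n_burnin = 1999, sample_every = 1,
                    seed = 21)
    run <- simulate_chromosomes(tab, force_field(), geometry("sphere", 1e6),
                                sch, init = init, walls = FALSE,
                                record_energy = FALSE)
    t_el <- 2000 * 0.01
    r2 <- rowSums((run$frames[, , 1] - init$positions)^2)
    slope <- mean(r2) / t_el
    se <- sd(r2 / t_el) / sqrt(n)
    expect_lt(abs(slope - 6 * Temp), 3 * se)
  }
})

test_that("the NE switch-on protocol is a null perturbation when the well is absent", {
  tab <- assign_activity(tiny_table(n = 2, len = 50), "inhomogeneous",
                         0.1, 20)
  geo <- geometry("sphere", R0 = 3.2)
  ff0 <- force_field(eps_ne = 1e-12)    # vanishing NE well
  sch <- schedule(n_steps = 4000, n_burnin = 2000, sample_every = 500,
                  seed = 2)
  ens <- lapply(1:3, function(s) {
    simulate_chromosomes(tab, ff0, geo,
                         schedule(n_steps = 3000, n_burnin = 1000,
                                  sample_every = 500, seed = s),
                         record_energy = FALSE)$final
  })
  sw <- ne_switch_protocol(tab, ff0, geo, NULL, ens,
                           times_steps = c(0, 1500, 3000), seed = 11)
  # t = 0 snapshots are exactly the input ensemble states
  expect_equal(sw$snapshots[["0"]][, , 1], ens[[1]]$positions)
  # with a vanishing well the radial statistics stay time-invariant
  m <- vapply(sw$snapshots, function(sn) {
    mean(vapply(1:3, function(k) {
      mean(sqrt(rowSums(sn[, , k]^2)))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(diff(range(m)), 0.15)
  # requesting more members than available is an error
  expect_error(ne_switch_protocol(tab, ff0, geo, NULL, ens[1:2],
                                  times_steps = 0, n_init = 3), "smaller")
})

test_that("an unstable spring stiffness aborts with a diagnostic", {
  tab <- tiny_table(n = 1, len = 2)
  ff <- force_field(k_bond = 5000)       # dt*2k/zeta = 100: explodes
  st <- sim_state(matrix(c(0, 0, 0, 1.4, 0, 0), 2, 3, byrow = TRUE))
  expect_error(
    simulate_chromosomes(tab, ff, geometry("sphere", 10),
                         schedule(n_steps = 50, n_burnin = 10,
                                  sample_every = 10, seed = 1), init = st),
    "drift|unstable")
})
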
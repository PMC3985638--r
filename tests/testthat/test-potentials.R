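test_that("bond energy and force follow the harmonic closed form", {
  ff <- force_field(k_bond = 10, r0 = 1)
  expect_equal(bond_energy(1, ff), 0)
  expect_equal(bond_force(1, ff), 0)
  expect_equal(bond_energy(2, ff), 5)           # (10/2)(2-1)^2
  # symmetric about the rest length
  d <- seq(0, 2, by = 0.25)
  expect_equal(bond_energy(d, ff), bond_energy(2 - d, ff))
  # compression pushes apart, extension pulls together
  expect_gt(bond_force(0.5, ff), 0)
  expect_lt(bond_force(1.5, ff), 0)
})

test_that("Gaussian-core pair potential matches its closed form and cutoff", {
  ff <- force_field(V0 = 2, sigma = 1)
  expect_equal(gaussian_core_energy(0, ff), 2)          # V0 at contact
  expect_equal(gaussian_core_energy(1, ff), 2 * exp(-0.5))
  expect_equal(gaussian_core_energy(10, ff), 0)         # beyond cutoff
  expect_equal(gaussian_core_force(10, ff), 0)
  # the shifted form is continuous at the cutoff
  eps <- 1e-9
  expect_lt(abs(gaussian_core_energy(ff$r_cut - eps, ff, shifted = TRUE)),
            1e-6)
  # force is the negative derivative of the energy
  h <- 1e-6
  for (d in c(0.3, 1, 2.5)) {
    num <- -(gaussian_core_energy(d + h, ff) -
               gaussian_core_energy(d - h, ff)) / (2 * h)
    expect_equal(gaussian_core_force(d, ff), num, tolerance = 1e-6)
  }
})

test_that("the wall potential vanishes inside and is harmonic outside", {
  ff <- force_field(k_wall = 100)
  geo <- geometry("sphere", R0 = 10)
  expect_equal(wall_energy(c(5, 0, 0), geo, ff), 0)
  expect_equal(wall_energy(c(11, 0, 0), geo, ff), 50)   # (100/2)(1)^2
  # continuity at the surface
  expect_lt(wall_energy(c(10 + 1e-8, 0, 0), geo, ff), 1e-10)
  # force points back toward the surface
  f <- wall_force(c(0, 0, 12), geo, ff)
  expect_equal(f[1, ], c(0, 0, -200), tolerance = 1e-12)
})

test_that("ellipsoid axes preserve volume", {
  ax <- ellipsoid_axes(3, 10)
  expect_equal(unname(ax[1]), 10 * 3^(-1 / 3), tolerance = 1e-12)
  expect_equal(unname(ax[3]), 3 * unname(ax[1]), tolerance = 1e-12)
  expect_equal(unname(ellipsoid_axes(1, 7)), c(7, 7, 7))
  for (aspect in c(0.1, 0.3, 0.9, 1.7, 3, 8)) {
    ax <- ellipsoid_axes(aspect, 10)
    expect_equal(prod(ax), 1000, tolerance = 1e-12)
  }
  expect_error(ellipsoid_axes(-1, 10), "positive")
})

test_that("surface distance is exact for spheres and oracle-accurate for spheroids", {
  geo <- geometry("sphere", R0 = 10)
  expect_equal(surface_distance(c(7, 0, 0), geo), -3)
  expect_equal(surface_distance(c(0, 0, 13), geo), 3)

  for (aspect in c(0.3, 3)) {
    ge <- geometry("ellipsoid", R0 = 10, aspect = aspect)
    A <- ge$axes[[1]]; C <- ge$axes[[3]]
    # on-surface points
    expect_equal(surface_distance(c(A, 0, 0), ge), 0, tolerance = 1e-10)
    expect_equal(surface_distance(c(0, 0, C), ge), 0, tolerance = 1e-10)
    # random interior and exterior points against the brute-force oracle,
    # including on-axis queries where the nearest point leaves the axis
    set.seed(20 + aspect * 10)
    pts <- rbind(matrix(runif(45, -0.9, 0.9), ncol = 3) %*% diag(c(A, A, C)),
                 matrix(runif(30, 1.05, 1.5), ncol = 3) %*% diag(c(A, A, C)),
                 c(0, 0, 0.3 * C), c(0.3 * A, 0, 0), c(0, 0, 0))
    d_pkg <- surface_distance(pts, ge)
    d_cpp <- surface_distance_cpp(pts, 1L, ge$R0, A, C)
    for (i in seq_len(nrow(pts))) {
      d_ref <- brute_surface_distance(pts[i, ], ge$axes)
      expect_equal(d_pkg[i], d_ref, tolerance = 1e-6)
      expect_equal(d_cpp[i], d_ref, tolerance = 1e-6)
    }
  }
})

test_that("equal surface distance implies equal confinement energy on spheroids", {
  ge <- geometry("ellipsoid", R0 = 8, aspect = 0.3)
  ff <- force_field()
  A <- ge$axes[[1]]; C <- ge$axes[[3]]
  set.seed(9)
  for (k in 1:20) {
    # two random surface points pushed outward along their normals by the
    # same depth must feel identical wall energies
    th <- runif(2, 0, 2 * pi); ph <- runif(2, -pi / 2, pi / 2)
    s <- cbind(A * cos(ph) * cos(th), A * cos(ph) * sin(th), C * sin(ph))
    nrm <- cbind(s[, 1] / A^2, s[, 2] / A^2, s[, 3] / C^2)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    d <- runif(1, 0.1, 2)
    p <- s + d * nrm
    dist <- surface_distance(p, ge)
    expect_equal(dist[1], d, tolerance = 1e-8)
    expect_equal(dist[2], d, tolerance = 1e-8)
    e <- wall_energy(p, ge, ff)
    expect_equal(e[1], e[2], tolerance = 1e-7)
  }
})

test_that("NE attraction acts on active monomers only, with its minimum at the surface", {
  ff <- force_field(eps_ne = 4, lambda_ne = 0.5)
  geo <- geometry("sphere", R0 = 10)
  # inactive monomer inside: only (zero) confinement
  expect_equal(ne_energy(c(5, 0, 0), FALSE, geo, ff), 0)
  # active monomer at the surface sits at the bottom of the well
  expect_equal(ne_energy(c(10, 0, 0), TRUE, geo, ff), -4)
  # short range: negligible far from the envelope
  expect_lt(abs(ne_energy(c(10 - 10 * ff$lambda_ne, 0, 0), TRUE, geo, ff)),
            1e-8)
  # force draws an interior active monomer outward, toward the envelope
  f <- ne_force(c(9.5, 0, 0), TRUE, geo, ff)
  expect_gt(f[1, 1], 0)
})

test_that("cell-list forces equal the exhaustive double loop", {
  kar <- karyotype(c("cA", "cB"), c(60L, 40L), 1L)
  tab <- build_monomer_table(kar, synthesize_gene_track(kar, seed = 6))
  tab <- assign_activity(tab, "inhomogeneous", 0.1, 20)
  ff <- force_field()
  for (cfg in list(list(geo = geometry("sphere", R0 = 4), ne = FALSE),
                   list(geo = geometry("sphere", R0 = 4), ne = TRUE),
                   list(geo = geometry("ellipsoid", R0 = 4, aspect = 3),
                        ne = TRUE))) {
    set.seed(31)
    pos <- random_positions_in_sphere(100, 3.9)
    loops <- generate_loops(tab, 0.1, ff, seed = 8)
    f_cell <- total_forces(pos, tab, loops, cfg$geo, ff, ne_on = cfg$ne)
    f_ref <- direct_forces(pos, tab, loops, cfg$geo, ff, ne_on = cfg$ne)
    expect_lt(max(abs(f_cell - f_ref)), 1e-10)
  }
})

test_that("forces are the negative gradient of the energy", {
  kar <- karyotype("cA", 30L, 1L)
  tab <- build_monomer_table(kar, synthesize_gene_track(kar, seed = 2))
  tab <- assign_activity(tab, "inhomogeneous", 0.2, 20)
  ff <- force_field()
  geo <- geometry("ellipsoid", R0 = 3, aspect = 0.3)
  loops <- generate_loops(tab, 0.2, ff, seed = 3)
  set.seed(12)
  pos <- random_positions_in_sphere(30, 3.2)
  f <- total_forces(pos, tab, loops, geo, ff, ne_on = TRUE)
  h <- 1e-6
  set.seed(13)
  for (k in 1:12) {
    i <- sample(30, 1); d <- sample(3, 1)
    pp <- pos; pp[i, d] <- pp[i, d] + h
    pm <- pos; pm[i, d] <- pm[i, d] - h
    num <- -(total_energy(pp, tab, loops, geo, ff, ne_on = TRUE) -
               total_energy(pm, tab, loops, geo, ff, ne_on = TRUE)) / (2 * h)
    expect_equal(f[i, d], num, tolerance = 1e-5)
  }
})

test_that("pairwise forces obey action-reaction (zero net force without walls)", {
  kar <- karyotype("cA", 50L, 2L)
  tab <- build_monomer_table(kar, synthesize_gene_track(kar, seed = 4))
  ff <- force_field()
  geo <- geometry("sphere", R0 = 5)
  loops <- generate_loops(tab, 0.15, ff, seed = 5)
  set.seed(77)
  pos <- random_positions_in_sphere(100, 4)
  f <- total_forces(pos, tab, loops, geo, ff, walls = FALSE)
  expect_lt(max(abs(colSums(f))), 1e-9)
})

test_that("degenerate inputs are rejected with useful messages", {
  expect_error(force_field(k_bond = -1), "positive")
  expect_error(force_field(loop_k_multiplier = 0.5), "positive|>= 1")
  expect_error(force_field(r_cut = 2), ">= 3")
  expect_error(geometry("ellipsoid", axes = c(1, 2, 3)), "revolution")
  tab <- tiny_table(1, 3)
  pos <- matrix(c(0, 0, 0, 1, 0, 0, NA, 0, 0), 3, byrow = TRUE)
  expect_error(total_forces(pos, tab, NULL, geometry("sphere", 5),
                            force_field()), "monomer id 2")
})
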
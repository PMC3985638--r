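test_that("the effective radial coordinate reduces to |r| in spheres", {
  geo <- geometry("sphere", R0 = 10)
  expect_equal(effective_radius(c(7, 0, 0), geo), 7)
  expect_equal(effective_radius(c(0, 10, 0), geo), 10)
  expect_error(effective_radius(c(20, 0, 0), geo), "outside")
})

test_that("equidistant-from-boundary points share one effective radius in spheroids", {
  ge <- geometry("ellipsoid", R0 = 10, aspect = 3)
  A <- ge$axes[[1]]; C <- ge$axes[[3]]
  expect_equal(effective_radius(c(0, 0, 0), ge), 0, tolerance = 1e-9)
  # boundary points all map to R0
  expect_equal(effective_radius(rbind(c(A, 0, 0), c(0, 0, C)), ge),
               c(10, 10), tolerance = 1e-9)
  # same inside depth along both principal directions -> same r_eff
  d <- 1.5
  r_eff <- effective_radius(rbind(c(A - d, 0, 0), c(0, 0, C - d)), ge)
  expect_equal(r_eff[1], r_eff[2], tolerance = 1e-6)
})

test_that("S(R) is a normalized density with the uniform r^2 law", {
  geo <- geometry("sphere", R0 = 10)
  n <- 100000
  pos <- random_positions_in_sphere(n, 10, seed = 44)
  kar <- karyotype("u", 1L, 1L)
  tab <- build_monomer_table(kar,
                             synthesize_gene_track(karyotype("u", 1L, 1L),
                                                   seed = 1))
  tab <- tab[rep(1, n), ]; tab$id <- seq_len(n) - 1L
  prof <- radial_S(pos, table = tab, geom = geo)
  dr <- prof$bin_hi - prof$bin_lo
  expect_equal(sum(prof$value * dr), 1, tolerance = 1e-12)
  fit <- fit_radial_power(prof)
  expect_equal(fit$slope, 2, tolerance = 0.05)
})

test_that("S(R) concentrates a thin shell into one bin and rejects empty selections", {
  geo <- geometry("sphere", R0 = 10)
  tab <- tiny_table(n = 1, len = 5)
  th <- seq(0, 2 * pi, length.out = 6)[1:5]
  pos <- cbind(5.05 * cos(th), 5.05 * sin(th), 0)
  prof <- radial_S(pos, table = tab, geom = geo, n_bins = 50)
  dr <- prof$bin_hi[1] - prof$bin_lo[1]
  hit <- which(prof$value > 0)
  expect_length(hit, 1)
  expect_equal(prof$value[hit], 1 / dr)
  expect_error(radial_S(pos, chromosomes = "nope", table = tab, geom = geo),
               "empty")
})

test_that("S(R) is invariant under global rotations in spheres", {
  geo <- geometry("sphere", R0 = 8)
  tab <- tiny_table(n = 1, len = 200)
  pos <- random_positions_in_sphere(200, 7.5, seed = 3)
  th <- 0.77
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  p1 <- radial_S(pos, table = tab, geom = geo)
  p2 <- radial_S(pos %*% t(Rz), table = tab, geom = geo)
  expect_equal(p1$value, p2$value)
})

test_that("activity profiles average T_eff per shell and rescale to (0,1)", {
  geo <- geometry("sphere", R0 = 10)
  tab <- tiny_table(n = 1, len = 100)
  # constructed two-population configuration: hot core, cold shell
  set.seed(6)
  r_in <- runif(50, 0.5, 4); r_out <- runif(50, 6, 9.5)
  dirs <- matrix(rnorm(300), 100, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pos <- dirs * c(r_in, r_out)
  tab$T_eff <- c(rep(20, 50), rep(1, 50))
  prof <- activity_profile(pos, n_bins = 10, table = tab, geom = geo)
  expect_equal(prof$value[prof$bin_hi <= 4], rep(20, 4))
  expect_equal(prof$value[prof$bin_lo >= 6], rep(1, 4))
  # empty shells are NA, not zero
  expect_true(anyNA(prof$value))
  # rescaled profile maps T_eq -> 0, T_a -> 1
  resc <- activity_profile(pos, n_bins = 10, rescale = TRUE, T_a = 20,
                           table = tab, geom = geo)
  ok <- is.finite(resc$value)
  expect_true(all(resc$value[ok] >= 0 & resc$value[ok] <= 1))
  # uniformly cold system rescales to a flat zero
  tab$T_eff <- rep(1, 100)
  flat <- activity_profile(pos, n_bins = 5, rescale = TRUE, T_a = 20,
                           table = tab, geom = geo)
  expect_equal(flat$value[is.finite(flat$value)],
               rep(0, sum(is.finite(flat$value))))
})

test_that("density profiles are normalized and weight-aware", {
  geo <- geometry("sphere", R0 = 10)
  tab <- tiny_table(n = 1, len = 2000)
  pos <- random_positions_in_sphere(2000, 10, seed = 5)
  tab$gene_content <- rep(1, 2000)
  dp <- density_profiles(pos, n_bins = 20, table = tab, geom = geo)
  dr <- dp$total$bin_hi - dp$total$bin_lo
  expect_equal(sum(dp$total$value * dr), 1, tolerance = 1e-12)
  expect_equal(sum(dp$gene$value * dr), 1, tolerance = 1e-12)
  # uniform weights: the two profiles coincide exactly
  expect_equal(dp$total$value, dp$gene$value)
  # all weight on one monomer -> a delta at its radius
  tab$gene_content <- c(rep(0, 1999), 5)
  dpw <- density_profiles(pos, n_bins = 20, table = tab, geom = geo)
  r_last <- sqrt(sum(pos[2000, ]^2))
  hit <- which(dpw$gene$value > 0)
  expect_length(hit, 1)
  expect_true(dpw$gene$bin_lo[hit] <= r_last && r_last <= dpw$gene$bin_hi[hit])
  # uniform points rise quadratically near the origin
  fit <- fit_radial_power(dp$total)
  expect_equal(fit$slope, 2, tolerance = 0.1)
})

test_that("territory index matches hand-countable configurations", {
  # a single isolated chain: all neighbours are same-chain
  tab <- tiny_table(n = 1, len = 10)
  pos <- cbind(seq(0, 4.5, by = 0.5), 0, 0)
  expect_equal(territory_index(pos, tab, R_sphere = 100), 9)
  # probe radius below the minimum pairwise distance
  expect_equal(territory_index(pos, tab, R_sphere = 0.4), 0)
  expect_error(territory_index(pos, tab, R_sphere = -1), "positive")

  # two interleaved 4-monomer chains on a unit lattice, against the
  # exhaustive double loop
  tab2 <- tiny_table(n = 2, len = 4)
  pos2 <- cbind(c(0, 1, 2, 3, 0.5, 1.5, 2.5, 3.5), 0, 0)
  for (Rs in c(0.6, 1.1, 2.1)) {
    ref <- brute_territory_index(pos2, tab2, Rs)
    expect_equal(territory_index(pos2, tab2, Rs, method = "grid"), ref)
    expect_equal(territory_index(pos2, tab2, Rs, method = "direct"), ref)
  }
})

test_that("grid-accelerated territory index equals the exhaustive loop", {
  kar <- karyotype(c("a", "b", "c"), c(100L, 80L, 70L), 1L)
  tab <- build_monomer_table(kar, synthesize_gene_track(kar, seed = 2))
  pos <- random_positions_in_sphere(250, 4, seed = 9)
  for (Rs in c(0.5, 1.5, 3)) {
    expect_equal(territory_index(pos, tab, Rs, method = "grid"),
                 territory_index(pos, tab, Rs, method = "direct"),
                 tolerance = 1e-12)
  }
  # homolog handling: copies of one chromosome count -1 under "copy"
  kar2 <- karyotype("a", 5L, 2L)
  tab2 <- build_monomer_table(kar2, synthesize_gene_track(kar2, seed = 3))
  pos2 <- rbind(cbind(1:5, 0, 0), cbind(1:5 + 0.2, 0, 0))
  expect_lt(territory_index(pos2, tab2, 0.5, homologs = "copy"), 0)
  expect_gt(territory_index(pos2, tab2, 0.5, homologs = "chromosome"), 0)
})

test_that("territory curves average frames and stay near zero at tiny radii", {
  tab <- tiny_table(n = 2, len = 20)
  frames <- array(NA_real_, c(40, 3, 3))
  set.seed(8)
  for (f in 1:3) frames[, , f] <- random_positions_in_sphere(40, 3)
  curve <- territory_curve(frames, c(0.05, 1, 2), table = tab,
                           geom = geometry("sphere", 3))
  expect_equal(nrow(curve), 3)
  expect_equal(curve$N_c[1], 0)
  expect_equal(curve$N_c[2],
               mean(vapply(1:3, function(f) {
                 brute_territory_index(frames[, , f], tab, 1)
               }, numeric(1))))
})

test_that("mean radius by group summarises segregation", {
  geo <- geometry("sphere", R0 = 10)
  tab <- tiny_table(n = 1, len = 4)
  tab$activity_class <- c("active", "active", "inactive", "inactive")
  pos <- rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 5), c(7, 0, 0))
  m <- mean_radius_by(pos, table = tab, geom = geo)
  expect_equal(unname(m["active"]), 1.5)
  expect_equal(unname(m["inactive"]), 6)
})
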
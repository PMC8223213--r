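# Centers of mass, periodic distances, leaflets and surface distance.

test_that("molecule COM handles weighting and periodic unwrap", {
  topo <- topology(1:2, c(1, 1), c("CM15", "CM15"))
  fr <- make_frame(c(0, 0, 0, 1, 0, 0))
  expect_equal(molecule_com(fr, topo, 1), c(0.5, 0, 0))

  # particles straddling the boundary: unwrap 0.2 -> 10.2, mean 10.0,
  # wrap back to 0.0
  fr2 <- make_frame(c(9.8, 0, 0, 0.2, 0, 0))
  expect_equal(molecule_com(fr2, topo, 1), c(0, 0, 0))

  topo_w <- topology(1:2, c(1, 1), c("CM15", "CM15"), mass = c(1, 3))
  fr3 <- make_frame(c(0, 0, 0, 1, 0, 0))
  expect_equal(molecule_com(fr3, topo_w, 1, weighting = "mass"),
               c(0.75, 0, 0))
  # geometric weighting ignores the masses
  expect_equal(molecule_com(fr3, topo_w, 1), c(0.5, 0, 0))
})

test_that("a molecule spanning more than half the box is rejected", {
  topo <- topology(1:2, c(1, 1), c("CM15", "CM15"))
  fr <- make_frame(c(0, 0, 0, 4.9, 0, 0))  # unwrapped span 4.9 < 5: fine
  expect_silent(molecule_com(fr, topo, 1))
  # three particles whose whole-molecule extent exceeds box/2
  topo3 <- topology(1:3, c(1, 1, 1), rep("CM15", 3))
  fr3 <- make_frame(c(0, 0, 0, 3, 0, 0, 6.2, 0, 0))
  expect_error(molecule_com(fr3, topo3, 1), "half the box")
})

test_that("COM distance matrix respects the pbc mode", {
  cs <- make_comset(c(1, 0, 0, 4, 0, 0))
  d <- com_distance_matrix(cs)
  expect_equal(d[1, 2], 3)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(0, 0), ignore_attr = TRUE)

  cs2 <- make_comset(c(1, 0, 0, 9, 0, 0))
  expect_equal(com_distance_matrix(cs2)[1, 2], 2)  # wraparound
  cs3 <- make_comset(c(1, 0, 0, 9, 0, 0), pbc_mode = "none")
  expect_equal(com_distance_matrix(cs3)[1, 2], 8)

  expect_error(com_distance_matrix(make_comset(c(1, 1, 1))), "2 molecules")
})

test_that("distances are invariant under integer-box translations", {
  set.seed(42)
  box <- c(8, 10, 12)
  for (rep in 1:5) {
    pts <- matrix(runif(30, 0, 8), ncol = 3)
    shift <- matrix(rep(sample(-3:3, 3, replace = TRUE) * box, each = 10),
                    ncol = 3)
    cs <- make_comset(t(t(pts)), box = box)
    cs$points <- pts
    cs_s <- cs; cs_s$points <- pts + shift
    expect_lt(max(abs(com_distance_matrix(cs) - com_distance_matrix(cs_s))),
              1e-9)
    # minimum-image distance never exceeds half the box diagonal
    expect_lte(max(com_distance_matrix(cs)), sqrt(sum((box / 2)^2)))
  }
})

test_that("leaflet assignment splits a slab and reports phosphorus z-COMs", {
  n <- 64
  topo <- make_topo(0, 0, n_lip = 2 * n)
  coords <- cbind(runif(2 * n, 0, 10), runif(2 * n, 0, 10),
                  rep(c(6, 2), each = n))
  fr <- frame(1, 0, c(10, 10, 10), coords)
  bl <- assign_leaflets(fr, topo)
  expect_equal(sum(bl$leaflet == "top"), n)
  expect_equal(sum(bl$leaflet == "bottom"), n)
  expect_equal(bl$z_top, 6)
  expect_equal(bl$z_bottom, 2)

  # one lipid perturbed from 6.0 to 6.3: top z-COM = (63*6.0 + 6.3)/64
  coords2 <- coords
  coords2[1, 3] <- 6.3
  bl2 <- assign_leaflets(frame(1, 0, c(10, 10, 10), coords2), topo)
  expect_equal(bl2$z_top, (63 * 6.0 + 6.3) / 64)

  # a lipid exactly at the midplane z-COM goes to the top leaflet
  topo3 <- make_topo(0, 0, n_lip = 3)
  fr3 <- make_frame(c(1, 1, 6, 2, 2, 2, 3, 3, 4), box = c(10, 10, 10))
  bl3 <- assign_leaflets(fr3, topo3)  # z-COM = 4; lipid 3 is at 4
  expect_equal(unname(bl3$leaflet[3]), "top")

  # all lipids at one height is not a bilayer
  fr4 <- frame(1, 0, c(10, 10, 10), cbind(runif(3), runif(3), 5))
  expect_error(assign_leaflets(fr4, topo3), "leaflet")
})

test_that("surface distance is the closed-form minimum over leaflets", {
  topo <- make_topo(0, 0, n_lip = 4)
  fr <- make_frame(c(1, 1, 2, 2, 2, 2, 3, 3, 6, 4, 4, 6))
  bl <- assign_leaflets(fr, topo)
  expect_equal(surface_distance(bl, 7), 1)
  expect_equal(surface_distance(bl, 6), 0)   # exactly at the top leaflet
  expect_equal(surface_distance(bl, 4), 2)   # midplane symmetry
  expect_equal(surface_distance(bl, c(7, 6, 4)), c(1, 0, 2))
  expect_true(all(surface_distance(bl, runif(20, -5, 15)) >= 0))
})

test_that("k-closest group distances rank per-molecule minima", {
  # three single-particle "choline" molecules at 0.5, 1.0, 2.0 nm from a
  # one-particle reference group
  topo <- make_topo(1, 3)
  fr <- make_frame(c(5, 5, 5, 5.5, 5, 5, 6, 5, 5, 7, 5, 5))
  ga <- select_particles(topo, species = "CM15")
  gb <- select_particles(topo, species = "SUR")
  expect_equal(unname(k_closest_group_distances(fr, topo, ga, gb, 3)),
               c(0.5, 1.0, 2.0))
  expect_error(k_closest_group_distances(fr, topo, ga, gb, 4),
               "exceeds")

  # minimum-image: nearest molecule sits 0.2 nm away across the boundary
  fr2 <- make_frame(c(0.1, 5, 5, 9.9, 5, 5, 3, 5, 5, 4, 5, 5))
  expect_equal(unname(k_closest_group_distances(fr2, topo, ga, gb, 1)),
               0.2)

  # two-frame series: rank-1 distances 0.4 and 0.6 -> mean 0.5, population
  # STD 0.1
  topo2 <- make_topo(1, 1)
  frames <- list(make_frame(c(5, 5, 5, 5.4, 5, 5), time = 0),
                 make_frame(c(5, 5, 5, 5.6, 5, 5), index = 2, time = 1))
  bun <- bundle(frames, topo2)
  st <- k_closest_series(bun, select_particles(topo2, species = "CM15"),
                         select_particles(topo2, species = "SUR"), 1)
  expect_equal(st$mean_nm, 0.5)
  expect_equal(st$sd_nm, 0.1)
  st2 <- k_closest_series(bun, select_particles(topo2, species = "CM15"),
                          select_particles(topo2, species = "SUR"), 1,
                          sd_convention = "sample")
  expect_equal(st2$sd_nm, sd(c(0.4, 0.6)))
})
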
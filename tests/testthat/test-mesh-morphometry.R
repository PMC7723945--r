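# Registration -------------------------------------------------------------

test_that("ICP on identical meshes returns the identity with zero residual", {
  ph <- small_plate()
  tf <- icp_register(ph$bone, ph$bone)
  expect_transform_equal(tf, rigid_transform(), tol = 1e-9)
  expect_lt(attr(tf, "rms"), 1e-9)
  expect_true(attr(tf, "converged"))
})

test_that("ICP recovers the inverse of known rigid motions", {
  ph <- small_plate(extent = c(20, 10), spacing = 0.5)
  # pure translation
  tf <- rigid_transform(diag(3), c(1.0, -0.5, 2.0))
  est <- icp_register(apply_transform(tf, ph$bone), ph$bone)
  expect_lt(max(abs(est$translation - c(-1.0, 0.5, -2.0))), 1e-3)
  expect_lt(max(abs(est$rotation - diag(3))), 1e-4)
  # rotation + translation: composition with the applied motion ~ identity
  cases <- list(
    rigid_transform(rotation_about("z", 5), c(1, 0, 0)),
    rigid_transform(rotation_about("x", -8) %*% rotation_about("z", 3),
                    c(2, -1, 0.5)))
  for (tf in cases) {
    est <- icp_register(apply_transform(tf, ph$bone), ph$bone)
    comp <- compose_transforms(est, tf)
    expect_lt(max(abs(comp$rotation - diag(3))), 1e-3)
    expect_lt(max(abs(comp$translation)), 1e-3)
    expect_lt(attr(est, "rms"), 1e-3)
  }
})

test_that("registration never worsens the residual and rejects empty input", {
  ph <- small_plate()
  moved <- apply_transform(
    rigid_transform(rotation_about("z", 30), c(8, 8, 0)), ph$bone)
  pre_rms <- sqrt(mean(nodewise_thickness(moved, ph$bone)^2))
  tf <- icp_register(moved, ph$bone, max_iter = 3)
  expect_lte(attr(tf, "rms"), pre_rms)
  expect_error(icp_register(list(), ph$bone), "surface_mesh")
})

# Thickness ----------------------------------------------------------------

test_that("parallel plates give uniform node-to-node thickness", {
  ph <- small_plate(gap = 3)
  th <- nodewise_thickness(ph$cartilage, ph$bone)
  expect_equal(th, rep(3, nrow(ph$cartilage$vertices)), tolerance = 1e-12)
  # single cartilage node vs single bone node: plain Euclidean distance
  expect_equal(nodewise_thickness(matrix(c(0, 0, 2.5), 1),
                                  matrix(0, 1, 3)), 2.5)
  expect_error(nodewise_thickness(ph$cartilage, matrix(0, 0, 3)), "empty")
})

test_that("paraboloid phantom matches its closed-form thickness field", {
  ph <- small_paraboloid(spacing = 0.5)
  th <- nodewise_thickness(ph$cartilage, ph$bone)
  truth <- ph$truth$thickness_mm
  # error bounded by one bone-mesh vertex spacing (here it is exact)
  expect_lt(max(abs(th - truth)), 0.5)
  expect_equal(th, truth, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("thickness is invariant under a common rigid motion", {
  ph <- small_paraboloid(spacing = 1)
  tf <- rigid_transform(rotation_about("y", 23) %*% rotation_about("z", -7),
                        c(4, -2, 11))
  th0 <- nodewise_thickness(ph$cartilage, ph$bone)
  th1 <- nodewise_thickness(apply_transform(tf, ph$cartilage),
                            apply_transform(tf, ph$bone))
  expect_lt(max(abs(th1 - th0)), 1e-9)
})

# Sampling grid ------------------------------------------------------------

test_that("grid sites fall at 25/50/75% of each plateau's bounding box", {
  ph <- small_plate(extent = c(40, 20), gap = 3, spacing = 1, jitter = 0)
  grid <- build_sampling_grid(ph$cartilage, split_axis = "x")
  med <- grid$sites[grid$sites$plateau == "medial", ]
  lat <- grid$sites[grid$sites$plateau == "lateral", ]
  expect_setequal(round(med$x, 9), c(5, 10, 15))
  expect_setequal(round(med$y, 9), c(5, 10, 15))
  expect_setequal(round(lat$x, 9), c(25, 30, 35))
  expect_equal(nrow(med), 9)
  expect_equal(nrow(lat), 9)
  # deterministic: same mesh, same grid
  expect_identical(build_sampling_grid(ph$cartilage)$sites, grid$sites)
})

test_that("grid construction is equivariant under reflection", {
  ph <- small_paraboloid(spacing = 1)
  g0 <- build_sampling_grid(ph$cartilage)
  mirrored <- ph$cartilage
  mirrored$vertices[, 1] <- -mirrored$vertices[, 1]
  g1 <- build_sampling_grid(mirrored)
  expect_equal(sort(-g1$sites$x), sort(g0$sites$x), tolerance = 1e-9)
  expect_equal(sort(g1$sites$y), sort(g0$sites$y), tolerance = 1e-9)
  expect_error(build_sampling_grid(
    surface_mesh(cbind(0, 0:2, 0), label = "cartilage")), "degenerate")
})

# Site averaging -----------------------------------------------------------

test_that("site averaging equals the brute-force neighborhood mean", {
  ph <- small_paraboloid(spacing = 0.5)
  # thickness linear in x: makes the neighborhood mean non-trivial
  v <- ph$cartilage$vertices
  th <- 1 + 0.1 * v[, 1]
  grid <- build_sampling_grid(ph$cartilage, radius = 2.5)
  got <- site_thickness(th, ph$cartilage, grid)
  for (i in seq_len(nrow(grid$sites))) {
    s <- grid$sites[i, ]
    d <- sqrt((v[, 1] - s$x)^2 + (v[, 2] - s$y)^2 + (v[, 3] - s$z)^2)
    sel <- d <= 2.5
    expect_identical(got$n_nodes[i], sum(sel))
    expect_identical(got$thickness_mm[i], mean(th[sel]))
  }
})

test_that("uniform thickness reports uniformly; empty neighborhoods flag missing", {
  ph <- small_plate(gap = 2, extent = c(40, 20), spacing = 1)
  grid <- build_sampling_grid(ph$cartilage)
  st <- site_thickness(rep(2, nrow(ph$cartilage$vertices)),
                       ph$cartilage, grid)
  expect_true(all(!st$missing))
  expect_equal(st$thickness_mm, rep(2, 18))
  expect_equal(mean_site_thickness(st), 2)
  # radius below vertex spacing, sites off-lattice: all sites miss
  off <- grid$sites
  off$x <- off$x + 0.37; off$y <- off$y + 0.29; off$z <- off$z + 0.11
  tiny <- sampling_grid(off, radius = 0.05)
  st2 <- site_thickness(rep(2, nrow(ph$cartilage$vertices)),
                        ph$cartilage, tiny)
  expect_true(all(st2$missing))
  expect_true(all(is.na(st2$thickness_mm)))
  expect_true(is.na(mean_site_thickness(st2)))
})

test_that("repeat scans with different tessellations agree to under 1%", {
  # same geometry meshed at two densities: the Eq.-3-style percent
  # difference of mean site thickness gauges technique repeatability
  a <- small_paraboloid(spacing = 0.5)
  b <- small_paraboloid(spacing = 0.4)
  grid <- build_sampling_grid(a$cartilage)
  ha <- mean_site_thickness(
    site_thickness(nodewise_thickness(a$cartilage, a$bone), a$cartilage,
                   grid))
  hb <- mean_site_thickness(
    site_thickness(nodewise_thickness(b$cartilage, b$bone), b$cartilage,
                   grid))
  expect_lt(abs(thickness_difference(ha, hb)), 1)
})
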
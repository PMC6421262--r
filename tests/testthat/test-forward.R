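test_that("total solid angle is 4*pi inside, 0 outside, scale-invariant", {
  h <- generate_heart(n_subdiv = 2, seed = 1)
  # a point inside the myocardial wall: midpoint of a transmural connector
  conn <- h$edges[h$edges$transmural, ][5, ]
  inside <- (h$mesh$vertices[conn$i, ] + h$mesh$vertices[conn$j, ]) / 2
  expect_equal(total_solid_angle(h$mesh, inside), 4 * pi, tolerance = 1e-10)
  expect_lt(abs(total_solid_angle(h$mesh, c(400, -250, 300))), 1e-10)
  # the blood-cavity side is outside the closed wall surface
  expect_lt(abs(total_solid_angle(h$mesh, c(0, 0, -40))), 1e-10)

  # doubling all coordinates leaves the solid angles unchanged
  h2 <- h
  h2$mesh$vertices <- 2 * h$mesh$vertices
  expect_equal(total_solid_angle(h2$mesh, 2 * inside), 4 * pi,
               tolerance = 1e-10)
})

test_that("lumped lead field is scale-invariant and electrodes are validated", {
  h <- generate_heart(n_subdiv = 1, seed = 2)
  to <- generate_torso(h, 16, 40, seed = 3)
  A <- solid_angle_transfer(h, to)
  expect_true(all(is.finite(A$A)))

  # scaling geometry: the area-weighted lead field (pure solid angle) is
  # unchanged even though the per-unit-area entries rescale
  h2 <- generate_heart(n_subdiv = 1, seed = 2)
  h2$mesh$vertices <- 2 * h2$mesh$vertices
  h2$node_areas <- vertex_areas(h2$mesh)
  to2 <- to
  to2$electrodes <- 2 * to$electrodes
  A2 <- solid_angle_transfer(h2, to2)
  Aw1 <- sweep(A$A, 2, h$node_areas, "*")
  Aw2 <- sweep(A2$A, 2, h2$node_areas, "*")
  expect_equal(Aw2, Aw1, tolerance = 1e-10)

  # electrode on the surface: singular, rejected naming the node
  bad <- to
  bad$electrodes[1, ] <- h$mesh$vertices[7, ]
  expect_error(solid_angle_transfer(h, bad), "node 7")
  # electrode inside the heart wall: rejected
  conn <- h$edges[h$edges$transmural, ][2, ]
  bad2 <- to
  bad2$electrodes[1, ] <- (h$mesh$vertices[conn$i, ] +
                           h$mesh$vertices[conn$j, ]) / 2
  expect_error(solid_angle_transfer(h, bad2), "inside")
})

test_that("closed fully-on dipole layer produces no external field", {
  h <- generate_heart(n_subdiv = 2, seed = 1)
  to <- generate_torso(h, 32, 40, seed = 2)
  A <- solid_angle_transfer(h, to)
  # area-weighted row sums ~ 0
  expect_lt(max(abs(A$A %*% h$node_areas)), 1e-12)

  tm <- compute_times_matrix(build_conduction_graph(h, 0.8))
  act <- activation_from_focus(tm, 25)
  Y <- simulate_bspm(A, act, h$node_areas, dt = 1)
  ratio <- max(abs(Y$Y[, ncol(Y$Y)])) / max(abs(Y$Y))
  expect_lt(ratio, 1e-6)
})

test_that("BSPM synthesis matches the direct Heaviside superposition", {
  h <- generate_heart(n_subdiv = 1, seed = 3)
  to <- generate_torso(h, 8, 40, seed = 4)
  A <- solid_angle_transfer(h, to)
  n <- nrow(h$mesh$vertices)
  set.seed(5)
  tau <- c(0, runif(n - 1, 0.5, 60))
  act <- make_activation(tau)
  dt <- 2
  Y <- simulate_bspm(A, act, h$node_areas, dt = dt)
  # independent direct evaluation: Y[, k] = Aw %*% (tau <= t_k), H(0) = 1
  Aw <- sweep(A$A, 2, h$node_areas, "*")
  tgrid <- (seq_len(ncol(Y$Y)) - 1) * dt
  direct <- sapply(tgrid, function(t) Aw %*% (tau <= t + 1e-9))
  expect_equal(Y$Y, direct, tolerance = 1e-9)

  # single activated node at t = 0: first column is its weighted lead field
  one <- make_activation(c(0, rep(50, n - 1)), focus = 1L)
  Y1 <- simulate_bspm(A, one, h$node_areas, dt = 1)
  expect_equal(Y1$Y[, 1], A$A[, 1] * h$node_areas[1], tolerance = 1e-12)

  # columns before the first activation are zero
  late <- make_activation(c(5, rep(50, n - 1)), focus = 1L)
  Y2 <- simulate_bspm(A, late, h$node_areas, dt = 1)
  expect_true(all(Y2$Y[, 1:5] == 0))
  expect_false(all(Y2$Y[, 6] == 0))

  # truncated span is rejected
  expect_error(simulate_bspm(A, act, h$node_areas, dt = 1, span = 10),
               "truncated")
})

test_that("the indicator-to-potential map is linear", {
  h <- generate_heart(n_subdiv = 1, seed = 3)
  to <- generate_torso(h, 8, 40, seed = 4)
  A <- solid_angle_transfer(h, to)
  Aw <- sweep(A$A, 2, h$node_areas, "*")
  n <- ncol(Aw)
  set.seed(6)
  for (k in 1:5) {
    S1 <- matrix(rbinom(n * 10, 1, 0.4), n)
    S2 <- matrix(rbinom(n * 10, 1, 0.4), n)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(Aw %*% (a * S1 + b * S2),
                 a * (Aw %*% S1) + b * (Aw %*% S2), tolerance = 1e-9)
  }
})

test_that("lead field converges under mesh refinement (logged)", {
  # relative change of the potential at a fixed electrode between
  # successive refinements; reported, asserted only loosely
  e <- matrix(c(150, 40, -30), 1)
  vals <- sapply(2:4, function(ns) {
    h <- generate_heart(n_subdiv = ns, seed = 1)
    tm <- compute_times_matrix(build_conduction_graph(h, 0.8))
    A <- solid_angle_transfer(h, e)
    f <- which.min(rowSums(sweep(h$mesh$vertices,
                                 2, c(0, 25, -45))^2))
    Y <- simulate_reference_bspm(h, A, tm, f, dt = 2, n_samples = 60)
    max(abs(Y$Y))
  })
  rel <- abs(diff(vals)) / vals[-1]
  message(sprintf("lead-field refinement relative changes: %s",
                  paste(signif(rel, 3), collapse = ", ")))
  expect_lt(rel[2], 0.25)
})

test_that("bounded-conductor correction: null field, gauge, infinite limit", {
  h <- generate_heart(n_subdiv = 2, seed = 3)
  to <- generate_torso(h, 32, 40, seed = 4, mesh = TRUE)
  A <- solid_angle_transfer(h, to)
  Ab <- bounded_torso_correction(A, h, to)
  expect_identical(Ab$medium, "bounded-homogeneous")

  # zero-mean gauge per source column
  expect_lt(max(abs(colMeans(Ab$A))), 1e-15)

  # fully activated heart: potentials ~ 0 relative to the map peak
  full <- Ab$A %*% h$node_areas
  tm <- compute_times_matrix(build_conduction_graph(h, 0.8))
  Yb <- simulate_bspm(Ab, activation_from_focus(tm, 10), h$node_areas, dt = 2)
  expect_lt(max(abs(full)) / max(abs(Yb$Y)), 1e-6)

  # very large torso with electrodes fixed near the heart: approaches the
  # infinite-medium lead field (compared in the same zero-mean gauge)
  near <- generate_torso(h, 16, 40, seed = 5)
  big <- generate_torso(h, 16, 2000, seed = 6, mesh = TRUE,
                        n_lat = 16, n_lon = 32)
  big$electrodes <- near$electrodes
  A_inf <- solid_angle_transfer(h, near)
  Ab2 <- bounded_torso_correction(A_inf, h, big)
  ref <- sweep(A_inf$A, 2, colMeans(A_inf$A))
  expect_lt(max(abs(Ab2$A - ref)) / max(abs(ref)), 1e-3)

  # open torso surface is rejected
  open <- to
  open$mesh$triangles <- open$mesh$triangles[-1, ]
  expect_error(bounded_torso_correction(A, h, open), "closed")
  expect_error(bounded_torso_correction(A, h, generate_torso(h, 8, 40)),
               "no surface mesh")
})

test_that("electrodes snap to coincident torso vertices with a message", {
  h <- generate_heart(n_subdiv = 1, seed = 3)
  to <- generate_torso(h, 8, 40, seed = 4, mesh = TRUE)
  to$electrodes <- to$mesh$vertices[c(5, 50, 100, 150), ]
  A <- solid_angle_transfer(h, to)
  expect_message(Ab <- bounded_torso_correction(A, h, to), "snapped")
  expect_true(all(is.finite(Ab$A)))
})
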
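test_that("generated hearts are closed genus-0 outward-oriented surfaces", {
  h <- generate_heart(n_subdiv = 3, long_axis = 90, short_axis = 50,
                      wall_thickness = 10, seed = 1)
  expect_true(is_closed_mesh(h$mesh))
  expect_identical(mesh_euler_characteristic(h$mesh), 2L)
  expect_gt(mesh_signed_volume(h$mesh), 0)
  expect_setequal(unique(h$mesh$labels), c("epi", "endo", "unlabeled"))

  # deleting one triangle breaks closedness
  broken <- h$mesh
  broken$triangles <- broken$triangles[-1, ]
  expect_false(is_closed_mesh(broken))
})

test_that("heart generation is deterministic and rejects degenerate axes", {
  h1 <- generate_heart(n_subdiv = 2, seed = 42)
  h2 <- generate_heart(n_subdiv = 2, seed = 42)
  expect_identical(h1$mesh$vertices, h2$mesh$vertices)
  expect_identical(h1$mesh$triangles, h2$mesh$triangles)
  h3 <- generate_heart(n_subdiv = 2, seed = 43)
  expect_false(identical(h1$mesh$vertices, h3$mesh$vertices))

  expect_error(generate_heart(short_axis = 18, wall_thickness = 10),
               "degenerate")
  expect_error(generate_heart(long_axis = 5, wall_thickness = 10),
               "degenerate")
  expect_error(generate_heart(wall_thickness = 0), "wall_thickness")
})

test_that("node area weights are barycentric and conserve total area", {
  h <- generate_heart(n_subdiv = 2, seed = 1)
  mesh <- h$mesh
  expect_true(all(h$node_areas > 0))
  expect_equal(sum(h$node_areas), sum(triangle_areas(mesh)), tolerance = 1e-12)
  # independent recomputation: one third of incident triangle areas
  ta <- triangle_areas(mesh)
  manual <- numeric(nrow(mesh$vertices))
  for (t in seq_len(nrow(mesh$triangles)))
    for (v in mesh$triangles[t, ])
      manual[v] <- manual[v] + ta[t] / 3
  expect_equal(h$node_areas, manual, tolerance = 1e-12)
})

test_that("transmural edges only join epi- and endo-labeled vertices", {
  h <- generate_heart(n_subdiv = 2, seed = 5)
  tr <- h$edges[h$edges$transmural, ]
  lab <- h$mesh$labels
  expect_gt(nrow(tr), 0)
  expect_true(all((lab[tr$i] == "epi" & lab[tr$j] == "endo") |
                  (lab[tr$i] == "endo" & lab[tr$j] == "epi")))
  # edge lengths match the vertex coordinates
  len <- sqrt(rowSums((h$mesh$vertices[h$edges$i, ] -
                       h$mesh$vertices[h$edges$j, ])^2))
  expect_equal(h$edges$length, len, tolerance = 1e-12)
})

test_that("geodesic distances match exhaustive Bellman-Ford and are metric", {
  h <- generate_heart(n_subdiv = 1, seed = 7)   # 68 nodes
  n <- nrow(h$mesh$vertices)
  surf <- h$edges[!h$edges$transmural, ]
  eo <- data.frame(i = surf$i, j = surf$j, w = surf$length)

  set.seed(1)
  for (src in sample(n, 4)) {
    expect_equal(geodesic_from(h, src), bellman_ford(n, eo, src),
                 tolerance = 1e-10)
  }

  expect_identical(geodesic_distance(h, 5, 5), 0)
  e1 <- surf[3, ]
  expect_equal(geodesic_distance(h, e1$i, e1$j), e1$length, tolerance = 1e-12)
  # geodesic >= euclidean
  set.seed(2)
  for (k in 1:10) {
    ij <- sample(n, 2)
    eu <- sqrt(sum((h$mesh$vertices[ij[1], ] - h$mesh$vertices[ij[2], ])^2))
    expect_gte(geodesic_distance(h, ij[1], ij[2]), eu - 1e-9)
  }

  # exhaustive triangle inequality on the full distance matrix
  D <- t(vapply(seq_len(n), function(v) geodesic_from(h, v), numeric(n)))
  for (k in seq_len(n))
    expect_true(all(D <= outer(D[, k], D[k, ], "+") + 1e-9))
  # symmetry
  expect_equal(D, t(D), tolerance = 1e-12)
})

test_that("epi-to-endo geodesics route through the rim, not the wall", {
  h <- generate_heart(n_subdiv = 2, seed = 1)
  # an epi vertex near the apex and its transmural partner on the endo side
  conn <- h$edges[h$edges$transmural, ]
  k <- which.min(h$mesh$vertices[conn$i, 3])
  i <- conn$i[k]; j <- conn$j[k]
  d <- geodesic_distance(h, i, j)
  expect_true(is.finite(d))
  # much longer than the direct wall crossing excluded from the path
  expect_gt(d, 3 * conn$length[k])
})

test_that("unreachable vertices are signalled", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0), c(11, 0, 0))
  h <- toy_heart(pos, data.frame(i = c(1, 3), j = c(2, 4),
                                 transmural = FALSE))
  expect_warning(d <- geodesic_distance(h, 1, 3), "unreachable")
  expect_identical(d, Inf)
})

test_that("torso electrodes are quasi-uniform, outside the heart, deterministic", {
  h <- generate_heart(n_subdiv = 2, seed = 1)
  t240 <- generate_torso(h, n_electrodes = 240, standoff = 40, seed = 3)
  expect_identical(nrow(t240$electrodes), 240L)
  expect_true(all(abs(total_solid_angle(h$mesh, t240$electrodes)) < 1e-6))

  t2 <- generate_torso(h, n_electrodes = 2, standoff = 40, seed = 3)
  expect_identical(nrow(t2$electrodes), 2L)

  ta <- generate_torso(h, 32, 40, seed = 9)
  tb <- generate_torso(h, 32, 40, seed = 9)
  expect_identical(ta$electrodes, tb$electrodes)

  expect_error(generate_torso(h, 1, 40), "n_electrodes")
  expect_error(generate_torso(h, 32, 0), "standoff")
})

test_that("torso surface mesh is closed and encloses the heart", {
  h <- generate_heart(n_subdiv = 1, seed = 2)
  to <- generate_torso(h, 16, 40, seed = 2, mesh = TRUE)
  expect_true(is_closed_mesh(to$mesh))
  expect_identical(mesh_euler_characteristic(to$mesh), 2L)
  expect_gt(mesh_signed_volume(to$mesh), 0)
  w <- total_solid_angle(to$mesh, h$mesh$vertices)
  expect_true(all(abs(w - 4 * pi) < 1e-6))
  # projected electrodes sit on the faceted surface
  w_e <- total_solid_angle(h$mesh, to$electrodes)
  expect_true(all(abs(w_e) < 1e-6))
})
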
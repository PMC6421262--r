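# Independent oracles and small fixture builders used across the suite.

# exhaustive Bellman-Ford relaxation over an undirected weighted edge list
bellman_ford <- function(n, edges, src) {
  d <- rep(Inf, n)
  d[src] <- 0
  for (iter in seq_len(n)) {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      i <- edges$i[k]; j <- edges$j[k]; w <- edges$w[k]
      if (is.finite(d[i]) && d[i] + w < d[j]) { d[j] <- d[i] + w; changed <- TRUE }
      if (is.finite(d[j]) && d[j] + w < d[i]) { d[i] <- d[j] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# independent all-pairs Floyd-Warshall
floyd_warshall <- function(n, edges, w = edges$w) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    D[edges$i[k], edges$j[k]] <- min(D[edges$i[k], edges$j[k]], w[k])
    D[edges$j[k], edges$i[k]] <- D[edges$i[k], edges$j[k]]
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# minimal heart_model over explicit node positions and an edge list
# (edges: data.frame with i, j, transmural); lengths from the positions
toy_heart <- function(positions, edges, labels = NULL) {
  positions <- as.matrix(positions)
  if (is.null(labels)) labels <- rep("unlabeled", nrow(positions))
  mesh <- structure(list(vertices = positions,
                         triangles = matrix(integer(0), 0, 3),
                         labels = labels),
                    class = "triangle_mesh")
  len <- sqrt(rowSums((positions[edges$i, , drop = FALSE] -
                       positions[edges$j, , drop = FALSE])^2))
  structure(list(mesh = mesh, node_areas = rep(1, nrow(positions)),
                 edges = data.frame(i = edges$i, j = edges$j, length = len,
                                    transmural = edges$transmural)),
            class = "heart_model")
}

# connected random graph as a toy heart: a random spanning tree plus extras
random_toy_heart <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  pos <- matrix(runif(3 * n, 0, 100), n, 3)
  e <- data.frame(i = integer(0), j = integer(0))
  for (v in 2:n) e <- rbind(e, data.frame(i = sample(v - 1L, 1), j = v))
  for (k in seq_len(extra)) {
    ij <- sort(sample(n, 2))
    e <- rbind(e, data.frame(i = ij[1], j = ij[2]))
  }
  e <- e[!duplicated(e), ]
  e$transmural <- FALSE
  toy_heart(pos, e)
}

# build an activation_sequence directly from times
make_activation <- function(tau, focus = which.min(tau)[1]) {
  structure(list(tau = tau, focus = focus), class = "activation_sequence")
}

# small self-consistent localization setup shared by inverse-search tests
small_setup <- function(n_subdiv = 2, n_electrodes = 32, seed = 3) {
  heart <- generate_heart(n_subdiv = n_subdiv, seed = seed)
  torso <- generate_torso(heart, n_electrodes = n_electrodes, standoff = 40,
                          seed = seed + 1)
  A <- solid_angle_transfer(heart, torso)
  times <- compute_times_matrix(build_conduction_graph(heart, 0.8))
  list(heart = heart, torso = torso, A = A, times = times)
}
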
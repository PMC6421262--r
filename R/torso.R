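# Moeller-Trumbore ray/triangle intersection: scale points radially from
# `center` so they land exactly on the triangulated surface; also reports
# which facet each point hit
project_radially_to_mesh <- function(mesh, center, points) {
  v <- mesh$vertices
  tri <- mesh$triangles
  v0 <- v[tri[, 1], , drop = FALSE]
  e1 <- v[tri[, 2], , drop = FALSE] - v0
  e2 <- v[tri[, 3], , drop = FALSE] - v0
  out <- points
  facet <- integer(nrow(points))
  for (p in seq_len(nrow(points))) {
    d <- points[p, ] - center
    d <- d / sqrt(sum(d^2))
    pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
                d[3] * e2[, 1] - d[1] * e2[, 3],
                d[1] * e2[, 2] - d[2] * e2[, 1])
    det <- rowSums(e1 * pv)
    tv <- matrix(center, nrow(v0), 3, byrow = TRUE) - v0
    u <- rowSums(tv * pv) / det
    qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
                tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
                tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
    w <- (qv %*% d) / det
    tt <- rowSums(qv * e2) / det
    hit <- abs(det) > 1e-12 & u >= -1e-9 & w >= -1e-9 & (u + w) <= 1 + 1e-9 & tt > 0
    if (!any(hit)) stop("electrode ray misses the torso surface")
    k <- which(hit)[which.min(tt[hit])]
    out[p, ] <- center + tt[k] * d
    facet[p] <- k
  }
  list(points = out, facet = facet)
}

# quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2 / 1  # golden-angle increments
  cbind(r * cos(phi), r * sin(phi), z)
}

# seeded random rotation (QR of a Gaussian matrix, determinant +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  q <- q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# closed UV ellipsoid mesh (two poles + latitude rings), outward oriented
ellipsoid_mesh <- function(center, semi, n_lat = 12L, n_lon = 24L) {
  th <- seq_len(n_lat - 1L) * pi / n_lat
  phi <- 2 * pi * (0:(n_lon - 1)) / n_lon
  rings <- lapply(th, function(t)
    cbind(semi[1] * sin(t) * cos(phi),
          semi[2] * sin(t) * sin(phi),
          semi[3] * cos(t)))
  v <- rbind(c(0, 0, semi[3]), do.call(rbind, rings), c(0, 0, -semi[3]))
  v <- sweep(v, 2, center, "+")
  npole <- 1L
  spole <- nrow(v)
  ring_idx <- function(i) 1L + (i - 1L) * n_lon + (1:n_lon)
  jn <- c(2:n_lon, 1)
  tris <- list(cbind(npole, ring_idx(1L), ring_idx(1L)[jn]))
  if (n_lat > 2L) for (i in seq_len(n_lat - 2L)) {
    lo <- ring_idx(i); hi <- ring_idx(i + 1L)
    tris[[length(tris) + 1]] <- rbind(cbind(lo, lo[jn], hi[jn]),
                                      cbind(lo, hi[jn], hi))
  }
  last <- ring_idx(n_lat - 1L)
  tris[[length(tris) + 1]] <- cbind(spole, last[jn], last)
  orient_mesh(triangle_mesh(v, do.call(rbind, tris)))
}

#' Synthetic torso electrode array
#'
#' Places `n_electrodes` quasi-uniformly (Fibonacci lattice with a seeded
#' random rotation) on an ellipsoid enclosing the heart at `standoff`
#' distance beyond the heart's bounding half-widths along each axis, and
#' optionally builds a closed torso-surface mesh on the same ellipsoid for
#' bounded-conductor (BEM) calculations.
#'
#' @param heart a [generate_heart()] model (or any `heart_model`).
#' @param n_electrodes integer >= 2 (clinical arrays use up to 240).
#' @param standoff distance margin (mm), > 0.
#' @param seed integer seed controlling the lattice rotation.
#' @param mesh logical: also triangulate the torso surface.
#' @param n_lat,n_lon torso mesh resolution.
#' @return an object of class `torso_model` with `electrodes`
#'   (P x 3 matrix, mm) and optionally `mesh` (a [triangle_mesh()]).
#' @export
generate_torso <- function(heart, n_electrodes = 64L, standoff = 40,
                           seed = 1L, mesh = FALSE,
                           n_lat = 12L, n_lon = 24L) {
  n_electrodes <- as.integer(n_electrodes)
  if (n_electrodes < 2L) stop("n_electrodes must be >= 2")
  if (!(standoff > 0)) stop("standoff must be > 0")
  v <- heart$mesh$vertices
  center <- colMeans(v)
  semi <- apply(abs(sweep(v, 2, center)), 2, max) + standoff

  pts <- fibonacci_sphere(n_electrodes) %*% t(random_rotation(seed))
  electrodes <- sweep(pts %*% diag(semi), 2, center, "+")

  # reject configurations with any electrode inside (or on) the heart
  w <- total_solid_angle(heart$mesh, electrodes)
  if (any(abs(w) > 2 * pi))
    stop("standoff too small: electrode inside the heart surface")
  # the torso ellipsoid must strictly enclose the heart
  sc <- sweep(sweep(v, 2, center), 2, semi, "/")
  if (any(rowSums(sc^2) >= 1))
    stop("standoff too small: heart not enclosed by the torso ellipsoid")

  tmesh <- NULL
  if (mesh) {
    tmesh <- ellipsoid_mesh(center, semi, n_lat, n_lon)
    # the faceted surface lies inside the smooth ellipsoid: move each
    # electrode radially onto its facet so it is an exact surface point
    electrodes <- project_radially_to_mesh(tmesh, center, electrodes)$points
  }
  structure(list(electrodes = electrodes, mesh = tmesh),
            class = "torso_model")
}

#' @export
print.torso_model <- function(x, ...) {
  cat("torso_model:", nrow(x$electrodes), "electrodes",
      if (!is.null(x$mesh)) sprintf("+ surface mesh (%d vertices)",
                                    nrow(x$mesh$vertices)) else "", "\n")
  invisible(x)
}
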
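# ---- equivalent-dipole-layer forward model --------------------------------

#' Total solid angle of a closed surface at observation points
#'
#' Sum of the signed per-triangle solid angles: 4*pi at interior points,
#' 0 at exterior points (outward-oriented closed surface).
#'
#' @param mesh a closed, outward-oriented [triangle_mesh()].
#' @param points P x 3 matrix (or single 3-vector) of observation points.
#' @return numeric vector of total solid angles (sr).
#' @export
total_solid_angle <- function(mesh, points) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  solid_angle_lumped_cpp(mesh$vertices, mesh$triangles, points)$total
}

#' Infinite-medium EDL transfer matrix via exact solid angles
#'
#' Assembles the lead-field matrix `A` (electrodes x heart nodes) of a
#' uniform double layer on the closed heart surface in an unbounded
#' homogeneous medium. Each triangle's signed solid angle at an electrode
#' (van Oosterom--Strackee formula) is lumped barycentrically to its
#' vertices, scaled by `1/(4*pi)` and divided by the vertex area weight, so
#' that `A[p, n]` is the potential per unit dipole-layer strength per unit
#' area at node `n`. The area-weighted row sums vanish for electrodes
#' outside the closed surface (a fully-on closed uniform double layer has
#' no external field).
#'
#' @param heart a [generate_heart()] model.
#' @param torso a [generate_torso()] model (only the electrodes are used).
#' @return an object of class `transfer_matrix` with fields `A` (P x N) and
#'   `medium = "infinite"`.
#' @export
solid_angle_transfer <- function(heart, torso) {
  electrodes <- if (is.matrix(torso)) torso else torso$electrodes
  mesh <- heart$mesh
  # a solid angle is singular for an observation point on the surface
  dmin <- apply(electrodes, 1, function(p)
    min(colSums((t(mesh$vertices) - p)^2)))
  if (any(dmin < 1e-12)) {
    bad <- which.min(dmin)
    stop("electrode ", bad, " coincides with heart node ",
         which.min(colSums((t(mesh$vertices) - electrodes[bad, ])^2)),
         ": solid angle singular")
  }
  sa <- solid_angle_lumped_cpp(mesh$vertices, mesh$triangles, electrodes)
  if (any(abs(sa$total) > 2 * pi))
    stop("electrode inside the closed heart surface")
  A <- sweep(sa$omega / (4 * pi), 2, heart$node_areas, "/")
  structure(list(A = A, medium = "infinite"), class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("transfer_matrix:", nrow(x$A), "electrodes x", ncol(x$A),
      "heart nodes, medium:", x$medium, "\n")
  invisible(x)
}

#' Body surface potential map container
#'
#' @param Y P x n_samples numeric matrix of electrode potentials.
#' @param dt sampling interval in ms (> 0).
#' @return an object of class `bspm`.
#' @export
bspm <- function(Y, dt) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (!(dt > 0)) stop("dt must be > 0")
  if (ncol(Y) < 2L) stop("a BSPM needs at least 2 time samples")
  structure(list(Y = Y, dt = as.numeric(dt)), class = "bspm")
}

#' @export
print.bspm <- function(x, ...) {
  cat("bspm:", nrow(x$Y), "electrodes x", ncol(x$Y),
      sprintf("samples, dt = %g ms (span %g ms)\n",
              x$dt, (ncol(x$Y) - 1) * x$dt))
  invisible(x)
}

#' Synthesize a BSPM from an activation sequence (Heaviside EDL sources)
#'
#' Column `k` (time `t_k = (k-1) * dt`) is the area-weighted sum of the
#' lead fields of all nodes already activated: `Y[, k] = sum_n A[, n] *
#' area_n * H(t_k - tau_n)` with `H(0) = 1` (a node contributes from its
#' own activation instant). Only depolarization is modelled; after the
#' last activation the closed layer is fully on and the external field of
#' the infinite-medium model vanishes.
#'
#' @param A a [solid_angle_transfer()] (or bounded) transfer matrix.
#' @param act an [activation_from_focus()] sequence.
#' @param node_areas per-node area weights (mm^2), e.g. `heart$node_areas`.
#' @param dt sampling interval in ms.
#' @param span temporal span in ms; sampling runs `0, dt, ..., span`.
#'   Defaults to `max(tau)` rounded up to a whole sample. Rejected when
#'   smaller than `max(tau)` (the QRS would be truncated).
#' @return a [bspm()].
#' @export
simulate_bspm <- function(A, act, node_areas, dt = 1, span = NULL) {
  if (!(dt > 0)) stop("dt must be > 0")
  tau <- act$tau
  if (any(!is.finite(tau))) stop("activation sequence has non-finite times")
  mx <- max(tau)
  if (is.null(span)) span <- ceiling(mx / dt) * dt
  if (span < mx - 1e-9) stop("span < max activation time: truncated QRS")
  Aw <- sweep(A$A, 2, node_areas, "*")
  ord <- order(tau)
  cum <- cbind(0, cumsum_columns_cpp(Aw[, ord, drop = FALSE]))
  tgrid <- seq(0, span + 1e-9, by = dt)
  counts <- findInterval(tgrid + 1e-9, tau[ord])
  bspm(cum[, counts + 1L, drop = FALSE], dt)
}

#' Reference BSPM for a focal activation, sampled on its own grid
#'
#' Convenience wrapper producing a self-consistent reference map: the
#' activation sequence from `focus` is linearly scaled so that its total
#' duration coincides exactly with the last sample `(n_samples - 1) * dt`,
#' then synthesized with [simulate_bspm()]. Candidate sequences scaled to
#' the same reference span by the inverse search then reproduce this map
#' exactly at the true focus (the "inverse crime" self-consistency used
#' for exactness checks).
#'
#' @param heart a [generate_heart()] model.
#' @param A transfer matrix for this heart/electrode layout.
#' @param times a [compute_times_matrix()] result, or an
#'   `activation_sequence` to use directly.
#' @param focus node index of the true origin.
#' @param dt sampling interval (ms).
#' @param n_samples number of samples; default: enough to cover the
#'   unscaled activation duration.
#' @return a [bspm()].
#' @export
simulate_reference_bspm <- function(heart, A, times, focus, dt = 1,
                                    n_samples = NULL) {
  act <- if (inherits(times, "activation_sequence")) times
         else activation_from_focus(times, focus)
  if (is.null(n_samples)) n_samples <- ceiling(max(act$tau) / dt) + 1L
  span <- (n_samples - 1L) * dt
  act <- scale_activation_duration(act, span)
  simulate_bspm(A, act, heart$node_areas, dt = dt, span = span)
}

# ---- bounded homogeneous conductor (BEM) ----------------------------------

#' Bounded-conductor correction of the transfer matrix (BEM)
#'
#' Solves the boundary integral equation for a homogeneous volume
#' conductor bounded by a closed torso surface (collocation with lumped
#' solid angles; the singular Neumann system is deflated with a rank-one
#' update). Surface potentials at the torso vertices are then evaluated at
#' the electrode positions: an electrode within `tol` of a torso vertex
#' takes that vertex's potential; otherwise the Green representation
#' formula `phi(e) = phi_inf(e) + (1/4 pi) * sum_j omega_j(e) * phi_j` is
#' used, with the winding factor handling electrodes on (0.5) or strictly
#' inside (1) the torso surface. Potentials of the insulated conductor are
#' defined up to a constant; a zero-mean gauge over the electrodes is
#' applied to each column.
#'
#' @param A_inf infinite-medium [solid_angle_transfer()] matrix for the
#'   same heart and electrodes.
#' @param heart the [generate_heart()] model that produced `A_inf`.
#' @param torso a [generate_torso()] model with a closed surface mesh.
#' @param tol snap distance (mm) for electrode-to-vertex matching.
#' @return a `transfer_matrix` with `medium = "bounded-homogeneous"`.
#' @export
bounded_torso_correction <- function(A_inf, heart, torso, tol = 1e-6) {
  if (is.null(torso$mesh)) stop("torso model has no surface mesh")
  tm <- torso$mesh
  if (!is_closed_mesh(tm)) stop("torso surface must be closed")
  # heart strictly inside the torso surface
  w_heart <- total_solid_angle(tm, heart$mesh$vertices)
  if (any(w_heart < 2 * pi)) stop("torso surface does not enclose the heart")

  nv <- nrow(tm$vertices)
  # infinite-medium potentials of unit sources at the torso vertices
  Av <- solid_angle_transfer(heart, tm$vertices)$A
  # collocation matrix: lumped solid angles at the torso's own vertices,
  # diagonal from the 2*pi principal-value row-sum identity
  om <- solid_angle_self_cpp(tm$vertices, tm$triangles)
  diag(om) <- 2 * pi - (rowSums(om) - diag(om))
  B <- om / (2 * pi)
  M <- diag(nv) - B + matrix(1 / nv, nv, nv)   # deflated system
  Phi <- solve(M, 2 * Av)

  electrodes <- torso$electrodes
  P <- nrow(electrodes)
  Ab <- matrix(0, P, ncol(Av))
  d2v <- t(apply(electrodes, 1, function(p) colSums((t(tm$vertices) - p)^2)))
  snapped <- 0L
  sa_e <- solid_angle_lumped_cpp(tm$vertices, tm$triangles, electrodes)
  ctr <- colMeans(tm$vertices)
  scale <- max(abs(sweep(tm$vertices, 2, ctr)))
  proj <- project_radially_to_mesh(tm, ctr, electrodes)
  for (p in seq_len(P)) {
    k <- which.min(d2v[p, ])
    if (sqrt(d2v[p, k]) <= tol) {
      Ab[p, ] <- Phi[k, ]
      snapped <- snapped + 1L
      next
    }
    om_row <- sa_e$omega[p, ]
    tot <- sa_e$total[p]
    if (sqrt(sum((electrodes[p, ] - proj$points[p, ])^2)) <= 1e-6 * scale) {
      # electrode on a facet: the facet's principal-value contribution is
      # zero (the kernel vanishes in-plane), so remove whatever the
      # near-singular numerical evaluation produced for it
      f <- proj$facet[p]
      of <- solid_angle_lumped_cpp(tm$vertices,
                                   tm$triangles[f, , drop = FALSE],
                                   electrodes[p, , drop = FALSE])$total
      tot <- tot - of
      om_row[tm$triangles[f, ]] <- om_row[tm$triangles[f, ]] - of / 3
    }
    w <- tot / (4 * pi)
    if (w < 0.25)
      stop("electrode ", p, " lies outside the torso surface")
    Ab[p, ] <- (A_inf$A[p, ] + (om_row %*% Phi) / (4 * pi)) / w
  }
  if (snapped > 0L)
    message(snapped, " electrode(s) snapped to the nearest torso vertex")
  Ab <- sweep(Ab, 2, colMeans(Ab))             # zero-mean gauge
  structure(list(A = Ab, medium = "bounded-homogeneous"),
            class = "transfer_matrix")
}

# ---- BSPM and transfer-matrix file I/O ------------------------------------

#' Read / write a BSPM as delimited text
#'
#' Format: a header line `dt=<ms>` followed by one row per electrode.
#'
#' @param x a [bspm()] (for writing).
#' @param path file path.
#' @return for `read_bspm`, a [bspm()]; for `write_bspm`, `path` invisibly.
#' @export
write_bspm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("dt=%.10g", x$dt), con)
  write.table(format(x$Y, digits = 10), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bspm
#' @export
read_bspm <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^dt=", first)) stop(path, ": missing 'dt=<ms>' header line")
  dt <- as.numeric(sub("^dt=", "", first))
  if (is.na(dt)) stop(path, ": malformed dt header")
  Y <- as.matrix(read.table(path, skip = 1L))
  dimnames(Y) <- NULL
  bspm(Y, dt)
}

mesh_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sprintf("%.8e", as.numeric(x)), f)
  unname(tools::md5sum(f))
}

#' Cache a transfer matrix with a JSON sidecar
#'
#' The matrix is serialized to `path` and a `<path>.json` sidecar records
#' the dimensions, medium and checksums of the heart mesh and electrode
#' coordinates, so that a stale cache is detected on load.
#'
#' @param A a `transfer_matrix`.
#' @param path cache file path.
#' @param heart,torso the geometry the matrix was computed for.
#' @return `path`, invisibly.
#' @export
save_transfer_cache <- function(A, path, heart, torso) {
  saveRDS(A, path)
  meta <- list(n_electrodes = nrow(A$A), n_nodes = ncol(A$A),
               medium = A$medium,
               heart_checksum = mesh_checksum(heart$mesh$vertices),
               electrode_checksum = mesh_checksum(torso$electrodes))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_transfer_cache
#' @export
load_transfer_cache <- function(path, heart, torso) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  if (!identical(meta$heart_checksum, mesh_checksum(heart$mesh$vertices)) ||
      !identical(meta$electrode_checksum, mesh_checksum(torso$electrodes)))
    stop("transfer cache ", path, " does not match the supplied geometry")
  readRDS(path)
}
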
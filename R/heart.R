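#' Synthetic ventricular heart model
#'
#' Builds a closed, labeled heart-surface model: an outer (epicardial) and
#' inner (endocardial) half-ellipsoid shell joined at a basal rim annulus.
#' The annulus carries an intermediate ring of unlabeled vertices, so no
#' mesh edge joins an epi- and an endo-labeled vertex directly: on-surface
#' (geodesic) paths between the two surfaces must route through the rim.
#' Explicit epi--endo connector edges are added across the wall (each endo
#' vertex to its nearest epi vertex) and flagged transmural; they take part
#' in conduction (at reduced speed) but are excluded from geodesics.
#'
#' The axes emulate a human ventricle: apex-to-base length `long_axis`,
#' equatorial diameter `short_axis`, wall thickness `wall_thickness`.
#' A small seeded azimuthal jitter of each vertex ring breaks the exact
#' rotational symmetry of the ellipsoid.
#'
#' @param n_subdiv integer >= 1, mesh refinement level; the vertex count
#'   grows roughly as `2 * (2 n + 3) * 6 n`.
#' @param long_axis apex-to-base length (mm), must exceed `wall_thickness`.
#' @param short_axis equatorial diameter (mm); `short_axis / 2` must exceed
#'   `wall_thickness`.
#' @param wall_thickness myocardial wall thickness (mm), > 0.
#' @param seed integer seed for the ring jitter; the output is identical
#'   for identical seeds.
#' @return an object of class `heart_model` with fields `mesh`
#'   ([triangle_mesh()]), `node_areas` (mm^2) and `edges` (data frame with
#'   columns `i`, `j`, `length` in mm, and logical `transmural`).
#' @export
generate_heart <- function(n_subdiv = 3, long_axis = 90, short_axis = 50,
                           wall_thickness = 10, seed = 1L) {
  n_subdiv <- as.integer(n_subdiv)
  if (n_subdiv < 1L) stop("n_subdiv must be >= 1")
  if (!(wall_thickness > 0)) stop("wall_thickness must be > 0")
  if (!(long_axis > wall_thickness))
    stop("degenerate axes: long_axis must exceed wall_thickness")
  if (!(short_axis / 2 > wall_thickness))
    stop("degenerate axes: short_axis / 2 must exceed wall_thickness")

  nr <- 2L * n_subdiv + 3L      # latitude rings per shell
  m  <- 6L * n_subdiv           # vertices per ring
  a_epi <- short_axis / 2
  c_epi <- long_axis
  a_endo <- a_epi - wall_thickness
  c_endo <- c_epi - wall_thickness

  set.seed(seed)
  jitter <- function() runif(nr, 0, 2 * pi / m)
  ph_epi <- jitter()
  ph_endo <- jitter()
  ph_mid <- runif(1, 0, 2 * pi / m)

  shell_vertices <- function(a, cz, phases) {
    v <- matrix(0, 1 + nr * m, 3)
    v[1, ] <- c(0, 0, -cz)
    for (i in seq_len(nr)) {
      th <- i * (pi / 2) / nr
      phi <- 2 * pi * (0:(m - 1)) / m + phases[i]
      rows <- 1 + (i - 1) * m + (1:m)
      v[rows, ] <- cbind(a * sin(th) * cos(phi),
                         a * sin(th) * sin(phi),
                         -cz * cos(th))
    }
    v
  }
  ring_idx <- function(offset, i) offset + 1 + (i - 1) * m + (1:m)

  n_shell <- 1 + nr * m
  v_epi <- shell_vertices(a_epi, c_epi, ph_epi)
  v_endo <- shell_vertices(a_endo, c_endo, ph_endo)
  phi_mid <- 2 * pi * (0:(m - 1)) / m + ph_mid
  a_mid <- (a_epi + a_endo) / 2
  v_mid <- cbind(a_mid * cos(phi_mid), a_mid * sin(phi_mid), 0)

  vertices <- rbind(v_epi, v_endo, v_mid)
  off_epi <- 0L
  off_endo <- n_shell
  off_mid <- 2L * n_shell
  labels <- c(rep("epi", n_shell), rep("endo", n_shell), rep("unlabeled", m))

  strip <- function(low, high) {
    # triangulate the band between two rings of m vertices each
    jn <- c(2:m, 1)
    rbind(cbind(low, low[jn], high[jn]),
          cbind(low, high[jn], high))
  }
  fan <- function(apex, ring) {
    jn <- c(2:m, 1)
    cbind(rep(apex, m), ring, ring[jn])
  }

  tris <- list()
  for (off in c(off_epi, off_endo)) {
    tris[[length(tris) + 1]] <- fan(off + 1L, ring_idx(off, 1L))
    if (nr > 1) for (i in seq_len(nr - 1L))
      tris[[length(tris) + 1]] <- strip(ring_idx(off, i), ring_idx(off, i + 1L))
  }
  mid_ring <- off_mid + (1:m)
  tris[[length(tris) + 1]] <- strip(ring_idx(off_epi, nr), mid_ring)
  tris[[length(tris) + 1]] <- strip(mid_ring, ring_idx(off_endo, nr))
  triangles <- do.call(rbind, tris)

  mesh <- orient_mesh(triangle_mesh(vertices, triangles, labels))

  et <- mesh_edge_table(mesh)
  len <- sqrt(rowSums((mesh$vertices[et$i, , drop = FALSE] -
                       mesh$vertices[et$j, , drop = FALSE])^2))
  edges <- data.frame(i = et$i, j = et$j, length = len,
                      transmural = (mesh$labels[et$i] == "epi" &
                                    mesh$labels[et$j] == "endo") |
                                   (mesh$labels[et$i] == "endo" &
                                    mesh$labels[et$j] == "epi"))

  # transmural connector edges: each endo vertex to its nearest epi vertex
  endo_idx <- which(mesh$labels == "endo")
  epi_idx <- which(mesh$labels == "epi")
  conn <- t(vapply(endo_idx, function(ii) {
    d2 <- colSums((t(mesh$vertices[epi_idx, , drop = FALSE]) -
                   mesh$vertices[ii, ])^2)
    k <- which.min(d2)
    c(epi_idx[k], ii, sqrt(d2[k]))
  }, numeric(3)))
  conn_df <- data.frame(i = pmin(conn[, 1], conn[, 2]),
                        j = pmax(conn[, 1], conn[, 2]),
                        length = conn[, 3], transmural = TRUE)
  edges <- rbind(edges, conn_df)
  edges <- edges[!duplicated(edges[, c("i", "j")]), ]
  rownames(edges) <- NULL

  structure(list(mesh = mesh, node_areas = vertex_areas(mesh), edges = edges),
            class = "heart_model")
}

#' @export
print.heart_model <- function(x, ...) {
  cat("heart_model:", nrow(x$mesh$vertices), "nodes,",
      nrow(x$mesh$triangles), "triangles,",
      sum(x$edges$transmural), "transmural edges\n")
  cat("total surface area:", round(sum(x$node_areas)), "mm^2\n")
  invisible(x)
}

#' Spherical region of modified conduction velocity
#'
#' @param center 3-D point (mm).
#' @param radius sphere radius (mm), > 0.
#' @param cv_factor multiplicative factor applied to the conduction
#'   velocity inside the sphere (e.g. `1/3` for a three-fold slowing), > 0.
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(center, radius, cv_factor) {
  center <- as.numeric(center)
  if (length(center) != 3L) stop("center must be a 3-D point")
  if (!(radius > 0)) stop("radius must be > 0")
  if (!(cv_factor > 0)) stop("cv_factor must be > 0")
  structure(list(center = center, radius = radius, cv_factor = cv_factor),
            class = "region_spec")
}

# igraph over the on-surface (non-transmural) edges
geodesic_graph <- function(heart) {
  e <- heart$edges[!heart$edges$transmural, ]
  igraph::graph_from_data_frame(
    data.frame(from = e$i, to = e$j, weight = e$length),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(heart$mesh$vertices))))
}

#' On-surface geodesic distances from one vertex
#'
#' Shortest-path distance along mesh edges, excluding transmural connector
#' edges, so epi-to-endo routes must pass the basal rim.
#'
#' @param heart a [generate_heart()] model.
#' @param from vertex index.
#' @return numeric vector of distances (mm) to every vertex; `Inf` marks
#'   unreachable vertices.
#' @export
geodesic_from <- function(heart, from) {
  n <- nrow(heart$mesh$vertices)
  if (from < 1 || from > n) stop("vertex index out of range")
  as.numeric(igraph::distances(geodesic_graph(heart), v = from))
}

#' On-surface geodesic distance between two vertices
#'
#' @param heart a [generate_heart()] model.
#' @param i,j vertex indices.
#' @return distance in mm; `Inf` with a warning when unreachable.
#' @export
geodesic_distance <- function(heart, i, j) {
  n <- nrow(heart$mesh$vertices)
  if (i < 1 || i > n || j < 1 || j > n) stop("vertex index out of range")
  if (i == j) return(0)
  d <- geodesic_from(heart, i)[j]
  if (!is.finite(d)) warning("vertices ", i, " and ", j, " are unreachable")
  d
}

#' Find a vertex at (approximately) a given geodesic distance
#'
#' Returns the vertex whose geodesic distance from `from` is closest to
#' `distance`, optionally restricted to a label.
#'
#' @param heart a [generate_heart()] model.
#' @param from source vertex index.
#' @param distance target distance (mm).
#' @param label optional restriction (`"epi"`, `"endo"`).
#' @return vertex index.
#' @export
vertex_at_geodesic_distance <- function(heart, from, distance, label = NULL) {
  d <- geodesic_from(heart, from)
  ok <- is.finite(d)
  if (!is.null(label)) ok <- ok & heart$mesh$labels == label
  idx <- which(ok)
  idx[which.min(abs(d[idx] - distance))]
}
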
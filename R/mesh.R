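#' Triangulated surface mesh
#'
#' Constructs a `triangle_mesh`: a set of 3-D vertices (mm), a triangle
#' index matrix, and an optional per-vertex label in `{"epi", "endo",
#' "unlabeled"}`. Vertex indices are 1-based throughout the package;
#' file formats using 0-based indices are converted at the I/O boundary.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @param labels optional character vector of length n with values
#'   `"epi"`, `"endo"` or `"unlabeled"`; defaults to all `"unlabeled"`.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  n <- nrow(vertices)
  if (nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > n)
      stop("triangle vertex index out of range [1, ", n, "]")
    if (any(triangles[, 1] == triangles[, 2] |
            triangles[, 2] == triangles[, 3] |
            triangles[, 1] == triangles[, 3]))
      stop("degenerate triangle with repeated vertex index")
  }
  if (is.null(labels)) labels <- rep("unlabeled", n)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have one entry per vertex")
  if (!all(labels %in% c("epi", "endo", "unlabeled")))
    stop("labels must be 'epi', 'endo' or 'unlabeled'")
  structure(list(vertices = vertices, triangles = triangles, labels = labels),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  tab <- table(x$labels)
  cat("labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# undirected edge table of a mesh: columns i, j (i < j), count = number of
# incident triangles
mesh_edge_table <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  i <- pmin(e[, 1], e[, 2])
  j <- pmax(e[, 1], e[, 2])
  key <- paste(i, j)
  agg <- table(key)
  parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
             count = as.integer(agg), row.names = NULL)
}

#' Closedness check
#'
#' A surface is closed (watertight) when every undirected edge is shared
#' by exactly two triangles.
#'
#' @param mesh a [triangle_mesh()].
#' @return `TRUE` or `FALSE`.
#' @export
is_closed_mesh <- function(mesh) {
  et <- mesh_edge_table(mesh)
  nrow(et) > 0L && all(et$count == 2L)
}

#' Euler characteristic V - E + F
#'
#' Equals 2 for a closed genus-0 surface.
#'
#' @param mesh a [triangle_mesh()].
#' @return integer.
#' @export
mesh_euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edge_table(mesh)) + nrow(mesh$triangles)
}

#' Signed enclosed volume
#'
#' Divergence-theorem signed volume; positive when the triangle winding is
#' consistently outward.
#'
#' @param mesh a [triangle_mesh()].
#' @return volume in mm^3 (signed).
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  t1 <- v[mesh$triangles[, 1], , drop = FALSE]
  t2 <- v[mesh$triangles[, 2], , drop = FALSE]
  t3 <- v[mesh$triangles[, 3], , drop = FALSE]
  cx <- t2[, 2] * t3[, 3] - t2[, 3] * t3[, 2]
  cy <- t2[, 3] * t3[, 1] - t2[, 1] * t3[, 3]
  cz <- t2[, 1] * t3[, 2] - t2[, 2] * t3[, 1]
  sum(t1[, 1] * cx + t1[, 2] * cy + t1[, 3] * cz) / 6
}

#' Per-triangle areas
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of areas (mm^2), one per triangle.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  a <- v[mesh$triangles[, 2], , drop = FALSE] - v[mesh$triangles[, 1], , drop = FALSE]
  b <- v[mesh$triangles[, 3], , drop = FALSE] - v[mesh$triangles[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Barycentric (lumped) vertex area weights
#'
#' Each vertex receives one third of the area of every incident triangle;
#' the weights are positive on a valid mesh and sum to the total surface
#' area, giving a conservative discretization of surface integrals.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh) / 3
  n <- nrow(mesh$vertices)
  out <- numeric(n)
  for (k in 1:3) {
    s <- tapply(ta, mesh$triangles[, k], sum)
    idx <- as.integer(names(s))
    out[idx] <- out[idx] + as.numeric(s)
  }
  out
}

#' Make triangle winding consistent and outward
#'
#' Propagates a consistent orientation over the triangle adjacency graph
#' (opposite traversal of each shared edge) and then flips the whole
#' surface if the signed volume is negative, so that normals point
#' outward. Requires a closed orientable surface.
#'
#' @param mesh a [triangle_mesh()].
#' @return the reoriented `triangle_mesh`.
#' @export
orient_mesh <- function(mesh) {
  tri <- mesh$triangles
  nf <- nrow(tri)
  if (nf == 0L) return(mesh)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(ekey(tri[, 1], tri[, 2]), ekey(tri[, 2], tri[, 3]),
            ekey(tri[, 3], tri[, 1]))
  tid <- rep(seq_len(nf), 3)
  by_edge <- split(tid, keys)
  # neighbor triangles per triangle
  nbrs <- vector("list", nf)
  for (tris in by_edge) {
    if (length(tris) == 2L) {
      nbrs[[tris[1]]] <- c(nbrs[[tris[1]]], tris[2])
      nbrs[[tris[2]]] <- c(nbrs[[tris[2]]], tris[1])
    }
  }
  directed <- function(t) {
    a <- tri[t, ]
    rbind(a[c(1, 2)], a[c(2, 3)], a[c(3, 1)])
  }
  visited <- rep(FALSE, nf)
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue) > 0L) {
    cur <- queue[1L]
    queue <- queue[-1L]
    dc <- directed(cur)
    for (nb in nbrs[[cur]]) {
      if (visited[nb]) next
      dn <- directed(nb)
      # shared directed edge appearing with the SAME direction in both
      # triangles means inconsistent winding -> flip the neighbor
      same <- any(outer(paste(dc[, 1], dc[, 2]), paste(dn[, 1], dn[, 2]), "=="))
      if (same) tri[nb, ] <- tri[nb, c(1, 3, 2)]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  if (!all(visited))
    stop("mesh is not edge-connected; cannot orient")
  out <- triangle_mesh(mesh$vertices, tri, mesh$labels)
  if (mesh_signed_volume(out) < 0)
    out$triangles <- out$triangles[, c(1, 3, 2), drop = FALSE]
  out
}
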
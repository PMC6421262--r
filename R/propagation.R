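# ---- fastest-route (shortest-path) activation model -----------------------

#' Conduction graph with per-edge travel times
#'
#' Converts the heart's edge graph into travel times (ms). A surface edge
#' takes `length / cv` with the global conduction velocity `cv_global`
#' expressed in m/s (numerically equal to mm/ms). Transmural edges are
#' slowed by `transmural_factor` (default 0.5: half the tangential speed,
#' mimicking transmural anisotropy). An edge lies inside a [region_spec()]
#' when its midpoint is within the sphere; its velocity is then multiplied
#' by the region's `cv_factor` (e.g. `1/3` for a three-fold slowing).
#'
#' @param heart a [generate_heart()] model.
#' @param cv_global global conduction velocity in m/s (> 0); 0.8 m/s is a
#'   typical working value.
#' @param transmural_factor velocity factor for transmural edges (> 0).
#' @param regions list of [region_spec()] objects (may be empty).
#' @return an object of class `conduction_graph` (edge table with a
#'   `time` column in ms, plus `n` vertices).
#' @export
build_conduction_graph <- function(heart, cv_global = 0.8,
                                   transmural_factor = 0.5,
                                   regions = list()) {
  if (!(cv_global > 0)) stop("cv_global must be > 0")
  if (!(transmural_factor > 0)) stop("transmural_factor must be > 0")
  if (inherits(regions, "region_spec")) regions <- list(regions)
  e <- heart$edges
  cv <- rep(cv_global, nrow(e))               # mm/ms == m/s numerically
  cv[e$transmural] <- cv[e$transmural] * transmural_factor
  if (length(regions) > 0) {
    mid <- (heart$mesh$vertices[e$i, , drop = FALSE] +
            heart$mesh$vertices[e$j, , drop = FALSE]) / 2
    for (rg in regions) {
      if (!inherits(rg, "region_spec")) stop("regions must be region_spec objects")
      inside <- rowSums(sweep(mid, 2, rg$center)^2) < rg$radius^2
      cv[inside] <- cv[inside] * rg$cv_factor
    }
  }
  structure(list(edges = data.frame(i = e$i, j = e$j, time = e$length / cv),
                 n = nrow(heart$mesh$vertices), cv_global = cv_global),
            class = "conduction_graph")
}

conduction_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = graph$edges$i, to = graph$edges$j,
               weight = graph$edges$time),
    directed = FALSE,
    vertices = data.frame(name = seq_len(graph$n)))
}

#' All-pairs fastest-route times matrix
#'
#' Dijkstra shortest-path travel times between all node pairs of the
#' conduction graph. The result is symmetric with zero diagonal and
#' satisfies the triangle inequality; unreachable pairs are `Inf` and
#' raise a warning.
#'
#' @param graph a [build_conduction_graph()] result.
#' @return an object of class `times_matrix` with fields `T` (N x N, ms)
#'   and `cv_global`.
#' @export
compute_times_matrix <- function(graph) {
  tm <- igraph::distances(conduction_igraph(graph), algorithm = "dijkstra")
  dimnames(tm) <- NULL
  if (any(!is.finite(tm)))
    warning("conduction graph is disconnected: unreachable entries are Inf")
  structure(list(T = tm, cv_global = graph$cv_global), class = "times_matrix")
}

#' Single-source fastest-route times
#'
#' One row of the times matrix, for when the full matrix is not needed
#' (e.g. simulating one reference activation).
#'
#' @param graph a [build_conduction_graph()] result.
#' @param focus source node index.
#' @return numeric vector of travel times (ms).
#' @export
times_from_focus <- function(graph, focus) {
  if (focus < 1 || focus > graph$n) stop("focus index out of range")
  tau <- as.numeric(igraph::distances(conduction_igraph(graph), v = focus,
                                      algorithm = "dijkstra"))
  tau
}

#' Candidate activation sequence for a focal source
#'
#' The activation time of every node is its fastest-route travel time from
#' the focus; the focus itself activates at 0 ms.
#'
#' @param times a [compute_times_matrix()] result.
#' @param focus node index of the initiating focus.
#' @return an object of class `activation_sequence` with fields `tau`
#'   (ms per node) and `focus`.
#' @export
activation_from_focus <- function(times, focus) {
  n <- nrow(times$T)
  if (focus < 1 || focus > n) stop("focus index out of range")
  structure(list(tau = times$T[focus, ], focus = as.integer(focus)),
            class = "activation_sequence")
}

#' Linear temporal scaling of an activation sequence
#'
#' Multiplies all activation times by `target_span / max(tau)` so that the
#' total activation duration matches a reference (e.g. the measured QRS
#' duration). The activation order of the nodes is unchanged.
#'
#' @param act an [activation_from_focus()] sequence.
#' @param target_span desired duration (ms), > 0.
#' @return the scaled `activation_sequence`.
#' @export
scale_activation_duration <- function(act, target_span) {
  if (!(target_span > 0)) stop("target_span must be > 0")
  mx <- max(act$tau)
  if (!(mx > 0)) stop("cannot scale an all-zero activation sequence")
  structure(list(tau = act$tau * (target_span / mx), focus = act$focus),
            class = "activation_sequence")
}

#' Combine several activation sequences (multi-foci forward simulation)
#'
#' Elementwise minimum of the activation times: each node activates with
#' the first wavefront that reaches it. Intended for forward simulation
#' only; the inverse search is single-focus.
#'
#' @param ... two or more `activation_sequence` objects.
#' @return an `activation_sequence` with `focus = NA` and an attribute
#'   `foci` listing the combined focus indices.
#' @export
combine_activations <- function(...) {
  acts <- list(...)
  if (length(acts) < 2L) stop("need at least two activation sequences")
  tau <- do.call(pmin, lapply(acts, function(a) a$tau))
  out <- structure(list(tau = tau, focus = NA_integer_),
                   class = "activation_sequence")
  attr(out, "foci") <- vapply(acts, function(a) a$focus, integer(1))
  out
}
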
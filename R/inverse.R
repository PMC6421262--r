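# ---- full-search inverse procedure (FRA and FRA-DTW) -----------------------

#' Column-wise BSPM normalization
#'
#' Each time column (the potentials of all electrodes at one instant) is
#' centered to zero mean and scaled to unit population variance across
#' electrodes. Columns with zero variance map to all-zero columns. This
#' removes the amplitude scale of the volume conductor before the signals
#' are compared.
#'
#' @param Y a [bspm()] or a P x T matrix (P >= 2 electrodes).
#' @return the normalized object, same type as the input.
#' @export
normalize_bspm <- function(Y) {
  is_b <- inherits(Y, "bspm")
  m <- if (is_b) Y$Y else as.matrix(Y)
  if (nrow(m) < 2L) stop("normalization needs at least 2 electrodes")
  mu <- colMeans(m)
  ctr <- sweep(m, 2, mu)
  s <- sqrt(colMeans(ctr^2))               # population standard deviation
  nz <- s > 0
  ctr[, nz] <- sweep(ctr[, nz, drop = FALSE], 2, s[nz], "/")
  ctr[, !nz] <- 0
  if (is_b) bspm(ctr, Y$dt) else ctr
}

#' Global correlation between two BSPMs
#'
#' Pearson correlation of the two matrices flattened jointly over
#' electrodes and time samples.
#'
#' @param test,ref [bspm()] objects or matrices with equal dimensions.
#' @return a scalar in `[-1, 1]`; 0 with a warning when either input has
#'   zero variance.
#' @export
correlation_score <- function(test, ref) {
  X <- as_channel_matrix(test)
  Y <- as_channel_matrix(ref)
  if (!all(dim(X) == dim(Y))) stop("shape mismatch")
  if (sd(as.vector(X)) == 0 || sd(as.vector(Y)) == 0) {
    warning("zero-variance input: correlation defined as 0")
    return(0)
  }
  cor(as.vector(X), as.vector(Y))
}

#' Reciprocal-distance similarity map
#'
#' Maps per-node DTW distances to scores `1 / c`, so that minimizing the
#' warping cost is equivalent to maximizing the score (and the map can be
#' displayed like a correlation map). An exact match (distance 0) maps to
#' `+Inf` and is flagged.
#'
#' @param distances nonnegative per-node total warping costs.
#' @return an object of class `similarity_map` with fields `scores`,
#'   `kind = "reciprocal_distance"`, `best_node`, and `exact_match_nodes`.
#' @export
reciprocal_map <- function(distances) {
  distances <- as.numeric(distances)
  if (any(distances < 0)) stop("distances must be >= 0")
  scores <- ifelse(distances == 0, Inf, 1 / distances)
  similarity_map(scores, "reciprocal_distance",
                 exact_match_nodes = which(distances == 0))
}

similarity_map <- function(scores, kind, exact_match_nodes = integer(0)) {
  best <- which.max(scores)                  # ties: lowest node index
  n_best <- sum(scores == scores[best])
  if (n_best > 1L)
    warning(n_best, " nodes tie for the best score; reporting the lowest index")
  structure(list(scores = scores, kind = kind, best_node = best,
                 n_tied = n_best, exact_match_nodes = exact_match_nodes),
            class = "similarity_map")
}

#' @export
print.similarity_map <- function(x, ...) {
  cat(sprintf("similarity_map (%s): best node %d, score %.6g over %d nodes\n",
              x$kind, x$best_node, x$scores[x$best_node], length(x$scores)))
  invisible(x)
}

#' Full-search similarity maps for both scoring methods
#'
#' For every heart node: take its fastest-route activation sequence, scale
#' it linearly to the reference duration, synthesize the test BSPM at the
#' reference sampling, normalize both maps column-wise, and score the pair
#' by the global correlation coefficient (classic FRA) and by the optimal
#' DTW warping cost (FRA-DTW). One sweep computes both scores.
#'
#' @param heart a [generate_heart()] model.
#' @param A transfer matrix for this heart and electrode layout.
#' @param times a [compute_times_matrix()] result on the same heart (the
#'   search model; typically the unaltered global-CV times matrix).
#' @param ref the reference [bspm()].
#' @return list with `cc` (correlation [similarity_map()]), `dtw`
#'   (reciprocal-distance map), `dtw_cost` (raw per-node costs) and
#'   `span` (ms).
#' @export
similarity_search <- function(heart, A, times, ref) {
  if (!inherits(ref, "bspm")) stop("ref must be a bspm")
  N <- ncol(A$A)
  if (nrow(times$T) != N || nrow(heart$mesh$vertices) != N)
    stop("heart, transfer matrix and times matrix are inconsistent")
  if (nrow(ref$Y) != nrow(A$A))
    stop("reference electrode count does not match the transfer matrix")
  n_samp <- ncol(ref$Y)
  span <- (n_samp - 1L) * ref$dt
  refn <- normalize_bspm(ref)
  cc <- numeric(N)
  cost <- numeric(N)
  for (f in seq_len(N)) {
    act <- scale_activation_duration(activation_from_focus(times, f), span)
    test <- simulate_bspm(A, act, heart$node_areas, dt = ref$dt, span = span)
    testn <- normalize_bspm(test)
    cc[f] <- suppressWarnings(correlation_score(testn, refn))
    cost[f] <- dtw_total_cost_cpp(dtw_cost_matrix_cpp(testn$Y, refn$Y))
  }
  list(cc = similarity_map(cc, "correlation"),
       dtw = reciprocal_map(cost),
       dtw_cost = cost,
       span = span)
}

#' Localize the activation origin of a reference BSPM
#'
#' Runs the full search over all heart nodes and returns the similarity
#' map of the requested method together with a localization result (error
#' metrics against `true_node` when known).
#'
#' @param heart a [generate_heart()] model.
#' @param A transfer matrix.
#' @param times search-model times matrix (global CV, unaltered).
#' @param ref reference [bspm()].
#' @param method `"fra_dtw"` (reciprocal DTW distance) or `"fra_cc"`
#'   (correlation).
#' @param true_node optional ground-truth origin for error metrics.
#' @param search optional precomputed [similarity_search()] result (both
#'   methods share one sweep).
#' @return list with `map` (a [similarity_map()]) and `result` (a
#'   `localization_result`).
#' @export
localize <- function(heart, A, times, ref, method = c("fra_dtw", "fra_cc"),
                     true_node = NULL, search = NULL) {
  method <- match.arg(method)
  if (is.null(search)) search <- similarity_search(heart, A, times, ref)
  map <- if (method == "fra_dtw") search$dtw else search$cc
  list(map = map,
       result = localization_result(heart, map$best_node, true_node))
}

localization_result <- function(heart, estimated_node, true_node = NULL) {
  out <- list(estimated_node = estimated_node, true_node = true_node,
              geodesic_error = NA_real_, euclidean_error = NA_real_,
              surface_match = NA)
  if (!is.null(true_node)) {
    out$geodesic_error <- geodesic_distance(heart, estimated_node, true_node)
    out$euclidean_error <- sqrt(sum((heart$mesh$vertices[estimated_node, ] -
                                     heart$mesh$vertices[true_node, ])^2))
    le <- heart$mesh$labels[estimated_node]
    lt <- heart$mesh$labels[true_node]
    out$surface_match <- if (le == "unlabeled" || lt == "unlabeled") NA
                         else le == lt
  }
  structure(out, class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat("localization_result: estimated node", x$estimated_node)
  if (!is.null(x$true_node))
    cat(sprintf(" (true %d, geodesic error %.2f mm, euclidean %.2f mm, %s surface)",
                x$true_node, x$geodesic_error, x$euclidean_error,
                if (isTRUE(x$surface_match)) "same" else "different"))
  cat("\n")
  invisible(x)
}

#' Read a scenario configuration (YAML or JSON)
#'
#' Fields: `cv_global` (m/s), `transmural_factor`, `focus` (node index),
#' `regions` (list of `{center, radius, cv_factor}`), and optionally
#' `dt` (ms) plus the geometry parameters `heart` / `torso` (argument
#' lists for [generate_heart()] and [generate_torso()]).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a named list with `regions` converted to [region_spec()]s.
#' @export
read_scenario_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported scenario config format: ", ext)
  if (is.null(cfg$cv_global)) cfg$cv_global <- 0.8
  if (is.null(cfg$transmural_factor)) cfg$transmural_factor <- 0.5
  if (is.null(cfg$dt)) cfg$dt <- 1
  if (!is.null(cfg$regions)) {
    if (is.data.frame(cfg$regions)) cfg$regions <- split(cfg$regions, seq_len(nrow(cfg$regions)))
    cfg$regions <- lapply(cfg$regions, function(r)
      region_spec(unlist(r$center), r$radius, r$cv_factor))
  } else cfg$regions <- list()
  cfg
}
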
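# ---- multichannel dynamic time warping -------------------------------------
#
# Boundary-anchored, monotone alignment of two equal-length multichannel
# sequences minimizing the summed euclidean local cost, solved by dynamic
# programming over the accumulated-cost matrix with sentinel row/column,
# plus an exhaustive path-enumeration oracle for testing.

as_channel_matrix <- function(x) {
  if (inherits(x, "bspm")) return(x$Y)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Euclidean local cost between two multichannel samples
#'
#' @param test_column,ref_column numeric vectors of equal length (one time
#'   sample across all channels).
#' @return the L2 norm of the difference (>= 0).
#' @export
local_cost <- function(test_column, ref_column) {
  if (length(test_column) != length(ref_column))
    stop("local_cost: channel count mismatch")
  sqrt(sum((test_column - ref_column)^2))
}

#' Local-cost matrix between all column pairs of two sequences
#'
#' `C[n, m] = ||test[, n] - ref[, m]||_2`; zero exactly when the columns
#' are equal.
#'
#' @param test,ref channels x samples matrices (or [bspm()] objects).
#' @return T x T nonnegative matrix.
#' @export
dtw_cost_matrix <- function(test, ref) {
  X <- as_channel_matrix(test)
  Y <- as_channel_matrix(ref)
  if (nrow(X) != nrow(Y)) stop("channel count mismatch")
  dtw_cost_matrix_cpp(X, Y)
}

#' Accumulated-cost matrix
#'
#' Dynamic-programming recursion
#' `D(n, m) = min{D(n-1, m-1), D(n-1, m), D(n, m-1)} + C(n, m)` with the
#' sentinel initialization `D(0, 0) = 0`, `D(0, m > 0) = D(n > 0, 0) = Inf`.
#' The returned matrix is (T+1) x (T+1); entry `[T+1, T+1]` is the optimal
#' total cost.
#'
#' @param C a square local-cost matrix.
#' @return the accumulated matrix `D`, with attribute `"T"`.
#' @export
dtw_accumulate <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("cost matrix must be square")
  D <- dtw_accumulate_cpp(C)
  attr(D, "T") <- nrow(C)
  D
}

#' Backtrack the optimal warping path
#'
#' Walks from `(T, T)` to `(1, 1)`: on the boundary rows the predecessor is
#' forced horizontal/vertical; elsewhere it is the argmin of the three
#' admissible predecessors, with ties broken diagonal-first, then vertical
#' `(n-1, m)`, then horizontal `(n, m-1)` (so identical sequences yield the
#' diagonal path).
#'
#' @param D an accumulated matrix from [dtw_accumulate()].
#' @return an L x 2 matrix of 1-based index pairs `(n_l, m_l)`, first row
#'   `(1, 1)`, last row `(T, T)`.
#' @export
dtw_backtrack <- function(D) {
  Tn <- attr(D, "T")
  if (is.null(Tn)) Tn <- nrow(D) - 1L
  n <- Tn; m <- Tn
  rev_path <- matrix(0L, 2L * Tn, 2L)
  k <- 1L
  rev_path[k, ] <- c(n, m)
  while (n > 1L || m > 1L) {
    if (n == 1L) {
      m <- m - 1L
    } else if (m == 1L) {
      n <- n - 1L
    } else {
      # D has a sentinel offset: D[n + 1, m + 1] is the path-level D(n, m)
      cand <- c(D[n, m], D[n, m + 1L], D[n + 1L, m])
      step <- which.min(cand)             # diagonal-first tie-break
      if (step == 1L) { n <- n - 1L; m <- m - 1L }
      else if (step == 2L) n <- n - 1L
      else m <- m - 1L
    }
    k <- k + 1L
    rev_path[k, ] <- c(n, m)
  }
  rev_path[k:1, , drop = FALSE]
}

#' Feasibility check for a warping path
#'
#' Verifies the boundary conditions `p_1 = (1, 1)` and `p_L = (T, T)`,
#' componentwise monotonicity, step sizes in `{(1,0), (0,1), (1,1)}`, and
#' the length bounds `T <= L <= 2T - 1`.
#'
#' @param path an L x 2 index matrix.
#' @param T sequence length.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_warping_path <- function(path, T) {
  path <- as.matrix(path)
  L <- nrow(path)
  if (L < T || L > 2L * T - 1L) return(FALSE)
  if (!all(path[1, ] == c(1L, 1L))) return(FALSE)
  if (!all(path[L, ] == c(T, T))) return(FALSE)
  if (L > 1L) {
    d <- diff(path)
    ok <- (d[, 1] == 1L & d[, 2] == 0L) |
          (d[, 1] == 0L & d[, 2] == 1L) |
          (d[, 1] == 1L & d[, 2] == 1L)
    if (!all(ok)) return(FALSE)
  }
  TRUE
}

# cost along a path, accumulated in path order (plain double additions, the
# same arithmetic as the DP recursion)
path_cost <- function(C, path) {
  tot <- 0
  for (l in seq_len(nrow(path))) tot <- tot + C[path[l, 1], path[l, 2]]
  tot
}

#' Dynamic time warping distance between two equal-length sequences
#'
#' Composition of the euclidean local cost, the accumulated-cost recursion
#' and the backtracking step. The returned total cost is verified against
#' the independent re-summation of the local costs along the returned path
#' (relative tolerance 1e-12).
#'
#' @param test,ref channels x samples matrices or [bspm()] objects with
#'   equal dimensions.
#' @return an object of class `dtw_result` with fields `total_cost`,
#'   `path` (L x 2, 1-based) and `L`.
#' @export
dtw_distance <- function(test, ref) {
  X <- as_channel_matrix(test)
  Y <- as_channel_matrix(ref)
  if (!all(dim(X) == dim(Y)))
    stop("test and reference must have equal channel and sample counts")
  C <- dtw_cost_matrix_cpp(X, Y)
  D <- dtw_accumulate(C)
  path <- dtw_backtrack(D)
  total <- D[nrow(D), ncol(D)]
  check <- path_cost(C, path)
  if (abs(check - total) > 1e-12 * max(1, abs(total)))
    stop("internal error: path cost does not match accumulated total")
  structure(list(total_cost = total, path = path, L = nrow(path)),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("dtw_result: total cost %.6g, path length %d\n",
              x$total_cost, x$L))
  invisible(x)
}

#' Exhaustively enumerate all feasible warping paths (testing oracle)
#'
#' All monotone, boundary-anchored paths with steps `{(1,0),(0,1),(1,1)}`
#' through a T x T grid; their count is the central Delannoy number
#' (1, 3, 13, 63, ... for T = 1, 2, 3, 4).
#'
#' @param T sequence length, at most 7.
#' @return list of L x 2 path matrices.
#' @export
enumerate_warping_paths <- function(T) {
  if (T > 7) stop("enumeration limited to T <= 7")
  if (T < 1) stop("T must be >= 1")
  paths <- list()
  recurse <- function(path, n, m) {
    if (n == T && m == T) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    if (n < T) recurse(rbind(path, c(n + 1L, m)), n + 1L, m)
    if (m < T) recurse(rbind(path, c(n, m + 1L)), n, m + 1L)
    if (n < T && m < T) recurse(rbind(path, c(n + 1L, m + 1L)), n + 1L, m + 1L)
  }
  recurse(matrix(c(1L, 1L), 1, 2), 1L, 1L)
  paths
}

#' Brute-force DTW by path enumeration (testing oracle)
#'
#' Minimizes the summed local cost over all feasible paths from
#' [enumerate_warping_paths()]; independent of the dynamic-programming
#' implementation.
#'
#' @param test,ref channels x samples matrices or [bspm()] objects with
#'   equal dimensions; at most 7 samples.
#' @return a `dtw_result`.
#' @export
oracle_dtw <- function(test, ref) {
  X <- as_channel_matrix(test)
  Y <- as_channel_matrix(ref)
  if (!all(dim(X) == dim(Y))) stop("shape mismatch")
  Tn <- ncol(X)
  # the same local-cost values as the DP path, so that the minimum over
  # paths is comparable at full floating-point precision; only the
  # path search itself is independent of the dynamic program
  C <- dtw_cost_matrix_cpp(X, Y)
  paths <- enumerate_warping_paths(Tn)
  costs <- vapply(paths, function(p) path_cost(C, p), numeric(1))
  best <- which.min(costs)
  structure(list(total_cost = costs[best], path = paths[[best]],
                 L = nrow(paths[[best]])),
            class = "dtw_result")
}

#' Dump DTW internals as delimited text (debugging aid)
#'
#' Writes the local-cost matrix, the accumulated matrix and the optimal
#' path to three files with suffixes `_C.txt`, `_D.txt`, `_path.txt`.
#'
#' @param test,ref sequences as in [dtw_distance()].
#' @param prefix output path prefix.
#' @return the `dtw_result`, invisibly.
#' @export
dtw_debug_dump <- function(test, ref, prefix) {
  C <- dtw_cost_matrix(test, ref)
  D <- dtw_accumulate(C)
  path <- dtw_backtrack(D)
  write.table(C, paste0(prefix, "_C.txt"), row.names = FALSE, col.names = FALSE)
  write.table(D, paste0(prefix, "_D.txt"), row.names = FALSE, col.names = FALSE)
  write.table(path, paste0(prefix, "_path.txt"), row.names = FALSE,
              col.names = FALSE)
  invisible(structure(list(total_cost = D[nrow(D), ncol(D)], path = path,
                           L = nrow(path)), class = "dtw_result"))
}
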
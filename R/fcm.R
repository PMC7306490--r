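# Fuzzy c-means clustering.
#
# The objective is the membership-weighted within-cluster sum of
# squares
#     J_f = sum_j sum_i mu_j(x_i)^b || x_i - m_j ||^2 ,   1 <= b < inf,
# minimized under the constraint sum_j mu_j(x_i) = 1 by alternating the
# stationarity conditions: centers are the mu^b-weighted means of the
# data, and memberships are
#     mu_j(x_i) = ||x_i - m_j||^{-2/(b-1)} / sum_s ||x_i - m_s||^{-2/(b-1)} .
# Iteration stops when max_{ij} |mu_j(x_i)^{(k+1)} - mu_j(x_i)^{(k)}|
# < epsilon.

fcm_memberships <- function(x, centers, b) {
  n <- nrow(x); k <- nrow(centers)
  d2 <- sapply(seq_len(k), function(j)
    rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  d2 <- matrix(d2, n, k)
  u <- matrix(0, n, k)
  zero <- d2 <= .Machine$double.eps^2
  has_zero <- rowSums(zero) > 0
  if (any(has_zero)) {
    # coincident point and center: full membership on the zero-distance
    # center(s), the limit of the update rule
    u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  }
  if (any(!has_zero)) {
    w <- d2[!has_zero, , drop = FALSE]^(-1 / (b - 1))
    u[!has_zero, ] <- w / rowSums(w)
  }
  u
}

fcm_centers <- function(x, u, b) {
  ub <- u^b
  (t(ub) %*% x) / colSums(ub)
}

fcm_objective <- function(x, u, centers, b) {
  n <- nrow(x)
  d2 <- sapply(seq_len(nrow(centers)), function(j)
    rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  sum(u^b * matrix(d2, n, nrow(centers)))
}

#' Fit a fuzzy c-means model
#'
#' Alternating optimization of the fuzzy c-means objective (see the
#' file header for the update equations). Each restart initializes the
#' cluster centers at `k` distinct randomly chosen data points (a
#' random membership matrix would start both centers at the global
#' mean -- the symmetric saddle point of the objective -- where the
#' membership-change criterion stops the iteration immediately), then
#' repeats: memberships from current centers, centers from current
#' memberships, until the largest absolute membership change falls
#' below `epsilon` or `max_iter` is reached. The restart with the
#' lowest final objective is kept. Deterministic given `seed`.
#'
#' @param x numeric matrix (n points x p features) or data.frame.
#' @param k number of clusters (1 <= k <= n).
#' @param b fuzzifier / weighting exponent, > 1 (default 2, the
#'   conventional choice).
#' @param epsilon convergence tolerance on memberships (default 1e-5).
#' @param max_iter iteration cap per restart (default 300).
#' @param n_restarts random restarts (default 10).
#' @param seed RNG seed.
#' @return object of class `fcm_model`: `k`, `b`, `centers` (k x p),
#'   `memberships` (n x k, rows sum to 1), `objective_trace` (J_f per
#'   iteration of the winning restart), `epsilon`, `iterations`,
#'   `converged`.
#' @export
fcm_fit <- function(x, k, b = 2, epsilon = 1e-5, max_iter = 300,
                    n_restarts = 10, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop_param("non-finite feature values")
  n <- nrow(x)
  if (k < 1 || k > n) stop_param("need 1 <= k <= n (k = %d, n = %d)", k, n)
  if (b <= 1) stop_param("b must be > 1")
  if (epsilon <= 0) stop_param("epsilon must be > 0")
  run_once <- function() {
    init <- if (k < n) sample.int(n, k) else seq_len(n)
    centers <- x[init, , drop = FALSE]
    u <- fcm_memberships(x, centers, b)
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      centers <- fcm_centers(x, u, b)
      u_new <- fcm_memberships(x, centers, b)
      trace <- c(trace, fcm_objective(x, u_new, centers, b))
      delta <- max(abs(u_new - u))
      u <- u_new
      if (delta < epsilon) { converged <- TRUE; break }
    }
    centers <- fcm_centers(x, u, b)
    list(u = u, centers = centers, trace = trace, iterations = iter,
         converged = converged,
         objective = fcm_objective(x, fcm_memberships(x, centers, b), centers, b))
  }
  best <- with_seed(seed, {
    fits <- lapply(seq_len(max(1L, n_restarts)), function(r) run_once())
    fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  })
  structure(list(k = k, b = b, centers = best$centers,
                 memberships = best$u, objective_trace = best$trace,
                 epsilon = epsilon, iterations = best$iterations,
                 converged = best$converged, objective = best$objective),
            class = "fcm_model")
}

#' Memberships and hard labels for new points
#'
#' Evaluates the membership update rule with the fitted centers frozen;
#' the hard label is the argmax membership. For two clusters with
#' b = 2 the implied decision boundary is the perpendicular bisector of
#' the segment joining the centers.
#'
#' @param model an `fcm_model`.
#' @param points matrix/data.frame with the model's feature
#'   dimensionality.
#' @return list with `memberships` (rows sum to 1) and `labels`
#'   (cluster indices).
#' @export
fcm_predict <- function(model, points) {
  stopifnot(inherits(model, "fcm_model"))
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != ncol(model$centers))
    stop_param("points have %d columns, model expects %d",
               ncol(pts), ncol(model$centers))
  u <- fcm_memberships(pts, model$centers, model$b)
  list(memberships = u, labels = max.col(u, ties.method = "first"))
}

#' @export
print.fcm_model <- function(x, ...) {
  cat(sprintf("<fcm_model> k = %d, b = %g: %s after %d iterations (J_f = %.6g)\n",
              x$k, x$b, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$objective))
  invisible(x)
}
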
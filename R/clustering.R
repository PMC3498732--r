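#' Positive-correlation distance between profiles
#'
#' d = 1 - Pearson r, so identically shaped profiles are at distance 0
#' and perfectly anti-correlated ones at distance 2. The distance ignores
#' scale and offset, which is why it is paired with mean-normalized
#' profiles. Convention for degenerate input: if both profiles are
#' constant they are at distance 0 when equal after mean normalization
#' (any two non-zero constants) and 1 otherwise; one constant profile
#' against a non-constant one is at distance 1 (uncorrelated).
#'
#' @param x,y numeric profiles of equal length >= 3.
#' @return distance in `[0, 2]`.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("profiles must have equal length >= 3")
  cx <- stats::sd(x) == 0
  cy <- stats::sd(y) == 0
  if (cx || cy) {
    if (cx && cy) {
      if ((x[1] == 0) != (y[1] == 0)) return(1)
      return(0)
    }
    return(1)
  }
  1 - stats::cor(x, y)
}

row_normalize <- function(m) {
  rm <- rowMeans(m)
  bad <- rm == 0
  m[!bad, ] <- m[!bad, , drop = FALSE] / rm[!bad]
  m
}

# genes x k matrix of 1 - cor(profile, centroid); constant rows fall back
# to the scalar convention
dist_to_centroids <- function(profiles, centroids) {
  sds_p <- apply(profiles, 1, stats::sd)
  sds_c <- apply(centroids, 1, stats::sd)
  d <- matrix(1, nrow(profiles), nrow(centroids))
  ok_p <- sds_p > 0
  ok_c <- sds_c > 0
  if (any(ok_p) && any(ok_c))
    d[ok_p, ok_c] <- 1 - stats::cor(t(profiles[ok_p, , drop = FALSE]),
                                    t(centroids[ok_c, , drop = FALSE]))
  if (any(!ok_p) && any(!ok_c))
    d[!ok_p, !ok_c] <- 0
  d
}

kmeans_once <- function(profiles, k, max_iterations) {
  n <- nrow(profiles)
  # k-means++-style seeding with d = 1 - r
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) for (j in 2:k) {
    d <- dist_to_centroids(profiles, profiles[centers[1:(j - 1)], , drop = FALSE])
    w <- apply(d, 1, min)
    w[centers[1:(j - 1)]] <- 0
    centers[j] <- if (sum(w) > 0) sample.int(n, 1, prob = w) else
      sample.int(n, 1)
  }
  centroids <- profiles[centers, , drop = FALSE]
  labels <- rep(0L, n)
  objective <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iterations)) {
    d <- dist_to_centroids(profiles, centroids)
    new_labels <- max.col(-d, ties.method = "first")
    # re-seed empty clusters with the point farthest from its centroid
    for (j in which(tabulate(new_labels, k) == 0)) {
      far <- which.max(d[cbind(seq_len(n), new_labels)])
      new_labels[far] <- j
      d[far, ] <- 0  # cannot be stolen again this round
    }
    new_centroids <- t(vapply(seq_len(k), function(j)
      colMeans(profiles[new_labels == j, , drop = FALSE]),
      numeric(ncol(profiles))))
    new_centroids <- row_normalize(new_centroids)
    new_obj <- sum(dist_to_centroids(profiles, new_centroids)[
      cbind(seq_len(n), new_labels)])
    if (new_obj > objective + 1e-12) break  # mean update no longer improves
    converged <- identical(new_labels, labels)
    labels <- new_labels
    centroids <- new_centroids
    objective <- new_obj
    trace <- c(trace, objective)
    if (converged) break
  }
  list(labels = labels, centroids = centroids, objective = objective,
       iterations = length(trace), trace = trace)
}

#' k-means clustering under the positive-correlation distance
#'
#' Lloyd iterations on mean-normalized profiles with d = 1 - Pearson r:
#' genes are assigned to the nearest centroid (ties to the lowest
#' cluster index) and centroids are updated as the arithmetic mean of
#' their members, re-mean-normalized to stay on the profile scale.
#' Iteration stops at label convergence, at `max_iterations`, or if the
#' mean update stops decreasing the objective (the mean is not the exact
#' minimizer of total correlation distance, so monotonicity is enforced
#' rather than assumed). The best of `n_restarts` distance-weighted
#' random initialisations by total objective is returned; results are
#' deterministic at a fixed seed.
#'
#' @param profiles genes x conditions matrix (mean-normalized; rows are
#'   re-normalized defensively).
#' @param k number of clusters (default 7).
#' @param max_iterations cap on Lloyd iterations per restart (default 1000).
#' @param n_restarts random restarts (default 10).
#' @param seed RNG seed.
#' @return a `cluster_assignment` list: `cluster` (named integer vector),
#'   `centroids` (k x conditions), `objective` (total 1 - r),
#'   `objective_trace`, `iterations`, `k`.
#' @export
kmeans_correlation <- function(profiles, k = 7, max_iterations = 1000,
                               n_restarts = 10, seed = 1) {
  stopifnot(is.matrix(profiles))
  if (k < 1 || max_iterations < 1) stop("k and max_iterations must be >= 1")
  if (nrow(profiles) < k)
    stop("fewer genes (", nrow(profiles), ") than clusters (", k, ")")
  profiles <- row_normalize(profiles)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    run <- kmeans_once(profiles, k, max_iterations)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  cl <- best$labels
  names(cl) <- rownames(profiles)
  rownames(best$centroids) <- paste0("cluster", seq_len(k))
  structure(list(cluster = cl, centroids = best$centroids,
                 objective = best$objective,
                 objective_trace = best$trace,
                 iterations = best$iterations, k = k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("k-means (correlation distance): k = %d, objective = %.4g\n",
              x$k, x$objective))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Detect a growth-rate expression threshold in a profile
#'
#' Fits, for every interior condition, a continuous flat-then-linear
#' model in log10(mu): constant at `plateau_level` below the candidate
#' breakpoint and linear above it. The breakpoint minimizing the SSE is
#' retained and compared against a single straight line by an F-test
#' (one extra parameter for the breakpoint); if the piecewise model is
#' not significantly better at `alpha` the profile is reported as having
#' no threshold. A globally flat or perfectly log-linear profile
#' therefore yields no threshold.
#'
#' @param values mean-normalized expression at each condition.
#' @param growth_rates matching specific growth rates (h^-1), >= 5.
#' @param alpha F-test level (default 0.05).
#' @return list `threshold` (logical), `breakpoint` (h^-1 or NA),
#'   `direction` (`"up"`/`"down"`: slope sign of the non-flat segment),
#'   `plateau_level`, `sse`, `p_value`.
#' @export
detect_threshold <- function(values, growth_rates, alpha = 0.05) {
  n <- length(values)
  if (n != length(growth_rates) || n < 5)
    stop("need >= 5 matched (value, growth rate) conditions")
  o <- order(growth_rates)
  x <- log10(growth_rates[o])
  y <- values[o]
  line <- stats::lm.fit(cbind(1, x), y)
  sse_line <- sum(line$residuals^2)
  scale <- max(sum((y - mean(y))^2), .Machine$double.eps)
  none <- list(threshold = FALSE, breakpoint = NA_real_,
               direction = NA_character_, plateau_level = mean(y),
               sse = sse_line, p_value = 1)
  if (sse_line <= 1e-10 * scale) return(none)  # a single line explains it
  best <- NULL
  for (b in 2:(n - 1)) {
    X <- cbind(1, pmax(x - x[b], 0))
    f <- stats::lm.fit(X, y)
    sse <- sum(f$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(b = b, sse = sse, coef = f$coefficients)
  }
  fstat <- (sse_line - best$sse) / (best$sse / (n - 3))
  p <- if (best$sse == 0) 0 else stats::pf(fstat, 1, n - 3, lower.tail = FALSE)
  if (!is.finite(p) || p >= alpha) return(none)
  list(threshold = TRUE, breakpoint = 10^x[best$b],
       direction = if (best$coef[2] >= 0) "up" else "down",
       plateau_level = unname(best$coef[1]), sse = best$sse, p_value = p)
}
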
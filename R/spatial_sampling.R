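# Geographically even selection of k sampling locations by simulated
# annealing over geodesic distances.

subset_objective <- function(dmat, idx, objective) {
  d <- dmat[idx, idx]
  offdiag <- d[upper.tri(d)]
  if (objective == "maximin") {
    # p-dispersion score; a vanishing share of the total distance breaks
    # ties among subsets with an equal minimum
    min(offdiag) + 1e-9 * sum(offdiag)
  } else {
    sum(offdiag)
  }
}

#' Select geographically even sampling locations by simulated annealing
#'
#' Chooses `k` of the candidate points so that the selected set is
#' geographically even under the chosen objective: `"maximin"` maximises
#' the minimum pairwise geodesic distance (p-dispersion, tie-broken by the
#' total pairwise distance), `"sumdist"` maximises the total pairwise
#' distance. Each annealing step proposes swapping one chosen point with
#' one unchosen point; temperature decays geometrically; the best subset
#' ever seen is returned. Deterministic for a given `seed`.
#'
#' @param coords Data frame with columns `id`, `lat`, `lon`.
#' @param k Number of locations to select (`k <= nrow(coords)`).
#' @param iterations Number of proposal steps (default 100000).
#' @param seed Optional integer seed for reproducibility.
#' @param objective `"maximin"` (default) or `"sumdist"`.
#' @param dmat Optional precomputed geodesic distance matrix.
#' @return An object of class `"spatial_selection"`: list with `chosen`
#'   (row indices), `ids`, `objective_value`, `objective`, `iterations`,
#'   `seed`.
#' @export
spatial_sample <- function(coords, k, iterations = 100000L, seed = NULL,
                           objective = c("maximin", "sumdist"), dmat = NULL) {
  objective <- match.arg(objective)
  n <- nrow(coords)
  if (k > n) stop("k cannot exceed the number of candidate locations", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (is.null(dmat)) dmat <- geodesic_matrix(coords)

  if (k == n) {
    return(new_selection(seq_len(n), coords, dmat, objective, 0L, seed))
  }

  with_seed(seed, {
    chosen <- sample.int(n, k)
    cur <- subset_objective(dmat, chosen, objective)
    best <- chosen
    best_val <- cur

    # initial temperature from the spread of proposal deltas
    deltas <- replicate(100, {
      i <- sample.int(k, 1L)
      out <- setdiff(seq_len(n), chosen)
      j <- out[sample.int(length(out), 1L)]
      trial <- chosen
      trial[i] <- j
      subset_objective(dmat, trial, objective) - cur
    })
    t0 <- stats::sd(deltas)
    if (!is.finite(t0) || t0 <= 0) t0 <- max(abs(deltas), 1e-9)
    tf <- t0 * 1e-4
    alpha <- (tf / t0)^(1 / iterations)

    temp <- t0
    unchosen <- setdiff(seq_len(n), chosen)
    for (step in seq_len(iterations)) {
      i <- sample.int(k, 1L)
      j <- sample.int(n - k, 1L)
      trial <- chosen
      trial[i] <- unchosen[j]
      val <- subset_objective(dmat, trial, objective)
      if (val > cur || stats::runif(1) < exp((val - cur) / temp)) {
        old <- chosen[i]
        chosen <- trial
        unchosen[j] <- old
        cur <- val
        if (cur > best_val) {
          best_val <- cur
          best <- chosen
        }
      }
      temp <- temp * alpha
    }
    new_selection(sort(best), coords, dmat, objective, iterations, seed)
  })
}

new_selection <- function(idx, coords, dmat, objective, iterations, seed) {
  structure(
    list(chosen = idx,
         ids = coords$id[idx],
         objective_value = subset_objective(dmat, idx, objective),
         objective = objective,
         iterations = iterations,
         seed = seed),
    class = "spatial_selection"
  )
}

#' @export
print.spatial_selection <- function(x, ...) {
  cat(sprintf("Spatial selection: k = %d, objective %s = %g (%d annealing steps)\n",
              length(x$chosen), x$objective, x$objective_value, x$iterations))
  invisible(x)
}

#' Exhaustive optimum for small location-selection instances
#'
#' Enumerates every k-subset; used as the independent reference for the
#' annealing sampler on instances small enough to enumerate.
#'
#' @inheritParams spatial_sample
#' @return A `"spatial_selection"` holding the global optimum.
#' @export
spatial_sample_exhaustive <- function(coords, k, objective = c("maximin", "sumdist"),
                                      dmat = NULL) {
  objective <- match.arg(objective)
  n <- nrow(coords)
  if (k > n) stop("k cannot exceed the number of candidate locations", call. = FALSE)
  if (is.null(dmat)) dmat <- geodesic_matrix(coords)
  subsets <- utils::combn(n, k)
  vals <- apply(subsets, 2, function(idx) subset_objective(dmat, idx, objective))
  best <- which.max(vals)
  new_selection(subsets[, best], coords, dmat, objective, 0L, NULL)
}
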
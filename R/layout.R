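# Deme layouts: grid (stepping-stone) and random (island) arrangements,
# migration matrices, and deme-size schedules.

METERS_PER_DEG_EQ <- pi * GRS80_A / 180  # arc length of 1 degree at the equator

new_layout <- function(coords, migration, model, structure = NA_character_,
                       grid = NULL, sizes = NULL, spacing_km = NA_real_) {
  structure(
    list(coords = coords, migration = migration, model = model,
         structure = structure, grid = grid, sizes = sizes,
         n_demes = nrow(coords), spacing_km = spacing_km),
    class = "deme_layout"
  )
}

#' @export
print.deme_layout <- function(x, ...) {
  cat(sprintf("Deme layout: %d demes, model %s%s\n", x$n_demes, x$model,
              if (!is.na(x$structure)) paste0(" (structure ", x$structure, ")") else ""))
  if (!is.null(x$sizes)) cat(sprintf("  sizes: total %d\n", sum(x$sizes)))
  invisible(x)
}

#' Stepping-stone deme layout on a designed grid
#'
#' Builds the four designed subpopulation structures: `"linear"` (L x 1),
#' `"circle"` (L x 1 ring), `"plane"` (sqrt(L) x sqrt(L) grid) and
#' `"cylinder"` (L/2 x 2 with wrap-around along the long axis, realised as
#' two concentric rings). Adjacency is grid-wise (at most four neighbours)
#' and every adjacent pair receives the same migration rate. Coordinates
#' are placed near the equator with (approximately) equal adjacent-deme
#' arc spacing.
#'
#' @param structure One of `"linear"`, `"circle"`, `"plane"`, `"cylinder"`.
#' @param migration_rate Per-generation rate between each adjacent pair.
#' @param n_demes Number of demes (perfect square for `"plane"`, even for
#'   `"cylinder"`).
#' @param spacing_km Arc distance between adjacent demes (default 10 km).
#' @return A `"deme_layout"`.
#' @export
build_grid_layout <- function(structure = c("linear", "circle", "plane", "cylinder"),
                              migration_rate, n_demes = 100L, spacing_km = 10) {
  structure <- match.arg(structure)
  if (migration_rate < 0 || migration_rate >= 1) {
    stop("migration_rate must be in [0, 1)", call. = FALSE)
  }
  L <- as.integer(n_demes)
  sp_deg <- spacing_km * 1000 / METERS_PER_DEG_EQ

  if (structure == "linear") {
    coords <- data.frame(id = seq_len(L), lat = 0, lon = (seq_len(L) - 1L) * sp_deg)
    adj <- cbind(seq_len(L - 1L), 2:L)
    grid <- list(nx = L, ny = 1L, x = seq_len(L), y = rep(1L, L))
  } else if (structure == "circle") {
    r_deg <- sp_deg * L / (2 * pi)
    th <- 2 * pi * (seq_len(L) - 1L) / L
    coords <- data.frame(id = seq_len(L), lat = r_deg * sin(th), lon = r_deg * cos(th))
    adj <- cbind(seq_len(L), c(2:L, 1L))
    grid <- list(nx = L, ny = 1L, x = seq_len(L), y = rep(1L, L))
  } else if (structure == "plane") {
    side <- round(sqrt(L))
    if (side^2 != L) stop("'plane' requires a perfect-square number of demes", call. = FALSE)
    gx <- rep(seq_len(side), times = side)
    gy <- rep(seq_len(side), each = side)
    coords <- data.frame(id = seq_len(L), lat = (gy - 1L) * sp_deg, lon = (gx - 1L) * sp_deg)
    adj <- grid_adjacency(gx, gy, wrap_x = FALSE)
    grid <- list(nx = side, ny = side, x = gx, y = gy)
  } else { # cylinder
    if (L %% 2L != 0L) stop("'cylinder' requires an even number of demes", call. = FALSE)
    nx <- L %/% 2L
    gx <- rep(seq_len(nx), times = 2L)
    gy <- rep(1:2, each = nx)
    r1 <- sp_deg * nx / (2 * pi)
    r <- ifelse(gy == 1L, r1, r1 + sp_deg)
    th <- 2 * pi * (gx - 1L) / nx
    coords <- data.frame(id = seq_len(L), lat = r * sin(th), lon = r * cos(th))
    adj <- grid_adjacency(gx, gy, wrap_x = TRUE)
    grid <- list(nx = nx, ny = 2L, x = gx, y = gy)
  }

  mig <- matrix(0, L, L)
  mig[adj] <- migration_rate
  mig[adj[, 2:1, drop = FALSE]] <- migration_rate
  new_layout(coords, mig, model = "stepping_stone", structure = structure,
             grid = grid, spacing_km = spacing_km)
}

grid_adjacency <- function(gx, gy, wrap_x) {
  nx <- max(gx)
  idx <- function(x, y) which(gx == x & gy == y)
  pairs <- NULL
  for (i in seq_along(gx)) {
    # right neighbour (wrapping if requested)
    xr <- gx[i] + 1L
    if (xr > nx && wrap_x) xr <- 1L
    if (xr <= nx && !(wrap_x && nx == 2L && xr == gx[i])) {
      j <- idx(xr, gy[i])
      if (length(j) == 1L && j != i) pairs <- rbind(pairs, c(i, j))
    }
    # upper neighbour
    j <- idx(gx[i], gy[i] + 1L)
    if (length(j) == 1L) pairs <- rbind(pairs, c(i, j))
  }
  unique(t(apply(pairs, 1, sort)))
}

#' Island-model layout with distance-dependent migration
#'
#' Places demes at independent uniform random coordinates and assigns
#' migration between every pair of demes, inversely proportional to their
#' GRS80 geodesic distance. Three scalings of the inverse-distance kernel
#' are offered:
#' \describe{
#'   \item{`"printed"` (default)}{`m_ij = (r/dbar) * (1/d_ij) / (1/sum d_kl)`,
#'     which simplifies to `r * L(L-1) / d_ij` with `d_ij` in metres. The
#'     absolute rates therefore depend on the geographic scale of the
#'     layout; on continental-to-global layouts they are small, giving
#'     strongly structured populations at low `r`.}
#'   \item{`"pair_mean"`}{`m_ij = r * (1/d_ij) / mean(1/d_kl)`: the mean
#'     rate over ordered deme pairs equals `r`.}
#'   \item{`"lineage_mean"`}{as `"pair_mean"` divided by `L - 1`: the mean
#'     total emigration rate of an individual equals `r`.}
#' }
#'
#' @param n_demes Number of demes.
#' @param migration_rate Migration level `r` (interpreted by `scaling`).
#' @param seed Optional seed for the random coordinates.
#' @param lat_range,lon_range Coordinate ranges (decimal degrees).
#' @param scaling Scaling of the inverse-distance kernel (see Details).
#' @param min_distance Distance floor (metres) applied to coincident
#'   points before inversion.
#' @return A `"deme_layout"`.
#' @export
build_island_layout <- function(n_demes = 100L, migration_rate, seed = NULL,
                                lat_range = c(-90, 90), lon_range = c(-180, 180),
                                scaling = c("printed", "pair_mean", "lineage_mean"),
                                min_distance = 1) {
  scaling <- match.arg(scaling)
  if (migration_rate <= 0 || migration_rate >= 1) {
    stop("migration_rate must be in (0, 1)", call. = FALSE)
  }
  L <- as.integer(n_demes)
  coords <- with_seed(seed, data.frame(
    id = seq_len(L),
    lat = stats::runif(L, lat_range[1], lat_range[2]),
    lon = stats::runif(L, lon_range[1], lon_range[2])
  ))
  d <- geodesic_matrix(coords)
  off <- row(d) != col(d)
  if (any(d[off] < min_distance)) {
    message("coincident or near-coincident demes; applying the minimum-distance floor")
    d[off & d < min_distance] <- min_distance
  }
  mig <- matrix(0, L, L)
  mig[off] <- switch(scaling,
    printed = {
      dbar <- mean(d[off])
      migration_rate / dbar * (1 / d[off]) / (1 / sum(d[off]))
    },
    pair_mean = migration_rate * (1 / d[off]) / mean(1 / d[off]),
    lineage_mean = migration_rate * (1 / d[off]) / mean(1 / d[off]) / (L - 1)
  )
  new_layout(coords, mig, model = "island")
}

#' Single-deme (panmictic) layout
#'
#' @param N Optional haploid population size (sets the deme size).
#' @param lat,lon Coordinates of the single deme (cosmetic).
#' @return A `"deme_layout"` with one deme and no migration.
#' @export
build_single_layout <- function(N = NULL, lat = 0, lon = 0) {
  lay <- new_layout(data.frame(id = 1L, lat = lat, lon = lon),
                    matrix(0, 1, 1), model = "single")
  if (!is.null(N)) lay$sizes <- as.integer(N)
  lay
}

#' Largest-remainder apportionment of a total into integer sizes
#'
#' Rounds all fractional sizes down, then hands out the remaining units
#' one by one to the entries with the largest rounded-down residuals
#' (ties broken by position), so the sizes sum exactly to `total`.
#'
#' @param weights Non-negative weights (any scale).
#' @param total Integer total to apportion.
#' @return Integer vector summing to `total`.
#' @examples
#' largest_remainder(c(3.6, 3.6, 2.8), 10)  # 4 3 3
#' @export
largest_remainder <- function(weights, total) {
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  x <- weights / sum(weights) * total
  flo <- floor(x)
  rem <- x - flo
  need <- as.integer(round(total - sum(flo)))
  if (need > 0L) {
    ord <- order(rem, decreasing = TRUE)
    flo[ord[seq_len(need)]] <- flo[ord[seq_len(need)]] + 1
  }
  as.integer(flo)
}

#' Assign deme sizes under a scheme
#'
#' Schemes: `"even"` (equal sizes), `"truncated_normal"` (grid position
#' mapped linearly into `[-3, 3]` per axis and weighted by the standard
#' normal density; the centre-periphery shape), `"latitude_normal"`
#' (weights `dnorm(0.027 * lat_i)`, larger sizes near the equator). All
#' schemes use largest-remainder apportionment so sizes are positive
#' integers summing exactly to `total`; zero sizes are promoted to 1 with
#' a compensating decrement of the largest deme.
#'
#' @param layout A `"deme_layout"`.
#' @param scheme Size scheme.
#' @param total Total number of haploid individuals.
#' @param lat_coef Coefficient of the latitude scheme (default 0.027).
#' @return The layout with its `sizes` field set.
#' @export
assign_sizes <- function(layout,
                         scheme = c("even", "truncated_normal", "latitude_normal"),
                         total, lat_coef = 0.027) {
  scheme <- match.arg(scheme)
  L <- layout$n_demes
  if (total < L) stop("total must be at least the number of demes", call. = FALSE)
  w <- switch(scheme,
    even = rep(1, L),
    truncated_normal = {
      g <- layout$grid
      if (is.null(g)) stop("truncated_normal requires a grid layout", call. = FALSE)
      zx <- if (g$nx > 1L) -3 + 6 * (g$x - 1L) / (g$nx - 1L) else rep(0, L)
      wx <- stats::dnorm(zx)
      if (g$ny > 1L) {
        zy <- -3 + 6 * (g$y - 1L) / (g$ny - 1L)
        wx * stats::dnorm(zy)
      } else {
        wx
      }
    },
    latitude_normal = stats::dnorm(lat_coef * layout$coords$lat)
  )
  sizes <- largest_remainder(w, total)
  zero <- sizes == 0L
  if (any(zero)) {
    message(sum(zero), " deme(s) apportioned zero individuals; promoted to 1")
    for (i in which(zero)) {
      big <- which.max(sizes)
      sizes[big] <- sizes[big] - 1L
      sizes[i] <- 1L
    }
  }
  layout$sizes <- sizes
  layout
}
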
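# Geodesic distances on the GRS80 reference ellipsoid.

GRS80_A <- 6378137        # semi-major axis, metres
GRS80_F <- 1 / 298.257222101  # flattening

#' Geodesic distance between points on the GRS80 ellipsoid
#'
#' Vectorised over coordinates; wraps [geosphere::distGeo()] with the
#' GRS80 ellipsoid parameters (semi-major axis 6378137 m, flattening
#' 1/298.257222101).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees
#'   (`lat` in `[-90, 90]`, `lon` in `[-180, 180)`).
#' @return Distance(s) in metres.
#' @examples
#' geodesic_distance(0, 0, 0, 1)  # ~111319.49 m
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2),
                     a = GRS80_A, f = GRS80_F)
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon >= 360)) stop("longitude out of range", call. = FALSE)
  invisible(NULL)
}

#' Pairwise geodesic distance matrix
#'
#' @param coords A data frame with columns `lat` and `lon` (decimal
#'   degrees), one row per point.
#' @return A symmetric matrix of distances in metres.
#' @export
geodesic_matrix <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d[i, j] <- geodesic_distance(coords$lat[i], coords$lon[i],
                                 coords$lat[j], coords$lon[j])
    d[j, i] <- d[i, j]
  }
  d
}
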
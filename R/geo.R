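#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over
#' coordinates given in decimal degrees.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees; latitudes must lie in
#'   \[-90, 90\].
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude out of [-90, 90]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Inverse-distance-weighted haplogroup frequency surface
#'
#' Average-weighted interpolation of observed population frequencies onto a
#' regular latitude/longitude grid: the value at a grid point is the
#' weighted mean of all observations within the search radius, with weights
#' `1 / max(d, d_floor)^power`; grid points with no observation in range
#' are `NA`. The distance floor — half the grid spacing, converted to km —
#' keeps a grid point coincident with an observation finite (it then
#' dominates the average, and an exactly coincident lone observation is
#' reproduced). The defaults, a 400 km search radius and a weight power of
#' 2, are the published mapping parameters.
#'
#' @param obs Data frame with columns `lat`, `lon`, `freq` (percent).
#' @param lat_range,lon_range Grid extents in degrees (default: observation
#'   bounding box padded by 2 degrees).
#' @param spacing Grid spacing in degrees (default 0.5).
#' @param radius_km Search radius in km (default 400).
#' @param power Weight exponent (default 2); larger values concentrate the
#'   surface towards the nearest observation.
#' @return Object of class `frequency_surface`: `lat`, `lon` (grid axes),
#'   `values` (matrix lat x lon, % or NA), `params`.
#' @export
interpolate_surface <- function(obs, lat_range = NULL, lon_range = NULL,
                                spacing = 0.5, radius_km = 400, power = 2) {
  obs <- as.data.frame(obs)
  if (!all(c("lat", "lon", "freq") %in% names(obs)))
    stop("obs needs columns lat, lon, freq")
  if (nrow(obs) == 0L) stop("no observations")
  if (any(abs(obs$lat) > 90)) stop("latitude out of [-90, 90]")
  if (radius_km <= 0) stop("radius must be positive")
  if (power < 0) stop("power must be non-negative")
  if (is.null(lat_range)) lat_range <- range(obs$lat) + c(-2, 2)
  if (is.null(lon_range)) lon_range <- range(obs$lon) + c(-2, 2)
  lat <- seq(lat_range[1], lat_range[2], by = spacing)
  lon <- seq(lon_range[1], lon_range[2], by = spacing)
  d_floor <- spacing * 111.195 / 2  # half grid spacing in km at the meridian
  vals <- matrix(NA_real_, length(lat), length(lon),
                 dimnames = list(lat = lat, lon = lon))
  for (i in seq_along(lat)) {
    d <- great_circle_km(rep(lat[i], nrow(obs) * length(lon)),
                         rep(lon, each = nrow(obs)),
                         rep(obs$lat, length(lon)),
                         rep(obs$lon, length(lon)))
    d <- matrix(d, nrow(obs), length(lon))
    w <- 1 / pmax(d, d_floor)^power
    w[d > radius_km] <- 0
    tot <- colSums(w)
    v <- as.numeric(crossprod(w, obs$freq)) / tot
    v[tot == 0] <- NA_real_
    vals[i, ] <- v
  }
  structure(list(lat = lat, lon = lon, values = vals,
                 params = list(spacing = spacing, radius_km = radius_km,
                               power = power, d_floor_km = d_floor)),
            class = "frequency_surface")
}

#' @export
print.frequency_surface <- function(x, ...) {
  cat(sprintf("<frequency_surface> %d x %d grid (%.2g deg), radius %g km, power %g\n",
              length(x$lat), length(x$lon), x$params$spacing,
              x$params$radius_km, x$params$power))
  cat(sprintf("  %d of %d cells interpolated, range %.1f-%.1f%%\n",
              sum(!is.na(x$values)), length(x$values),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' @export
as.data.frame.frequency_surface <- function(x, ...) {
  data.frame(lon = rep(x$lon, each = length(x$lat)),
             lat = rep(x$lat, length(x$lon)),
             value = as.numeric(x$values))
}

#' Write a frequency surface as a plain-text raster
#'
#' Long-format TSV (`lon`, `lat`, `value`), NA cells written as `NA`.
#'
#' @param surface A [interpolate_surface()] result.
#' @param path Output path.
#' @export
write_surface <- function(surface, path) {
  utils::write.table(as.data.frame(surface), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
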
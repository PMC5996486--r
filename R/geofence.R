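# Sphere radius used throughout; sub-metre ellipsoid error is irrelevant at
# the 0.2-3 km fence scales.
EARTH_RADIUS_KM <- 6371

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized over pairs;
#' scalar arguments recycle.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

check_coords <- function(lat, lon) {
  if (any(is.na(lat)) || any(is.na(lon)) ||
      any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("coordinates out of bounds: latitude in [-90, 90], longitude in ",
         "[-180, 180]", call. = FALSE)
  }
  invisible(NULL)
}

#' Load points of interest from CSV
#'
#' OurAirports-compatible columns: `id`, `type`, `name`, `latitude_deg`,
#' `longitude_deg`. Rows whose `type` does not match `class_filter` are
#' dropped; rows with missing or out-of-bounds coordinates are skipped with
#' a message.
#'
#' @param path CSV path.
#' @param kind `"airport"` or `"hospital"` label attached to the result.
#' @param class_filter Keep only rows with this `type` value (e.g.
#'   `"large_airport"`); `NULL` keeps all.
#' @return A tibble with columns `poi_id`, `kind`, `name`, `lat`, `lon`,
#'   `poi_class`.
#' @export
load_pois <- function(path, kind = c("airport", "hospital"),
                      class_filter = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  need <- c("id", "type", "latitude_deg", "longitude_deg")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("POI file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(class_filter)) {
    df <- df[df$type %in% class_filter, , drop = FALSE]
  }
  lat <- suppressWarnings(as.numeric(df$latitude_deg))
  lon <- suppressWarnings(as.numeric(df$longitude_deg))
  bad <- is.na(lat) | is.na(lon) | abs(lat) > 90 | abs(lon) > 180
  if (any(bad)) {
    message("skipping ", sum(bad), " POI rows with invalid coordinates")
  }
  keep <- !bad
  tibble::tibble(
    poi_id = df$id[keep],
    kind = kind,
    name = if ("name" %in% names(df)) df$name[keep] else df$id[keep],
    lat = lat[keep],
    lon = lon[keep],
    poi_class = df$type[keep]
  )
}

# Unit-sphere Cartesian coordinates; chord length is monotone in
# great-circle distance, so nearest-by-chord == nearest-by-arc.
to_xyz <- function(lat, lon) {
  la <- lat * pi / 180
  lo <- lon * pi / 180
  cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

chord_to_km <- function(chord) {
  2 * EARTH_RADIUS_KM * asin(pmin(1, chord / 2))
}

#' Distance to the nearest POI
#'
#' For each query point, the great-circle distance (km) to the closest POI.
#' `method = "brute"` scans all POIs and is the reference; `method = "grid"`
#' uses a 3-D cell index over unit-sphere coordinates with expanding-ring
#' search and returns identical results.
#'
#' @param lat,lon Query coordinates (degrees), equal length.
#' @param pois POI tibble from [load_pois()] or [generate_pois()].
#' @param method `"brute"` or `"grid"`.
#' @return Numeric vector of nearest distances; `Inf` where `pois` is empty.
#' @export
nearest_poi_km <- function(lat, lon, pois, method = c("brute", "grid")) {
  method <- match.arg(method)
  n <- length(lat)
  if (is.null(pois) || nrow(pois) == 0) return(rep(Inf, n))
  check_coords(lat, lon)
  check_coords(pois$lat, pois$lon)
  if (method == "brute") {
    out <- numeric(n)
    pm <- cbind(pois$lon, pois$lat)
    for (i in seq_len(n)) {
      d <- geosphere::distHaversine(c(lon[i], lat[i]), pm,
                                    r = EARTH_RADIUS_KM * 1000) / 1000
      out[i] <- min(d)
    }
    return(out)
  }
  nearest_poi_km_grid(lat, lon, pois)
}

nearest_poi_km_grid <- function(lat, lon, pois, cell = 0.2) {
  pxyz <- to_xyz(pois$lat, pois$lon)
  key <- function(m) paste(floor(m[, 1] / cell), floor(m[, 2] / cell),
                           floor(m[, 3] / cell), sep = ",")
  buckets <- split(seq_len(nrow(pois)), key(pxyz))
  qxyz <- to_xyz(lat, lon)
  out <- numeric(length(lat))
  max_ring <- ceiling(2 / cell) + 1
  # cell offsets at each Chebyshev ring, computed once
  ring_offs <- lapply(0:max_ring, function(ring) {
    offs <- expand.grid(dx = -ring:ring, dy = -ring:ring, dz = -ring:ring)
    as.matrix(offs[pmax(abs(offs$dx), abs(offs$dy), abs(offs$dz)) == ring, ,
                   drop = FALSE])
  })
  for (i in seq_along(lat)) {
    q <- qxyz[i, ]
    cq <- floor(q / cell)
    best <- Inf
    for (ring in 0:max_ring) {
      # a point in a ring-k cell is at least (k-1)*cell away in chord space,
      # so once a candidate is closer than that the search can stop
      if (is.finite(best) && (ring - 1) * cell > best) break
      offs <- ring_offs[[ring + 1]]
      keys <- paste(cq[1] + offs[, 1], cq[2] + offs[, 2], cq[3] + offs[, 3],
                    sep = ",")
      idx <- unlist(buckets[keys], use.names = FALSE)
      if (length(idx) > 0) {
        d2 <- sqrt(colSums((t(pxyz[idx, , drop = FALSE]) - q)^2))
        best <- min(best, min(d2))
      }
    }
    out[i] <- chord_to_km(best)
  }
  out
}

#' Assign tweets to the airport / hospital / geolocated collections
#'
#' Membership is a radial geofence: a tweet belongs to a collection when its
#' great-circle distance to the nearest POI of that kind is at most the
#' collection radius (boundary inclusive). A tweet may be in both the
#' airport and hospital collections; "geolocated" means in neither.
#'
#' @param tweets Tweet tibble with `tweet_id`, `lat`, `lon`.
#' @param airports,hospitals POI tibbles (may be empty).
#' @param airport_radius_km Airport fence radius, default 3.
#' @param hospital_radius_km Hospital fence radius, default 0.2.
#' @param method Nearest-neighbour search method, see [nearest_poi_km()].
#' @return A tibble with columns `tweet_id`, `in_airport`, `in_hospital`,
#'   `nearest_airport_km`, `nearest_hospital_km`, `collection`
#'   (`"airport"`, `"hospital"`, `"both"`, or `"geolocated"`).
#' @export
classify_tweets <- function(tweets, airports, hospitals,
                            airport_radius_km = 3, hospital_radius_km = 0.2,
                            method = "brute") {
  da <- nearest_poi_km(tweets$lat, tweets$lon, airports, method = method)
  dh <- nearest_poi_km(tweets$lat, tweets$lon, hospitals, method = method)
  in_a <- da <= airport_radius_km
  in_h <- dh <= hospital_radius_km
  tibble::tibble(
    tweet_id = tweets$tweet_id,
    in_airport = in_a,
    in_hospital = in_h,
    nearest_airport_km = da,
    nearest_hospital_km = dh,
    collection = dplyr::case_when(
      in_a & in_h ~ "both",
      in_a ~ "airport",
      in_h ~ "hospital",
      TRUE ~ "geolocated"
    )
  )
}
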
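#' Great-circle distance between GPS coordinates
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius), via `geosphere::distHaversine()`. Vectorized over fixes.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in metres.
#' @examples
#' haversine_m(0, 0, 0, 1)  # ~111.195 km
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8)
}

#' Personal place maps
#'
#' A personal map is a per-user registry of named places (Home, Office,
#' Restaurant, Gym, Mall) with a centre coordinate and a matching radius in
#' metres, enabling user-centric location labels: the same coordinates can
#' be one user's Home and another's Office.
#'
#' @param user_id Character user identifier.
#' @param places Data frame with columns `label`, `lat`, `lon`, `radius_m`.
#'   Labels must be unique and drawn from [location_labels()]; radii must be
#'   positive.
#' @return An object of class `personal_map`.
#' @export
personal_map <- function(user_id, places) {
  places <- tibble::as_tibble(places)
  stopifnot(all(c("label", "lat", "lon", "radius_m") %in% names(places)))
  check_labels(places$label, "location")
  if (anyDuplicated(places$label)) stop("duplicate place label in map")
  if (any(places$radius_m <= 0)) stop("place radius must be positive")
  if (any(abs(places$lat) > 90) || any(abs(places$lon) > 180)) {
    stop("coordinates out of range")
  }
  structure(list(user_id = as.character(user_id), places = places),
            class = "personal_map")
}

#' @export
print.personal_map <- function(x, ...) {
  cat(sprintf("Personal map for %s (%d places)\n", x$user_id,
              nrow(x$places)))
  print(x$places)
  invisible(x)
}

#' @rdname personal_map
#' @param path JSON file with fields `user` and
#'   `places: [{label, lat, lon, radius_m}]`.
#' @export
read_personal_map <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  personal_map(raw$user, tibble::as_tibble(raw$places))
}

#' @rdname personal_map
#' @param map A `personal_map`.
#' @export
write_personal_map <- function(map, path) {
  jsonlite::write_json(list(user = map$user_id, places = map$places), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Resolve GPS fixes to personal place labels
#'
#' Each fix is assigned the label of the nearest place whose distance does
#' not exceed that place's radius, or `"Unknown"` when every place is out
#' of range. Ties (equal distances) break lexicographically by label, so
#' resolution is deterministic.
#'
#' @param fixes Data frame of fixes with columns `t`, `lat`, `lon`.
#' @param map A [personal_map()].
#' @return The `fixes` tibble with an added `label` column.
#' @export
resolve_place <- function(fixes, map) {
  stopifnot(inherits(map, "personal_map"))
  if (nrow(map$places) == 0) stop("personal map is empty")
  fixes <- tibble::as_tibble(fixes)
  if (any(abs(fixes$lat) > 90) || any(abs(fixes$lon) > 180)) {
    stop("fix coordinates out of range")
  }
  pl <- map$places
  # fixes x places distance matrix
  d <- vapply(seq_len(nrow(pl)), function(j) {
    haversine_m(fixes$lat, fixes$lon, pl$lat[j], pl$lon[j])
  }, numeric(nrow(fixes)))
  d <- matrix(d, nrow = nrow(fixes))
  in_range <- sweep(d, 2, pl$radius_m, "<=")
  labels <- vapply(seq_len(nrow(fixes)), function(i) {
    cand <- which(in_range[i, ])
    if (length(cand) == 0) return("Unknown")
    cand <- cand[order(d[i, cand], pl$label[cand], method = "radix")]
    pl$label[cand[1]]
  }, character(1))
  dplyr::mutate(fixes, label = labels)
}
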
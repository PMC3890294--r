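#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6,371,000 m, vectorised over the
#' inputs. Thin wrapper around [geosphere::distHaversine()] with the Earth
#' radius fixed so every distance in the package is computed identically.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in metres.
#' @export
#' @examples
#' haversine_distance(0, 0, 0, 0.001) # ~111.2 m at the equator
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

#' Extract effective staying positions from GPS track points
#'
#' Scans each trajectory for maximal sub-sequences of points that are
#' spatially confined (the 10 m rule) for long enough (the 120 s rule). The
#' mean latitude/longitude of a qualifying sub-sequence is its center — an
#' "effective staying position" — with the staying time defined as the span
#' between its first and last record.
#'
#' Two confinement rules are available. `"consecutive"` (the default)
#' requires every pair of *consecutive* points in the sub-sequence to be less
#' than `d_max` apart; `"all-pairs"` requires every pair of points in the
#' sub-sequence to be within `d_max`. The rules differ on slowly drifting
#' tracks; both use a strict `< d_max` distance test and a strict
#' `> t_min` duration test, and both require at least two member points
#' (a duration needs two records). Scanning is greedy left-to-right and
#' resumes at the first point after each accepted sub-sequence, so
#' staypoints never overlap in time.
#'
#' @param points Track-point tibble (see [read_plt()]); may contain many
#'   files, identified by `user_id` + `file_id`.
#' @param d_max Spatial resolution in metres (default 10).
#' @param t_min Temporal resolution in seconds (default 120).
#' @param rule Confinement rule, `"consecutive"` or `"all-pairs"`.
#' @return A tibble with one row per staypoint: `user_id`, `file_id`,
#'   `center_latitude`, `center_longitude`, `arrival`, `departure`
#'   (POSIXct), `staying_time` (s), `n_members`, in temporal order.
#' @export
extract_staypoints <- function(points, d_max = 10, t_min = 120,
                               rule = c("consecutive", "all-pairs")) {
  rule <- match.arg(rule)
  if (nrow(points) == 0) return(empty_staypoints())
  points |>
    dplyr::group_by(.data$user_id, .data$file_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(extract_staypoints_one, d_max = d_max, t_min = t_min,
                   rule = rule)
}

empty_staypoints <- function() {
  tibble(
    user_id = character(), file_id = character(),
    center_latitude = double(), center_longitude = double(),
    arrival = as.POSIXct(character(), tz = "UTC"),
    departure = as.POSIXct(character(), tz = "UTC"),
    staying_time = double(), n_members = integer()
  )
}

extract_staypoints_one <- function(traj, d_max, t_min, rule) {
  n <- nrow(traj)
  if (n < 2) return(empty_staypoints())
  lat <- traj$latitude
  lon <- traj$longitude
  ts <- as.numeric(traj$timestamp)

  starts <- integer(0)
  ends <- integer(0)

  if (rule == "consecutive") {
    # gap_ok[i]: point i and i+1 are within d_max
    gap_ok <- haversine_distance(lat[-n], lon[-n], lat[-1], lon[-1]) < d_max
    i <- 1L
    while (i < n) {
      if (!gap_ok[i]) { i <- i + 1L; next }
      j <- i + 1L
      while (j < n && gap_ok[j]) j <- j + 1L
      # maximal chain i..j; any sub-chain has a shorter span, so on failure
      # nothing inside the chain can qualify and the scan jumps past it
      if (ts[j] - ts[i] > t_min) {
        starts <- c(starts, i); ends <- c(ends, j)
      }
      i <- j + 1L
    }
  } else {
    i <- 1L
    while (i < n) {
      j <- i
      while (j < n &&
             all(haversine_distance(lat[i:j], lon[i:j],
                                    lat[j + 1L], lon[j + 1L]) < d_max)) {
        j <- j + 1L
      }
      if (j > i && ts[j] - ts[i] > t_min) {
        starts <- c(starts, i); ends <- c(ends, j)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }

  if (length(starts) == 0) return(empty_staypoints())
  tibble(
    user_id = traj$user_id[1],
    file_id = traj$file_id[1],
    center_latitude = purrr::map2_dbl(starts, ends, ~mean(lat[.x:.y])),
    center_longitude = purrr::map2_dbl(starts, ends, ~mean(lon[.x:.y])),
    arrival = as.POSIXct(ts[starts], tz = "UTC", origin = "1970-01-01"),
    departure = as.POSIXct(ts[ends], tz = "UTC", origin = "1970-01-01"),
    staying_time = ts[ends] - ts[starts],
    n_members = ends - starts + 1L
  )
}
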
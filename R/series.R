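#' Build displacement series from staypoint sequences
#'
#' Converts each file's ordered staypoints into movement records: the
#' displacement is the great-circle distance between the centers of two
#' consecutive staypoints, the elapsed time is the travel time from leaving
#' the first (its departure) to reaching the second (its arrival), the speed
#' is their ratio, and `preceding_staytime` carries the staying time of the
#' origin staypoint so that staytime–displacement dependence can be tested
#' pairwise. A file with `N` staypoints yields `N - 1` records; files with
#' fewer than two staypoints contribute none.
#'
#' @param staypoints A staypoint tibble (see [extract_staypoints()]).
#' @return A tibble with columns `user_id`, `file_id`, `step`,
#'   `displacement` (m), `elapsed_time` (s), `speed` (m/s),
#'   `preceding_staytime` (s).
#' @export
build_series <- function(staypoints) {
  if (nrow(staypoints) < 2) return(empty_series())
  staypoints |>
    dplyr::group_by(.data$user_id, .data$file_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(build_series_one)
}

empty_series <- function() {
  tibble(
    user_id = character(), file_id = character(), step = integer(),
    displacement = double(), elapsed_time = double(), speed = double(),
    preceding_staytime = double()
  )
}

build_series_one <- function(sp) {
  n <- nrow(sp)
  if (n < 2) return(empty_series())
  dr <- haversine_distance(
    sp$center_latitude[-n], sp$center_longitude[-n],
    sp$center_latitude[-1], sp$center_longitude[-1]
  )
  dte <- as.numeric(sp$arrival[-1]) - as.numeric(sp$departure[-n])
  tibble(
    user_id = sp$user_id[1], file_id = sp$file_id[1],
    step = seq_len(n - 1L),
    displacement = dr,
    elapsed_time = dte,
    speed = dr / dte,
    preceding_staytime = sp$staying_time[-n]
  )
}

#' Add per-user relative displacements
#'
#' The relative displacement divides each displacement by the mean
#' displacement of its user (pooled over all the user's files), removing
#' between-user scale heterogeneity before pooling series across users.
#' By construction the mean relative displacement of each user equals 1.
#'
#' @param series A movement-record tibble.
#' @return `series` with an added `rel_displacement` column.
#' @export
add_relative_displacement <- function(series) {
  series |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(rel_displacement = .data$displacement /
                    mean(.data$displacement)) |>
    dplyr::ungroup()
}

#' Pool population-level samples from a movement-record tibble
#'
#' Concatenates displacements, preceding staying times and elapsed times over
#' all files. Within-file ordering is preserved in `series` itself (pairs for
#' lagged statistics are always formed inside a file), so this helper only
#' collects the marginal samples used for population-level distributions.
#'
#' @param series A movement-record tibble.
#' @return A list with vectors `displacement`, `staying_time`,
#'   `elapsed_time` and the record count `n`.
#' @export
pool_population <- function(series) {
  list(
    displacement = series$displacement,
    staying_time = series$preceding_staytime,
    elapsed_time = series$elapsed_time,
    n = nrow(series)
  )
}

#' Speed versus displacement pattern
#'
#' Every movement contributes one point (displacement, speed). The point
#' cloud is summarised with a log-binned median-speed curve and a two-segment
#' log-log slope fit split at `split_at` metres, which captures the
#' walk-to-vehicle transition where the speed–displacement relation changes
#' from roughly linear to square-root-like.
#'
#' @param series A movement-record tibble.
#' @param bins_per_decade Log bins per decade of displacement (default 10).
#' @param split_at Displacement (m) separating the two fitted segments
#'   (default 1000).
#' @param per_user If `TRUE`, collapse to one point per user (mean
#'   displacement, mean speed) before binning; the default uses per-movement
#'   points.
#' @return A list of class `speed_pattern` with elements `points` (tibble of
#'   displacement/speed pairs), `curve` (tibble of bin centers and median
#'   speeds), `slope_low`, `slope_high` (log-log OLS slopes of the median
#'   curve below/above `split_at`) and `split_at`.
#' @export
speed_displacement_pattern <- function(series, bins_per_decade = 10,
                                       split_at = 1000, per_user = FALSE) {
  pts <- series |>
    dplyr::filter(.data$displacement > 0, .data$elapsed_time > 0)
  if (per_user) {
    pts <- pts |>
      dplyr::group_by(.data$user_id) |>
      dplyr::summarise(displacement = mean(.data$displacement),
                       speed = mean(.data$speed), .groups = "drop")
  }
  pts <- dplyr::select(pts, dplyr::any_of(c("user_id", "displacement", "speed")))
  if (nrow(pts) == 0) {
    abort("no positive displacement/elapsed-time records to analyse",
          class = "mobiscale_empty_series")
  }
  edges <- log_bin_edges(pts$displacement, bins_per_decade)
  idx <- findInterval(pts$displacement, edges, rightmost.closed = TRUE)
  curve <- tibble(
    bin = idx,
    displacement = pts$displacement,
    speed = pts$speed
  ) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      center = sqrt(edges[.data$bin[1]] * edges[.data$bin[1] + 1L]),
      median_speed = median(.data$speed),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$center)

  slope_for <- function(sub) {
    if (nrow(sub) < 2) return(NA_real_)
    unname(coef(lm(log10(median_speed) ~ log10(center), data = sub))[2])
  }
  structure(
    list(
      points = pts,
      curve = curve,
      slope_low = slope_for(dplyr::filter(curve, .data$center < split_at)),
      slope_high = slope_for(dplyr::filter(curve, .data$center >= split_at)),
      split_at = split_at
    ),
    class = "speed_pattern"
  )
}

#' @export
print.speed_pattern <- function(x, ...) {
  cat("Speed-displacement pattern:", nrow(x$points), "movements\n")
  cat(sprintf("  log-log slope below %g m: %.3f\n", x$split_at, x$slope_low))
  cat(sprintf("  log-log slope above %g m: %.3f\n", x$split_at, x$slope_high))
  invisible(x)
}
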
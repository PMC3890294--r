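# Exhaustive O(n^2) pair-enumeration oracle for Kendall's tau-a.
tau_brute <- function(x, y) {
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  s <- sx * sy
  sum(s[upper.tri(s)]) / (length(x) * (length(x) - 1) / 2)
}

# A 17-point track: points 3-7 dwell within a few metres for over two
# minutes, points 10-15 likewise, the rest are travel points spaced far
# apart. Yields exactly two staypoints under the 10 m / 120 s rule.
make_two_cluster_track <- function() {
  deg <- 1 / 111194.93 # ~1 m in latitude degrees
  lat0 <- 40
  lon0 <- 116
  lat <- c(
    lat0 + 0 * deg,            # P1 travel
    lat0 + 50 * deg,           # P2 travel
    lat0 + 100 * deg + c(0, 2, 4, 2, 0) * deg,   # P3-P7 cluster 1
    lat0 + 160 * deg,          # P8 travel
    lat0 + 220 * deg,          # P9 travel
    lat0 + 280 * deg + c(0, 3, 1, 4, 2, 0) * deg, # P10-P15 cluster 2
    lat0 + 340 * deg,          # P16 travel
    lat0 + 400 * deg           # P17 travel
  )
  lon <- rep(lon0, 17)
  ts <- as.POSIXct("2008-05-01 08:00:00", tz = "UTC") +
    c(0, 30, 60, 100, 140, 180, 220, 250, 280,
      310, 350, 390, 430, 470, 510, 540, 570)
  tibble::tibble(
    user_id = "fig", file_id = "fig.plt",
    latitude = lat, longitude = lon, altitude = NA_real_, timestamp = ts
  )
}

# Movement-record tibble built directly from vectors (single file).
make_series <- function(displacement, elapsed_time = NULL, staytime = NULL,
                        user_id = "u1", file_id = "f1") {
  n <- length(displacement)
  if (is.null(elapsed_time)) elapsed_time <- rep(60, n)
  if (is.null(staytime)) staytime <- rep(300, n)
  tibble::tibble(
    user_id = user_id, file_id = file_id, step = seq_len(n),
    displacement = displacement, elapsed_time = elapsed_time,
    speed = displacement / elapsed_time, preceding_staytime = staytime
  )
}

# Exact piecewise power-law density packaged as a binned_dist.
make_piecewise_binned <- function(slope_low = -1.5, slope_high = -2.5,
                                  break_at = 1e3, lo_dec = 1, hi_dec = 5,
                                  step = 0.1) {
  centers <- 10^seq(lo_dec, hi_dec, by = step)
  dens <- ifelse(centers < break_at, centers^slope_low,
                 break_at^(slope_low - slope_high) * centers^slope_high)
  structure(
    tibble::tibble(
      low = centers / 10^(step / 2), high = centers * 10^(step / 2),
      center = centers, count = rep(100L, length(centers)), density = dens
    ),
    n = 1000L,
    class = c("binned_dist", class(tibble::tibble()))
  )
}
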
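M_PER_DEG <- 6371000 * pi / 180 # metres per degree of latitude

offset_latlon <- function(lat, lon, dx, dy) {
  # planar metre offsets -> degrees (valid for the sub-kilometre scales used)
  list(
    lat = lat + dy / M_PER_DEG,
    lon = lon + dx / (M_PER_DEG * cos(lat * pi / 180))
  )
}

#' Plan a synthetic itinerary of staypoints and travel legs
#'
#' Lays out `n_staypoints` dwell locations connected by straight travel
#' legs. Headings rotate by the golden angle so consecutive legs never
#' retrace each other; the construction is deterministic (randomness enters
#' only in [generate_trajectory()]).
#'
#' @param n_staypoints Number of planted staypoints.
#' @param dwell Dwell duration(s) in seconds (recycled; default 300, above
#'   the 120 s staypoint threshold).
#' @param leg_length Travel-leg length(s) in metres (recycled).
#' @param leg_duration Travel-leg duration(s) in seconds (recycled).
#' @param origin `c(latitude, longitude)` of the first staypoint.
#' @return A tibble with one row per staypoint: `latitude`, `longitude`,
#'   `dwell`, `travel_length`, `travel_time` (the leg leaving this
#'   staypoint; `NA` for the last).
#' @export
itinerary_plan <- function(n_staypoints = 5, dwell = 300, leg_length = 500,
                           leg_duration = 180, origin = c(39.98, 116.3)) {
  stopifnot(n_staypoints >= 1)
  dwell <- rep_len(dwell, n_staypoints)
  leg_length <- rep_len(leg_length, max(1, n_staypoints - 1))
  leg_duration <- rep_len(leg_duration, max(1, n_staypoints - 1))
  lat <- numeric(n_staypoints); lon <- numeric(n_staypoints)
  lat[1] <- origin[1]; lon[1] <- origin[2]
  golden <- pi * (3 - sqrt(5))
  if (n_staypoints > 1) {
    for (k in seq_len(n_staypoints - 1)) {
      th <- (k - 1) * golden
      p <- offset_latlon(lat[k], lon[k],
                         leg_length[k] * cos(th), leg_length[k] * sin(th))
      lat[k + 1] <- p$lat; lon[k + 1] <- p$lon
    }
  }
  tibble(
    latitude = lat, longitude = lon, dwell = dwell,
    travel_length = c(leg_length[seq_len(max(0, n_staypoints - 1))], NA),
    travel_time = c(leg_duration[seq_len(max(0, n_staypoints - 1))], NA)
  )
}

#' Generate a GPS trajectory with planted staypoints
#'
#' Emulates a handheld-GPS track: inside each planned dwell, points are
#' sampled every `sampling_interval` seconds and jittered uniformly within
#' a disc of radius `jitter` metres around the planned center; between
#' dwells the track moves along a straight leg with points spaced at least
#' `min_travel_spacing` metres apart, so travel points can never merge
#' into a dwell cluster. The planted ground truth is returned alongside
#' the track for recovery testing.
#'
#' @param plan An itinerary from [itinerary_plan()].
#' @param seed Integer seed.
#' @param sampling_interval GPS sampling period in seconds (default 3,
#'   typical of handheld loggers that record every 2-5 s).
#' @param jitter Dwell jitter radius in metres (default 2, well under the
#'   10 m staypoint resolution so a dwell is never split; must stay below
#'   half the staypoint distance threshold for guaranteed recovery under
#'   the consecutive-pair rule).
#' @param min_travel_spacing Minimum spacing of travel points in metres
#'   (default 15, above the 10 m threshold).
#' @param user_id,file_id Identifiers stamped on the points.
#' @param start_time First timestamp (POSIXct or seconds since epoch).
#' @return A list with `trajectory` (track-point tibble as from
#'   [read_plt()]) and `truth` (tibble of the planted centers with
#'   `latitude`, `longitude`, `arrival`, `departure`, `dwell`).
#' @export
generate_trajectory <- function(plan, seed = 1, sampling_interval = 3,
                                jitter = 2, min_travel_spacing = 15,
                                user_id = "synth", file_id = "synth_000.plt",
                                start_time = as.POSIXct("2008-05-01 00:00:00",
                                                        tz = "UTC")) {
  n_sp <- nrow(plan)
  t0 <- as.numeric(start_time)
  with_seed(seed, {
    lat <- c(); lon <- c(); ts <- c()
    truth_arr <- numeric(n_sp); truth_dep <- numeric(n_sp)
    t_cur <- t0
    for (k in seq_len(n_sp)) {
      n_dwell <- floor(plan$dwell[k] / sampling_interval) + 1L
      times <- t_cur + (seq_len(n_dwell) - 1L) * sampling_interval
      r <- jitter * sqrt(runif(n_dwell))
      th <- runif(n_dwell, 0, 2 * pi)
      p <- offset_latlon(plan$latitude[k], plan$longitude[k],
                         r * cos(th), r * sin(th))
      lat <- c(lat, p$lat); lon <- c(lon, p$lon); ts <- c(ts, times)
      truth_arr[k] <- times[1]; truth_dep[k] <- times[n_dwell]
      t_cur <- times[n_dwell]
      if (k < n_sp) {
        leg_len <- plan$travel_length[k]
        leg_t <- plan$travel_time[k]
        n_travel <- max(0L, min(
          floor(leg_t / sampling_interval) - 1L,
          floor(leg_len / min_travel_spacing) - 1L
        ))
        if (n_travel > 0) {
          fr <- seq_len(n_travel) / (n_travel + 1L)
          tl <- plan$latitude[k] + fr * (plan$latitude[k + 1] - plan$latitude[k])
          tn <- plan$longitude[k] + fr * (plan$longitude[k + 1] - plan$longitude[k])
          lat <- c(lat, tl); lon <- c(lon, tn)
          ts <- c(ts, t_cur + fr * leg_t)
        }
        t_cur <- t_cur + leg_t
      }
    }
    list(
      trajectory = tibble(
        user_id = user_id, file_id = file_id,
        latitude = lat, longitude = lon, altitude = NA_real_,
        timestamp = as.POSIXct(ts, tz = "UTC", origin = "1970-01-01")
      ),
      truth = tibble(
        latitude = plan$latitude, longitude = plan$longitude,
        arrival = as.POSIXct(truth_arr, tz = "UTC", origin = "1970-01-01"),
        departure = as.POSIXct(truth_dep, tz = "UTC", origin = "1970-01-01"),
        dwell = plan$dwell
      )
    )
  })
}

#' Fractional Gaussian noise
#'
#' Exact simulation by circulant embedding (Davies-Harte): the target
#' autocovariance `0.5 (|k+1|^(2H) - 2 |k|^(2H) + |k-1|^(2H))` is embedded
#' in a circulant matrix whose eigenvalues weight independent Gaussian
#' spectral amplitudes. Unit marginal variance.
#'
#' @param n Length of the series.
#' @param hurst Hurst exponent in (0, 1); 0.5 gives white noise.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
rfgn <- function(n, hurst, seed = NULL) {
  stopifnot(hurst > 0, hurst < 1, n >= 2)
  with_seed(seed, {
    h2 <- 2 * hurst
    gam <- function(k) 0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
    m <- 2L * n
    k <- 0:(m - 1L)
    circ <- gam(pmin(k, m - k))
    lambda <- Re(fft(circ))
    lambda[lambda < 0] <- 0 # clip numerically tiny negatives
    z <- complex(length.out = m)
    z[1] <- sqrt(lambda[1]) * rnorm(1)
    z[n + 1] <- sqrt(lambda[n + 1]) * rnorm(1)
    a <- rnorm(n - 1); b <- rnorm(n - 1)
    z[2:n] <- sqrt(lambda[2:n] / 2) * complex(real = a, imaginary = b)
    z[m:(n + 2)] <- Conj(z[2:n])
    Re(fft(z))[seq_len(n)] / sqrt(m)
  })
}

#' Generate a displacement series with controlled correlation structure
#'
#' Produces a positive displacement series whose log-displacements follow
#' one of four generators: independent Gaussian (`"iid-lognormal"`), a
#' stationary AR(1) with coefficient `phi` (`"log-ar1"`, the canonical
#' cascading-like generator: each movement conditions the scale of the
#' next), fractional Gaussian noise with Hurst exponent `hurst` (`"fgn"`,
#' long-term persistence), or a multiplicative cascade (`"cascade"`,
#' hierarchical weights giving persistence and a heavy tail jointly). The
#' log series is scaled by `sdlog` and shifted by `meanlog` before
#' exponentiation. Because Kendall's tau is invariant under the monotone
#' exponential map, the rank correlation of the displacements equals that
#' of the underlying Gaussian series.
#'
#' @param kind Generator kind.
#' @param n Series length.
#' @param seed Integer seed.
#' @param phi AR(1) coefficient in (-1, 1) (log-ar1).
#' @param hurst Hurst exponent in (0, 1) (fgn).
#' @param meanlog,sdlog Location and scale of the log-displacements
#'   (defaults log(500) and 1: typical urban trips of hundreds of metres
#'   spanning a few orders of magnitude).
#' @param levels Cascade depth (cascade only).
#' @param user_id,file_id Identifiers for the returned records.
#' @return A movement-record tibble.
#' @export
generate_series <- function(kind = c("iid-lognormal", "log-ar1", "fgn",
                                     "cascade"),
                            n = 1000, seed = 1, phi = 0.7, hurst = 0.8,
                            meanlog = log(500), sdlog = 1, levels = 10,
                            user_id = "synth", file_id = "series_1") {
  kind <- match.arg(kind)
  stopifnot(n >= 2)
  with_seed(seed, {
    z <- switch(kind,
      "iid-lognormal" = rnorm(n),
      "log-ar1" = {
        stopifnot(abs(phi) < 1)
        e <- rnorm(n)
        z <- numeric(n)
        z[1] <- e[1]
        for (t in 2:n) z[t] <- phi * z[t - 1] + sqrt(1 - phi^2) * e[t]
        z
      },
      "fgn" = rfgn(n, hurst),
      "cascade" = {
        z <- numeric(n)
        for (lev in seq_len(levels)) {
          block <- max(1L, 2L^(levels - lev))
          w <- rnorm(ceiling(n / block))
          z <- z + rep(w, each = block)[seq_len(n)]
        }
        z / sqrt(levels)
      }
    )
    disp <- exp(meanlog + sdlog * z)
    tibble(
      user_id = user_id, file_id = file_id, step = seq_len(n),
      displacement = disp,
      elapsed_time = rep(60, n),
      speed = disp / 60,
      preceding_staytime = rlnorm(n, log(300), 0.5)
    )
  })
}

#' Generate a multi-user cohort with coupled correlation and tail form
#'
#' Builds `n_users` synthetic users spanning weak to strong consecutive
#' displacement correlation (AR(1) coefficients spread over `phi_range`)
#' and, when `coupled = TRUE`, couples correlation strength to the
#' cleanliness of the displacement distribution's power-law tail: user
#' `i`'s displacements are a quantile mixture
#' `(1 - m_i) * Q_pareto + m_i * Q_lognormal` driven by the same uniformised
#' AR(1) series, where the contamination `m_i` decreases as `phi_i` grows.
#' Strongly correlated users therefore have near-pure Pareto displacement
#' distributions, weakly correlated users a lognormal-bumped one — the
#' construction under which the cross-user association between correlation
#' strength and power-law fit quality must come out positive. With
#' `coupled = FALSE` the contamination levels are randomly permuted across
#' users, destroying the association.
#'
#' @param n_users Number of users.
#' @param n_per_user Displacements per user.
#' @param seed Integer seed.
#' @param coupled Couple contamination to correlation strength?
#' @param phi_range Range of AR(1) coefficients across users.
#' @param pareto_alpha,pareto_xmin Pareto component parameters.
#' @return A list with `series` (movement-record tibble over all users)
#'   and `expected` (tibble of each user's `phi` and `contamination`).
#' @export
generate_cohort <- function(n_users = 16, n_per_user = 400, seed = 1,
                            coupled = TRUE, phi_range = c(0.05, 0.85),
                            pareto_alpha = 2, pareto_xmin = 10) {
  with_seed(seed, {
    phis <- seq(phi_range[1], phi_range[2], length.out = n_users)
    contamination <- seq(0.85, 0, length.out = n_users)
    if (!coupled) contamination <- sample(contamination)
    series <- purrr::map_dfr(seq_len(n_users), function(i) {
      e <- rnorm(n_per_user)
      z <- numeric(n_per_user)
      z[1] <- e[1]
      for (t in 2:n_per_user) {
        z[t] <- phis[i] * z[t - 1] + sqrt(1 - phis[i]^2) * e[t]
      }
      u <- stats::pnorm(z)
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      q_pl <- pareto_xmin * (1 - u)^(-1 / (pareto_alpha - 1))
      q_ln <- stats::qlnorm(u, meanlog = log(300), sdlog = 0.35)
      disp <- (1 - contamination[i]) * q_pl + contamination[i] * q_ln
      tibble(
        user_id = sprintf("user%02d", i),
        file_id = sprintf("user%02d_f1", i),
        step = seq_len(n_per_user),
        displacement = disp,
        elapsed_time = rep(60, n_per_user),
        speed = disp / 60,
        preceding_staytime = rlnorm(n_per_user, log(300), 0.5)
      )
    })
    list(
      series = series,
      expected = tibble(
        user_id = sprintf("user%02d", seq_len(n_users)),
        phi = phis, contamination = contamination
      )
    )
  })
}
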
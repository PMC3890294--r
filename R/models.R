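model_series <- function(model, seed, displacement, elapsed_time = NULL,
                         staytime = NULL) {
  n <- length(displacement)
  if (is.null(elapsed_time)) elapsed_time <- rep(1, n)
  tibble(
    user_id = model,
    file_id = sprintf("%s_seed%d", model, seed),
    step = seq_len(n),
    displacement = displacement,
    elapsed_time = elapsed_time,
    speed = displacement / elapsed_time,
    preceding_staytime = if (is.null(staytime)) rep(NA_real_, n) else staytime
  )
}

#' Pure Levy-flight displacement series
#'
#' A planar random walk with independent, identically distributed
#' power-law (Pareto) move lengths and uniform headings. Successive move
#' lengths are independent, so the expected correlation between
#' consecutive displacements is zero — the null model against which
#' correlated mobility is judged.
#'
#' @param n_steps Number of moves.
#' @param alpha Tail exponent of the move-length density (> 1).
#' @param x_min Minimum move length.
#' @param seed Integer seed; identical seed and parameters give an
#'   identical series.
#' @return A movement-record tibble (see [build_series()] for columns).
#' @export
simulate_levy <- function(n_steps = 2000, alpha = 2, x_min = 1, seed = 1) {
  with_seed(seed, {
    model_series("levy", seed, rpareto(n_steps, alpha, x_min))
  })
}

#' Continuous-time random walk displacement series
#'
#' Independent heavy-tailed waiting times and jump lengths: the walker
#' waits a Pareto-distributed time at each location, then makes a
#' Pareto-distributed jump in a uniform direction. Neither the jumps nor
#' the waits carry any serial or cross dependence.
#'
#' @inheritParams simulate_levy
#' @param wait_alpha,wait_min Tail exponent and lower bound of the waiting
#'   time distribution.
#' @return A movement-record tibble; `preceding_staytime` holds the waits.
#' @export
simulate_ctrw <- function(n_steps = 2000, alpha = 2, x_min = 1,
                          wait_alpha = 2, wait_min = 60, seed = 1) {
  with_seed(seed, {
    model_series("ctrw", seed,
                 displacement = rpareto(n_steps, alpha, x_min),
                 staytime = rpareto(n_steps, wait_alpha, wait_min))
  })
}

#' Exploration / preferential-return displacement series
#'
#' At each step the agent explores a brand-new location with probability
#' `rho * S^(-gamma)` (where `S` is the number of distinct locations
#' visited so far), jumping a Pareto-distributed distance in a uniform
#' direction; otherwise it returns to a previously visited location chosen
#' with probability proportional to that location's visit count (the
#' current location is excluded so every step produces a positive
#' displacement). The number of distinct locations grows sublinearly, and
#' consecutive displacements pick up a positive correlation through the
#' shared geometry of the visited set, but the correlation does not extend
#' to longer lags.
#'
#' @inheritParams simulate_levy
#' @param rho Exploration rate scale (0 < rho <= 1).
#' @param gamma Exploration decay exponent (>= 0).
#' @return A movement-record tibble.
#' @export
simulate_epr <- function(n_steps = 2000, rho = 0.6, gamma = 0.21,
                         alpha = 2, x_min = 1, seed = 1) {
  stopifnot(rho > 0, rho <= 1, gamma >= 0)
  with_seed(seed, {
    cap <- n_steps + 1L
    xs <- numeric(cap); ys <- numeric(cap); visits <- integer(cap)
    xs[1] <- 0; ys[1] <- 0; visits[1] <- 1L
    s <- 1L           # distinct locations so far
    cur <- 1L
    disp <- numeric(n_steps)
    for (t in seq_len(n_steps)) {
      # with a single known location a "return" has no target: must explore
      if (s == 1L || runif(1) < min(1, rho * s^(-gamma))) {
        r <- rpareto(1, alpha, x_min)
        th <- runif(1, 0, 2 * pi)
        s <- s + 1L
        xs[s] <- xs[cur] + r * cos(th)
        ys[s] <- ys[cur] + r * sin(th)
        nxt <- s
      } else {
        w <- visits[seq_len(s)]
        w[cur] <- 0L
        nxt <- sample.int(s, 1L, prob = w)
      }
      disp[t] <- sqrt((xs[nxt] - xs[cur])^2 + (ys[nxt] - ys[cur])^2)
      visits[nxt] <- visits[nxt] + 1L
      cur <- nxt
    }
    model_series("epr", seed, disp)
  })
}

# Self-similar waypoint landscape by recursive quadrant subdivision.
# Point counts cascade down a quadtree; at each split the four children
# receive multinomial shares with Dirichlet-distributed weights whose
# concentration grows with the landscape Hurst exponent, so low H gives a
# lumpy, strongly clustered landscape and high H a nearly uniform one.
slaw_landscape <- function(n_waypoints, hurst, levels = 8, area = 1000) {
  conc <- (hurst / (1 - hurst))^2 / 10
  cells <- tibble(x0 = 0, y0 = 0, size = area, count = n_waypoints)
  for (lev in seq_len(levels)) {
    half <- cells$size / 2
    parts <- purrr::pmap(list(cells$x0, cells$y0, half, cells$count),
                         function(x0, y0, h, cnt) {
      if (cnt == 0) return(NULL)
      w <- stats::rgamma(4, shape = conc) + 1e-12
      counts <- stats::rmultinom(1, cnt, w / sum(w))[, 1]
      tibble(
        x0 = x0 + c(0, h, 0, h),
        y0 = y0 + c(0, 0, h, h),
        size = h,
        count = counts
      )
    })
    cells <- dplyr::bind_rows(parts) |> dplyr::filter(.data$count > 0)
  }
  # place points uniformly inside their terminal cell
  idx <- rep(seq_len(nrow(cells)), cells$count)
  n <- length(idx)
  tibble(
    x = cells$x0[idx] + runif(n) * cells$size[idx],
    y = cells$y0[idx] + runif(n) * cells$size[idx]
  )
}

#' Self-similar least-action walk (SLAW-style) displacement series
#'
#' Generates a fractal waypoint landscape whose clustering is controlled
#' by a Hurst exponent (lower `hurst` gives stronger clustering), then
#' walks over it: from the current waypoint the next one is chosen among
#' the not-yet-visited waypoints with probability proportional to
#' `1 / distance^beta`. When every waypoint has been visited the visited
#' set is cleared and the walk continues (no per-trip waypoint subsets; a
#' single continuous walk). Strong clustering makes runs of short
#' intra-cluster moves alternate with rare long inter-cluster jumps,
#' producing positive short-lag displacement correlation that decays
#' quickly (roughly exponentially) with lag.
#'
#' @param n_waypoints Number of waypoints in the landscape.
#' @param hurst Landscape Hurst exponent in (0, 1).
#' @param beta Distance-preference exponent (default 1).
#' @param n_steps Number of moves.
#' @param area Side of the square landscape (metres).
#' @param seed Integer seed.
#' @return A movement-record tibble.
#' @export
simulate_slaw <- function(n_waypoints = 1000, hurst = 0.75, beta = 1,
                          n_steps = 2000, area = 1000, seed = 1) {
  stopifnot(hurst > 0, hurst < 1)
  with_seed(seed, {
    wp <- slaw_landscape(n_waypoints, hurst, area = area)
    m <- nrow(wp)
    visited <- logical(m)
    cur <- sample.int(m, 1)
    visited[cur] <- TRUE
    disp <- numeric(n_steps)
    for (t in seq_len(n_steps)) {
      if (all(visited)) { visited[] <- FALSE; visited[cur] <- TRUE }
      d <- sqrt((wp$x - wp$x[cur])^2 + (wp$y - wp$y[cur])^2)
      w <- ifelse(visited | d == 0, 0, 1 / d^beta)
      nxt <- sample.int(m, 1L, prob = w)
      disp[t] <- d[nxt]
      visited[nxt] <- TRUE
      cur <- nxt
    }
    model_series("slaw", seed, disp)
  })
}

#' Hierarchical-traffic-system (HTS) displacement series
#'
#' Builds a layered geographic network on a square: each layer's nodes are
#' scattered uniformly at random, every node is linked to its nearest node
#' in the layer above, and the (few) top-layer nodes are linked to each
#' other. A node in layer `l` (1 = top) carries weight
#' `weight_base^(n_layers - l)`, so upper-layer nodes attract the walker
#' more strongly. The agent performs a random walk along network links,
#' moving to a neighbouring node with probability proportional to that
#' node's weight; the displacement series is the sequence of planar
#' link lengths traversed. Because long links exist only between
#' high-layer nodes, displacements change gradually and the series carries
#' an inherent positive, slowly decaying correlation.
#'
#' The default layer sizes and weight base were fixed by a calibration
#' sweep (see `scripts/calibrate_hts.R` in the source repository) so that
#' the consecutive-displacement Kendall's tau of the default configuration
#' is about 0.39.
#'
#' @param n_steps Number of moves (default 10000).
#' @param layer_sizes Nodes per layer, top first.
#' @param weight_base Layer weight base `A > 1`.
#' @param area Side of the square (arbitrary units).
#' @param seed Integer seed.
#' @return A movement-record tibble.
#' @export
simulate_hts <- function(n_steps = 10000, layer_sizes = c(2, 8, 32, 128),
                         weight_base = 3.25, area = 1, seed = 1) {
  stopifnot(weight_base > 1, all(layer_sizes >= 1))
  n_layers <- length(layer_sizes)
  with_seed(seed, {
    n_nodes <- sum(layer_sizes)
    layer <- rep(seq_len(n_layers), layer_sizes)
    x <- runif(n_nodes, 0, area)
    y <- runif(n_nodes, 0, area)
    wgt <- weight_base^(n_layers - layer)

    edges_from <- integer(0); edges_to <- integer(0)
    top <- which(layer == 1L)
    if (length(top) > 1) {
      cmb <- utils::combn(top, 2)
      edges_from <- c(edges_from, cmb[1, ]); edges_to <- c(edges_to, cmb[2, ])
    }
    for (l in 2:n_layers) {
      below <- which(layer == l)
      above <- which(layer == l - 1L)
      for (i in below) {
        d2 <- (x[above] - x[i])^2 + (y[above] - y[i])^2
        j <- above[which.min(d2)]
        edges_from <- c(edges_from, i); edges_to <- c(edges_to, j)
      }
    }
    nbrs <- vector("list", n_nodes)
    for (e in seq_along(edges_from)) {
      a <- edges_from[e]; b <- edges_to[e]
      nbrs[[a]] <- c(nbrs[[a]], b)
      nbrs[[b]] <- c(nbrs[[b]], a)
    }

    cur <- sample.int(n_nodes, 1)
    disp <- numeric(n_steps)
    for (t in seq_len(n_steps)) {
      nb <- nbrs[[cur]]
      nxt <- if (length(nb) == 1L) nb else {
        nb[sample.int(length(nb), 1L, prob = wgt[nb])]
      }
      disp[t] <- sqrt((x[nxt] - x[cur])^2 + (y[nxt] - y[cur])^2)
      cur <- nxt
    }
    model_series("hts", seed, disp)
  })
}
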
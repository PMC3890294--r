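test_that("haversine distance matches closed form and is symmetric", {
  expect_equal(haversine_distance(40, 116, 40, 116), 0)
  # closed-form haversine at the equator: R * dlon(rad)
  expect_equal(haversine_distance(0, 0, 0, 0.001),
               6371000 * 0.001 * pi / 180, tolerance = 1e-6)
  set.seed(7)
  a <- cbind(runif(100, -80, 80), runif(100, -170, 170))
  b <- cbind(runif(100, -80, 80), runif(100, -170, 170))
  expect_equal(haversine_distance(a[, 1], a[, 2], b[, 1], b[, 2]),
               haversine_distance(b[, 1], b[, 2], a[, 1], a[, 2]))
  expect_true(all(haversine_distance(a[, 1], a[, 2], b[, 1], b[, 2]) >= 0))
})

test_that("two planted dwell clusters yield exactly two staypoints", {
  tr <- make_two_cluster_track()
  for (rule in c("consecutive", "all-pairs")) {
    sp <- extract_staypoints(tr, d_max = 10, t_min = 120, rule = rule)
    expect_equal(nrow(sp), 2)
    # centers are the mean coordinates of the member points
    expect_equal(sp$center_latitude[1], mean(tr$latitude[3:7]))
    expect_equal(sp$center_latitude[2], mean(tr$latitude[10:15]))
    expect_equal(sp$staying_time, c(160, 200))
    expect_equal(sp$n_members, c(5L, 6L))
  }
})

test_that("tracks with all consecutive gaps above d_max yield no staypoints", {
  deg <- 1 / 111194.93
  tr <- tibble::tibble(
    user_id = "u", file_id = "f",
    latitude = 40 + (0:20) * 50 * deg, longitude = 116, altitude = NA_real_,
    timestamp = as.POSIXct("2008-05-01", tz = "UTC") + (0:20) * 300
  )
  expect_equal(nrow(extract_staypoints(tr)), 0)
  expect_equal(nrow(extract_staypoints(tr[0, ])), 0)
})

test_that("planted staypoints are fully recovered with small center error", {
  plan <- itinerary_plan(n_staypoints = 5, dwell = 300, leg_length = 600)
  g <- generate_trajectory(plan, seed = 11, jitter = 4)
  for (rule in c("consecutive", "all-pairs")) {
    sp <- extract_staypoints(g$trajectory, rule = rule)
    expect_equal(nrow(sp), 5)
    err <- haversine_distance(sp$center_latitude, sp$center_longitude,
                              g$truth$latitude, g$truth$longitude)
    expect_lt(max(err), 5)
  }
})

test_that("staypoints are temporally disjoint and in order", {
  plan <- itinerary_plan(n_staypoints = 8, dwell = c(200, 400), leg_length = 300)
  g <- generate_trajectory(plan, seed = 3)
  sp <- extract_staypoints(g$trajectory)
  expect_true(all(diff(as.numeric(sp$arrival)) > 0))
  expect_true(all(as.numeric(sp$departure[-nrow(sp)]) <
                    as.numeric(sp$arrival[-1])))
  expect_true(all(sp$staying_time > 120))
  expect_true(all(sp$n_members >= 2))
})

test_that("appending far-away points after the last cluster changes nothing", {
  plan <- itinerary_plan(n_staypoints = 3)
  g <- generate_trajectory(plan, seed = 9)
  sp0 <- extract_staypoints(g$trajectory)
  deg <- 1 / 111194.93
  last_t <- max(g$trajectory$timestamp)
  extra <- tibble::tibble(
    user_id = g$trajectory$user_id[1], file_id = g$trajectory$file_id[1],
    latitude = max(g$trajectory$latitude) + (1:5) * 100 * deg,
    longitude = g$trajectory$longitude[1], altitude = NA_real_,
    timestamp = last_t + (1:5) * 60
  )
  sp1 <- extract_staypoints(dplyr::bind_rows(g$trajectory, extra))
  expect_equal(as.data.frame(sp1), as.data.frame(sp0))
})

test_that("dwells shorter than t_min are not staypoints", {
  plan <- itinerary_plan(n_staypoints = 3, dwell = c(300, 60, 300),
                         leg_length = 500)
  g <- generate_trajectory(plan, seed = 21)
  sp <- extract_staypoints(g$trajectory)
  expect_equal(nrow(sp), 2)
  # the middle 60 s dwell is absent: recovered centers match dwells 1 and 3
  err <- haversine_distance(sp$center_latitude, sp$center_longitude,
                            g$truth$latitude[c(1, 3)],
                            g$truth$longitude[c(1, 3)])
  expect_lt(max(err), 5)
})
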
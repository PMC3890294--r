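test_that("movement records carry distance / time / speed arithmetic", {
  deg500 <- 500 / (6371000 * pi / 180)
  sp <- tibble::tibble(
    user_id = "u", file_id = "f",
    center_latitude = c(40, 40 + deg500), center_longitude = 116,
    arrival = as.POSIXct("2008-05-01", tz = "UTC") + c(0, 700),
    departure = as.POSIXct("2008-05-01", tz = "UTC") + c(600, 1000),
    staying_time = c(600, 300), n_members = c(10L, 5L)
  )
  s <- build_series(sp)
  expect_equal(nrow(s), 1)
  expect_equal(s$displacement, 500, tolerance = 1e-6)
  expect_equal(s$elapsed_time, 100) # departure of 1st to arrival of 2nd
  expect_equal(s$speed, 5, tolerance = 1e-6)
  expect_equal(s$preceding_staytime, 600)
})

test_that("displacements match the planted itinerary legs", {
  legs <- c(400, 900, 250, 1500)
  plan <- itinerary_plan(n_staypoints = 5, leg_length = legs,
                         leg_duration = 300)
  g <- generate_trajectory(plan, seed = 2, jitter = 0)
  s <- build_series(extract_staypoints(g$trajectory))
  expect_lt(max(abs(s$displacement - legs)), 1) # within 1 m of the plan
})

test_that("record counts follow the staypoint counts per file", {
  set.seed(4)
  pts <- dplyr::bind_rows(lapply(1:3, function(i) {
    plan <- itinerary_plan(n_staypoints = i + 2)
    generate_trajectory(plan, seed = i, file_id = sprintf("f%d.plt", i)
    )$trajectory
  }))
  sp <- extract_staypoints(pts)
  s <- build_series(sp)
  per_file_sp <- dplyr::count(sp, .data$file_id)
  per_file_s <- dplyr::count(s, .data$file_id)
  expect_equal(per_file_s$n, per_file_sp$n - 1L)
  expect_equal(pool_population(s)$n, sum(per_file_sp$n - 1L))
  expect_equal(s$speed * s$elapsed_time, s$displacement)
  # fewer than two staypoints -> empty series, not an error
  expect_equal(nrow(build_series(sp[1, ])), 0)
})

test_that("relative displacements average to one per user", {
  set.seed(8)
  s <- dplyr::bind_rows(
    make_series(rlnorm(200, 5, 1), user_id = "a", file_id = "a1"),
    make_series(rlnorm(150, 7, 1), user_id = "a", file_id = "a2"),
    make_series(rlnorm(100, 3, 1), user_id = "b", file_id = "b1")
  )
  rel <- add_relative_displacement(s)
  means <- rel |>
    dplyr::group_by(user_id) |>
    dplyr::summarise(m = mean(rel_displacement))
  expect_equal(means$m, c(1, 1), tolerance = 1e-9)
})

test_that("speed-displacement slopes recover constructed relationships", {
  set.seed(10)
  dr <- 10^runif(4000, 1, 5)
  # constant speed: flat curve
  flat <- make_series(dr, elapsed_time = dr / 7)
  p_flat <- speed_displacement_pattern(flat)
  expect_equal(p_flat$slope_low, 0, tolerance = 1e-8)
  expect_equal(p_flat$slope_high, 0, tolerance = 1e-8)
  # exact linear speed: both slopes one (up to median-vs-center binning)
  lin <- make_series(dr, elapsed_time = rep(10, length(dr)))
  p_lin <- speed_displacement_pattern(lin)
  expect_equal(p_lin$slope_low, 1, tolerance = 0.02)
  expect_equal(p_lin$slope_high, 1, tolerance = 0.02)
  # linear below 1 km, square-root above
  v <- ifelse(dr < 1e3, dr, sqrt(1e3 * dr))
  two <- make_series(dr, elapsed_time = dr / v)
  p_two <- speed_displacement_pattern(two)
  expect_equal(p_two$slope_low, 1, tolerance = 0.02)
  expect_equal(p_two$slope_high, 0.5, tolerance = 0.02)
})

test_that("per-user mode collapses the point cloud to one point per user", {
  s <- dplyr::bind_rows(
    make_series(c(100, 200, 300), user_id = "a"),
    make_series(c(1000, 2000), user_id = "b", file_id = "b1")
  )
  p <- speed_displacement_pattern(s, per_user = TRUE)
  expect_equal(nrow(p$points), 2)
})
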
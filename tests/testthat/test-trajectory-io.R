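test_that("read_plt parses records in chronological order", {
  f <- withr::local_tempfile(fileext = ".plt")
  writeLines(c(
    "Geolife trajectory", "WGS 84", "Altitude is in Feet", "Reserved 3",
    "0,2,255,My Track,0,0,2,8421376", "0",
    "39.906631,116.385564,0,492,39448.345,2008-01-01,08:16:53",
    "39.906554,116.385625,0,492,39448.346,2008-01-01,08:18:17",
    "39.906462,116.385892,0,491,39448.347,2008-01-01,08:19:42"
  ), f)
  tr <- read_plt(f, user_id = "000", file_id = "t.plt")
  expect_equal(nrow(tr), 3)
  expect_equal(tr$latitude, c(39.906631, 39.906554, 39.906462))
  expect_equal(tr$longitude[1], 116.385564)
  expect_equal(tr$altitude[1], 492 * 0.3048)
  expect_equal(format(tr$timestamp[1], "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               "2008-01-01 08:16:53")
  expect_true(!is.unsorted(tr$timestamp))
})

test_that("malformed lines are skipped and counted, empty files error", {
  f <- withr::local_tempfile(fileext = ".plt")
  writeLines(c(
    rep("header", 6),
    "39.9,116.3,0,100,39448.1,2008-01-01,08:00:00",
    "not,a,valid,record",
    "39.901,116.3,0,100,39448.2,2008-01-01,08:01:00",
    "991.0,116.3,0,100,39448.3,2008-01-01,08:02:00", # latitude out of range
    "39.902,116.3,0,100,39448.4,2008-01-01,08:03:00",
    "39.903,116.3,0,100,39448.5,2008-01-01,08:04:00"
  ), f)
  expect_message(tr <- read_plt(f), "skipped 2")
  expect_equal(nrow(tr), 4)

  g <- withr::local_tempfile(fileext = ".plt")
  writeLines(c(rep("header", 6), "junk,junk"), g)
  expect_error(read_plt(g, quiet = TRUE), class = "mobiscale_empty_trajectory")
  expect_error(read_plt(file.path(tempdir(), "nope.plt")),
               class = "mobiscale_io_error")
})

test_that("write_plt then read_plt round-trips coordinates and timestamps", {
  plan <- itinerary_plan(n_staypoints = 3)
  traj <- generate_trajectory(plan, seed = 5)$trajectory
  f <- withr::local_tempfile(fileext = ".plt")
  write_plt(traj, f)
  back <- read_plt(f, user_id = traj$user_id[1], file_id = traj$file_id[1],
                   quiet = TRUE)
  expect_equal(nrow(back), nrow(traj))
  expect_equal(back$latitude, traj$latitude, tolerance = 1e-6)
  expect_equal(back$longitude, traj$longitude, tolerance = 1e-6)
  expect_equal(as.numeric(back$timestamp), round(as.numeric(traj$timestamp)))
})

test_that("filter_trajectories keeps files by recording span", {
  mk <- function(id, hours) tibble::tibble(
    user_id = "u", file_id = id, latitude = 40, longitude = 116,
    altitude = NA_real_,
    timestamp = as.POSIXct("2008-05-01", tz = "UTC") + c(0, hours * 3600)
  )
  pts <- dplyr::bind_rows(lapply(1:10, function(h) mk(paste0("f", h), h)))
  kept <- filter_trajectories(pts, 6 * 3600)
  expect_equal(dplyr::n_distinct(kept$file_id), 5) # spans 6..10 h
  expect_false("f5" %in% kept$file_id)
  expect_true("f7" %in% kept$file_id)
  # threshold zero keeps everything
  expect_equal(nrow(filter_trajectories(pts, 0)), nrow(pts))
  # idempotent
  expect_identical(filter_trajectories(kept, 6 * 3600), kept)
})

test_that("series files round-trip losslessly", {
  s <- make_series(rpareto(1000, 2, 10))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_series(s, f)
  back <- read_series(f)
  expect_equal(as.data.frame(back), as.data.frame(s), tolerance = 1e-15)
  # the write/read cycle reaches a byte-stable fixed point
  f2 <- withr::local_tempfile(fileext = ".tsv")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_series(back, f2)
  write_series(read_series(f2), f3)
  expect_identical(readLines(f2), readLines(f3))

  e <- make_series(numeric(0))
  fe <- withr::local_tempfile(fileext = ".tsv")
  write_series(e, fe)
  expect_equal(nrow(read_series(fe)), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(a = 1), bad)
  expect_error(read_series(bad), class = "mobiscale_format_error")
})
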
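test_that("THI formula reproduces hand-computed values and rejects bad input", {
  # hand evaluation: 25 - 0.55 * 0.4 * (25 - 14.4) = 22.668
  expect_equal(compute_thi(25, 60), 22.668)
  # the correction term vanishes at T = 14.4 and at RH = 100
  expect_equal(compute_thi(14.4, 37), 14.4)
  expect_equal(compute_thi(30, 100), 30)
  expect_error(compute_thi(NA, 50), "finite")
  expect_error(compute_thi(20, 101), "0, 100")
  expect_error(compute_thi(20, -1), "0, 100")
})

test_that("THI identities hold on a grid and THI is linear in T at fixed RH", {
  tgrid <- seq(-10, 40, by = 2.5)
  rhgrid <- seq(0, 100, by = 5)
  expect_equal(compute_thi(tgrid, rep(100, length(tgrid))), tgrid)
  expect_equal(compute_thi(rep(14.4, length(rhgrid)), rhgrid),
               rep(14.4, length(rhgrid)))
  for (rh in c(0, 30, 75)) {
    vals <- compute_thi(tgrid, rep(rh, length(tgrid)))
    expect_equal(diff(vals, differences = 2), rep(0, length(tgrid) - 2))
  }
})

test_that("farms map to the nearest station, with deterministic tie-breaks", {
  one <- data.frame(id = "W1", lat = 40.5, lon = 23.0)
  farms <- data.frame(id = c("f1", "f2", "f3"), lat = c(40, 41, 39.5),
                      lon = c(22, 23, 24))
  m <- match_stations(farms, one)
  expect_equal(unique(m$station_id), "W1")

  # farm at a station's exact location
  st <- data.frame(id = c("W1", "W2"), lat = c(40, 41), lon = c(22, 23))
  m2 <- match_stations(data.frame(id = "f", lat = 41, lon = 23), st)
  expect_equal(m2$station_id, "W2")
  expect_equal(m2$distance, 0)

  # 3 farms / 2 stations on a line, euclidean: brute-force comparison
  farms3 <- data.frame(id = c("a", "b", "c"), lat = c(0, 4, 10), lon = 0)
  st2 <- data.frame(id = c("W1", "W2"), lat = c(1, 9), lon = 0)
  m3 <- match_stations(farms3, st2, method = "euclidean")
  brute <- apply(abs(outer(farms3$lat, st2$lat, `-`)), 1, which.min)
  expect_equal(m3$station_id, st2$id[brute])

  # tie: equidistant farm goes to the lowest station id
  tie <- match_stations(data.frame(id = "t", lat = 5, lon = 0), st2,
                        method = "euclidean")
  expect_equal(tie$station_id, "W1")

  expect_error(match_stations(data.frame(id = "f", lat = NA, lon = 1), one), "f")
})

test_that("same-day lookup returns station values and flags missing dates", {
  w <- tibble::tibble(station_id = "S1",
                      date = seq(as.Date("2015-01-01"), by = "day", length.out = 30),
                      tavg = 20, rhavg = 60)
  expect_equal(covariate_on_day(w, "S1", as.Date("2015-01-15")), 20)
  single <- w[10, ]
  expect_equal(covariate_on_day(single, "S1", single$date), 20)
  expect_true(is.na(covariate_on_day(w, "S1", as.Date("2014-12-25"))))
  expect_true(is.na(covariate_on_day(w, "S9", as.Date("2015-01-15"))))
})

test_that("lag7 averages the 7 days strictly before the test day", {
  d0 <- as.Date("2015-03-10")
  w <- tibble::tibble(station_id = "S1", date = d0 - 7:0,
                      tavg = c(1:7, 100), rhavg = 60)
  # mean of 1..7, the test-day value of 100 is excluded
  expect_equal(covariate_lag7(w, "S1", d0), 4)
  # the including window picks up the test day instead of d-7
  expect_equal(covariate_lag7(w, "S1", d0, window = "including"),
               mean(c(2:7, 100)))
  # test day with d-7..d-1 all zero
  w0 <- tibble::tibble(station_id = "S1", date = d0 - 7:0,
                       tavg = c(rep(0, 7), 100), rhavg = 60)
  expect_equal(covariate_lag7(w0, "S1", d0), 0)
  # constant series: lag7 equals same-day value
  wc <- tibble::tibble(station_id = "S1", date = d0 - 10:0, tavg = 20, rhavg = 60)
  expect_equal(covariate_lag7(wc, "S1", d0), covariate_on_day(wc, "S1", d0))
  # any missing day in the window yields NA
  wmiss <- w[-3, ]
  expect_true(is.na(covariate_lag7(wmiss, "S1", d0)))
})

test_that("lag7 is permutation invariant and bounded by the window extremes", {
  set.seed(41)
  d0 <- as.Date("2016-06-01")
  for (rep in 1:5) {
    vals <- stats::rnorm(7, 15, 5)
    w <- tibble::tibble(station_id = "S1", date = d0 - 7:1, tavg = vals, rhavg = 50)
    wp <- tibble::tibble(station_id = "S1", date = d0 - 7:1, tavg = sample(vals),
                         rhavg = 50)
    l1 <- covariate_lag7(w, "S1", d0)
    expect_equal(l1, covariate_lag7(wp, "S1", d0))
    expect_gte(l1, min(vals))
    expect_lte(l1, max(vals))
  }
})

test_that("add_weather joins covariates, drops unresolvable records, and logs", {
  dates <- seq(as.Date("2015-01-01"), as.Date("2015-03-01"), by = "day")
  w <- tibble::tibble(station_id = "S1", date = dates, tavg = 10, rhavg = 70)
  recs <- tibble::tibble(
    flock_id = "F1",
    test_date = as.Date(c("2015-02-01", "2015-01-04", "2015-03-20")),
    animal_id = c("a", "b", "c")
  )
  # record 2 has an incomplete lag window, record 3 no weather at all
  out <- add_weather(recs, w)
  expect_equal(nrow(out), 1L)
  expect_equal(out$tavg, 10)
  expect_equal(out$tavg_lag7, 10)
  expect_equal(out$thi, compute_thi(10, 70))
  log <- attr(out, "weather_log")
  expect_equal(log$n_dropped, 2L)
  expect_equal(log$n_output + log$n_dropped, log$n_input)
  kept <- add_weather(recs, w, drop = FALSE)
  expect_equal(nrow(kept), 3L)
  expect_true(anyNA(kept$tavg_lag7))
})
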
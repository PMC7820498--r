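test_that("one-generation pedigrees are founders only and deterministic", {
  ped <- sim_pedigree(50, 1, seed = 701)
  expect_equal(nrow(ped), 50L)
  expect_true(all(is.na(ped$sire) & is.na(ped$dam)))
  expect_equal(as.matrix(a_inverse(ped[, c("animal", "sire", "dam")])),
               diag(50), ignore_attr = TRUE)
  ped2 <- sim_pedigree(50, 1, seed = 701)
  expect_identical(ped, ped2)
})

test_that("offspring-parent relationship averages 0.5 in a two-generation design", {
  ped <- sim_pedigree(120, 2, n_per_generation = 150, n_sires = 10, seed = 702)
  A <- tabular_a(ped[, c("animal", "sire", "dam")])
  off <- ped[ped$generation == 2L, ]
  rel <- mapply(function(o, s) A[o, s], off$animal, off$sire)
  expect_equal(mean(rel), 0.5, tolerance = 1e-12)  # founders are non-inbred
  expect_error(sim_pedigree(2, 5, prop_male = 1), "dams|sires")
})

test_that("zero-noise weather is an exact sinusoid peaking in mid-summer", {
  w <- sim_weather("2015-01-01", "2015-12-31", t_mean = 16, t_amplitude = 9,
                   innovation_sd = 0, rh_sd = 0, rh_temp_slope = 0, seed = 703)
  doy <- as.integer(format(w$date, "%j"))
  expect_equal(w$tavg, 16 + 9 * cos(2 * pi * (doy - 197) / 365.25))
  expect_equal(as.integer(format(w$date[which.max(w$tavg)], "%m")), 7L)
  expect_equal(w$thi, compute_thi(w$tavg, w$rhavg))
})

test_that("weather is seed-reproducible with the configured annual mean", {
  w1 <- sim_weather("2012-01-01", "2017-12-31", seed = 704)
  w2 <- sim_weather("2012-01-01", "2017-12-31", seed = 704)
  expect_identical(w1, w2)
  # AR(1) stationary SD = innovation / sqrt(1 - phi^2); mean within 3 SE
  se_mean <- (1.8 / sqrt(1 - 0.7^2)) / sqrt(nrow(w1) / 30)  # ~monthly blocks
  expect_lt(abs(mean(w1$tavg) - 16), 3 * se_mean + 0.5)
  expect_true(all(w1$rhavg >= 0 & w1$rhavg <= 100))
})

test_that("breeding values follow the pedigree covariance structure", {
  G0 <- matrix(c(0.5, 0.2, 0.2, 0.3), 2, 2)
  founders <- unrelated_pedigree(sprintf("f%04d", 1:3000))
  bv <- sim_breeding_values(founders, G0, seed = 705)
  expect_equal(stats::cov(bv), G0, tolerance = 0.05)
  expect_equal(sim_breeding_values(founders, matrix(0, 2, 2), seed = 1),
               matrix(0, 3000, 2, dimnames = list(founders$animal, NULL)))
  # full sibs share half the additive variance
  ns <- 1500
  ped <- data.frame(
    animal = c("S", "D", sprintf("o%04d", 1:ns)),
    sire = c(NA, NA, rep("S", ns)),
    dam = c(NA, NA, rep("D", ns))
  )
  bv1 <- sim_breeding_values(ped, matrix(1), seed = 706)
  sibs <- bv1[-(1:2), 1]
  # var within the sibship is the Mendelian half; the midparent shifts the mean
  expect_equal(stats::var(sibs), 0.5, tolerance = 0.08)
})

test_that("noise-free test days equal flock + Wilmink + population curve", {
  cfg <- sim_config()
  cfg$n_flocks <- 2L
  cfg$G0 <- cfg$P0 <- matrix(0, 3, 3)
  cfg$residual_sd <- 0; cfg$flock_sd <- 0; cfg$year_sd <- 0
  cfg$parity_effects <- c(0, 0, 0)
  ped <- sim_pedigree(30, 2, 60, 5, seed = 707)
  w <- sim_weather("2011-01-01", "2018-12-31", n_stations = 1,
                   t_mean = cfg$t_mean, t_amplitude = cfg$t_amplitude,
                   innovation_sd = 0, rh_sd = 0, rh_temp_slope = 0, seed = 708)
  rec <- sim_testdays(ped, w, cfg, seed = 709)
  truth <- attr(rec, "truth")
  season <- as.character(assign_season(rec$lambing_date))
  wil <- cfg$wilmink
  basis <- truth$basis
  expected <- vapply(seq_len(nrow(rec)), function(i) {
    tv <- w$tavg[match(rec$test_date[i], w$date)]
    tv <- min(cfg$x_range[2], max(cfg$x_range[1], tv))
    wil["a"] + wil["b"] * exp(-wil["k"] * rec$dim[i]) + wil["c"] * rec$dim[i] +
      sum(eval_basis(basis, tv) * cfg$beta_season[[season[i]]])
  }, 0)
  # exact up to the tiny jitter used to keep zero covariances factorable
  expect_lt(max(abs(rec$milk_kg - pmax(0.05, unname(expected)))), 1e-4)
})

test_that("monthly recording yields at least five tests per lactation", {
  cfg <- sim_config()
  ped <- sim_pedigree(40, 2, 80, 5, seed = 710)
  w <- sim_weather("2011-01-01", "2018-12-31", seed = 711)
  rec <- sim_testdays(ped, w, cfg, seed = 712)
  per_lact <- dplyr::count(rec, animal_id, lambing_date)
  expect_true(all(per_lact$n >= 5))
  # no record inside the suckling period: generated data pass the dim edit
  expect_true(all(rec$dim >= 42))
  ed <- edit_records(rec)
  expect_equal(edit_report(ed)$n_dim_filter, 0L)
  # determinism of the full generator chain
  rec2 <- sim_testdays(ped, w, cfg, seed = 712)
  expect_identical(dplyr::as_tibble(rec), dplyr::as_tibble(rec2))
})

test_that("direct traits honour the requested h2, rA and rP", {
  founders <- unrelated_pedigree(sprintf("f%04d", 1:5000))
  d <- sim_direct_traits(founders, h2 = c(0.15, 0.14), rA = -0.27, rP = -0.09,
                         seed = 713)
  truth <- attr(d, "truth")
  bv <- truth$bv[d$animal_id, ]
  r_bv <- stats::cor(bv[, 1], bv[, 2])
  se <- (1 - (-0.27)^2) / sqrt(nrow(d))
  expect_lt(abs(r_bv - (-0.27)), 3 * se)
  expect_lt(abs(stats::cor(d$y1, d$y2) - (-0.09)), 0.06)
  # h2 = 1 with no residual: phenotype equals mean + group + BV exactly
  d1 <- sim_direct_traits(founders[1:100, ], h2 = 1, n_groups = 0L, seed = 714)
  expect_lt(max(abs(d1$y1 - attr(d1, "truth")$bv[d1$animal_id, 1])), 1e-4)
  # independent traits give uncorrelated breeding values
  d0 <- sim_direct_traits(founders[1:3000, ], h2 = c(0.3, 0.3), rA = 0,
                          seed = 715)
  bv0 <- attr(d0, "truth")$bv
  expect_lt(abs(stats::cor(bv0[, 1], bv0[, 2])), 3 / sqrt(3000))
  # impossible residual covariance is rejected
  expect_error(sim_direct_traits(founders, h2 = c(0.9, 0.9), rA = -0.9,
                                 rP = 0.9, seed = 1), "inadmissible")
})
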
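test_that("lambing seasons follow the September-May calendar", {
  d <- as.Date(c("2015-10-15", "2016-01-03", "2015-07-01", "2015-09-01",
                 "2015-11-30", "2015-12-01", "2016-02-29", "2016-03-01",
                 "2016-05-31", "2016-06-01", "2016-08-31"))
  s <- assign_season(d)
  expect_equal(as.character(s),
               c("autumn", "winter", NA, "autumn", "autumn", "winter", "winter",
                 "spring", "spring", NA, NA))
  expect_equal(levels(s), c("autumn", "winter", "spring"))
})

make_records <- function(n, dim = NULL, milk = NULL, animal = NULL) {
  tibble::tibble(
    animal_id = animal %||% sprintf("an%03d", seq_len(n)),
    flock_id = "F1",
    dim = dim %||% rep(60, n),
    milk_kg = milk %||% rep(2, n)
  )
}

test_that("the 42-day filter removes dim 41 and keeps dim 42", {
  r <- make_records(4, dim = c(41, 42, 43, 200))
  out <- edit_records(r, min_records = 1L)
  expect_equal(sort(out$dim), c(42, 43, 200))
  expect_equal(edit_report(out)$n_dim_filter, 1L)
})

test_that("a planted extreme outlier is removed by the 4-SD rule", {
  set.seed(11)
  milk <- c(rnorm(19, 2, 0.3), 2 + 10 * 0.3 * 4)  # ~10 SD above the group mean
  r <- make_records(20, dim = rep(60, 20), milk = milk)
  out <- edit_records(r, min_records = 1L)
  expect_equal(nrow(out), 19L)
  expect_false(max(milk) %in% out$milk_kg)
  rep_ <- edit_report(out)
  expect_equal(rep_$n_sd_filter, 1L)
  # groups with fewer than 3 records are exempt from the SD rule
  tiny <- make_records(2, dim = c(60, 60), milk = c(2, 50))
  expect_equal(nrow(edit_records(tiny, min_records = 1L)), 2L)
})

test_that("animals need at least three surviving records", {
  r <- dplyr::bind_rows(
    make_records(3, animal = rep("keep", 3), dim = c(60, 90, 120)),
    make_records(2, animal = rep("drop", 2), dim = c(60, 90)),
    make_records(3, animal = rep("edge", 3), dim = c(41, 60, 90))  # loses one
  )
  out <- edit_records(r)
  expect_setequal(unique(out$animal_id), "keep")
  expect_equal(edit_report(out)$n_minrecords_filter, 4L)
})

test_that("record edits are idempotent and only remove records", {
  set.seed(12)
  r <- tibble::tibble(
    animal_id = rep(sprintf("an%02d", 1:30), each = 5),
    flock_id = rep(c("F1", "F2"), length.out = 150),
    dim = sample(20:200, 150, replace = TRUE),
    milk_kg = pmax(0.1, rnorm(150, 2, 0.5))
  )
  r$milk_kg[c(10, 77)] <- c(25, 30)  # gross outliers
  once <- edit_records(r)
  twice <- edit_records(once)
  expect_equal(strip_report(once), strip_report(twice))
  # retained set is a subset of the input
  key <- function(d) paste(d$animal_id, d$dim, d$milk_kg)
  expect_true(all(key(once) %in% key(r)))
  rep_ <- edit_report(once)
  expect_equal(rep_$n_input - rep_$n_output,
               rep_$n_dim_filter + rep_$n_sd_filter + rep_$n_minrecords_filter)
  # empty input yields an empty, zeroed report
  e <- edit_records(r[0, ])
  expect_equal(nrow(e), 0L)
  expect_equal(edit_report(e)$n_input, 0L)
})

test_that("lifetime milk yield follows the test-interval method", {
  # single record: 50 * 2 + 15 * 2 = 130
  r1 <- tibble::tibble(animal_id = "a", lambing_date = as.Date("2015-10-01"),
                       dim = 50, milk_kg = 2)
  out1 <- lifetime_milk(r1)
  expect_equal(out1$lifetime_milk_kg, 130)
  expect_equal(as.character(out1$season), "autumn")
  # two records: 50*2 + 30*(2+1)/2 + 15*1 = 160
  r2 <- tibble::tibble(animal_id = "a", lambing_date = as.Date("2015-10-01"),
                       dim = c(50, 80), milk_kg = c(2, 1))
  expect_equal(lifetime_milk(r2)$lifetime_milk_kg, 160)
  # the tail is capped so lactation dim does not exceed 210 days
  r3 <- tibble::tibble(animal_id = "a", lambing_date = as.Date("2015-10-01"),
                       dim = 205, milk_kg = 2)
  out3 <- lifetime_milk(r3)
  expect_equal(out3$lifetime_milk_kg, 205 * 2 + 5 * 2)
  expect_equal(out3$total_dim, 210)
})

test_that("lactations accumulate within animal and season; summer lambings drop", {
  r <- dplyr::bind_rows(
    tibble::tibble(animal_id = "a", lambing_date = as.Date("2014-10-01"),
                   dim = 50, milk_kg = 2),
    tibble::tibble(animal_id = "a", lambing_date = as.Date("2015-11-01"),
                   dim = 50, milk_kg = 2),
    tibble::tibble(animal_id = "a", lambing_date = as.Date("2016-01-15"),
                   dim = 50, milk_kg = 1),
    tibble::tibble(animal_id = "a", lambing_date = as.Date("2016-07-15"),
                   dim = 50, milk_kg = 9)
  )
  out <- lifetime_milk(r)
  aut <- out[out$season == "autumn", ]
  expect_equal(aut$lifetime_milk_kg, 2 * 130)  # both autumn lambings summed
  expect_equal(aut$total_lactations, 2L)
  expect_equal(out$lifetime_milk_kg[out$season == "winter"], 65)
  expect_equal(nrow(out), 2L)  # no July season row
})

test_that("lifetime milk is additive over lactations and linear in yields", {
  set.seed(13)
  base <- tibble::tibble(
    animal_id = "a",
    lambing_date = rep(as.Date(c("2014-10-01", "2015-10-01")), each = 4),
    dim = rep(c(50, 80, 110, 140), 2),
    milk_kg = stats::runif(8, 1, 3)
  )
  whole <- lifetime_milk(base)$lifetime_milk_kg
  parts <- sum(vapply(split(base, base$lambing_date),
                      function(d) lifetime_milk(d)$lifetime_milk_kg, 0))
  expect_equal(whole, parts)
  doubled <- base; doubled$milk_kg <- 2 * doubled$milk_kg
  expect_equal(lifetime_milk(doubled)$lifetime_milk_kg, 2 * whole)
})
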
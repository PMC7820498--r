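#' Calendar season of lambing
#'
#' Lambings are grouped into autumn (September-November), winter
#' (December-February) and spring (March-May). June-August lambings fall
#' outside the normal lambing period and return \code{NA} (the records are
#' excluded from seasonal analyses).
#'
#' @param lambing_date Date vector.
#' @return Factor with levels \code{autumn, winter, spring}; \code{NA} for
#'   June-August dates.
#' @export
assign_season <- function(lambing_date) {
  m <- as.integer(format(as.Date(lambing_date), "%m"))
  s <- rep(NA_character_, length(m))
  s[m %in% c(9L, 10L, 11L)] <- "autumn"
  s[m %in% c(12L, 1L, 2L)] <- "winter"
  s[m %in% c(3L, 4L, 5L)] <- "spring"
  factor(s, levels = c("autumn", "winter", "spring"))
}

#' Apply the test-day record edits
#'
#' Three sequential filters, applied once in this order:
#' \enumerate{
#'   \item remove records taken less than 42 days after lambing
#'     (\code{dim < 42}, the suckling period);
#'   \item within each month of lactation (\code{floor(dim / 30.44) + 1}),
#'     remove records more than four standard deviations from the group mean
#'     (mean and sample SD computed on the data surviving filter 1; groups
#'     with fewer than 3 records are exempt);
#'   \item remove all records of animals left with fewer than three records
#'     over their productive life.
#' }
#' Group statistics are not recomputed after removals, so the edit is a single
#' deterministic pass and is idempotent.
#'
#' @param records Tibble with columns \code{animal_id, dim, milk_kg} (other
#'   columns are carried through).
#' @param sd_grouping \code{"pooled"} (default; month-of-lactation groups pool
#'   across flocks) or \code{"within_flock"}.
#' @param min_dim Minimum days in milk (default 42).
#' @param sd_limit Outlier threshold in SD units (default 4).
#' @param min_records Minimum surviving records per animal (default 3).
#' @return The retained records, with an \code{"edit_report"} attribute listing
#'   \code{n_input, n_dim_filter, n_sd_filter, n_minrecords_filter, n_output}
#'   (see \code{\link{edit_report}}).
#' @export
edit_records <- function(records, sd_grouping = c("pooled", "within_flock"),
                         min_dim = 42, sd_limit = 4, min_records = 3L) {
  sd_grouping <- match.arg(sd_grouping)
  stopifnot_cols(records, c("animal_id", "dim", "milk_kg"), "`records`")
  records <- as_tibble(records)
  n_input <- nrow(records)

  r1 <- records[records$dim >= min_dim, , drop = FALSE]
  n_dim <- n_input - nrow(r1)

  if (nrow(r1)) {
    lact_month <- floor(r1$dim / 30.44) + 1
    grp <- if (sd_grouping == "within_flock" && "flock_id" %in% names(r1)) {
      paste(r1$flock_id, lact_month)
    } else {
      as.character(lact_month)
    }
    gm <- tapply(r1$milk_kg, grp, mean)
    gs <- tapply(r1$milk_kg, grp, sd)
    gn <- tapply(r1$milk_kg, grp, length)
    dev <- abs(r1$milk_kg - gm[grp])
    keep <- gn[grp] < 3 | is.na(gs[grp]) | dev <= sd_limit * gs[grp]
    r2 <- r1[keep, , drop = FALSE]
  } else {
    r2 <- r1
  }
  n_sd <- nrow(r1) - nrow(r2)

  cnt <- table(r2$animal_id)
  keep_an <- names(cnt)[cnt >= min_records]
  r3 <- r2[as.character(r2$animal_id) %in% keep_an, , drop = FALSE]
  n_min <- nrow(r2) - nrow(r3)

  attr(r3, "edit_report") <- list(
    n_input = n_input, n_dim_filter = n_dim, n_sd_filter = n_sd,
    n_minrecords_filter = n_min, n_output = nrow(r3)
  )
  r3
}

#' Retrieve the edit report of \code{\link{edit_records}}
#' @param records Output of \code{edit_records}.
#' @return Named list of record counts removed per filter.
#' @export
edit_report <- function(records) {
  rep <- attr(records, "edit_report")
  if (is.null(rep)) abort("no edit report attached; run edit_records() first.")
  rep
}

#' Lifetime milk yield per animal and lambing season
#'
#' Accumulates, per lactation, a test-interval (Fleischmann) yield from the
#' monthly test-day records: the first interval credits \code{dim_1 * y_1},
#' interior intervals \code{(dim_{i+1} - dim_i) * (y_i + y_{i+1}) / 2}, and a
#' configurable tail of \code{tail_days} at the last recorded yield, capped so
#' the lactation does not exceed \code{max_dim} days. Lactation yields are then
#' summed within animal and calendar season of the corresponding lambing; an
#' animal lambing in different seasons contributes one row per season.
#'
#' @param records Edited test-day records with columns \code{animal_id,
#'   lambing_date, dim, milk_kg} (and optionally \code{lactation_number}).
#' @param tail_days Days credited after the last test (default 15).
#' @param max_dim Cap on total days in milk per lactation (default 210).
#' @return Tibble \code{animal_id, season, lifetime_milk_kg, total_dim,
#'   total_lactations}. Lambings outside the three seasons are excluded.
#' @export
lifetime_milk <- function(records, tail_days = 15, max_dim = 210) {
  stopifnot_cols(records, c("animal_id", "lambing_date", "dim", "milk_kg"),
                 "`records`")
  records <- as_tibble(records)
  records$season <- assign_season(records$lambing_date)
  records <- records[!is.na(records$season), , drop = FALSE]
  if (!nrow(records)) {
    return(tibble(animal_id = character(), season = factor(levels = levels(assign_season(Sys.Date()))),
                  lifetime_milk_kg = numeric(), total_dim = numeric(),
                  total_lactations = integer()))
  }
  per_lact <- records |>
    group_by(.data$animal_id, .data$lambing_date, .data$season) |>
    arrange(.data$dim, .by_group = TRUE) |>
    summarise(
      yield = fleischmann_yield(.data$dim, .data$milk_kg, tail_days, max_dim),
      lact_dim = min(max(.data$dim) + tail_days, max_dim),
      .groups = "drop"
    )
  per_lact |>
    group_by(.data$animal_id, .data$season) |>
    summarise(
      lifetime_milk_kg = sum(.data$yield),
      total_dim = sum(.data$lact_dim),
      total_lactations = dplyr::n(),
      .groups = "drop"
    )
}

# test-interval yield for one lactation; dim sorted ascending
fleischmann_yield <- function(dim, y, tail_days, max_dim) {
  n <- length(dim)
  first <- dim[1] * y[1]
  interior <- if (n > 1) sum(diff(dim) * (y[-n] + y[-1]) / 2) else 0
  tail_len <- max(0, min(tail_days, max_dim - dim[n]))
  first + interior + tail_len * y[n]
}
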
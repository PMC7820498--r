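#' Run the full synthetic-to-genetics pipeline
#'
#' Executes the whole analysis on synthetic data: simulate pedigree, weather
#' and test-day records; attach weather covariates; apply the record edits and
#' compute lifetime milk yields; fit the seasonal Legendre reaction norms for
#' the same-day and week-preceding temperature covariates; derive the slope
#' phenotypes at 10 and 25 degC; and estimate genetic parameters
#' (heritabilities per trait and season, plus representative bivariate
#' correlations). Writes the phenotype CSV, summary tables shaped like the
#' descriptive/heritability/correlation reporting tables, the fit summaries
#' (JSON), the edit report (JSON) and a reproducibility manifest into
#' \code{out_dir}.
#'
#' @param out_dir Output directory (created if needed); \code{NULL} skips all
#'   file output.
#' @param seed Master seed; sub-generator streams are derived from it.
#' @param config Configuration list from \code{\link{sim_config}}.
#' @param quantgen Run the genetic-parameter stage (default TRUE).
#' @param verbose Print stage progress.
#' @return (Invisibly) a list with all stage outputs: \code{records},
#'   \code{edited}, \code{lifetime}, \code{fits}, \code{phenotypes},
#'   \code{summary}, \code{heritability}, \code{correlations},
#'   \code{manifest}.
#' @export
run_pipeline <- function(out_dir = NULL, seed = 1L, config = sim_config(seed),
                         quantgen = TRUE, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  say("simulate: pedigree, weather, test days")
  ped <- stage("simulate", sim_pedigree(
    n_founders = config$n_founders, n_generations = config$n_generations,
    n_per_generation = config$n_per_generation, n_sires = config$n_sires,
    prop_male = config$prop_male, seed = seed * 100L + 1L))
  weather <- stage("simulate", sim_weather(
    config$weather_start, config$weather_end, n_stations = config$n_stations,
    t_mean = config$t_mean, t_amplitude = config$t_amplitude,
    phi = config$t_phi, innovation_sd = config$t_innovation_sd,
    rh_mean = config$rh_mean, rh_sd = config$rh_sd,
    rh_temp_slope = config$rh_temp_slope, peak_doy = config$peak_doy,
    seed = seed * 100L + 2L))
  records <- stage("simulate", sim_testdays(ped, weather, config,
                                            seed = seed * 100L + 3L))
  truth <- attr(records, "truth")

  say("weather: covariates for %d records", nrow(records))
  station_map <- tibble(farm_id = names(truth$station_of_flock),
                        station_id = unname(truth$station_of_flock))
  records_w <- stage("weather", add_weather(records, weather, station_map))

  say("prep: edits and lifetime yields")
  edited <- stage("prep", edit_records(records_w))
  edited$season <- assign_season(edited$lambing_date)
  edited <- edited[!is.na(edited$season), , drop = FALSE]
  lifetime <- stage("prep", lifetime_milk(edited))

  say("fit-rn: seasonal reaction norms")
  fits <- list()
  for (season in levels(edited$season)) {
    for (cov in c("tavg", "tavg_lag7")) {
      recs <- edited[edited$season == season, , drop = FALSE]
      if (nrow(recs) < 50) next
      fits[[paste(season, cov, sep = ".")]] <-
        stage("fit-rn", fit_reaction_norm(recs, covariate = cov, season = season))
    }
  }

  say("phenotypes: slopes at 10 and 25 degC")
  phenotypes <- stage("phenotypes", derive_phenotypes(fits))
  summary_tbl <- phenotype_summary(phenotypes)

  herit <- NULL; correlations <- NULL
  if (quantgen) {
    say("quantgen: pedigree REML on derived phenotypes")
    Ainv <- a_inverse(ped[, c("animal", "sire", "dam")])
    wide <- tidyr::pivot_wider(phenotypes,
                               id_cols = "animal_id",
                               names_from = c("trait", "season"),
                               values_from = "slope")
    lt_wide <- tidyr::pivot_wider(lifetime, id_cols = "animal_id",
                                  names_from = "season",
                                  values_from = "lifetime_milk_kg",
                                  names_prefix = "milk_")
    wide <- left_join(wide, lt_wide, by = "animal_id")
    herit <- purrr::map_dfr(
      setdiff(names(wide), "animal_id"),
      function(tr) {
        d <- wide[!is.na(wide[[tr]]), c("animal_id", tr)]
        if (nrow(d) < 100) return(NULL)
        fit <- stage("quantgen", reml_univariate(d, tr, Ainv))
        parts <- strsplit(tr, "_(?=[a-z]+$)", perl = TRUE)[[1]]
        tibble(trait = tr, h2 = fit$h2, se_h2 = fit$se_h2,
               stars = fit$tests$stars[fit$tests$term == "h2"],
               lrt = fit$lrt, p_lrt = fit$p_lrt, n = fit$n)
      })
    # representative bivariate runs: resilience vs lifetime milk within season,
    # one between-season pair, one daily vs week-cumulative pair
    pairs <- list(
      c("Tavg10_autumn", "milk_autumn", "resilience-vs-milk"),
      c("Tavg10_winter", "milk_winter", "resilience-vs-milk"),
      c("Tavg10_spring", "milk_spring", "resilience-vs-milk"),
      c("Tavg10_autumn", "Tavg10_winter", "between-season"),
      c("Tavg10_autumn", "Tavg10_lag7_autumn", "daily-vs-lag7")
    )
    correlations <- purrr::map_dfr(pairs, function(pr) {
      if (!all(pr[1:2] %in% names(wide))) return(NULL)
      d <- wide[, c("animal_id", pr[1:2])]
      d <- d[rowSums(!is.na(d[, pr[1:2]])) > 0, ]
      if (sum(stats::complete.cases(d)) < 100) return(NULL)
      fit <- stage("quantgen", reml_bivariate(d, pr[1:2], Ainv))
      tibble(trait1 = pr[1], trait2 = pr[2], kind = pr[3],
             rP = fit$rP, se_rP = fit$se_rP, rA = fit$rA, se_rA = fit$se_rA,
             stars = fit$tests$stars[fit$tests$term == "rA"], n = fit$n)
    })
  }

  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("thermoresil")),
    counts = list(
      pedigree = nrow(ped), weather_days = nrow(weather),
      records_simulated = nrow(records),
      records_with_weather = nrow(records_w),
      records_edited = nrow(edited),
      animals_phenotyped = length(unique(phenotypes$animal_id)),
      fits = length(fits)
    ),
    edit_report = edit_report(edited),
    weather_log = attr(records_w, "weather_log")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(phenotypes, file.path(out_dir, "phenotypes.csv"), row.names = FALSE)
    utils::write.csv(summary_tbl, file.path(out_dir, "phenotype_summary.csv"), row.names = FALSE)
    utils::write.csv(lifetime, file.path(out_dir, "lifetime_milk.csv"), row.names = FALSE)
    if (!is.null(herit)) {
      utils::write.csv(herit, file.path(out_dir, "heritability.csv"), row.names = FALSE)
    }
    if (!is.null(correlations)) {
      utils::write.csv(correlations, file.path(out_dir, "correlations.csv"), row.names = FALSE)
    }
    curves <- purrr::imap_dfr(fits, function(f, nm) {
      dplyr::mutate(population_curve(f), fit = nm)
    })
    utils::write.csv(curves, file.path(out_dir, "population_curves.csv"), row.names = FALSE)
    fitsum <- purrr::imap(fits, function(f, nm) {
      list(season = f$season, covariate = f$covariate, beta = unname(f$beta),
           G0 = unname(f$G0), sigma2e = f$sigma2e, loglik = f$loglik,
           iterations = f$iterations, converged = f$converged,
           x_range = c(f$basis$x_min, f$basis$x_max))
    })
    jsonlite::write_json(fitsum, file.path(out_dir, "fit_summaries.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest$edit_report, file.path(out_dir, "edit_report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(pedigree = ped, weather = weather, records = records,
                 records_weather = records_w, edited = edited,
                 lifetime = lifetime, fits = fits, phenotypes = phenotypes,
                 summary = summary_tbl, heritability = herit,
                 correlations = correlations, manifest = manifest,
                 truth = truth))
}

#' Plot phenotype distributions by season
#'
#' Density plot of the derived slope phenotypes, one panel per trait.
#'
#' @param phenotypes Output of \code{\link{derive_phenotypes}}.
#' @return A ggplot object.
#' @export
plot_phenotypes <- function(phenotypes) {
  stopifnot_cols(phenotypes, c("season", "trait", "slope"), "`phenotypes`")
  ggplot2::ggplot(phenotypes,
                  ggplot2::aes(x = .data$slope, colour = .data$season)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = "slope (kg milk per degC)", y = "density") +
    ggplot2::theme_minimal()
}
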
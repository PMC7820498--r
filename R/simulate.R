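#' Default configuration of the synthetic study
#'
#' Returns the default parameter list for the synthetic Mediterranean
#' dairy-sheep study emulated by the generators: a multi-generation random
#' mating pedigree, a sinusoidal + AR(1) daily weather series, September-May
#' lambings with seasonal proportions matching the real recording scheme's
#' animal counts (17,899 : 24,837 : 8,363 for autumn : winter : spring),
#' monthly test-day recording from day 42 over a 5-6-month lactation, a
#' Wilmink lactation-curve baseline, and season-specific population reaction
#' norms with animal-specific Legendre deviations. The reaction-norm
#' covariances are set so the derived slope phenotypes have season-level
#' spread comparable to real Chios data (slope SDs around 0.014-0.018
#' kg/degC).
#'
#' @param seed Master seed; each sub-generator derives its own stream from it
#'   so that, e.g., adding flocks does not perturb the weather.
#' @return Named list of parameters (see the methods vignette for units and
#'   rationale).
#' @export
sim_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    # pedigree
    n_founders = 400L, n_generations = 3L, n_per_generation = 700L,
    n_sires = 25L, prop_male = 0.5,
    # weather
    weather_start = as.Date("2011-01-01"), weather_end = as.Date("2018-12-31"),
    n_stations = 2L, t_mean = 16.5, t_amplitude = 10.5, t_phi = 0.7,
    t_innovation_sd = 1.8, rh_mean = 65, rh_sd = 10, rh_temp_slope = -1.2,
    peak_doy = 197L,
    # recording scheme
    n_flocks = 8L,
    season_props = c(autumn = 17899, winter = 24837, spring = 8363) / 51099,
    lambing_years = 2012:2016,
    recording_interval = 30L, first_test_dim = 42L, lactation_length = 200L,
    max_lactations = 3L, prob_next_lactation = 0.6,
    # lactation baseline (Wilmink): a + b * exp(-k * dim) + c * dim
    wilmink = c(a = 2.0, b = -0.6, k = 0.05, c = -0.004),
    # reaction norm, standard Legendre basis on x_range
    x_range = c(0, 30),
    beta_season = list(
      autumn = c(0, 0.15, 0),
      winter = c(0.05, 0.115, -0.095),
      spring = c(-0.05, -0.045, 0.075)
    ),
    G0 = diag(c(0.04, 0.022, 0.0035)),   # additive-genetic curve covariance
    P0 = diag(c(0.04, 0.022, 0.0035)),   # permanent-environment curve covariance
    residual_sd = 0.35,
    flock_sd = 0.15, year_sd = 0.05,
    parity_effects = c(-0.2, 0, 0.05)
  )
}

#' Simulate a discrete-generation random-mating pedigree
#'
#' Founders form generation 1; each later generation is produced by random
#' mating of a limited set of sires with the previous generation's females.
#'
#' @param n_founders Number of founder animals (>= 2).
#' @param n_generations Total number of generations (>= 1); 1 gives founders
#'   only.
#' @param n_per_generation Offspring per non-founder generation.
#' @param n_sires Breeding males drawn per generation.
#' @param prop_male Probability an animal is male.
#' @param seed Optional seed for this generator.
#' @return Tibble \code{animal, sire, dam, sex, generation} sorted
#'   parents-first.
#' @export
sim_pedigree <- function(n_founders = 400L, n_generations = 3L,
                         n_per_generation = 700L, n_sires = 25L,
                         prop_male = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_founders < 2L) abort("need at least 2 founders.")
  if (n_generations < 1L) abort("need at least 1 generation.")
  sex <- sample(c("M", "F"), n_founders, replace = TRUE,
                prob = c(prop_male, 1 - prop_male))
  # guarantee both sexes among founders
  if (!any(sex == "M")) sex[1] <- "M"
  if (!any(sex == "F")) sex[1] <- "F"
  ped <- tibble(animal = sprintf("A%05d", seq_len(n_founders)),
                sire = NA_character_, dam = NA_character_,
                sex = sex, generation = 1L)
  nid <- n_founders
  for (g in seq_len(n_generations - 1L) + 1L) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    if (!length(males) || !length(females)) {
      abort(sprintf("generation %d has no available %s.", g - 1L,
                    if (!length(males)) "sires" else "dams"))
    }
    sires <- sample(males, min(n_sires, length(males)))
    off_sire <- sample(sires, n_per_generation, replace = TRUE)
    off_dam <- sample(females, n_per_generation, replace = TRUE)
    off_sex <- sample(c("M", "F"), n_per_generation, replace = TRUE,
                      prob = c(prop_male, 1 - prop_male))
    ped <- bind_rows(ped, tibble(
      animal = sprintf("A%05d", nid + seq_len(n_per_generation)),
      sire = off_sire, dam = off_dam, sex = off_sex, generation = g
    ))
    nid <- nid + n_per_generation
  }
  ped
}

#' Simulate daily station weather
#'
#' Daily mean air temperature follows an annual sinusoid (maximum at
#' \code{peak_doy}, mid-July by default) plus stationary AR(1) noise; relative
#' humidity is drawn around a mean that decreases with the temperature anomaly
#' and truncated to \[0, 100\]; THI is computed from the two.
#'
#' @param start,end Date range (inclusive).
#' @param n_stations Number of stations (independent noise, shared climate).
#' @param t_mean,t_amplitude Annual mean and half-range of the sinusoid
#'   (degrees C).
#' @param phi,innovation_sd AR(1) coefficient and innovation SD of the
#'   temperature noise.
#' @param rh_mean,rh_sd,rh_temp_slope Relative-humidity mean, SD, and change
#'   per degree of temperature anomaly (negative: hot spells are drier).
#' @param peak_doy Day of year of the temperature maximum.
#' @param seed Optional seed.
#' @return Tibble \code{station_id, date, tavg, rhavg, thi}.
#' @export
sim_weather <- function(start, end, n_stations = 1L, t_mean = 16,
                        t_amplitude = 9, phi = 0.7, innovation_sd = 1.8,
                        rh_mean = 65, rh_sd = 10, rh_temp_slope = -1.2,
                        peak_doy = 197L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  if (!length(dates)) abort("empty date range.")
  doy <- as.integer(format(dates, "%j"))
  base <- t_mean + t_amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
  nd <- length(dates)
  purrr::map_dfr(seq_len(n_stations), function(s) {
    ar <- numeric(nd)
    sd_stat <- if (phi == 0) innovation_sd else innovation_sd / sqrt(1 - phi^2)
    if (innovation_sd > 0) {
      ar[1] <- rnorm(1, 0, sd_stat)
      eps <- rnorm(nd - 1, 0, innovation_sd)
      for (i in 2:nd) ar[i] <- phi * ar[i - 1] + eps[i - 1]
    }
    tavg <- base + ar
    rh <- rh_mean + rh_temp_slope * ar +
      if (rh_sd > 0) rnorm(nd, 0, rh_sd) else 0
    rh <- pmin(100, pmax(0, rh))
    tibble(station_id = sprintf("S%02d", s), date = dates,
           tavg = tavg, rhavg = rh, thi = compute_thi(tavg, rh))
  })
}

#' Simulate additive-genetic values down a pedigree
#'
#' Founders draw coefficient vectors from \eqn{N(0, G_0)}; descendants receive
#' the parent average plus Mendelian sampling with covariance
#' \eqn{0.5 G_0 (1 - (F_s + F_d)/2)} (inbreeding coefficients from
#' \code{\link{inbreeding}}); with one unknown parent the Mendelian-sampling
#' covariance is \eqn{(0.75 - 0.25 F_{known}) G_0}.
#'
#' @param ped Pedigree data frame.
#' @param G0 Positive semi-definite covariance of the coefficient vector.
#' @param seed Optional seed.
#' @return Matrix (animals x coefficients) with rownames the animal ids, in
#'   parents-first order.
#' @export
sim_breeding_values <- function(ped, G0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G0 <- as.matrix(G0)
  k <- nrow(G0)
  if (!is_psd(G0)) abort("G0 must be positive semi-definite.")
  pedn <- ped_normalise(ped)
  n <- nrow(pedn)
  Fc <- inbreeding(pedn)
  ev <- eigen(G0, symmetric = TRUE)
  Lh <- ev$vectors %*% diag(sqrt(pmax(0, ev$values)), k)
  BV <- matrix(0, n, k, dimnames = list(pedn$animal, NULL))
  Zs <- matrix(rnorm(n * k), n, k)
  s <- pedn$sire_i; d <- pedn$dam_i
  for (i in seq_len(n)) {
    if (s[i] == 0L && d[i] == 0L) {
      BV[i, ] <- Lh %*% Zs[i, ]
    } else if (s[i] > 0L && d[i] > 0L) {
      msv <- 0.5 * (1 - (Fc[s[i]] + Fc[d[i]]) / 2)
      BV[i, ] <- 0.5 * (BV[s[i], ] + BV[d[i], ]) + sqrt(msv) * (Lh %*% Zs[i, ])
    } else {
      known <- max(s[i], d[i])
      msv <- 0.75 - 0.25 * Fc[known]
      BV[i, ] <- 0.5 * BV[known, ] + sqrt(msv) * (Lh %*% Zs[i, ])
    }
  }
  BV
}

#' Simulate monthly test-day milk records
#'
#' Each female of the later generations receives 1 or more lactations with
#' lambing dates drawn by season (September-May) in configured proportions;
#' monthly tests run from day 42 after lambing to dry-off. Test-day yield is
#' \deqn{y = flock + parity + year + Wilmink(dim) +
#'       \Phi(tavg) (\beta_{season} + g_i + p_i) + e}
#' with \eqn{g_i} additive-genetic and \eqn{p_i} permanent-environment
#' Legendre coefficient vectors and the standard (unnormalised) basis over
#' \code{config$x_range}. Temperatures outside the range are clipped for the
#' curve evaluation.
#'
#' @param ped Pedigree from \code{\link{sim_pedigree}} (needs \code{sex} and
#'   \code{generation} columns).
#' @param weather Weather from \code{\link{sim_weather}}.
#' @param config List as from \code{\link{sim_config}}.
#' @param phenotyped_generations Generations whose females are recorded
#'   (default: all but the first).
#' @param seed Optional seed.
#' @return Tibble \code{animal_id, flock_id, lambing_date, test_date,
#'   lactation_number, dim, milk_kg} with a \code{"truth"} attribute holding
#'   the generating values (beta per season, genetic and permanent
#'   coefficients, effects).
#' @export
sim_testdays <- function(ped, weather, config = sim_config(),
                         phenotyped_generations = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  gens <- phenotyped_generations %||% setdiff(unique(ped$generation), 1L)
  ewes <- ped$animal[ped$sex == "F" & ped$generation %in% gens]
  if (!length(ewes)) abort("no phenotyped females in the requested generations.")
  basis <- legendre_basis(cfg$x_range[1], cfg$x_range[2], 2, "standard")

  g_coef <- sim_breeding_values(ped, cfg$G0)
  pe_coef <- matrix(rnorm(length(ewes) * 3), length(ewes), 3) %*%
    chol(cfg$P0 + diag(1e-12, 3))
  rownames(pe_coef) <- ewes

  flocks <- sprintf("F%02d", seq_len(cfg$n_flocks))
  flock_eff <- setNames(rnorm(cfg$n_flocks, 0, cfg$flock_sd), flocks)
  years <- cfg$lambing_years
  year_eff <- setNames(rnorm(length(years), 0, cfg$year_sd), as.character(years))
  flock_of <- setNames(sample(flocks, length(ewes), replace = TRUE), ewes)
  stations <- unique(weather$station_id)
  station_of_flock <- setNames(stations[(seq_along(flocks) - 1L) %% length(stations) + 1L],
                               flocks)

  season_months <- list(autumn = 9:11, winter = c(12, 1, 2), spring = 3:5)
  wil <- cfg$wilmink
  wkey <- paste(weather$station_id, as.integer(weather$date))
  wtavg <- setNames(weather$tavg, wkey)

  recs <- vector("list", length(ewes))
  for (ei in seq_along(ewes)) {
    a <- ewes[ei]
    n_lact <- 1L
    while (n_lact < cfg$max_lactations && runif(1) < cfg$prob_next_lactation) {
      n_lact <- n_lact + 1L
    }
    first_year <- sample(years[seq_len(max(1L, length(years) - n_lact + 1L))], 1L)
    rows <- vector("list", n_lact)
    for (l in seq_len(n_lact)) {
      season <- sample(names(cfg$season_props), 1L, prob = cfg$season_props)
      month <- sample(season_months[[season]], 1L)
      yr <- first_year + (l - 1L)
      # December-February lambings of season year y span the year boundary
      lamb_year <- if (season == "winter" && month %in% 1:2) yr + 1L else yr
      lambing <- as.Date(sprintf("%d-%02d-%02d", lamb_year, month,
                                 sample(1:28, 1L)))
      dims <- seq(cfg$first_test_dim, cfg$lactation_length,
                  by = cfg$recording_interval)
      test_dates <- lambing + dims
      tv <- wtavg[paste(station_of_flock[flock_of[a]], as.integer(test_dates))]
      if (anyNA(tv)) next  # weather does not cover this lactation
      xcl <- pmin(cfg$x_range[2], pmax(cfg$x_range[1], tv))
      Phi <- eval_basis(basis, xcl)
      curve <- as.numeric(Phi %*% (cfg$beta_season[[season]] + g_coef[a, ] + pe_coef[a, ]))
      ye <- year_eff[as.character(lamb_year)]
      if (is.na(ye)) ye <- 0  # lambing shifted past the configured year range
      y <- flock_eff[flock_of[a]] +
        cfg$parity_effects[min(l, length(cfg$parity_effects))] +
        ye +
        wil["a"] + wil["b"] * exp(-wil["k"] * dims) + wil["c"] * dims +
        curve + rnorm(length(dims), 0, cfg$residual_sd)
      rows[[l]] <- tibble(
        animal_id = a, flock_id = unname(flock_of[a]),
        lambing_date = lambing, test_date = test_dates,
        lactation_number = l, dim = dims, milk_kg = pmax(0.05, unname(y))
      )
    }
    recs[[ei]] <- bind_rows(rows)
  }
  out <- bind_rows(recs)
  attr(out, "truth") <- list(
    basis = basis, beta_season = cfg$beta_season,
    g_coef = g_coef, pe_coef = pe_coef,
    flock_eff = flock_eff, year_eff = year_eff,
    parity_effects = cfg$parity_effects, wilmink = wil,
    station_of_flock = station_of_flock, residual_sd = cfg$residual_sd
  )
  out
}

#' Simulate one or two direct animal traits with known genetic parameters
#'
#' Generates scalar phenotypes \eqn{y = \mu + group + BV + e} on a pedigree
#' with the additive and residual (co)variances solving the requested
#' heritabilities and correlations at unit phenotypic variance: at unit scale
#' \eqn{\sigma^2_{a,t} = h^2_t}, \eqn{\sigma_{a12} = r_A \sqrt{h^2_1 h^2_2}}
#' and \eqn{\sigma_{e12} = r_P - \sigma_{a12}}. An inadmissible implied
#' residual covariance is an error.
#'
#' @param ped Pedigree data frame.
#' @param h2 Heritabilities, length 1 or 2, each in (0, 1\].
#' @param rA Genetic correlation (two-trait case).
#' @param rP Phenotypic correlation (two-trait case); defaults to \code{rA *
#'   sqrt(h2_1 * h2_2)}, i.e. zero residual correlation.
#' @param phenotyped Animal ids to phenotype; default all females, or all
#'   animals when the pedigree has no \code{sex} column.
#' @param n_groups Levels of a random-levels fixed "flock" factor (default
#'   10; set 0 for none).
#' @param group_sd SD of the fixed-effect level values (default 0.25).
#' @param mu Overall mean.
#' @param seed Optional seed.
#' @return Tibble \code{animal_id, group, y1[, y2]} with a \code{"truth"}
#'   attribute (G0, E0, breeding values).
#' @export
sim_direct_traits <- function(ped, h2, rA = NULL, rP = NULL, phenotyped = NULL,
                              n_groups = 10L, group_sd = 0.25, mu = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(h2)
  if (!k %in% 1:2) abort("`h2` must have length 1 or 2.")
  if (any(h2 <= 0 | h2 > 1)) abort("each h2 must be in (0, 1].")
  if (k == 1L) {
    G0 <- matrix(h2, 1, 1)
    E0 <- matrix(1 - h2, 1, 1)
  } else {
    if (is.null(rA)) abort("`rA` is required for two traits.")
    if (abs(rA) > 1) abort("|rA| must be <= 1.")
    sa12 <- rA * sqrt(h2[1] * h2[2])
    rP <- rP %||% sa12
    se12 <- rP - sa12
    G0 <- matrix(c(h2[1], sa12, sa12, h2[2]), 2, 2)
    E0 <- matrix(c(1 - h2[1], se12, se12, 1 - h2[2]), 2, 2)
    if (!is_psd(E0) || any(diag(E0) < 0)) {
      abort(sprintf("implied residual covariance %.3f is inadmissible for h2 = (%g, %g).",
                    se12, h2[1], h2[2]))
    }
  }
  pedn <- ped_normalise(ped)
  BV <- sim_breeding_values(pedn, G0)
  phen <- phenotyped %||% (
    if ("sex" %in% names(ped)) as.character(ped$animal[ped$sex == "F"]) else pedn$animal
  )
  phen <- intersect(pedn$animal, phen)
  np <- length(phen)
  if (!np) abort("no animals to phenotype.")
  E <- matrix(rnorm(np * k), np, k) %*% chol(E0 + diag(1e-12, k))
  if (n_groups > 0L) {
    geff <- rnorm(n_groups, 0, group_sd)
    grp <- sample.int(n_groups, np, replace = TRUE)
  } else {
    geff <- 0; grp <- rep(1L, np)
  }
  Y <- mu + geff[grp] + BV[phen, , drop = FALSE] + E
  out <- tibble(animal_id = phen, group = factor(grp))
  for (t in seq_len(k)) out[[paste0("y", t)]] <- unname(Y[, t])
  attr(out, "truth") <- list(G0 = G0, E0 = E0, bv = BV)
  out
}
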
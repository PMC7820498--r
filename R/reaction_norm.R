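#' Fit a Legendre reaction-norm model to test-day records
#'
#' Fits the random-regression model
#' \deqn{y = X b + \Phi \beta + Z (\Phi \circ a) + e}
#' in which test-day milk yield responds to a weather covariate through a
#' second-degree Legendre polynomial: \eqn{\Phi \beta} is the population
#' reaction norm and each animal carries a random 3-vector of curve
#' coefficients \eqn{a_i \sim N(0, G_0)} (unstructured 3x3 covariance,
#' i.i.d. across animals at this stage; genetic structure enters later, on the
#' derived slope phenotypes). Variance components are estimated by REML with
#' average-information updates; \eqn{\beta} and the \eqn{a_i} are the
#' GLS/BLUP solutions at the converged components.
#'
#' Default fixed effects are farm, lactation number, lambing year, lambing
#' month and 30-day days-in-milk classes, each with a set-to-zero constraint
#' on its first level; confounded levels are dropped with a warning.
#'
#' @param records Tibble with columns \code{animal_id, flock_id, lambing_date,
#'   lactation_number, dim, milk_kg} and the covariate column.
#' @param covariate Name of the covariate column (\code{"tavg"},
#'   \code{"tavg_lag7"}, \code{"thi"}, \code{"thi_lag7"}).
#' @param basis A \code{\link{legendre_basis}}; by default degree 2 over the
#'   observed covariate range (stored with the fit so later slope queries are
#'   validated against it).
#' @param fixed Optional one-sided formula replacing the default fixed
#'   effects; terms must name columns of \code{records}.
#' @param season Optional season label stored with the fit; taken from a
#'   \code{season} column when unique.
#' @param ... Passed to the REML engine (\code{max_iter}, \code{tol_loglik},
#'   \code{tol_param}, \code{verbose}).
#' @return Object of class \code{"rn_fit"}: population coefficients
#'   \code{beta}, per-animal random coefficients \code{u}, covariance
#'   \code{G0}, residual variance \code{sigma2e}, the basis, log-likelihood
#'   and iteration count.
#' @export
fit_reaction_norm <- function(records, covariate = "tavg", basis = NULL,
                              fixed = NULL, season = NULL, ...) {
  stopifnot_cols(records, c("animal_id", "milk_kg", covariate), "`records`")
  records <- as_tibble(records)
  records <- records[!is.na(records[[covariate]]), , drop = FALSE]
  x <- records[[covariate]]
  if (length(unique(x)) < 2L) abort("need at least 2 distinct covariate values.")
  basis <- basis %||% legendre_basis(min(x), max(x))
  if (is.null(season) && "season" %in% names(records)) {
    ss <- unique(as.character(records$season))
    if (length(ss) == 1L) season <- ss
  }

  Phi <- eval_basis(basis, x)
  colnames(Phi) <- paste0("phi", 0:basis$degree)

  if (is.null(fixed)) {
    col <- function(nm, default) {
      if (nm %in% names(records)) records[[nm]] else default
    }
    df <- tibble(
      farm = factor(col("flock_id", "farm1")),
      lact = factor(col("lactation_number", 1L)),
      lamb_year = factor(format(as.Date(col("lambing_date", Sys.Date())), "%Y")),
      lamb_month = factor(format(as.Date(col("lambing_date", Sys.Date())), "%m")),
      dim_class = factor(pmin(floor(col("dim", 0) / 30), 7L))
    )
    keep <- vapply(df, function(f) nlevels(droplevels(f)) > 1L, TRUE)
    df <- droplevels(df[, keep, drop = FALSE])
    Xf <- if (ncol(df)) {
      stats::model.matrix(stats::reformulate(names(df)), data = df)[, -1, drop = FALSE]
    } else {
      matrix(0, nrow(records), 0)
    }
  } else {
    Xf <- stats::model.matrix(fixed, data = records)[, -1, drop = FALSE]
  }
  X <- cbind(Phi, Xf)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    if (any(dropped %in% colnames(Phi))) {
      abort("the Legendre regression columns are confounded with the fixed effects.")
    }
    warn(sprintf("dropping %d confounded fixed-effect column(s): %s",
                 length(dropped), paste(utils::head(dropped, 5), collapse = ", ")))
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  }

  animals <- sort(unique(as.character(records$animal_id)))
  q <- length(animals)
  ai <- match(as.character(records$animal_id), animals)
  nb <- basis$degree + 1L
  n <- nrow(records)
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(n), nb),
    j = as.integer(outer(ai, (seq_len(nb) - 1L) * q, `+`)),
    x = as.numeric(Phi),
    dims = c(n, nb * q)
  )

  fit <- reml_ai(records$milk_kg, X, Z, q = q, k = nb, Ainv = NULL,
                 resid = resid_iid(), ...)

  bn <- colnames(X)
  beta <- fit$fixed[match(colnames(Phi), bn)]
  other <- setdiff(bn, colnames(Phi))
  b_other <- fit$fixed[match(other, bn)]
  mean_fixed <- if (length(other)) {
    mean(as.numeric(X[, other, drop = FALSE] %*% b_other))
  } else 0
  u <- fit$u
  rownames(u) <- animals
  structure(
    list(beta = setNames(beta, colnames(Phi)), u = u, G0 = fit$Sigma0,
         sigma2e = fit$sigma2e, basis = basis, covariate = covariate,
         season = season, fixed_effects = setNames(b_other, other),
         mean_fixed = mean_fixed, loglik = fit$loglik,
         iterations = fit$iterations, converged = fit$converged,
         boundary = fit$boundary, acov = fit$acov, AI = fit$AI,
         n = n, n_animals = q, animals = animals),
    class = "rn_fit"
  )
}

#' @export
print.rn_fit <- function(x, ...) {
  cat(sprintf("Legendre reaction-norm fit (%s%s): %d records, %d animals\n",
              x$covariate, if (!is.null(x$season)) paste0(", ", x$season) else "",
              x$n, x$n_animals))
  cat(sprintf("  basis range [%g, %g] degC; logLik %.2f in %d iterations\n",
              x$basis$x_min, x$basis$x_max, x$loglik, x$iterations))
  cat("  beta:", sprintf("%.4f", x$beta), "\n")
  cat(sprintf("  sigma2e %.4f; diag(G0): %s\n", x$sigma2e,
              paste(sprintf("%.4f", diag(x$G0)), collapse = ", ")))
  invisible(x)
}

#' Population reaction-norm curve
#'
#' Evaluates the fitted population-level curve (mean fixed-effect contribution
#' plus \eqn{\Phi(x) \beta}) on a covariate grid.
#'
#' @param fit An \code{rn_fit}.
#' @param x Covariate grid; defaults to 100 points across the basis range.
#' @return Tibble \code{x, yhat}.
#' @export
population_curve <- function(fit, x = NULL) {
  x <- x %||% seq(fit$basis$x_min, fit$basis$x_max, length.out = 100)
  tibble(x = x,
         yhat = fit$mean_fixed + as.numeric(eval_basis(fit$basis, x) %*% fit$beta))
}

#' Slope of fitted reaction norms at a temperature
#'
#' Analytic derivative (kg milk per degree C) of each animal's fitted curve at
#' \code{x0}, using the chain-rule factor \code{2 / (x_max - x_min)} of the
#' rescaled Legendre argument. Mode \code{"total"} (default) differentiates
#' population + individual deviation; \code{"deviation"} the deviation only.
#'
#' @param fit An \code{rn_fit}.
#' @param x0 Temperature at which to evaluate the slope (within the basis
#'   range).
#' @param animals Animal ids (default: all in the fit). Unknown ids are an
#'   error.
#' @param mode \code{"total"} or \code{"deviation"}.
#' @return Tibble \code{animal_id, slope}.
#' @export
slope_at <- function(fit, x0, animals = NULL, mode = c("total", "deviation")) {
  mode <- match.arg(mode)
  if (!inherits(fit, "rn_fit")) abort("`fit` must be an rn_fit.")
  if (length(x0) != 1L) abort("`x0` must be a single temperature.")
  animals <- as.character(animals %||% fit$animals)
  miss <- setdiff(animals, fit$animals)
  if (length(miss)) {
    abort(sprintf("animal(s) not in fit: %s", paste(utils::head(miss, 5), collapse = ", ")))
  }
  dphi <- as.numeric(eval_basis_deriv(fit$basis, x0))
  coefs <- fit$u[animals, , drop = FALSE]
  if (mode == "total") coefs <- sweep(coefs, 2L, fit$beta, `+`)
  tibble(animal_id = animals, slope = as.numeric(coefs %*% dphi))
}

#' Derive seasonal resilience phenotypes from reaction-norm fits
#'
#' Emits one slope phenotype per animal, season, temperature and lag variant:
#' \code{Tavg10}/\code{Tavg25} from same-day-covariate fits and
#' \code{Tavg10_lag7}/\code{Tavg25_lag7} from week-preceding fits. A
#' temperature outside a fit's observed covariate range skips that trait for
#' that season with a warning.
#'
#' @param fits List of \code{rn_fit} objects (one per season x covariate),
#'   each carrying its \code{season} and \code{covariate} tags.
#' @param temps Temperatures (degrees C) at which slopes are evaluated;
#'   defaults to 10 (cold) and 25 (heat stress).
#' @param mode Slope mode, see \code{\link{slope_at}}.
#' @return Tibble \code{animal_id, season, trait, slope}.
#' @export
derive_phenotypes <- function(fits, temps = c(10, 25), mode = c("total", "deviation")) {
  mode <- match.arg(mode)
  if (inherits(fits, "rn_fit")) fits <- list(fits)
  out <- list()
  for (fit in fits) {
    if (!inherits(fit, "rn_fit")) abort("`fits` must contain rn_fit objects.")
    lag <- grepl("lag7$", fit$covariate)
    for (tp in temps) {
      trait <- paste0("Tavg", tp, if (lag) "_lag7" else "")
      if (tp < fit$basis$x_min || tp > fit$basis$x_max) {
        warn(sprintf("%g degC is outside the observed %s range [%g, %g] for season %s; trait %s skipped.",
                     tp, fit$covariate, fit$basis$x_min, fit$basis$x_max,
                     fit$season %||% "?", trait))
        next
      }
      sl <- slope_at(fit, tp, mode = mode)
      sl$season <- fit$season %||% NA_character_
      sl$trait <- trait
      out[[length(out) + 1L]] <- sl
    }
  }
  if (!length(out)) {
    return(tibble(animal_id = character(), season = character(),
                  trait = character(), slope = numeric()))
  }
  dplyr::select(bind_rows(out), "animal_id", "season", "trait", "slope")
}

#' Summarise resilience phenotypes by season and trait
#'
#' @param phenotypes Output of \code{\link{derive_phenotypes}}.
#' @return Tibble \code{trait, season, n, mean, sd} (one row per season x
#'   trait, the layout used for descriptive reporting).
#' @export
phenotype_summary <- function(phenotypes) {
  stopifnot_cols(phenotypes, c("season", "trait", "slope"), "`phenotypes`")
  phenotypes |>
    group_by(.data$trait, .data$season) |>
    summarise(n = dplyr::n(), mean = mean(.data$slope), sd = sd(.data$slope),
              .groups = "drop")
}

#' @method tidy rn_fit
#' @export
tidy.rn_fit <- function(x, ...) {
  tibble(term = names(x$beta), estimate = as.numeric(x$beta))
}

#' @method glance rn_fit
#' @export
glance.rn_fit <- function(x, ...) {
  tibble(logLik = x$loglik, sigma2e = x$sigma2e,
         g_intercept = x$G0[1, 1], g_linear = x$G0[2, 2], g_quadratic = x$G0[3, 3],
         iterations = x$iterations, converged = x$converged,
         n = x$n, n_animals = x$n_animals)
}

#' Plot a fitted reaction norm
#'
#' Population curve (solid) with a sample of individual animal curves
#' (population + deviation), across the covariate range.
#'
#' @param object An \code{rn_fit}.
#' @param n_animals Number of individual curves to draw (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rn_fit
#' @export
autoplot.rn_fit <- function(object, n_animals = 50, ...) {
  grid <- seq(object$basis$x_min, object$basis$x_max, length.out = 80)
  Phi <- eval_basis(object$basis, grid)
  pop <- population_curve(object, grid)
  ids <- utils::head(object$animals, n_animals)
  ind <- purrr::map_dfr(ids, function(a) {
    tibble(animal_id = a, x = grid,
           yhat = object$mean_fixed +
             as.numeric(Phi %*% (object$beta + object$u[a, ])))
  })
  ggplot2::ggplot(ind, ggplot2::aes(x = .data$x, y = .data$yhat)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$animal_id),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = pop, colour = "red", linewidth = 1) +
    ggplot2::labs(
      x = sprintf("%s (degC)", object$covariate), y = "daily milk yield (kg)",
      title = sprintf("Reaction norms%s",
                      if (!is.null(object$season)) paste0(" - ", object$season) else "")
    ) +
    ggplot2::theme_minimal()
}
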
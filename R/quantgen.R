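#' Univariate animal-model REML
#'
#' Estimates additive-genetic and residual variances for one trait under the
#' animal model \eqn{y = X b + Z a + e}, \eqn{a \sim N(0, \sigma^2_a A)}, with
#' the pedigree relationship structure entering through the sparse
#' \eqn{A^{-1}} of \code{\link{a_inverse}}. Heritability
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)} and its standard error
#' (delta method on the inverse average-information matrix) are returned,
#' together with a likelihood-ratio test of the animal effect against the
#' fixed-effects-only model (null distribution: 50:50 mixture of
#' \eqn{\chi^2_0} and \eqn{\chi^2_1}, standard for a variance bounded at
#' zero) and a two-tailed t-test on residual degrees of freedom.
#'
#' @param data Tibble with the response, fixed-effect columns and an animal id
#'   column; repeated records per animal are allowed (the random effect is then
#'   shared).
#' @param response Name of the response column.
#' @param pedigree Pedigree data frame (\code{animal, sire, dam}) or a
#'   precomputed \code{\link{a_inverse}} matrix. Every phenotyped animal must
#'   appear in it.
#' @param fixed One-sided formula of fixed effects (default intercept only).
#' @param animal Name of the animal id column (default \code{"animal_id"}).
#' @param ... Passed to the REML engine.
#' @return Object of class \code{"gen_fit"}.
#' @export
reml_univariate <- function(data, response, pedigree, fixed = ~1,
                            animal = "animal_id", ...) {
  stopifnot_cols(data, c(response, animal), "`data`")
  data <- as_tibble(data)
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  Ainv <- resolve_ainverse(pedigree)
  ids <- rownames(Ainv)
  pos <- match(as.character(data[[animal]]), ids)
  if (anyNA(pos)) {
    miss <- unique(as.character(data[[animal]])[is.na(pos)])
    abort(sprintf("phenotyped animal(s) absent from pedigree: %s",
                  paste(utils::head(miss, 5), collapse = ", ")))
  }
  y <- data[[response]]
  X <- build_fixed(data, fixed)
  q <- length(ids)
  n <- length(y)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = pos, x = 1, dims = c(n, q))
  fit <- reml_ai(y, X, Z, q = q, k = 1L, Ainv = Ainv,
                 logdet_A = attr(Ainv, "logdet_A"), resid = resid_iid(), ...)
  null <- reml_null(y, X)
  s2a <- fit$Sigma0[1, 1]; s2e <- fit$R0
  h2 <- s2a / (s2a + s2e)
  gr <- c(s2e, -s2a) / (s2a + s2e)^2
  se_h2 <- sqrt(max(0, drop(t(gr) %*% fit$acov %*% gr)))
  lrt <- max(0, 2 * (fit$loglik - null$loglik))
  res <- structure(
    list(trait = response, sigma2_a = s2a, sigma2_e = s2e, h2 = h2,
         se_sigma2_a = sqrt(max(0, fit$acov[1, 1])),
         se_sigma2_e = sqrt(max(0, fit$acov[2, 2])),
         se_h2 = se_h2, loglik = fit$loglik, loglik_null = null$loglik,
         lrt = lrt, df_t = fit$n - fit$p, n = fit$n, p = fit$p,
         iterations = fit$iterations, converged = fit$converged,
         boundary = fit$boundary, acov = fit$acov,
         blup = setNames(fit$u[, 1], ids)),
    class = "gen_fit"
  )
  significance(res)
}

#' Bivariate animal-model REML
#'
#' Joint REML for two traits with additive-genetic covariance
#' \eqn{G_0 \otimes A} and an unstructured 2x2 residual covariance per animal;
#' animals recorded for only one trait contribute through the corresponding
#' marginal residual block. Returns genetic and phenotypic correlations
#' \deqn{r_A = \sigma_{a12} / \sqrt{\sigma^2_{a1} \sigma^2_{a2}}, \quad
#'       r_P = (\sigma_{a12} + \sigma_{e12}) /
#'             \sqrt{(\sigma^2_{a1}+\sigma^2_{e1})(\sigma^2_{a2}+\sigma^2_{e2})}}
#' with delta-method standard errors from the inverse average-information
#' matrix.
#'
#' @param data Wide tibble: one row per animal with both trait columns
#'   (\code{NA} where unrecorded), fixed-effect columns and the animal id.
#' @param traits Character vector of the two trait column names.
#' @inheritParams reml_univariate
#' @return Object of class \code{"gen_fit2"}.
#' @export
reml_bivariate <- function(data, traits, pedigree, fixed = ~1,
                           animal = "animal_id", ...) {
  if (length(traits) != 2L) abort("`traits` must name exactly two columns.")
  stopifnot_cols(data, c(traits, animal), "`data`")
  data <- as_tibble(data)
  Ainv <- resolve_ainverse(pedigree)
  ids <- rownames(Ainv)
  q <- length(ids)

  rows <- list(); Xs <- list()
  for (t in 1:2) {
    dt <- data[!is.na(data[[traits[t]]]), , drop = FALSE]
    if (!nrow(dt)) abort(sprintf("trait '%s' has no records.", traits[t]))
    pos <- match(as.character(dt[[animal]]), ids)
    if (anyNA(pos)) {
      miss <- unique(as.character(dt[[animal]])[is.na(pos)])
      abort(sprintf("phenotyped animal(s) absent from pedigree: %s",
                    paste(utils::head(miss, 5), collapse = ", ")))
    }
    rows[[t]] <- tibble(y = dt[[traits[t]]], pos = pos, trait = t,
                        unit = as.character(dt[[animal]]))
    Xs[[t]] <- build_fixed(dt, fixed)
  }
  long <- bind_rows(rows)
  n <- nrow(long)
  X <- Matrix::bdiag(Xs[[1]], Xs[[2]])
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = (long$trait - 1L) * q + long$pos,
                            x = 1, dims = c(n, 2L * q))
  fit <- reml_ai(long$y, X, Z, q = q, k = 2L, Ainv = Ainv,
                 logdet_A = attr(Ainv, "logdet_A"),
                 resid = resid_unstructured(long$unit, long$trait, 2L), ...)
  null <- reml_null(long$y, as.matrix(X),
                    resid = resid_unstructured(long$unit, long$trait, 2L))
  G0 <- fit$Sigma0; R0 <- fit$R0

  derived <- function(theta) {
    G <- unvech(theta[1:3], 2); R <- unvech(theta[4:6], 2)
    h2 <- diag(G) / (diag(G) + diag(R))
    rA <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])
    rP <- (G[1, 2] + R[1, 2]) / sqrt(prod(diag(G) + diag(R)))
    c(h2_1 = h2[1], h2_2 = h2[2], rA = rA, rP = rP)
  }
  est <- derived(fit$theta)
  J <- num_jacobian(derived, fit$theta)
  vc <- J %*% fit$acov %*% t(J)
  ses <- sqrt(pmax(0, diag(vc)))
  clamp <- function(r) {
    if (is.finite(r) && abs(r) > 1) {
      warn(sprintf("correlation %.3f outside [-1, 1]; clamped.", r))
      sign(r)
    } else r
  }
  lrt <- max(0, 2 * (fit$loglik - null$loglik))
  res <- structure(
    list(traits = traits, G0 = G0, R0 = R0,
         h2 = setNames(est[1:2], traits), se_h2 = setNames(ses[1:2], traits),
         rA = clamp(unname(est[3])), se_rA = ses[3],
         rP = clamp(unname(est[4])), se_rP = ses[4],
         loglik = fit$loglik, loglik_null = null$loglik, lrt = lrt,
         df_t = fit$n - fit$p, n = fit$n, p = fit$p,
         iterations = fit$iterations, converged = fit$converged,
         boundary = fit$boundary, acov = fit$acov),
    class = "gen_fit2"
  )
  significance(res)
}

# accepts a pedigree data frame or an a_inverse() matrix
resolve_ainverse <- function(pedigree) {
  if (inherits(pedigree, "sparseMatrix")) {
    if (is.null(attr(pedigree, "logdet_A"))) {
      abort("`pedigree` matrix must come from a_inverse() (missing logdet attribute).")
    }
    return(pedigree)
  }
  a_inverse(pedigree)
}

num_jacobian <- function(f, x, rel = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- rel * (abs(x[j]) + 1e-8)
    up <- x; up[j] <- up[j] + h
    dn <- x; dn[j] <- dn[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  rownames(J) <- names(f0)
  J
}

#' Significance annotation of genetic-parameter estimates
#'
#' Adds two-tailed t-tests (estimate / SE on residual degrees of freedom) for
#' each derived parameter and the likelihood-ratio test of the animal genetic
#' effect, with p-values from the 50:50 \eqn{\chi^2_0 : \chi^2_1} mixture.
#' Estimates significant at P < 0.01 are starred, mirroring the reporting
#' convention for these traits.
#'
#' @param fit A \code{gen_fit} or \code{gen_fit2}.
#' @return The fit with \code{tests} (tibble) and \code{p_lrt} elements filled.
#' @export
significance <- function(fit) {
  tt <- function(est, se) {
    if (!is.finite(se) || se <= 0) {
      return(list(stat = NA_real_, p = NA_real_))
    }
    stat <- est / se
    list(stat = stat, p = 2 * pt(-abs(stat), df = fit$df_t))
  }
  if (inherits(fit, "gen_fit")) {
    rows <- list(
      c(term = "h2", estimate = fit$h2, se = fit$se_h2),
      c(term = "sigma2_a", estimate = fit$sigma2_a, se = fit$se_sigma2_a),
      c(term = "sigma2_e", estimate = fit$sigma2_e, se = fit$se_sigma2_e)
    )
  } else if (inherits(fit, "gen_fit2")) {
    rows <- list(
      c(term = paste0("h2_", fit$traits[1]), estimate = fit$h2[1], se = fit$se_h2[1]),
      c(term = paste0("h2_", fit$traits[2]), estimate = fit$h2[2], se = fit$se_h2[2]),
      c(term = "rA", estimate = fit$rA, se = fit$se_rA),
      c(term = "rP", estimate = fit$rP, se = fit$se_rP)
    )
  } else {
    abort("`fit` must be a gen_fit or gen_fit2.")
  }
  tests <- purrr::map_dfr(rows, function(r) {
    est <- as.numeric(r["estimate"]); se <- as.numeric(r["se"])
    ts <- tt(est, se)
    tibble(term = unname(r["term"]), estimate = est, std.error = se,
           statistic = ts$stat, p.value = ts$p, stars = sig_stars(ts$p))
  })
  fit$tests <- tests
  fit$p_lrt <- if (fit$lrt <= 0) 0.5 else 0.5 * pchisq(fit$lrt, df = 1, lower.tail = FALSE)
  fit
}

#' @export
print.gen_fit <- function(x, ...) {
  cat(sprintf("Animal-model REML: trait '%s', n = %d\n", x$trait, x$n))
  cat(sprintf("  sigma2_a %.4f  sigma2_e %.4f  h2 %.3f (SE %.3f)%s\n",
              x$sigma2_a, x$sigma2_e, x$h2, x$se_h2,
              sig_stars(x$tests$p.value[x$tests$term == "h2"])))
  cat(sprintf("  LRT (animal effect) %.2f, P = %.3g\n", x$lrt, x$p_lrt))
  invisible(x)
}

#' @export
print.gen_fit2 <- function(x, ...) {
  cat(sprintf("Bivariate animal-model REML: '%s' & '%s', n = %d records\n",
              x$traits[1], x$traits[2], x$n))
  cat(sprintf("  h2: %.3f (%.3f), %.3f (%.3f)\n",
              x$h2[1], x$se_h2[1], x$h2[2], x$se_h2[2]))
  cat(sprintf("  rA %.3f (%.3f)  rP %.3f (%.3f)\n", x$rA, x$se_rA, x$rP, x$se_rP))
  cat(sprintf("  LRT (animal effect) %.2f, P = %.3g\n", x$lrt, x$p_lrt))
  invisible(x)
}

#' @method tidy gen_fit
#' @export
tidy.gen_fit <- function(x, ...) x$tests

#' @method tidy gen_fit2
#' @export
tidy.gen_fit2 <- function(x, ...) x$tests

#' @method glance gen_fit
#' @export
glance.gen_fit <- function(x, ...) {
  tibble(logLik = x$loglik, logLik_null = x$loglik_null, lrt = x$lrt,
         p.lrt = x$p_lrt, n = x$n, iterations = x$iterations,
         converged = x$converged, boundary = x$boundary)
}

#' @method glance gen_fit2
#' @export
glance.gen_fit2 <- function(x, ...) glance.gen_fit(x, ...)
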
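test_that("noiseless data from a known population curve are recovered exactly", {
  set.seed(601)
  basis <- legendre_basis(0, 30, 2, "standard")
  beta <- c(1.8, 0.25, -0.12)
  x <- runif(200, 0, 30)
  recs <- tibble::tibble(
    animal_id = rep(sprintf("a%02d", 1:40), each = 5),
    milk_kg = as.numeric(eval_basis(basis, x) %*% beta),
    tavg = x
  )
  fit <- fit_reaction_norm(recs, basis = basis)
  expect_equal(unname(fit$beta), beta, tolerance = 1e-4)
  expect_lt(max(diag(fit$G0)), 1e-4)
  expect_lt(fit$sigma2e, 1e-4)
})

test_that("variance components are recovered on simulated random regressions", {
  set.seed(602)
  basis <- legendre_basis(0, 30, 2, "normalized")
  G0 <- diag(c(0.2, 0.1, 0.05))
  s2e <- 0.5
  beta <- c(2.5, 0.4, -0.2)
  nrep <- 5
  est <- matrix(0, nrep, 4)
  for (r in seq_len(nrep)) {
    recs <- sim_rr_records(400, 8, beta, G0, s2e, basis)
    fit <- fit_reaction_norm(recs, basis = basis)
    est[r, ] <- c(diag(fit$G0), fit$sigma2e)
  }
  truth <- c(diag(G0), s2e)
  mc_se <- apply(est, 2, sd) / sqrt(nrep)
  for (j in 1:4) {
    expect_lt(abs(mean(est[, j]) - truth[j]), 3 * mc_se[j] + 0.01 * truth[j])
  }
})

test_that("fitted population curves track the generating curve", {
  set.seed(603)
  basis <- legendre_basis(0, 30, 2, "normalized")
  beta <- c(2.5, 0.4, -0.35)  # heat-stress shape: interior maximum
  recs <- sim_rr_records(500, 8, beta, diag(c(0.1, 0.05, 0.02)), 0.3, basis)
  fit <- fit_reaction_norm(recs, basis = basis)
  grid <- seq(1, 29, length.out = 50)
  truth_curve <- as.numeric(eval_basis(basis, grid) %*% beta)
  fit_curve <- population_curve(fit, grid)$yhat
  expect_lt(max(abs(fit_curve - truth_curve)), 0.1)
  # declines beyond its interior maximum
  pk <- which.max(fit_curve)
  expect_gt(pk, 1)
  expect_lt(pk, 50)
  expect_lt(fit_curve[50], fit_curve[pk])
})

test_that("slopes are linear in coefficients and analytic equals finite difference", {
  set.seed(604)
  basis <- legendre_basis(0, 30, 2, "normalized")
  recs <- sim_rr_records(60, 6, c(2, 0.3, -0.1), diag(c(0.1, 0.05, 0.02)), 0.2,
                         basis)
  fit <- fit_reaction_norm(recs, basis = basis)
  for (x0 in c(10, 25)) {
    tot <- slope_at(fit, x0)$slope
    dev <- slope_at(fit, x0, mode = "deviation")$slope
    pop <- sum(as.numeric(eval_basis_deriv(basis, x0)) * fit$beta)
    expect_equal(tot, dev + pop, tolerance = 1e-10)
    # finite-difference oracle on the total individual curves
    h <- 0.01
    for (a in fit$animals[1:5]) {
      cf <- fit$beta + fit$u[a, ]
      fd <- (sum(eval_basis(basis, x0 + h) * cf) -
               sum(eval_basis(basis, x0 - h) * cf)) / (2 * h)
      expect_equal(slope_at(fit, x0, animals = a)$slope, fd, tolerance = 1e-6)
    }
  }
  expect_error(slope_at(fit, 10, animals = "nobody"), "not in fit")
  expect_error(slope_at(fit, 99), "outside")
})

test_that("a curve with no quadratic part has a constant slope", {
  basis <- legendre_basis(0, 30, 2, "standard")
  fit <- structure(
    list(beta = c(phi0 = 1, phi1 = 0.6, phi2 = 0),
         u = matrix(0, 1, 3, dimnames = list("a1", NULL)),
         basis = basis, animals = "a1", mean_fixed = 0),
    class = "rn_fit"
  )
  slopes <- vapply(c(2, 15, 28), function(x0) slope_at(fit, x0)$slope, 0)
  expect_equal(slopes, rep(0.6 * 2 / 30, 3))
  # all-zero coefficients give a zero slope everywhere
  fit$beta[] <- 0
  expect_equal(slope_at(fit, 17)$slope, 0)
})

test_that("identical animals get identical phenotypes; deviations centre near zero", {
  set.seed(605)
  basis <- legendre_basis(0, 30, 2, "normalized")
  recs <- sim_rr_records(80, 6, c(2, 0.3, -0.1), diag(c(0.1, 0.05, 0.02)), 0.2,
                         basis)
  clone <- recs[recs$animal_id == "rr0001", ]
  clone$animal_id <- "clone"
  fit <- fit_reaction_norm(dplyr::bind_rows(recs, clone), basis = basis)
  s <- slope_at(fit, 12, animals = c("rr0001", "clone"))
  expect_equal(s$slope[1], s$slope[2], tolerance = 1e-8)
  dev <- slope_at(fit, 12, mode = "deviation")$slope
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(length(dev)) + 1e-3)
})

test_that("phenotype derivation tags traits and skips out-of-range temperatures", {
  set.seed(606)
  basis <- legendre_basis(12, 30, 2, "normalized")  # cold end unobserved
  recs <- sim_rr_records(50, 6, c(2, 0.3, 0), diag(c(0.1, 0.05, 0.02)), 0.2,
                         basis)
  recs$tavg_lag7 <- recs$tavg
  fit_day <- fit_reaction_norm(recs, "tavg", basis = basis, season = "spring")
  fit_lag <- fit_reaction_norm(recs, "tavg_lag7", basis = basis, season = "spring")
  expect_warning(ph <- derive_phenotypes(list(fit_day, fit_lag)), "outside")
  expect_setequal(unique(ph$trait), c("Tavg25", "Tavg25_lag7"))
  expect_setequal(unique(ph$season), "spring")
  smry <- phenotype_summary(ph)
  expect_equal(nrow(smry), 2L)
  expect_equal(smry$n, rep(50L, 2))
})

test_that("tidy, glance and autoplot work on reaction-norm fits", {
  set.seed(607)
  basis <- legendre_basis(0, 30, 2, "normalized")
  recs <- sim_rr_records(40, 5, c(2, 0.3, -0.1), diag(c(0.1, 0.05, 0.02)), 0.2,
                         basis)
  fit <- fit_reaction_norm(recs, basis = basis)
  expect_equal(tidy(fit)$term, c("phi0", "phi1", "phi2"))
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$n_animals, 40L)
  p <- autoplot(fit, n_animals = 10)
  expect_s3_class(p, "ggplot")
})
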
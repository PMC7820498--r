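# Independent oracles used across the suite.

# Numerator relationship matrix by the tabular method (dense, recursive),
# independent of the package's Henderson-rules assembly.
tabular_a <- function(ped) {
  pn <- thermoresil::ped_normalise(ped)
  n <- nrow(pn)
  A <- matrix(0, n, n, dimnames = list(pn$animal, pn$animal))
  for (i in seq_len(n)) {
    s <- pn$sire_i[i]; d <- pn$dam_i[i]
    for (j in seq_len(i - 1L)) {
      A[i, j] <- A[j, i] <-
        0.5 * ((if (s > 0) A[j, s] else 0) + (if (d > 0) A[j, d] else 0))
    }
    A[i, i] <- 1 + (if (s > 0 && d > 0) 0.5 * A[s, d] else 0)
  }
  A
}

# random valid pedigree of n animals with roughly prob_parents of the later
# animals having two (earlier) parents
random_pedigree <- function(n, prob_parents = 0.8) {
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (stats::runif(1) < prob_parents) {
      pr <- sample.int(i - 1L, 2L)
      sire[i] <- paste0("x", pr[1]); dam[i] <- paste0("x", pr[2])
    }
  }
  data.frame(animal = paste0("x", seq_len(n)), sire = sire, dam = dam)
}

# direct random-regression test-day simulator (no pedigree, no fixed effects):
# y = Phi(x) (beta + a_i) + e with a_i ~ N(0, G0) iid
sim_rr_records <- function(n_animals, n_records, beta, G0, sigma2e, basis) {
  x <- stats::runif(n_animals * n_records, basis$x_min, basis$x_max)
  id <- rep(seq_len(n_animals), each = n_records)
  a <- matrix(stats::rnorm(n_animals * 3), n_animals, 3) %*% chol(G0 + diag(1e-12, 3))
  Phi <- thermoresil::eval_basis(basis, x)
  y <- as.numeric(Phi %*% beta) + rowSums(Phi * a[id, , drop = FALSE]) +
    stats::rnorm(length(x), 0, sqrt(sigma2e))
  tibble::tibble(animal_id = sprintf("rr%04d", id), milk_kg = y, tavg = x)
}

# balanced half-sib dataset: ns unrelated sires, np progeny records each
sim_half_sib <- function(ns, np, sigma2s, sigma2e) {
  sire_eff <- stats::rnorm(ns, 0, sqrt(sigma2s))
  data.frame(
    animal_id = rep(sprintf("S%03d", seq_len(ns)), each = np),
    y = sire_eff[rep(seq_len(ns), each = np)] +
      stats::rnorm(ns * np, 0, sqrt(sigma2e))
  )
}

unrelated_pedigree <- function(ids) {
  data.frame(animal = ids, sire = NA_character_, dam = NA_character_)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# drop the edit-report attribute so idempotence compares the record set itself
strip_report <- function(d) {
  attr(d, "edit_report") <- NULL
  as.data.frame(d)
}
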
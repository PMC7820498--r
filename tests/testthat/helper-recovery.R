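# Parameter-recovery protocol: simulate traits with known genetic parameters
# on a 3-generation pedigree and refit them with pedigree REML. Used by the
# recovery test blocks.

recover_h2 <- function(h2, seeds, n_per_generation = 3000L, n_founders = 1000L,
                       n_sires = 60L) {
  vapply(seeds, function(r) {
    ped <- sim_pedigree(n_founders, 3L, n_per_generation, n_sires,
                        seed = 70000L + r)
    d <- sim_direct_traits(ped, h2 = h2, seed = 90000L + r)
    fit <- reml_univariate(d, "y1", ped[, c("animal", "sire", "dam")],
                           fixed = ~group)
    fit$h2
  }, 0)
}

recover_rA <- function(h2, rA, rP, seeds, n_per_generation = 3000L,
                       n_founders = 1000L, n_sires = 60L) {
  vapply(seeds, function(r) {
    ped <- sim_pedigree(n_founders, 3L, n_per_generation, n_sires,
                        seed = 70000L + r)
    d <- sim_direct_traits(ped, h2 = h2, rA = rA, rP = rP, seed = 90000L + r)
    fit <- reml_bivariate(d, c("y1", "y2"), ped[, c("animal", "sire", "dam")],
                          fixed = ~group)
    fit$rA
  }, 0)
}
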
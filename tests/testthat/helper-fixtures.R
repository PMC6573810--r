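# Shared small fixtures (built in code) and memoised heavy runs used by the
# acceptance checks. The cache lives for one test_dir() invocation.

scenario_a <- architecture_scenario("A")
grid_a <- build_scenario_grid(scenario_a)

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# full-scale cohort run for one disease preset (shared across tests)
acceptance_cohort <- function(preset, n = 1e7, reps = 10, seed = 1) {
  cached(paste("cohort", preset, n, reps, seed), {
    run_cohort(sim_config(preset = preset, n = n, seed = seed,
                          replicates = reps))
  })
}

# relative decline of the largest-effect variant's IVA case/control MAF
# difference: late-age window (90-99) over the first ten reporting years
iva_decline_ratios <- function(n = 2e6, reps = 4, seed = 1) {
  cached(paste("decline", n, reps, seed), {
    sapply(lod_preset_names(), function(p) {
      cfg <- sim_config(preset = p, n = n, seed = seed, replicates = reps,
                        mode = "iva")
      rec <- run_iva(cfg)$records
      i0 <- which(rec$cum_incidence >= 0.0025)[1]
      d <- rec$dmaf_s1_m5_o5
      mean(d[rec$age %in% 90:99], na.rm = TRUE) /
        mean(d[i0:(i0 + 9)], na.rm = TRUE)
    })
  })
}

# Hardy-Weinberg exhaustive enumeration of the PRS variance for a tiny
# variant set: the brute-force counterpart of the analytic variance
enumerate_prs_variance <- function(variants) {
  k <- nrow(variants)
  genos <- as.matrix(expand.grid(rep(list(0:2), k)))
  probs <- apply(genos, 1, function(g)
    prod(stats::dbinom(g, 2, variants$eaf)))
  prs <- as.numeric(genos %*% log(variants$odds_ratio))
  mu <- sum(probs * prs)
  sum(probs * (prs - mu)^2)
}
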
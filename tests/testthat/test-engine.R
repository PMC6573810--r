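test_that("odds-to-hazard conversion matches the baseline-rate adjustment", {
  expect_equal(or_to_hr(1, 0.3), 1)
  expect_equal(or_to_hr(1.15, 0), 1.15)
  expect_equal(or_to_hr(1.15, 0.2), 1.15 / 1.03, tolerance = 1e-9)
  expect_equal(or_to_hr(1.15, 1e-9), 1.15, tolerance = 1e-6)
  expect_equal(or_to_hr(2.5, 0.4, mode = "identity"), 2.5)
  expect_error(or_to_hr(1.2, 1), "baseline_rate")
  expect_error(or_to_hr(-1, 0.1), "or_value")
})

test_that("diagnose_year samples unaffected individuals proportionally to hazard", {
  arch <- genetic_architecture(0.095)
  pop <- sample_population(5e4, arch, seed = 21)
  # uniform weights: case allele frequencies match the population's
  flat <- pop
  flat$prs[] <- 0
  set.seed(31)
  flat <- diagnose_year(flat, 5000, age = 50)
  idx <- attr(flat, "indices")
  expect_length(unique(idx), 5000)
  expect_identical(unique(flat$diagnosed_age[idx]), 50L)
  for (v in c("s1_m5_o5", "s1_m1_o1")) {
    p <- mean(pop$tracked[, v]) / 2
    pc <- mean(pop$tracked[idx, v]) / 2
    expect_lt(abs(pc - p), 3 * sqrt(p * (1 - p) / (2 * 5000)))
  }
  # hazard-weighted first draws reproduce the closed-form enrichment
  set.seed(32)
  freqs <- replicate(30, {
    d <- diagnose_year(pop, 200, age = 50)
    colMeans(pop$tracked[attr(d, "indices"), c("s1_m5_o5", "s1_m3_o5")]) / 2
  })
  expect_lt(abs(mean(freqs[1, ]) - zero_incidence_case_maf(0.5, 1.15)), 0.015)
  expect_lt(abs(mean(freqs[2, ]) - zero_incidence_case_maf(0.286, 1.15)), 0.015)
  expect_error(diagnose_year(pop, pop$n + 1, 50), "exceeds")
})

test_that("yearly case counts follow the incidence rate with carried remainders", {
  cfg <- sim_config(preset = "lung", n = 1e4, mode = "iva", seed = 13,
                    replicates = 1)
  rec <- run_iva(cfg)$records
  carry <- 0
  It <- incidence_at(cfg$incidence, rec$age)
  for (i in seq_len(nrow(rec))) {
    x <- It[i] * rec$n_at_risk[i] + carry
    n_exp <- min(round(x), rec$n_at_risk[i])
    expect_identical(rec$n_new_cases[i], as.numeric(n_exp))
    carry <- x - n_exp
  }
  # no one is lost: cases plus survivors partition the population
  expect_equal(rec$n_at_risk - rec$n_new_cases,
               c(rec$n_at_risk[-1], tail(rec$n_at_risk, 1) -
                   tail(rec$n_new_cases, 1)))
})

test_that("individuals are conserved and status transitions are one-way", {
  arch <- genetic_architecture(0.41)
  pop <- sample_population(2e4, arch, seed = 17)
  inc <- make_lod_preset("stroke")$incidence
  mort <- mortality_model(case_multiplier = 2)   # exercises case redraws
  res <- lodsim:::.run_once(pop, inc, mort, 100L, "zhang_yu", seed = 18)
  dead_by <- vapply(0:99, function(t)
    sum(res$death_age >= 0 & res$death_age <= t), numeric(1))
  expect_equal(res$eoy_un_cnt + res$eoy_case_cnt + dead_by, rep(2e4, 100))
  both <- res$diag_age >= 0 & res$death_age >= 0
  expect_true(all(res$death_age[both] >= res$diag_age[both]))
  # diagnosis only from the unaffected pool: diagnosed never exceed incidence
  expect_true(all(res$n_new <= res$nu_before))
  expect_true(all(res$eoy_un_cnt >= 0 & res$eoy_case_cnt >= 0))
})

test_that("IVA contrasts vanish without heritability and decline with it", {
  # near-zero effect sizes: no case/control divergence beyond noise
  sc0 <- architecture_scenario("custom", maf_low = 0.2, maf_high = 0.5,
                               or_low = 1.0001, or_high = 1.0002,
                               digits = 6)
  arch0 <- genetic_architecture(0, sc0, n_sets = 1)
  cfg0 <- sim_config(architecture = arch0,
                     incidence = incidence_model("constant", i0 = 0.01, t0 = 20),
                     n = 1e5, mode = "iva", seed = 23, replicates = 3)
  r0 <- run_iva(cfg0)
  rows <- which(r0$records$n_new_cases * 3 >= 500)
  dev <- abs(r0$records$dmaf_s1_m5_o5[rows])
  expect_lt(stats::median(dev, na.rm = TRUE), 0.005)

  # positive heritability: new cases start high-risk, then the contrast decays
  cfg <- sim_config(preset = "breast", n = 2e5, mode = "iva", seed = 29,
                    replicates = 2)
  r <- run_iva(cfg)
  rec <- r$records
  i0 <- which(rec$cum_incidence >= 0.0025)[1]
  early <- mean(rec$case_prs_mean[i0:(i0 + 2)])
  # earliest cases' mean PRS is close to the PRS variance (undepleted limit)
  expect_lt(abs(early - cfg$architecture$variance), 0.3)
  expect_gt(early, 0)
  late <- mean(rec$case_prs_mean[rec$age %in% 90:99])
  expect_lt(late, early)
  # the unaffected pool's mean PRS is nonincreasing within noise
  expect_true(all(diff(rec$unaff_prs_mean[i0:100]) < 2e-2))
  expect_lt(tail(rec$unaff_prs_mean[!is.na(rec$unaff_prs_mean)], 1), 0)
})

test_that("cohort bookkeeping accumulates surviving cases exactly", {
  arch <- genetic_architecture(0.31)
  pop <- sample_population(2e4, arch, seed = 41)
  inc <- make_lod_preset("breast")$incidence
  res <- lodsim:::.run_once(pop, inc, mortality_model("none"), 100L,
                            "zhang_yu", seed = 42)
  # without mortality the case pool is the running total of new cases
  expect_equal(res$eoy_case_cnt, cumsum(res$n_new), tolerance = 1e-12)
  expect_equal(res$eoy_case_geno_sum[, 1], cumsum(res$new_geno_sum[, 1]),
               tolerance = 1e-9)
  expect_equal(res$eoy_case_prs_sum, cumsum(res$new_prs_sum), tolerance = 1e-9)
})

test_that("cohort records honour the reporting window and replicate determinism", {
  cfg <- sim_config(preset = "lung", n = 5e4, seed = 51, replicates = 2)
  rc <- run_cohort(cfg)
  expect_true(all(rc$records$case_frac >= 0.0025))
  expect_true(all(rc$records$control_frac >= 0.0025))
  expect_equal(youngest_cohort_age(rc), rc$records$mid_age[1])
  rc2 <- run_cohort(cfg)
  expect_identical(rc$records, rc2$records)
  # a 1-year span without mortality counts everyone ill by each age as a
  # case, so the case pool only accumulates
  cfg1 <- sim_config(preset = "lung", n = 5e4, seed = 51, replicates = 1,
                     span = 1, mortality = mortality_model("none"))
  r1 <- run_cohort(cfg1)
  expect_true(all(diff(r1$all_records$case_frac) >= 0))
  expect_equal(r1$all_records$mid_age, 0:99)
})
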
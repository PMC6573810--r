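test_that("incidence models evaluate their yearly hazards", {
  cm <- incidence_model("constant", i0 = 0.01, t0 = 20)
  expect_equal(incidence_at(cm, c(20, 50, 99)), rep(0.01, 3))
  expect_equal(incidence_at(cm, 10), 0)
  expect_error(incidence_at(cm, 101), "range")

  em <- incidence_model("exponential", t0 = 50, i0 = 1e-4, r = log(2) / 7)
  expect_equal(incidence_at(em, 57), 2e-4, tolerance = 1e-12)

  cp <- incidence_model("exponential_capped", t0 = 30, i0 = 1e-4, r = 0.12,
                        i_max = 0.02)
  expect_true(all(incidence_at(cp, 0:100) <= 0.02))
  # below the cap the form tracks the exponential
  expect_equal(incidence_at(cp, 31), 1e-4 * exp(0.12), tolerance = 1e-2)
})

test_that("cumulative incidence equals the yearly survival product", {
  cm <- incidence_model("constant", i0 = 0.01, t0 = 0)
  expect_equal(cumulative_incidence(cm, 10), 1 - 0.99^10, tolerance = 1e-12)
  expect_equal(cumulative_incidence(incidence_model("constant", i0 = 0, t0 = 0),
                                    80), 0)
  one <- incidence_model("constant", i0 = 0.02, t0 = 0, max_age = 1)
  expect_equal(cumulative_incidence(one, 1), 0.02)
  # refinement invariance: recursion year by year equals the closed form
  m <- make_lod_preset("stroke")$incidence
  nu <- 1
  for (t in 0:79) nu <- nu * (1 - incidence_at(m, t))
  expect_equal(cumulative_incidence(m, 80), 1 - nu, tolerance = 1e-12)
  expect_true(all(diff(cumulative_incidence(m, 0:100)) >= 0))
})

test_that("exponential fitting recovers rates from log-linear points", {
  ages <- 40:70
  pts <- data.frame(age = ages, rate = 2e-5 * exp(0.09 * (ages - 40)))
  fit <- fit_exponential(pts)
  expect_equal(fit$r, 0.09, tolerance = 1e-10)
  expect_equal(fit$i0, 2e-5, tolerance = 1e-8)
  two <- fit_exponential(data.frame(age = c(50, 57), rate = c(1e-4, 2e-4)))
  expect_equal(log(2) / two$r, 7, tolerance = 1e-9)
  flat <- fit_exponential(data.frame(age = c(40, 60), rate = c(1e-3, 1e-3)))
  expect_equal(flat$r, 0, tolerance = 1e-12)
  expect_error(fit_exponential(data.frame(age = 1:3, rate = c(1, 0, 1))),
               "positive")
})

test_that("validation models reach one cumulative incidence by three routes", {
  mods <- make_validation_models(80, 0.2)
  for (m in mods)
    expect_lt(abs(cumulative_incidence(m, 80) - 0.2), 1e-9)
  # inverse of the closed-form product for the constant member
  mc <- make_validation_models(10, 1 - 0.99^10)$constant
  expect_equal(mc$i0, 0.01, tolerance = 1e-9)
  # the exponential member grows monotonically
  expect_true(all(diff(incidence_at(mods$exponential, 0:80)) >= 0))
  expect_error(make_validation_models(5, 0.9999), "unreachable")
})

test_that("parametric mortality behaves like a life table stand-in", {
  m <- mortality_model()
  q <- mortality_at(m, 0:119)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[31:120]) >= 0))
  surv <- cumprod(1 - mortality_at(m, 0:104))
  expect_lt(surv[105], 0.01)          # under 1% alive at 105
  expect_gt(surv[81], 0.3)            # but most of midlife survives
  expect_equal(mortality_at(m, 50, case = TRUE), mortality_at(m, 50))
  dbl <- mortality_model(case_multiplier = 2)
  expect_equal(mortality_at(dbl, 50, case = TRUE),
               2 * mortality_at(dbl, 50))
  expect_equal(mortality_at(mortality_model("none"), 0:100), rep(0, 101))
})

test_that("disease presets satisfy their published calibration constraints", {
  mort <- mortality_model()
  for (nm in lod_preset_names()) {
    p <- make_lod_preset(nm)
    con <- p$constraints
    It <- incidence_at(p$incidence, 0:99)
    # yearly incidence cap (AD instead must pass 20% before 100)
    if (!is.na(con$max_yearly)) expect_lte(max(It), con$max_yearly)
    if (!is.na(con$peak_at_least)) expect_gte(max(It), con$peak_at_least)
    # lifetime risk, by the measure the preset is calibrated under
    lr_mort <- lifetime_risk(p$incidence, mort)
    lr_cum <- cumulative_incidence(p$incidence, 100)
    band <- con$lifetime_band
    switch(con$lifetime_measure,
      cumulative = {
        expect_gte(lr_cum, band[1]); expect_lte(lr_cum, band[2])
      },
      mortality = {
        expect_gte(lr_mort, band[1]); expect_lte(lr_mort, band[2])
      },
      bracket = {
        expect_lte(lr_mort, band[2]); expect_gte(lr_cum, band[1])
      })
    # exponential growth (doubling time 5-8.5 years) up to the stated age
    pos <- which(It > 0) - 1L
    upto <- pos[pos <= min(con$exp_until, 98)]
    dbl <- log(2) / diff(log(It[upto + 1L]))
    expect_true(all(dbl > 4.99 & dbl < 8.51),
                label = paste(nm, "doubling band"))
    expect_identical(25L * p$n_sets,
                     c(AD = 3575L, T2D = 2125L, CAD = 1175L, stroke = 625L,
                       breast = 400L, prostate = 1250L, colorectal = 600L,
                       lung = 100L)[[nm]])
  }
  # spot values quoted in the published tables
  lung <- make_lod_preset("lung")
  expect_lte(cumulative_incidence(lung$incidence, 100), 0.069)
  expect_lte(max(incidence_at(lung$incidence, 0:100)), 0.006)
  expect_equal(make_lod_preset("breast")$target_h2, 0.31)
  expect_equal(make_lod_preset("T2D")$constraints$exp_until, 55)
  expect_error(make_lod_preset("gout"), "unknown preset")
})
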
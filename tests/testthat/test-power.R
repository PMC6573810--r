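test_that("non-centrality parameter follows N * p1 * p2 * delta^2", {
  expect_equal(gwas_ncp(98000, 0.035), 30.0125, tolerance = 1e-10)
  expect_equal(gwas_ncp(1e5, 0), 0)
  expect_equal(gwas_ncp(2e5, 0.02), 2 * gwas_ncp(1e5, 0.02))
  expect_error(gwas_ncp(4, 0.1), "n_total")
  expect_error(gwas_ncp(100, 0.1, p1 = 0.6, p2 = 0.5), "summing to 1")
})

test_that("power is the test size at zero non-centrality and rises with lambda", {
  expect_equal(power_at(1e6, 0), 5e-8, tolerance = 1e-6)
  expect_equal(power_at(1e4, 0), 5e-8, tolerance = 1e-6)
  expect_equal(power_at(1e6, 39.61), 0.800, tolerance = 1e-3)
  expect_equal(power_at(1e6, 29.72), 0.50, tolerance = 1e-3)
  lam <- seq(0, 60, by = 5)
  expect_true(all(diff(power_at(1e6, lam)) > 0))
  # stricter thresholds lower power
  expect_lt(power_at(1e6, 30, significance = 0.99999995),
            power_at(1e6, 30, significance = 0.999))
})

test_that("noncentral F converges to the chi-square limit as 1/N", {
  chi_power <- function(lam, sig = 0.99999995)
    1 - stats::pchisq(stats::qchisq(sig, 1), 1, ncp = lam)
  # the denominator degrees of freedom shift the threshold by O(1/N)
  for (lam in c(5, 29.72, 39.61, 60)) {
    for (n in c(1e4, 1e5, 1e6))
      expect_lt(abs(power_at(n, lam) - chi_power(lam)), 25 / n)
    expect_lt(abs(power_at(1e6, lam) - chi_power(lam)), 1e-4)
  }
})

test_that("the cases solver hits the target power and the inverse-square law", {
  for (d in c(0.0349, 0.01)) {
    nc <- cases_for_power(d)
    p <- power_at(2 * nc, gwas_ncp(2 * nc, d))
    expect_lt(abs(p - 0.8), 1e-4)       # round trip within 0.01%
  }
  expect_equal(cases_for_power(0.0349), 65026, tolerance = 1e-3)
  expect_equal(cases_for_power(0.0349, target_power = 0.5), 48796,
               tolerance = 1e-3)
  # halving delta quadruples the cases needed
  expect_equal(cases_for_power(0.0175) / cases_for_power(0.035), 4,
               tolerance = 1e-3)
  expect_error(cases_for_power(0), "non-zero")
})

test_that("the cases-needed multiple is a pure delta ratio, invariant to the solver constants", {
  rec <- data.frame(mid_age = c(55, 65, 80),
                    dmaf_s1_m5_o5 = c(0.034, 0.031, 0.028))
  pm <- power_multiple(rec, "s1_m5_o5")
  expect_equal(pm$multiple, (0.034 / rec$dmaf_s1_m5_o5)^2, tolerance = 1e-4)
  # invariance to significance threshold and power target
  pm2 <- power_multiple(rec, "s1_m5_o5", target_power = 0.5,
                        significance = 0.999)
  expect_equal(pm$multiple, pm2$multiple, tolerance = 1e-4)
  # constant delta means all multiples are 1
  flat <- data.frame(mid_age = 1:3, dmaf_v = rep(0.02, 3))
  expect_equal(power_multiple(flat, "v")$multiple, rep(1, 3), tolerance = 1e-12)
  # derived example: 0.034 -> 0.028 needs about 1.47x the cases
  expect_equal(pm$multiple[3], (34 / 28)^2, tolerance = 1e-3)
  # zero delta is reported missing
  z <- power_multiple(data.frame(mid_age = 1:2, dmaf_v = c(0.02, 0)), "v")
  expect_true(is.na(z$multiple[2]))
})
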
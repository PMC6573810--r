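test_that("scenario grids discretize frequency and effect bounds", {
  expect_equal(sort(unique(grid_a$eaf)), c(0.073, 0.180, 0.286, 0.393, 0.500))
  expect_equal(sort(unique(grid_a$odds_ratio)),
               c(1.05, 1.075, 1.10, 1.125, 1.15))
  expect_equal(nrow(grid_a), 25L)
  # pairing orientation: ORs descend as MAFs ascend
  expect_equal(grid_a$eaf[1], 0.073)
  expect_equal(grid_a$odds_ratio[1], 1.15)
  expect_true(all(abs(grid_a$log_or - log(grid_a$odds_ratio)) < 1e-15))

  e <- build_scenario_grid(architecture_scenario("E"))
  expect_equal(range(e$eaf), c(0.0073, 0.0499))
  expect_equal(range(e$odds_ratio), c(1.63, 4.05))

  g2 <- build_scenario_grid(architecture_scenario(
    "custom", maf_low = 0.1, maf_high = 0.2, or_low = 1.1, or_high = 1.2,
    grid_points = 2))
  expect_equal(nrow(g2), 4L)
  expect_equal(nrow(unique(g2[, c("eaf", "odds_ratio")])), 4L)

  expect_error(architecture_scenario("custom", maf_low = 0.3, maf_high = 0.2,
                                     or_low = 1.1, or_high = 1.2), "MAF")
  # determinism: identical inputs give byte-identical grids
  expect_identical(grid_a, build_scenario_grid(architecture_scenario("A")))
})

test_that("liability variance matches the published single-set value and hand evaluations", {
  expect_lt(abs(architecture_variance(grid_a) - 0.09098), 1e-5)
  one <- data.frame(variant_id = "v", eaf = 0.5, odds_ratio = 1.15,
                    log_or = log(1.15))
  expect_equal(architecture_variance(one), 2 * 0.25 * log(1.15)^2,
               tolerance = 1e-12)
  null <- transform(one, odds_ratio = 1, log_or = 0)
  expect_equal(architecture_variance(null), 0)
  # additivity over concatenated sets
  two <- rbind(grid_a, build_scenario_grid(scenario_a, set = 2))
  expect_equal(architecture_variance(two), 2 * architecture_variance(grid_a),
               tolerance = 1e-9)
})

test_that("analytic variance equals Hardy-Weinberg exhaustive enumeration", {
  for (rows in list(1:2, c(1, 13, 25))) {
    v <- grid_a[rows, ]
    expect_equal(architecture_variance(v), enumerate_prs_variance(v),
                 tolerance = 1e-12)
  }
})

test_that("heritability maps variance through the logistic liability scale", {
  expect_equal(heritability_from_variance(0), 0)
  expect_equal(heritability_from_variance(pi^2 / 3), 0.5)
  expect_lt(abs(heritability_from_variance(25 * architecture_variance(grid_a)) -
                  0.40876), 1e-4)
  expect_error(heritability_from_variance(-1), "variance")
  # strictly increasing
  v <- seq(0, 5, by = 0.5)
  expect_true(all(diff(heritability_from_variance(v)) > 0))
  # round trip with the inverse
  expect_equal(variance_for_heritability(heritability_from_variance(1.7)), 1.7,
               tolerance = 1e-12)
})

test_that("nearest-set sizing reproduces the published variant counts", {
  expect_identical(sets_for_heritability(0.41), 25L)    # stroke: 625 variants
  expect_identical(sets_for_heritability(0.31), 16L)    # breast: 400
  expect_identical(sets_for_heritability(0.40), 24L)    # colorectal: 600
  expect_identical(sets_for_heritability(0.095), 4L)    # lung: 100
  expect_identical(sets_for_heritability(0), 0L)
  expect_error(sets_for_heritability(1), "target_h2")
  # sizing round-trips to within one set's worth of heritability
  for (h2 in c(0.095, 0.31, 0.55, 0.795)) {
    arch <- genetic_architecture(h2)
    v1 <- architecture_variance(grid_a)
    h_lo <- heritability_from_variance((arch$n_sets - 1) * v1)
    h_hi <- heritability_from_variance((arch$n_sets + 1) * v1)
    expect_gt(h2, h_lo)
    expect_lt(h2, h_hi)
    expect_equal(arch$variance, arch$n_sets * v1, tolerance = 1e-9)
  }
})

test_that("population mean offset is twice the frequency-weighted log odds", {
  one <- data.frame(variant_id = "v", eaf = 0.5, odds_ratio = 1.15,
                    log_or = log(1.15))
  expect_equal(mean_prs_offset(one), log(1.15), tolerance = 1e-12)
  expect_equal(mean_prs_offset(transform(one, odds_ratio = 1, log_or = 0)), 0)
  expect_equal(mean_prs_offset(rbind(grid_a, grid_a)),
               2 * mean_prs_offset(grid_a), tolerance = 1e-12)
})

test_that("explicit set-count override and tracked subgrid are honoured", {
  arch <- genetic_architecture(0.795, n_sets = 143L)   # published AD count
  expect_identical(nrow(arch$variants), 143L * 25L)
  expect_identical(length(arch$tracked_ids), 9L)
  # the default tracked set is the 3x3 corner/middle subgrid of set 1
  expect_setequal(arch$tracked_ids,
                  as.character(outer(c(1, 3, 5), c(1, 3, 5), function(m, o)
                    sprintf("s1_m%d_o%d", m, o))))
  expect_error(genetic_architecture(0.3, tracked = "nope"), "tracked")
})

test_that("architecture tables round-trip through the 3-column text layout", {
  arch <- genetic_architecture(0.095)
  path <- withr::local_tempfile(fileext = ".txt")
  write_architecture(arch, path)
  back <- read_architecture(path)
  expect_equal(back$eaf, arch$variants$eaf)
  expect_equal(back$odds_ratio, arch$variants$odds_ratio)
  expect_equal(back$variant_id, arch$variants$variant_id)
  expect_equal(architecture_variance(back), arch$variance, tolerance = 1e-12)
  # the shipped example listing is the scenario-A single set
  shipped <- read_architecture(system.file("extdata", "scenario_A_set1.txt",
                                           package = "lodsim"))
  expect_equal(shipped$eaf, grid_a$eaf)
  expect_equal(shipped$odds_ratio, grid_a$odds_ratio)
})
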
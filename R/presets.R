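# Calibrated constants for the eight late-onset disease presets.
#
# Each incidence curve is a soft-plateau exponential (see incidence_model),
# except Alzheimer's disease, whose incidence keeps rising exponentially to a
# very advanced age. All capped curves share one anchor: the curve reaches
# half its plateau at the age where the exponential regime ends, with the
# local doubling time exactly 8.5 years there, which fixes the growth rate at
# r = 0.1176 per year (base doubling time 5.9 years, inside the 5-8.5-year
# band throughout the exponential regime). The remaining free parameter, the
# plateau i_max, is pinned per disease:
#  * T2D, CAD, stroke: i_max equals the published maximum yearly incidence
#    (the registry plateau). Their published lifetime risks are
#    mortality-limited and fall between the simulated mortality-adjusted
#    diagnosed fraction and the mortality-free cumulative incidence
#    ("bracket" check).
#  * breast, prostate, colorectal, lung: mortality interacts only weakly with
#    diagnosis accumulation at these incidence levels, and the published
#    cancer lifetime risks track the cumulative diagnosed fraction, so i_max
#    is solved so the no-mortality cumulative incidence at 100 equals the
#    published lifetime risk ("cumulative" check).
#  * AD: pure exponential with a 5-year doubling time, scaled so the
#    mortality-adjusted diagnosed fraction is 15% (mid published band;
#    "mortality" check). Its yearly incidence passes 20% before age 100, as
#    published; a no-mortality cumulative-incidence band would be
#    inconsistent with that.
# Constants were calibrated once, offline, against those constraints and are
# shipped as fixed values, not refit at runtime.
.lod_presets <- list(
  AD = list(
    target_h2 = 0.795, n_sets = 143L,    # 3,575 variants (published count)
    form = "exponential", t0 = 60, r = 0.13862944, i0 = 0.00104128, i_max = 1,
    exp_until = 103, max_yearly = NA_real_, peak_at_least = 0.20,
    lifetime_band = c(0.10, 0.20), lifetime_measure = "mortality"),
  T2D = list(
    target_h2 = 0.69, n_sets = 85L,      # 2,125 variants
    form = "exponential_capped", t0 = 25, r = 0.1176471,
    i0 = 5.081143e-04, i_max = 0.025,
    exp_until = 55, max_yearly = 0.025, peak_at_least = NA_real_,
    lifetime_band = c(0.50, 0.60), lifetime_measure = "bracket"),
  CAD = list(
    target_h2 = 0.55, n_sets = 47L,      # 1,175 variants
    form = "exponential_capped", t0 = 30, r = 0.1176471,
    i0 = 6.1853043e-05, i_max = 0.036,
    exp_until = 81, max_yearly = 0.036, peak_at_least = NA_real_,
    lifetime_band = c(0.32, 0.49), lifetime_measure = "bracket"),
  stroke = list(
    target_h2 = 0.41, n_sets = 25L,      # 625 variants (nearest-set rule)
    form = "exponential_capped", t0 = 30, r = 0.1176471,
    i0 = 9.5652909e-05, i_max = 0.044,
    exp_until = 79, max_yearly = 0.044, peak_at_least = NA_real_,
    lifetime_band = c(0.25, 0.30), lifetime_measure = "bracket"),
  breast = list(
    target_h2 = 0.31, n_sets = 16L,      # 400 variants
    form = "exponential_capped", t0 = 25, r = 0.1176471,
    i0 = 1.1992543e-05, i_max = 0.0043599231,
    exp_until = 72, max_yearly = 0.005, peak_at_least = NA_real_,
    lifetime_band = c(0.10, 0.14), lifetime_measure = "cumulative"),
  prostate = list(
    target_h2 = 0.57, n_sets = 50L,      # 1,250 variants
    form = "exponential_capped", t0 = 35, r = 0.1176471,
    i0 = 3.6786595e-04, i_max = 0.00244951,
    exp_until = 48, max_yearly = 0.008, peak_at_least = NA_real_,
    lifetime_band = c(0.10, 0.14), lifetime_measure = "cumulative"),
  colorectal = list(
    target_h2 = 0.40, n_sets = 24L,      # 600 variants
    form = "exponential_capped", t0 = 30, r = 0.1176471,
    i0 = 1.7591025e-05, i_max = 0.0010951073,
    exp_until = 62, max_yearly = 0.006, peak_at_least = NA_real_,
    lifetime_band = c(0.00, 0.045), lifetime_measure = "cumulative"),
  lung = list(
    target_h2 = 0.095, n_sets = 4L,      # 100 variants
    form = "exponential_capped", t0 = 35, r = 0.1176471,
    i0 = 2.2364319e-05, i_max = 0.0019815344,
    exp_until = 70, max_yearly = 0.006, peak_at_least = NA_real_,
    lifetime_band = c(0.00, 0.069), lifetime_measure = "cumulative"))

#' Names of the built-in late-onset disease presets
#' @return Character vector of the eight preset names.
#' @export
lod_preset_names <- function() names(.lod_presets)

#' Late-onset disease presets
#'
#' Returns the calibrated preset for one of the eight modelled late-onset
#' diseases: Alzheimer's disease (`AD`), type 2 diabetes (`T2D`), coronary
#' artery disease (`CAD`), cerebral `stroke`, and `breast`, `prostate`,
#' `colorectal` and `lung` cancer. A preset bundles the disease's target
#' liability-scale heritability (with the published scenario-A variant
#' count), a calibrated yearly incidence model, and the published
#' epidemiological constraints the curve satisfies: a lifetime-risk band
#' (with the measure it is checked by, see the comments in the preset
#' source), a maximum yearly incidence, and the age up to which incidence
#' grows exponentially with a doubling time of 5-8.5 years.
#'
#' @param name Preset name, see [lod_preset_names()].
#' @param max_age Simulation horizon passed to the incidence model.
#' @return An object of class `lod_preset`: list with `name`, `target_h2`,
#'   `n_sets`, `incidence` ([incidence_model()]) and `constraints`.
#' @examples
#' p <- make_lod_preset("lung")
#' cumulative_incidence(p$incidence, 100)   # lifetime risk 6%, below 6.9%
#' @export
make_lod_preset <- function(name, max_age = 100) {
  if (!name %in% names(.lod_presets))
    stop("unknown preset '", name, "'; see lod_preset_names()")
  p <- .lod_presets[[name]]
  inc <- if (p$form == "exponential")
    incidence_model("exponential", t0 = p$t0, i0 = p$i0, r = p$r,
                    i_max = p$i_max, max_age = max_age)
  else
    incidence_model("exponential_capped", t0 = p$t0, i0 = p$i0, r = p$r,
                    i_max = p$i_max, max_age = max_age)
  structure(list(name = name, target_h2 = p$target_h2, n_sets = p$n_sets,
                 incidence = inc,
                 constraints = list(lifetime_band = p$lifetime_band,
                                    lifetime_measure = p$lifetime_measure,
                                    max_yearly = p$max_yearly,
                                    peak_at_least = p$peak_at_least,
                                    exp_until = p$exp_until)),
            class = "lod_preset")
}

#' @export
print.lod_preset <- function(x, ...) {
  cat(sprintf(paste0("LOD preset '%s': h2 = %.3g (%d sets, %d variants)\n",
                     "  lifetime-risk band %.1f-%.1f%% (%s measure),",
                     " exponential to age %d\n"),
              x$name, x$target_h2, x$n_sets, 25L * x$n_sets,
              100 * x$constraints$lifetime_band[1],
              100 * x$constraints$lifetime_band[2],
              x$constraints$lifetime_measure, x$constraints$exp_until))
  print(x$incidence)
  invisible(x)
}

#' Lifetime risk accounting for competing mortality
#'
#' The probability that an individual is diagnosed before dying:
#' `sum_t I(t) * S(t)` where `S(t)` is the joint probability of being alive
#' and unaffected entering age-year `t` under the given mortality model.
#' Deterministic (expected-value) computation, no simulation.
#'
#' @param incidence An [incidence_model()].
#' @param mortality A [mortality_model()].
#' @param max_age Horizon (default the incidence model's).
#' @return Probability of ever being diagnosed.
#' @export
lifetime_risk <- function(incidence, mortality = mortality_model(), max_age = NULL) {
  if (is.null(max_age)) max_age <- incidence$max_age
  ages <- 0:(max_age - 1)
  It <- incidence_at(incidence, ages)
  qt <- mortality_at(mortality, ages)
  S <- cumprod(c(1, (1 - It) * (1 - qt)))[seq_along(ages)]
  sum(It * S)
}
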
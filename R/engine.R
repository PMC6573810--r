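#' Odds-ratio to hazard-multiplier conversion
#'
#' For a disease with yearly baseline incidence `P0`, the relative risk
#' implied by an odds ratio is `RR = OR / (1 - P0 + P0 * OR)`; the yearly
#' diagnosis sampling weight uses this adjusted multiplier. When incidence is
#' low (`P0 -> 0`) odds ratios and hazard ratios coincide, which is the
#' `identity` mode.
#'
#' @param or_value Odds ratio(s), > 0.
#' @param baseline_rate Current-year baseline incidence `P0` in `[0, 1)`.
#' @param mode `"zhang_yu"` (the adjustment above) or `"identity"`.
#' @return Hazard multiplier(s).
#' @examples
#' or_to_hr(1.15, 0.2)    # 1.15 / 1.03
#' or_to_hr(1.15, 0)      # unchanged
#' @export
or_to_hr <- function(or_value, baseline_rate = 0,
                     mode = c("zhang_yu", "identity")) {
  mode <- match.arg(mode)
  if (any(or_value <= 0)) stop("or_value must be > 0")
  if (any(baseline_rate < 0 | baseline_rate >= 1))
    stop("baseline_rate must lie in [0, 1)")
  if (mode == "identity") return(or_value)
  or_value / (1 - baseline_rate + baseline_rate * or_value)
}

#' Simulation configuration
#'
#' Bundles everything a run needs: a genetic architecture (or a disease
#' preset that implies one), incidence and mortality models, the population
#' size, analysis mode, cohort span, seed and replicate count.
#'
#' @param preset A preset name (see [lod_preset_names()]) or an
#'   [make_lod_preset()] object; supplies architecture sizing and incidence.
#' @param architecture A [genetic_architecture()] (overrides the preset's).
#' @param incidence An [incidence_model()] (overrides the preset's).
#' @param mortality A [mortality_model()]; default parametric with equal
#'   case/control mortality. Ignored in IVA mode.
#' @param n Population size at birth (>= 10^4).
#' @param mode `"cohort"` (10-year-span case/control accumulation with
#'   mortality) or `"iva"` (1-year age slices, newly diagnosed vs currently
#'   unaffected, no mortality).
#' @param span Cohort age span in years (default 10; 1 gives the cumulative
#'   individual-values design).
#' @param max_age Simulation horizon in years (default 100).
#' @param seed Integer seed (required).
#' @param replicates Number of independent replicate runs averaged together.
#' @param or_to_hr_mode `"zhang_yu"` (default) or `"identity"` conversion of
#'   polygenic odds to yearly sampling hazards.
#' @param tracked Optional tracked-variant labels passed to the architecture.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(preset = "lung", n = 1e5, seed = 1, replicates = 2)
#' @export
sim_config <- function(preset = NULL, architecture = NULL, incidence = NULL,
                       mortality = mortality_model(), n = 1e6,
                       mode = c("cohort", "iva"), span = 10, max_age = 100,
                       seed, replicates = 1, or_to_hr_mode = c("zhang_yu", "identity"),
                       tracked = NULL) {
  mode <- match.arg(mode)
  or_to_hr_mode <- match.arg(or_to_hr_mode)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  preset_name <- NULL
  if (!is.null(preset)) {
    if (is.character(preset)) preset <- make_lod_preset(preset, max_age = max_age)
    stopifnot(inherits(preset, "lod_preset"))
    preset_name <- preset$name
    if (is.null(architecture))
      architecture <- genetic_architecture(preset$target_h2,
                                           n_sets = preset$n_sets,
                                           tracked = tracked)
    if (is.null(incidence)) incidence <- preset$incidence
  }
  if (is.null(architecture) || is.null(incidence))
    stop("supply a preset, or both an architecture and an incidence model")
  stopifnot(inherits(architecture, "genetic_architecture"),
            inherits(incidence, "incidence_model"),
            inherits(mortality, "mortality_model"))
  n <- as.numeric(n)
  if (n < 1e4) stop("n_population must be >= 10^4")
  span <- as.integer(span)
  if (span < 1L) stop("cohort span must be >= 1")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  if (max_age <= incidence$t0) stop("max_age must exceed the onset age")
  structure(list(preset = preset_name, architecture = architecture,
                 incidence = incidence, mortality = mortality, n = n,
                 mode = mode, span = span, max_age = as.integer(max_age),
                 seed = as.integer(seed), replicates = replicates,
                 or_to_hr_mode = or_to_hr_mode),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation config: %s mode%s, n = %.3g, span %d,",
                     " max age %d, %d replicate(s), seed %d, OR->HR %s\n"),
              x$mode,
              if (is.null(x$preset)) "" else paste0(" (preset ", x$preset, ")"),
              x$n, x$span, x$max_age, x$replicates, x$seed, x$or_to_hr_mode))
  invisible(x)
}

# replicate seeds are salted by the run configuration so runs sharing a
# user seed (e.g. several presets in one study) draw independent streams
.config_salt <- function(config) {
  key <- sprintf("%s#%d#%.10g#%.10g#%s", config$mode,
                 config$architecture$n_sets, config$architecture$variance,
                 incidence_at(config$incidence, config$max_age - 1L),
                 config$or_to_hr_mode)
  sum(utf8ToInt(key) * seq_len(nchar(key))) %% 2^20
}

.rep_seed <- function(seed, k, salt = 0)
  (as.double(seed) * 2654435761 + salt * 69069 + k * 40503) %% 2^31

#' Diagnose one year's cases by hazard-weighted sampling
#'
#' Samples `n_new_cases` distinct unaffected individuals without
#' replacement, with inclusion weight proportional to each individual's
#' hazard multiplier `exp(PRS)` (after OR-to-HR adjustment at the supplied
#' baseline rate), and marks them diagnosed at `age`. This is the reference
#' R implementation of a single year of the sampling algorithm; the full
#' simulation loop runs in compiled code.
#'
#' @param population A [sample_population()] result.
#' @param n_new_cases Number of individuals to diagnose.
#' @param age Age recorded for the new diagnoses.
#' @param baseline_rate Current-year baseline incidence for the OR-to-HR
#'   adjustment.
#' @param mode OR-to-HR conversion mode, see [or_to_hr()].
#' @return The population with updated `diagnosed_age`, and the drawn
#'   indices in attribute `"indices"`.
#' @export
diagnose_year <- function(population, n_new_cases, age, baseline_rate = 0,
                          mode = c("zhang_yu", "identity")) {
  stopifnot(inherits(population, "lod_population"))
  mode <- match.arg(mode)
  pool <- which(is.na(population$diagnosed_age) & is.na(population$death_age))
  if (n_new_cases > length(pool))
    stop("n_new_cases exceeds the unaffected pool")
  w <- or_to_hr(exp(population$prs[pool]), baseline_rate, mode)
  if (sum(w) <= 0) stop("zero total sampling weight")
  idx <- pool[sample.int(length(pool), n_new_cases, replace = FALSE, prob = w)]
  population$diagnosed_age[idx] <- as.integer(age)
  attr(population, "indices") <- idx
  population
}

# one replicate: returns the raw per-age arrays from the compiled engine
.run_once <- function(population, incidence, mortality, max_age,
                      or_to_hr_mode, seed) {
  ages <- 0:(max_age - 1L)
  inc <- incidence_at(incidence, ages)
  q <- mortality_at(mortality, ages)
  cpp_run_engine(population$prs, population$tracked, inc, q,
                 case_mult = mortality$case_multiplier,
                 zhang_yu = identical(or_to_hr_mode, "zhang_yu"),
                 seed = as.double(seed))
}

.safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)

.moments <- function(s, s2, cnt) {
  m <- .safe_div(s, cnt)
  v <- ifelse(cnt > 1, (s2 - cnt * m^2) / (cnt - 1), NA_real_)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

# per-replicate IVA data.frame from raw engine output
.iva_frame <- function(res, vids, incidence, max_age) {
  ages <- 0:(max_age - 1L)
  cs <- .moments(res$new_prs_sum, res$new_prs2_sum, res$n_new)
  us <- .moments(res$un_prs_sum, res$un_prs2_sum, res$un_cnt)
  out <- data.frame(age = ages, n_at_risk = res$nu_before,
                    n_new_cases = res$n_new,
                    cum_incidence = cumulative_incidence(incidence, ages + 1L),
                    case_prs_mean = cs$mean, case_prs_sd = cs$sd,
                    unaff_prs_mean = us$mean, unaff_prs_sd = us$sd)
  for (k in seq_along(vids)) {
    out[[paste0("maf_cases_", vids[k])]] <-
      .safe_div(res$new_geno_sum[, k], 2 * res$n_new)
    out[[paste0("maf_unaff_", vids[k])]] <-
      .safe_div(res$un_geno_sum[, k], 2 * res$un_cnt)
  }
  for (k in seq_along(vids))
    out[[paste0("dmaf_", vids[k])]] <-
      out[[paste0("maf_cases_", vids[k])]] - out[[paste0("maf_unaff_", vids[k])]]
  out
}

# per-replicate cohort data.frame: pool `span` consecutive end-of-year
# age slices; equivalent to the staggered entry of `span` birth cohorts
# because incidence and mortality depend on age only
.cohort_frame <- function(res, vids, n, span, max_age) {
  A <- max_age
  a0s <- 0:(A - span)
  pool <- function(x) {
    cs <- cumsum(x)
    cs[a0s + span] - c(0, cs)[a0s + 1L]
  }
  ca <- pool(res$eoy_case_cnt); ua <- pool(res$eoy_un_cnt)
  cm <- .moments(pool(res$eoy_case_prs_sum), pool(res$eoy_case_prs2_sum), ca)
  um <- .moments(pool(res$eoy_un_prs_sum), pool(res$eoy_un_prs2_sum), ua)
  out <- data.frame(mid_age = a0s + span %/% 2L,
                    case_frac = ca / (span * n), control_frac = ua / (span * n),
                    case_prs_mean = cm$mean, case_prs_sd = cm$sd,
                    control_prs_mean = um$mean, control_prs_sd = um$sd)
  for (k in seq_along(vids)) {
    mc <- .safe_div(pool(res$eoy_case_geno_sum[, k]), 2 * ca)
    mu <- .safe_div(pool(res$eoy_un_geno_sum[, k]), 2 * ua)
    out[[paste0("maf_cases_", vids[k])]] <- mc
    out[[paste0("maf_controls_", vids[k])]] <- mu
  }
  for (k in seq_along(vids))
    out[[paste0("dmaf_", vids[k])]] <-
      out[[paste0("maf_cases_", vids[k])]] - out[[paste0("maf_controls_", vids[k])]]
  out
}

# average a list of identically shaped data.frames; returns mean and
# standard-error frames (SE = SD / sqrt(replicates), NA-aware)
.average_frames <- function(frames) {
  R <- length(frames)
  arr <- simplify2array(lapply(frames, as.matrix))
  if (R == 1L) {
    mean_df <- as.data.frame(arr[, , 1L])
    se <- mean_df
    se[] <- NA_real_
    return(list(mean = mean_df, se = se, replicates = 1L))
  }
  mu <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  nn <- apply(!is.na(arr), c(1, 2), sum)
  sdv <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
  se <- sdv / sqrt(pmax(nn, 1))
  mu[nn == 0] <- NA_real_
  list(mean = as.data.frame(mu), se = as.data.frame(se), replicates = R)
}

.replicate_run <- function(config, mortality) {
  vids <- config$architecture$tracked_ids
  frames <- vector("list", config$replicates)
  last <- NULL
  salt <- .config_salt(config)
  for (k in seq_len(config$replicates)) {
    rs <- .rep_seed(config$seed, k, salt)
    pop <- sample_population(config$n, config$architecture, seed = rs)
    res <- .run_once(pop, config$incidence, mortality, config$max_age,
                     config$or_to_hr_mode, seed = rs + 1)
    frames[[k]] <- if (config$mode == "iva")
      .iva_frame(res, vids, config$incidence, config$max_age)
    else .cohort_frame(res, vids, config$n, config$span, config$max_age)
    last <- res
  }
  list(frames = frames, last = last)
}

#' Individual-values analysis (IVA)
#'
#' Runs the yearly diagnosis loop in 1-year age slices without mortality and
#' contrasts, at every age, the newly diagnosed individuals against the
#' remaining unaffected population: PRS moments, tracked-variant allele
#' frequencies in both groups, and their difference. Statistics are averaged
#' over `config$replicates` independent runs; the returned object carries a
#' Monte-Carlo standard-error frame (`$se`, SD across replicates divided by
#' `sqrt(replicates)`).
#'
#' @param config A [sim_config()] with `mode = "iva"`.
#' @return An object of class `lod_iva`: list with `records` (averaged
#'   per-age data.frame), `se`, `config`, `status` (final diagnosis/death
#'   ages of the last replicate, for auditing).
#' @export
run_iva <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "iva") stop("config mode must be 'iva'")
  run <- .replicate_run(config, mortality_model("none"))
  avg <- .average_frames(run$frames)
  if (min(run$last$un_cnt) <= 0)
    warning("unaffected pool exhausted before max_age")
  structure(list(records = avg$mean, se = avg$se, config = config,
                 status = list(diag_age = run$last$diag_age,
                               death_age = run$last$death_age)),
            class = "lod_iva")
}

#' Age-matched cohort simulation
#'
#' Simulates the accumulation design of a clinical case/control cohort
#' study: cases are everyone diagnosed at or before their current age and
#' still alive, controls the currently unaffected survivors, pooled over a
#' `span`-year age window with statistics indexed by the mid-cohort age
#' (`youngest age in the window + span/2`). Yearly mortality applies to both
#' pools (cases optionally at a hazard multiple). Records are reported from
#' the youngest cohort (the first mid-cohort age whose cumulative case pool
#' reaches 0.25% of the initial population) until either pool falls below
#' that same threshold.
#'
#' Because incidence and mortality depend on age only, the staggered entry
#' of `span` birth cohorts is statistically equivalent to pooling `span`
#' consecutive age slices of a single birth cohort, which is how the records
#' are assembled.
#'
#' @param config A [sim_config()] with `mode = "cohort"`.
#' @return An object of class `lod_cohort`: list with `records` (averaged
#'   per-mid-cohort-age data.frame, restricted to the reporting window and
#'   including per-variant `dmaf_*` and cases-needed-for-80%-power
#'   `cases80_*` columns), `se`, `all_records` (unrestricted), `config`,
#'   `status`.
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "cohort") stop("config mode must be 'cohort'")
  run <- .replicate_run(config, config$mortality)
  avg <- .average_frames(run$frames)
  rec <- avg$mean
  vids <- config$architecture$tracked_ids
  keep <- rec$case_frac >= 0.0025 & rec$control_frac >= 0.0025
  first <- which(keep)[1L]
  window <- if (is.na(first)) logical(nrow(rec)) else {
    stop_at <- which(!keep & seq_len(nrow(rec)) > first)[1L]
    seq_len(nrow(rec)) >= first &
      (is.na(stop_at) | seq_len(nrow(rec)) < stop_at)
  }
  for (v in vids) {
    d <- rec[[paste0("dmaf_", v)]]
    rec[[paste0("cases80_", v)]] <-
      vapply(ifelse(window, d, NA_real_), function(dd) {
        if (is.na(dd) || dd == 0) NA_real_ else cases_for_power(dd)
      }, numeric(1))
  }
  structure(list(records = rec[window, , drop = FALSE],
                 se = avg$se[window, , drop = FALSE],
                 all_records = rec, all_se = avg$se, config = config,
                 status = list(diag_age = run$last$diag_age,
                               death_age = run$last$death_age)),
            class = "lod_cohort")
}

#' @export
print.lod_iva <- function(x, ...) {
  cat(sprintf("IVA result: %d ages, %d replicate(s), %d tracked variants\n",
              nrow(x$records), x$config$replicates,
              length(x$config$architecture$tracked_ids)))
  invisible(x)
}

#' @export
print.lod_cohort <- function(x, ...) {
  ya <- if (nrow(x$records)) x$records$mid_age[1L] else NA
  cat(sprintf(paste0("Cohort result: mid-cohort ages %s-%s (youngest %s),",
                     " %d replicate(s)\n"),
              ya, if (nrow(x$records)) max(x$records$mid_age) else NA, ya,
              x$config$replicates))
  invisible(x)
}
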
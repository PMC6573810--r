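#' Youngest well-powered cohort age
#'
#' The youngest cohort is the first mid-cohort age at which the cohort's
#' cumulative case pool reaches 0.25% of the initial population -- the
#' smallest cumulative incidence allowing a well-powered case/control study.
#'
#' @param x A [run_cohort()] result, or an [incidence_model()].
#' @param ... Passed on to methods.
#' @return The youngest mid-cohort age, or `NA` (with a message) if the
#'   threshold is never reached.
#' @export
youngest_cohort_age <- function(x, ...) UseMethod("youngest_cohort_age")

#' @rdname youngest_cohort_age
#' @export
youngest_cohort_age.lod_cohort <- function(x, ...) {
  rec <- x$all_records
  i <- which(rec$case_frac >= 0.0025)[1L]
  if (is.na(i)) {
    message("cumulative incidence never reaches 0.25%: youngest cohort missing")
    return(NA_real_)
  }
  rec$mid_age[i]
}

#' @rdname youngest_cohort_age
#' @param span Cohort age span in years.
#' @param max_age Horizon searched.
#' @export
youngest_cohort_age.incidence_model <- function(x, span = 10, max_age = NULL, ...) {
  if (is.null(max_age)) max_age <- x$max_age
  cum <- cumulative_incidence(x, seq_len(max_age))  # end of each age-year
  a0s <- 0:(max_age - span)
  pooled <- vapply(a0s, function(a0) mean(cum[a0 + seq_len(span)]), numeric(1))
  i <- which(pooled >= 0.0025)[1L]
  if (is.na(i)) {
    message("cumulative incidence never reaches 0.25%: youngest cohort missing")
    return(NA_real_)
  }
  a0s[i] + span %/% 2
}

#' Cohort-summary table across disease presets
#'
#' Assembles the headline cohort statistics for each completed run, for one
#' tracked variant (by default the largest-effect one, MAF 0.5 / OR 1.15 in
#' scenario A, which needs the fewest cases): the case/control
#' allele-frequency difference at the youngest cohort and at mid-cohort ages
#' 80 and 100, the cases needed for 80% discovery power at those ages, and
#' the cases-needed multiple from the youngest cohort to age 80.
#' Frequencies are rounded to 3 decimals and multiples to 2; ages outside a
#' run's reporting window are flagged missing. Re-assembly from the same
#' runs is deterministic.
#'
#' @param runs A named list of [run_cohort()] results (names are used as row
#'   labels; unnamed lists fall back to preset names).
#' @param variant Tracked variant label, or `NULL` for the largest-effect
#'   tracked variant of each run.
#' @return A data.frame with one row per run.
#' @export
summary_table <- function(runs, variant = NULL) {
  if (inherits(runs, "lod_cohort")) runs <- list(runs)
  nms <- names(runs)
  if (is.null(nms))
    nms <- vapply(runs, function(r)
      if (!is.null(r$config$preset)) r$config$preset else "run", character(1))
  rows <- lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    pm <- power_multiple(r, variant = variant)
    at_age <- function(col, age) {
      j <- which(pm$mid_age == age)
      if (length(j) == 0L) NA_real_ else pm[[col]][j]
    }
    young <- pm$mid_age[1L]
    data.frame(
      run = nms[i],
      youngest_age = young,
      dmaf_youngest = round(pm$dmaf[1L], 3),
      dmaf_80 = round(at_age("dmaf", 80), 3),
      dmaf_100 = round(at_age("dmaf", 100), 3),
      cases_youngest = pm$cases_needed[1L],
      cases_80 = at_age("cases_needed", 80),
      cases_100 = at_age("cases_needed", 100),
      multiple_80 = round(at_age("multiple", 80), 2),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write simulation records and a run manifest
#'
#' Writes the averaged records of an IVA or cohort run as a comma-separated
#' file (header row, '.' decimal, UTF-8) whose name embeds the preset or
#' scenario, mode and seed, together with a plain-text manifest recording
#' the configuration, seed, replicate count and package version, so every
#' reported statistic is traceable to its (seed, config) pair.
#'
#' @param result A [run_iva()] or [run_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param stem Optional file stem overriding the generated one.
#' @return Invisibly, the paths written (records, se, manifest).
#' @export
write_simulation_csv <- function(result, dir = ".", stem = NULL) {
  stopifnot(inherits(result, c("lod_iva", "lod_cohort")))
  cfg <- result$config
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem))
    stem <- sprintf("%s_%s_%s_n%g_seed%d",
                    if (is.null(cfg$preset)) "custom" else cfg$preset,
                    cfg$architecture$scenario$name, cfg$mode, cfg$n, cfg$seed)
  paths <- file.path(dir, paste0(stem, c(".csv", "_se.csv", "_manifest.txt")))
  utils::write.csv(result$records, paths[1], row.names = FALSE)
  utils::write.csv(result$se, paths[2], row.names = FALSE)
  man <- c(
    sprintf("package: lodsim %s", as.character(utils::packageVersion("lodsim"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("preset: %s", if (is.null(cfg$preset)) "none" else cfg$preset),
    sprintf("scenario: %s", cfg$architecture$scenario$name),
    sprintf("n_sets: %d", cfg$architecture$n_sets),
    sprintf("target_h2: %g", cfg$architecture$target_h2),
    sprintf("mode: %s", cfg$mode),
    sprintf("n_population: %g", cfg$n),
    sprintf("span: %d", cfg$span),
    sprintf("max_age: %d", cfg$max_age),
    sprintf("seed: %d", cfg$seed),
    sprintf("replicates: %d", cfg$replicates),
    sprintf("replicate_seeds: %s",
            paste(.rep_seed(cfg$seed, seq_len(cfg$replicates), .config_salt(cfg)),
                  collapse = " ")),
    sprintf("or_to_hr: %s", cfg$or_to_hr_mode),
    sprintf("records: %s", basename(paths[1])),
    sprintf("se: %s", basename(paths[2])))
  writeLines(man, paths[3])
  invisible(paths)
}
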
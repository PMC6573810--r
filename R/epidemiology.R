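#' Yearly disease incidence models
#'
#' Incidence is modelled as a deterministic yearly hazard `I(t)`: the
#' probability that an individual unaffected at the start of age-year `t`
#' is diagnosed during that year. Four functional forms are supported:
#'
#' * `constant`: `I(t) = i0` for `t >= t0`;
#' * `linear`: `I(t) = slope * (t - t0 + 1)` for `t >= t0`;
#' * `exponential`: `I(t) = i0 * exp(r * (t - t0))`, doubling time `ln 2 / r`;
#' * `exponential_capped`: a soft plateau,
#'   `I(t) = i_max * (1 - exp(-x(t)))` with `x(t) = (i0/i_max) * exp(r*(t-t0))`,
#'   which equals the exponential while `x` is small and approaches `i_max`
#'   smoothly; the local doubling time is `ln(2) / (r * g(x))` with
#'   `g(x) = x e^-x / (1 - e^-x)`.
#'
#' All forms return 0 below the onset age `t0` and are clamped to `[0, 1]`.
#'
#' @param form One of `"constant"`, `"linear"`, `"exponential"`,
#'   `"exponential_capped"`.
#' @param t0 Onset age in years (hazard is zero below it).
#' @param i0 Base yearly rate: the constant rate, or the rate at `t0` for the
#'   exponential forms.
#' @param r Exponential growth rate per year.
#' @param i_max Plateau rate for the capped form (also used as a hard cap for
#'   the plain exponential when supplied).
#' @param slope Yearly increment for the linear form.
#' @param max_age Largest age the model is defined for (default 100).
#' @return An object of class `incidence_model`.
#' @examples
#' m <- incidence_model("exponential", t0 = 50, i0 = 1e-4, r = log(2)/7)
#' incidence_at(m, c(50, 57))   # doubles over one doubling time
#' @export
incidence_model <- function(form = c("constant", "linear", "exponential",
                                     "exponential_capped"),
                            t0 = 0, i0 = NULL, r = NULL, i_max = NULL,
                            slope = NULL, max_age = 100) {
  form <- match.arg(form)
  stopifnot(t0 >= 0, max_age > t0)
  pars <- switch(form,
    constant = {
      stopifnot(!is.null(i0), i0 >= 0, i0 <= 1)
      list(i0 = i0)
    },
    linear = {
      stopifnot(!is.null(slope), slope >= 0)
      list(slope = slope)
    },
    exponential = {
      stopifnot(!is.null(i0), i0 > 0, !is.null(r))
      list(i0 = i0, r = r, i_max = if (is.null(i_max)) 1 else i_max)
    },
    exponential_capped = {
      stopifnot(!is.null(i0), i0 > 0, !is.null(r), r > 0,
                !is.null(i_max), i_max > 0, i_max <= 1)
      list(i0 = i0, r = r, i_max = i_max)
    })
  structure(c(list(form = form, t0 = t0, max_age = max_age), pars),
            class = "incidence_model")
}

#' @export
print.incidence_model <- function(x, ...) {
  p <- x[setdiff(names(x), c("form", "t0", "max_age"))]
  cat(sprintf("Incidence model: %s, onset age %g, max age %g\n  %s\n",
              x$form, x$t0, x$max_age,
              paste(sprintf("%s = %.6g", names(p), unlist(p)), collapse = ", ")))
  invisible(x)
}

#' Yearly hazard of an incidence model
#'
#' @param model An [incidence_model()].
#' @param age Vector of ages in `[0, max_age]`.
#' @return Yearly diagnosis probability at each age (deterministic).
#' @export
incidence_at <- function(model, age) {
  stopifnot(inherits(model, "incidence_model"))
  if (any(age < 0 | age > model$max_age))
    stop("age out of range [0, max_age]")
  rate <- switch(model$form,
    constant = rep_len(model$i0, length(age)),
    linear = model$slope * (age - model$t0 + 1),
    exponential = pmin(model$i_max, model$i0 * exp(model$r * (age - model$t0))),
    exponential_capped =
      model$i_max * (1 - exp(-(model$i0 / model$i_max) *
                               exp(model$r * (age - model$t0)))))
  ifelse(age < model$t0, 0, pmin(1, pmax(0, rate)))
}

#' Cumulative incidence in the absence of mortality
#'
#' The fraction of a birth cohort diagnosed by a given age when nobody dies:
#' the unaffected pool satisfies `N_u(t+1) = N_u(t) * (1 - I(t))`, so the
#' cumulative incidence at age `a` is `1 - prod_(t < a) (1 - I(t))` over
#' whole age-years. Nondecreasing in age.
#'
#' @param model An [incidence_model()].
#' @param age Vector of ages (each `<= max_age`).
#' @return Fraction of the cohort diagnosed before reaching each age.
#' @export
cumulative_incidence <- function(model, age) {
  stopifnot(inherits(model, "incidence_model"))
  if (any(age > model$max_age)) stop("age out of range")
  amax <- max(0L, as.integer(ceiling(max(age))))
  surv <- cumprod(1 - incidence_at(model, seq_len(amax) - 1L))
  vapply(age, function(a) {
    a <- as.integer(floor(a))
    if (a <= 0L) 0 else 1 - surv[a]
  }, numeric(1))
}

#' Least-squares exponential fit to incidence points
#'
#' Ordinary least squares of `log(rate)` on age. Returns the growth rate
#' (slope) and the fitted rate at the earliest supplied age, as an
#' `exponential` [incidence_model()] with fields `i0`, `r`, `t0`.
#'
#' @param points A data.frame or matrix with columns age and rate (two or
#'   more points, all rates positive), or a 2-column file read with
#'   [read_incidence_points()].
#' @return An `incidence_model` of form `exponential`; its `i0` is the
#'   fitted rate at `t0 = min(age)` and `r` the fitted yearly log-slope.
#' @examples
#' fit <- fit_exponential(data.frame(age = c(50, 57), rate = c(1e-4, 2e-4)))
#' log(2) / fit$r   # doubling time: 7 years
#' @export
fit_exponential <- function(points) {
  points <- as.data.frame(points)
  if (ncol(points) < 2L || nrow(points) < 2L)
    stop("need >= 2 (age, rate) points")
  age <- as.numeric(points[[1L]]); rate <- as.numeric(points[[2L]])
  if (any(rate <= 0)) stop("rates must be positive for a log-scale fit")
  co <- stats::coef(stats::lm(log(rate) ~ age))
  t0 <- min(age)
  r <- unname(co[2L])
  i0 <- exp(unname(co[1L]) + r * t0)
  incidence_model("exponential", t0 = t0, i0 = i0, r = r,
                  max_age = max(100, max(age)))
}

#' @rdname fit_exponential
#' @param path Path to a two-column delimited text file (age, rate).
#' @export
read_incidence_points <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  stats::setNames(tab[, 1:2], c("age", "rate"))
}

#' Matched-cumulative-incidence validation models
#'
#' Returns constant, linear and exponential incidence models that all reach
#' the same cumulative incidence at the horizon age, solved numerically to
#' 1e-10. Used to demonstrate that case/control allele distributions depend
#' on cumulative incidence, not on the shape of the incidence curve.
#'
#' @param horizon Age at which the cumulative incidences match.
#' @param target_cumulative Common cumulative incidence in (0, 1).
#' @param t0 Common onset age (default 0).
#' @param doubling_time Doubling time of the exponential member (years).
#' @param max_age Model horizon (default `max(100, horizon)`).
#' @param max_rate Largest admissible yearly hazard (default 0.95): a shape
#'   that would need a rate beyond this before the horizon does not reach
#'   the target as that shape and is rejected.
#' @return Named list of three `incidence_model`s.
#' @export
make_validation_models <- function(horizon, target_cumulative, t0 = 0,
                                   doubling_time = 7, max_age = NULL,
                                   max_rate = 0.95) {
  stopifnot(target_cumulative > 0, target_cumulative < 1, horizon > t0)
  if (is.null(max_age)) max_age <- max(100, horizon)
  nyr <- floor(horizon) - t0
  # upper brackets keep the yearly rate at or below max_rate through the
  # horizon; a target beyond the bracket would need a larger rate -> rejected
  solve_par <- function(build, upper) {
    f <- function(par) cumulative_incidence(build(par), horizon) - target_cumulative
    if (f(upper) < 0) stop("unreachable target cumulative incidence (needs I > 1)")
    stats::uniroot(f, c(1e-12, upper), tol = 1e-14)$root
  }
  if (1 - (1 - target_cumulative)^(1 / nyr) > max_rate)
    stop("unreachable target cumulative incidence (needs I > 1)")
  const <- incidence_model("constant", t0 = t0, max_age = max_age,
                           i0 = 1 - (1 - target_cumulative)^(1 / nyr))
  k <- solve_par(function(s) incidence_model("linear", t0 = t0, slope = s,
                                             max_age = max_age), max_rate / nyr)
  lin <- incidence_model("linear", t0 = t0, slope = k, max_age = max_age)
  r <- log(2) / doubling_time
  i0 <- solve_par(function(i) incidence_model("exponential", t0 = t0, i0 = i,
                                              r = r, max_age = max_age),
                  max_rate * exp(-r * (nyr - 1)))
  expo <- incidence_model("exponential", t0 = t0, i0 = i0, r = r, max_age = max_age)
  list(constant = const, linear = lin, exponential = expo)
}

#' Yearly mortality models
#'
#' A parametric Gompertz-Makeham stand-in for actuarial life tables: the
#' yearly death probability is `q(t) = min(1, a + b * exp(t / c))`, with an
#' age-independent accident term `a` and an exponentially rising senescent
#' term. The defaults (`a = 2e-4`, `b = 2.7e-5`, `c = 10`) give a
#' survivorship curve with under 1% of the cohort alive at 105. Cases can be
#' subjected to a hazard multiple of the control mortality
#' (`case_multiplier`): 1 for equal case/control mortality, 2 for the
#' double-case-mortality stress scenario, with `form = "none"` switching
#' mortality off entirely.
#'
#' @param form `"parametric"` or `"none"`.
#' @param a,b,c Gompertz-Makeham parameters (`c` in years).
#' @param case_multiplier Multiple applied to the yearly death probability of
#'   diagnosed individuals (capped at 1).
#' @return An object of class `mortality_model`.
#' @export
mortality_model <- function(form = c("parametric", "none"),
                            a = 2e-4, b = 2.7e-5, c = 10,
                            case_multiplier = 1) {
  form <- match.arg(form)
  stopifnot(a >= 0, b >= 0, c > 0, case_multiplier >= 0)
  structure(list(form = form, a = a, b = b, c = c,
                 case_multiplier = case_multiplier),
            class = "mortality_model")
}

#' @export
print.mortality_model <- function(x, ...) {
  if (x$form == "none") cat("Mortality model: none\n")
  else cat(sprintf(
    "Mortality model: Gompertz-Makeham a=%.3g b=%.3g c=%.3g, case multiplier %.1f\n",
    x$a, x$b, x$c, x$case_multiplier))
  invisible(x)
}

#' Yearly death probability
#'
#' @param model A [mortality_model()].
#' @param age Vector of ages.
#' @param case Logical; apply the case multiplier.
#' @return Yearly death probability in `[0, 1]` at each age.
#' @export
mortality_at <- function(model, age, case = FALSE) {
  stopifnot(inherits(model, "mortality_model"))
  if (model$form == "none") return(rep_len(0, length(age)))
  q <- model$a + model$b * exp(age / model$c)
  if (case) q <- q * model$case_multiplier
  pmin(1, pmax(0, q))
}
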
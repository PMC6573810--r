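#' Non-centrality parameter of a case/control allele test
#'
#' For a variant whose allele frequency differs by `delta` between cases and
#' controls, the association test's non-centrality parameter is
#' `lambda = N * p1 * p2 * delta^2`, with `N` the total sample size and
#' `p1`, `p2` the case and control fractions (1:1 by default).
#'
#' @param n_total Total cases + controls (> 4).
#' @param delta Case-minus-control allele-frequency difference.
#' @param p1,p2 Case and control fractions; must sum to 1.
#' @return The non-centrality parameter.
#' @examples
#' gwas_ncp(98000, 0.035)
#' @export
gwas_ncp <- function(n_total, delta, p1 = 0.5, p2 = 0.5) {
  if (any(n_total <= 4)) stop("n_total must exceed 4")
  if (abs(p1 + p2 - 1) > 1e-12 || p1 <= 0 || p2 <= 0)
    stop("p1 and p2 must be positive fractions summing to 1")
  if (any(!is.finite(delta))) stop("delta must be finite")
  n_total * p1 * p2 * delta^2
}

#' GWAS discovery power at a genome-wide threshold
#'
#' Power of the 1-df association test: the upper tail of the noncentral
#' `F(1, N-4, lambda)` distribution beyond the central-F quantile at the
#' significance quantile `PSign`. The default `PSign = 0.99999995`
#' corresponds to the genome-wide significance level 5e-8. At `lambda = 0`
#' the value is exactly `1 - PSign` (the test's size).
#'
#' @param n_total Total sample size (> 4).
#' @param lambda Non-centrality parameter (>= 0), see [gwas_ncp()].
#' @param significance Upper quantile `PSign` in (0, 1).
#' @return Power in (0, 1); monotone increasing in `lambda`.
#' @examples
#' power_at(1e6, 39.6)    # about 80% power
#' power_at(1e6, 0)       # 5e-8, the size under the null
#' @export
power_at <- function(n_total, lambda, significance = 0.99999995) {
  if (any(n_total <= 4)) stop("n_total must exceed 4")
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (any(significance <= 0 | significance >= 1))
    stop("significance must lie in (0, 1)")
  crit <- stats::qf(significance, 1, n_total - 4)
  1 - stats::pf(crit, 1, n_total - 4, ncp = lambda)
}

#' Cases needed for a target GWAS discovery power
#'
#' Solves for the total sample size `N` (equal cases and controls by
#' default) at which the association-test power for an allele-frequency
#' difference `delta` reaches the target, then returns the implied number of
#' cases `N * p1`. The solve is a monotone bisection in `log N`, iterated
#' until the achieved power matches the target to better than 0.01%.
#'
#' @param delta Case-minus-control allele-frequency difference (non-zero).
#' @param target_power Target power (default 0.8).
#' @param significance Upper quantile `PSign`, see [power_at()].
#' @param p1,p2 Case and control fractions (default 0.5 each).
#' @return Number of cases (not rounded).
#' @examples
#' cases_for_power(0.0349)          # about 6.5e4 cases for 80% power
#' cases_for_power(0.0349, 0.5)     # about 4.9e4 cases for 50% power
#' @export
cases_for_power <- function(delta, target_power = 0.8,
                            significance = 0.99999995, p1 = 0.5, p2 = 0.5) {
  if (length(delta) > 1L)
    return(vapply(delta, cases_for_power, numeric(1),
                  target_power = target_power, significance = significance,
                  p1 = p1, p2 = p2))
  if (!is.finite(delta) || delta == 0)
    stop("delta must be non-zero for a power solve")
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must lie in (0, 1)")
  f <- function(logn) {
    n <- exp(logn)
    power_at(n, gwas_ncp(n, delta, p1, p2), significance) - target_power
  }
  lo <- log(6); hi <- log(1e15)
  if (f(lo) > 0) return(exp(lo) * p1)
  sol <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  exp(sol$root) * p1
}

#' Cases-needed multiple relative to the youngest cohort
#'
#' For one tracked variant, the ratio of cases needed for the target power
#' at each mid-cohort age to the cases needed at the youngest cohort. Since
#' `N` scales as `1/delta^2` (up to the slowly varying degrees of freedom),
#' the multiple equals `(delta_youngest / delta_age)^2` up to solver
#' tolerance and is invariant to the significance threshold and the power
#' target. Ages where the allele-frequency difference is zero or missing are
#' reported as missing.
#'
#' @param cohort A [run_cohort()] result (or its `records` data.frame).
#' @param variant Tracked variant label; default the largest-effect tracked
#'   variant (highest OR, then highest MAF).
#' @param target_power,significance Passed to [cases_for_power()].
#' @return A data.frame with `mid_age`, `dmaf`, `cases_needed`, `multiple`.
#' @export
power_multiple <- function(cohort, variant = NULL, target_power = 0.8,
                           significance = 0.99999995) {
  rec <- if (inherits(cohort, "lod_cohort")) cohort$records else cohort
  if (is.null(variant)) {
    if (!inherits(cohort, "lod_cohort")) {
      # bare records frame: fall back to the default largest-effect label
      if ("dmaf_s1_m5_o5" %in% names(rec)) variant <- "s1_m5_o5"
      else stop("variant must be named when passing a bare records frame")
    }
  }
  if (is.null(variant)) {
    ti <- cohort$config$architecture$variants
    ti <- ti[ti$variant_id %in% cohort$config$architecture$tracked_ids, ]
    ti <- ti[order(-ti$log_or, -ti$eaf), ]
    variant <- ti$variant_id[1L]
  }
  d <- rec[[paste0("dmaf_", variant)]]
  if (is.null(d)) stop("variant '", variant, "' is not tracked in this run")
  if (nrow(rec) == 0L) stop("no reported cohort records (youngest cohort missing)")
  cn <- vapply(d, function(dd) {
    if (is.na(dd) || dd == 0) NA_real_
    else cases_for_power(dd, target_power, significance)
  }, numeric(1))
  data.frame(mid_age = rec$mid_age, dmaf = d, cases_needed = cn,
             multiple = cn / cn[1L])
}
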
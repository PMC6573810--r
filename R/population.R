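#' Sample a birth population from a genetic architecture
#'
#' Each individual's risk-allele count at each variant is drawn independently
#' under Hardy-Weinberg equilibrium (2 with probability `p^2`, 1 with
#' `2p(1-p)`, 0 with `(1-p)^2`), and the polygenic risk score is the sum of
#' allele counts times per-allele log odds ratios, centred by
#' [mean_prs_offset()] so the initial population mean is zero.
#'
#' Only the scalar PRS and the tracked variants' genotypes are stored per
#' individual. Untracked variants sharing the same (frequency, effect) grid
#' cell are drawn as their exact aggregate: the summed allele count of `m`
#' independent Hardy-Weinberg variants is `Binomial(2m, p)`, so populations
#' of 10^7 and beyond need no per-variant genotype storage.
#'
#' @param n Number of individuals (>= 1).
#' @param architecture A [genetic_architecture()].
#' @param seed Integer seed; required, there is no silent nondeterminism.
#' @return An object of class `lod_population`: list with `n`, `prs`
#'   (centred scores), `tracked` (n x k allele-count matrix, columns named by
#'   variant label), `tracked_info` (per-variant `eaf`, `log_or`),
#'   `variance` (the architecture's theoretical PRS variance) and `seed`.
#' @examples
#' arch <- genetic_architecture(0.095)           # lung-cancer sizing
#' pop <- sample_population(1e4, arch, seed = 1)
#' mean(pop$prs); var(pop$prs)                   # ~0 and ~arch$variance
#' @export
sample_population <- function(n, architecture, seed) {
  stopifnot(inherits(architecture, "genetic_architecture"))
  n <- as.numeric(n)
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be >= 1")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  v <- architecture$variants
  if (nrow(v) == 0L) stop("architecture has no variants")
  tracked <- architecture$tracked_ids
  ti <- match(tracked, v$variant_id)
  untracked <- v[-ti, , drop = FALSE]
  combos <- if (nrow(untracked) > 0L) {
    key <- paste(untracked$eaf, untracked$log_or)
    agg <- untracked[!duplicated(key), c("eaf", "log_or")]
    agg$m <- as.integer(table(key)[paste(agg$eaf, agg$log_or)])
    agg
  } else data.frame(eaf = numeric(0), log_or = numeric(0), m = integer(0))
  center <- mean_prs_offset(v)
  res <- cpp_sample_population(
    as.integer(n),
    combo_m = 2L * combos$m, combo_p = combos$eaf, combo_beta = combos$log_or,
    tracked_p = v$eaf[ti], tracked_beta = v$log_or[ti],
    center = center, seed = as.double(seed))
  colnames(res$geno) <- tracked
  structure(list(n = as.integer(n), prs = res$prs, tracked = res$geno,
                 tracked_info = data.frame(variant_id = tracked,
                                           eaf = v$eaf[ti],
                                           log_or = v$log_or[ti],
                                           stringsAsFactors = FALSE),
                 variance = architecture$variance,
                 diagnosed_age = rep(NA_integer_, as.integer(n)),
                 death_age = rep(NA_integer_, as.integer(n)),
                 seed = seed),
            class = "lod_population")
}

#' @export
print.lod_population <- function(x, ...) {
  cat(sprintf(paste0("Population: %d individuals, PRS mean %.4f, variance %.4f",
                     " (theory %.4f)\n  %d tracked variants; %d diagnosed, %d dead\n"),
              x$n, mean(x$prs), stats::var(x$prs), x$variance,
              ncol(x$tracked), sum(!is.na(x$diagnosed_age)),
              sum(!is.na(x$death_age))))
  invisible(x)
}

#' Subset statistics of a population
#'
#' Count, PRS mean and standard deviation, and per-tracked-variant allele
#' frequency of the selected individuals. An empty selection is flagged and
#' its statistics reported as missing (`NA`) rather than propagating NaN.
#'
#' @param population A [sample_population()] result.
#' @param mask Logical or integer index selecting a subset (default: all).
#' @return A list with `n`, `prs_mean`, `prs_sd`, `allele_freq` (named
#'   vector) and `empty` flag.
#' @export
population_summary <- function(population, mask = NULL) {
  stopifnot(inherits(population, "lod_population"))
  idx <- if (is.null(mask)) seq_len(population$n)
         else if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0L)
    return(list(n = 0L, prs_mean = NA_real_, prs_sd = NA_real_,
                allele_freq = stats::setNames(
                  rep(NA_real_, ncol(population$tracked)),
                  colnames(population$tracked)),
                empty = TRUE))
  p <- population$prs[idx]
  g <- population$tracked[idx, , drop = FALSE]
  list(n = length(idx), prs_mean = mean(p),
       prs_sd = if (length(idx) > 1L) stats::sd(p) else NA_real_,
       allele_freq = colSums(g) / (2 * length(idx)),
       empty = FALSE)
}
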
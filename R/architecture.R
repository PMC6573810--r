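#' Genetic architecture scenarios
#'
#' Five named scenarios span the spectrum from common low-effect to rare
#' high-effect causal alleles. Each scenario is a rectangular grid: minor
#' allele frequencies (MAF) and per-allele odds ratios (OR) are discretized
#' into `grid_points` equally spaced values within the scenario bounds, and
#' every MAF is paired with every OR, so a single set holds
#' `grid_points^2` variants. The grid allele is always the risk allele
#' (OR > 1), so effect-allele frequency and MAF coincide.
#'
#' @param name Scenario label, one of `"A"` (common low), `"B"` (modest low),
#'   `"C"` (rare low), `"D"` (rare medium), `"E"` (rare high); or `"custom"`,
#'   in which case the bounds must be supplied.
#' @param maf_low,maf_high Minor-allele-frequency bounds, each in (0, 0.5].
#' @param or_low,or_high Per-allele odds-ratio bounds, each > 1.
#' @param grid_points Number of grid values per axis (default 5).
#' @param digits Grid values are rounded to this many decimals so variant
#'   parameters match their printed/tabulated form exactly; defaults to 3
#'   when all bounds have at most 3 decimals and 4 otherwise.
#' @return An object of class `architecture_scenario`.
#' @examples
#' architecture_scenario("A")
#' architecture_scenario("custom", maf_low = 0.1, maf_high = 0.2,
#'                       or_low = 1.1, or_high = 1.2, grid_points = 2)
#' @export
architecture_scenario <- function(name = c("A", "B", "C", "D", "E", "custom"),
                                  maf_low = NULL, maf_high = NULL,
                                  or_low = NULL, or_high = NULL,
                                  grid_points = 5L, digits = NULL) {
  name <- match.arg(name)
  defaults <- list(
    A = c(0.073,  0.500,  1.05, 1.15),
    B = c(0.0365, 0.2495, 1.05, 1.15),
    C = c(0.0146, 0.0998, 1.05, 1.15),
    D = c(0.0146, 0.0998, 1.28, 2.01),
    E = c(0.0073, 0.0499, 1.63, 4.05))
  if (name != "custom") {
    b <- defaults[[name]]
    if (is.null(maf_low))  maf_low  <- b[1]
    if (is.null(maf_high)) maf_high <- b[2]
    if (is.null(or_low))   or_low   <- b[3]
    if (is.null(or_high))  or_high  <- b[4]
  }
  stopifnot(is.numeric(maf_low), is.numeric(maf_high),
            is.numeric(or_low), is.numeric(or_high))
  if (!(maf_low > 0 && maf_high <= 0.5 && maf_low < maf_high))
    stop("invalid MAF bounds: need 0 < maf_low < maf_high <= 0.5")
  if (!(or_low > 1 && or_low < or_high))
    stop("invalid OR bounds: need 1 < or_low < or_high")
  grid_points <- as.integer(grid_points)
  if (grid_points < 2L) stop("grid_points must be >= 2")
  if (is.null(digits)) {
    ndec <- function(x) {
      s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(x, scientific = FALSE)))
      nchar(s)
    }
    digits <- if (max(vapply(c(maf_low, maf_high, or_low, or_high), ndec, 1L)) <= 3L) 3L else 4L
  }
  structure(list(name = name, maf_low = maf_low, maf_high = maf_high,
                 or_low = or_low, or_high = or_high,
                 grid_points = grid_points, digits = as.integer(digits)),
            class = "architecture_scenario")
}

#' @export
print.architecture_scenario <- function(x, ...) {
  cat(sprintf("Genetic architecture scenario %s: MAF %g-%g, OR %g-%g, %dx%d grid\n",
              x$name, x$maf_low, x$maf_high, x$or_low, x$or_high,
              x$grid_points, x$grid_points))
  invisible(x)
}

#' Build the variant grid of one scenario set
#'
#' MAFs are discretized into equally spaced values ascending from `maf_low`
#' to `maf_high`; ORs likewise, and every MAF is crossed with every OR so
#' each frequency and each effect size appear in equal proportion. Variants
#' are listed with ORs descending as MAFs ascend (the pairing orientation is
#' immaterial to any variance computed over the full cross-product, but is
#' fixed so variant labels are reproducible). Grid values are rounded to the
#' scenario's `digits` so they match their printed form; for scenario A this
#' yields MAFs 0.073, 0.180, 0.286, 0.393, 0.500 and ORs 1.05 to 1.15.
#'
#' @param scenario An [architecture_scenario()] object.
#' @param set Integer set index used only for variant labels.
#' @return A data.frame of class `variant_grid` with columns `variant_id`,
#'   `eaf`, `odds_ratio`, `log_or`.
#' @examples
#' g <- build_scenario_grid(architecture_scenario("A"))
#' unique(g$eaf)
#' @export
build_scenario_grid <- function(scenario, set = 1L) {
  stopifnot(inherits(scenario, "architecture_scenario"))
  mafs <- round(seq(scenario$maf_low, scenario$maf_high,
                    length.out = scenario$grid_points), scenario$digits)
  ors <- round(seq(scenario$or_low, scenario$or_high,
                   length.out = scenario$grid_points), scenario$digits)
  k <- scenario$grid_points
  mi <- rep(seq_len(k), each = k)           # MAF ascending
  oi <- rep(rev(seq_len(k)), times = k)     # OR descending within each MAF
  out <- data.frame(
    variant_id = sprintf("s%d_m%d_o%d", as.integer(set), mi, oi),
    eaf = mafs[mi],
    odds_ratio = ors[oi],
    stringsAsFactors = FALSE)
  out$log_or <- log(out$odds_ratio)
  class(out) <- c("variant_grid", "data.frame")
  out
}

.check_variants <- function(variants) {
  if (!is.data.frame(variants) || nrow(variants) == 0L)
    stop("variants must be a non-empty data.frame")
  need <- c("eaf", "odds_ratio")
  if (!all(need %in% names(variants)))
    stop("variants needs columns 'eaf' and 'odds_ratio'")
  if (any(variants$eaf <= 0 | variants$eaf >= 1))
    stop("effect-allele frequencies must lie in (0, 1)")
  invisible(variants)
}

#' Liability variance of a variant set
#'
#' The genetic variance contributed on the log-odds (liability) scale by a
#' set of independent biallelic variants under Hardy-Weinberg equilibrium:
#' `2 * sum(p * (1 - p) * log(OR)^2)`. Additive over concatenated sets.
#'
#' @param variants A data.frame with columns `eaf` and `odds_ratio` (e.g. a
#'   [build_scenario_grid()] result, or several stacked sets).
#' @return Variance in squared log-odds units.
#' @examples
#' architecture_variance(build_scenario_grid(architecture_scenario("A")))
#' @export
architecture_variance <- function(variants) {
  .check_variants(variants)
  2 * sum(variants$eaf * (1 - variants$eaf) * log(variants$odds_ratio)^2)
}

#' Liability-scale heritability implied by a genetic variance
#'
#' Under the logistic liability model the narrow-sense heritability is the
#' genetic variance over genetic-plus-logistic variance,
#' `h2 = var / (var + pi^2/3)`, where `pi^2/3` is the variance of the
#' standard logistic distribution.
#'
#' @param variance Genetic variance in squared log-odds units (>= 0).
#' @return Heritability in `[0, 1)`.
#' @export
heritability_from_variance <- function(variance) {
  if (any(!is.finite(variance)) || any(variance < 0))
    stop("variance must be finite and >= 0")
  variance / (variance + pi^2 / 3)
}

#' Genetic variance required for a target heritability
#'
#' Inverse of [heritability_from_variance()].
#'
#' @param target_h2 Liability-scale heritability in `[0, 1)`.
#' @return Required variance in squared log-odds units.
#' @export
variance_for_heritability <- function(target_h2) {
  if (any(target_h2 < 0) || any(target_h2 >= 1))
    stop("target_h2 must lie in [0, 1)")
  target_h2 / (1 - target_h2) * pi^2 / 3
}

#' Number of replicated variant sets for a target heritability
#'
#' The required liability variance `target_h2/(1-target_h2) * pi^2/3` is
#' divided by the variance of a single scenario grid set and rounded to the
#' nearest integer. For scenario A this sizing reproduces the published
#' variant counts for cerebral stroke (25 sets, 625 variants), breast cancer
#' (16 sets, 400), colorectal cancer (24 sets, 600) and lung cancer
#' (4 sets, 100).
#'
#' @param target_h2 Target liability-scale heritability in `[0, 1)`.
#' @param scenario An [architecture_scenario()], or a single-set variance.
#' @return Integer number of sets.
#' @export
sets_for_heritability <- function(target_h2, scenario = architecture_scenario("A")) {
  v1 <- if (inherits(scenario, "architecture_scenario"))
    architecture_variance(build_scenario_grid(scenario)) else as.numeric(scenario)
  as.integer(round(variance_for_heritability(target_h2) / v1))
}

#' Population mean of the polygenic score
#'
#' The population mean of the raw polygenic score (sum of risk-allele counts
#' times log odds ratios) is `2 * sum(p * log(OR))` under Hardy-Weinberg
#' genotype frequencies. Individual scores are centred by this offset so the
#' initial population PRS has mean zero.
#'
#' @inheritParams architecture_variance
#' @return The mean offset in log-odds units.
#' @export
mean_prs_offset <- function(variants) {
  .check_variants(variants)
  2 * sum(variants$eaf * log(variants$odds_ratio))
}

#' Assemble a replicated genetic architecture
#'
#' Builds `n_sets` copies of the scenario grid (labelled `s1 ...`,
#' `s2 ...`), where `n_sets` is either given explicitly or sized to the
#' target heritability by [sets_for_heritability()]. Nine variants of set 1
#' are tracked by default: the 3x3 subgrid crossing the lowest, middle and
#' highest MAF with the lowest, middle and highest OR. Tracked variants are
#' the ones whose genotypes are stored per individual during simulation.
#'
#' @param target_h2 Target liability-scale heritability in `[0, 1)`.
#' @param scenario An [architecture_scenario()] (default scenario A).
#' @param n_sets Optional explicit set count overriding the nearest-set rule
#'   (used by the disease presets whose published counts exceed it).
#' @param tracked Character vector of variant labels to track, or `NULL` for
#'   the default 3x3 subgrid of set 1.
#' @return An object of class `genetic_architecture`: list with elements
#'   `scenario`, `n_sets`, `variants`, `target_h2`, `variance`,
#'   `achieved_h2`, `tracked_ids`.
#' @examples
#' arch <- genetic_architecture(0.41)   # cerebral-stroke sizing: 625 variants
#' nrow(arch$variants); arch$achieved_h2
#' @export
genetic_architecture <- function(target_h2, scenario = architecture_scenario("A"),
                                 n_sets = NULL, tracked = NULL) {
  stopifnot(inherits(scenario, "architecture_scenario"))
  if (is.null(n_sets)) n_sets <- sets_for_heritability(target_h2, scenario)
  n_sets <- as.integer(n_sets)
  if (n_sets < 0L) stop("n_sets must be >= 0")
  grids <- lapply(seq_len(n_sets), function(s) build_scenario_grid(scenario, set = s))
  variants <- if (n_sets > 0L) do.call(rbind, grids) else
    build_scenario_grid(scenario)[0L, ]
  variance <- if (n_sets > 0L) architecture_variance(variants) else 0
  if (is.null(tracked)) {
    if (n_sets > 0L) {
      k <- scenario$grid_points
      idx <- unique(round(c(1, (k + 1) / 2, k)))
      tracked <- as.character(outer(idx, idx, function(m, o)
        sprintf("s1_m%d_o%d", m, o)))
    } else tracked <- character(0)
  }
  if (n_sets > 0L && !all(tracked %in% variants$variant_id))
    stop("tracked ids not present in the architecture")
  structure(list(scenario = scenario, n_sets = n_sets, variants = variants,
                 target_h2 = target_h2, variance = variance,
                 achieved_h2 = heritability_from_variance(variance),
                 tracked_ids = tracked),
            class = "genetic_architecture")
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat(sprintf(paste0("Genetic architecture: scenario %s, %d sets (%d variants)\n",
                     "  target h2 = %.4g, achieved h2 = %.4g (variance %.5g)\n",
                     "  tracked: %s\n"),
              x$scenario$name, x$n_sets, nrow(x$variants),
              x$target_h2, x$achieved_h2, x$variance,
              paste(x$tracked_ids, collapse = " ")))
  invisible(x)
}

#' Write / read an architecture variant table
#'
#' Three-column whitespace-delimited text (`SNP`, `EAF`, `OR`), the layout
#' used by the published architecture listings.
#'
#' @param architecture A `genetic_architecture` or `variant_grid`.
#' @param path File path.
#' @return `write_architecture` returns `path` invisibly; `read_architecture`
#'   returns a `variant_grid` data.frame.
#' @export
write_architecture <- function(architecture, path) {
  v <- if (inherits(architecture, "genetic_architecture"))
    architecture$variants else architecture
  .check_variants(v)
  out <- data.frame(SNP = v$variant_id, EAF = v$eaf, OR = v$odds_ratio)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_architecture
#' @examples
#' g <- read_architecture(system.file("extdata", "scenario_A_set1.txt",
#'                                    package = "lodsim"))
#' architecture_variance(g)
#' @export
read_architecture <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("expected three columns: SNP, EAF, OR")
  out <- data.frame(variant_id = as.character(tab[[1L]]), eaf = as.numeric(tab[[2L]]),
                    odds_ratio = as.numeric(tab[[3L]]), stringsAsFactors = FALSE)
  out$log_or <- log(out$odds_ratio)
  .check_variants(out)
  class(out) <- c("variant_grid", "data.frame")
  out
}
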
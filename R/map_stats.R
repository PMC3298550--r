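#' Intermarker distance statistics
#'
#' Mean and maximum distance between adjacent mapped markers. The mean is
#' the summed map length divided by the number of intervals
#' (`n_markers - n_groups`); the maximum is taken over all adjacent
#' intervals.
#'
#' @param map A `genetic_map`.
#' @return List with `mean_cM`, `max_cM`, `summed_length_cM`, `n_markers`,
#'   `n_groups`.
#' @export
intermarker_stats <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  lg <- group_lengths(map)
  n <- nrow(map)
  k <- nrow(lg)
  if (n - k == 0L) stop("map has no adjacent-marker intervals")
  gaps <- unlist(lapply(split(map$pos_cM, map$group), diff))
  list(mean_cM = sum(lg$length_cM) / (n - k),
       max_cM = max(gaps),
       summed_length_cM = sum(lg$length_cM),
       n_markers = n, n_groups = k)
}

#' Corrected total map length
#'
#' Chromosome-end correction for map length: each linkage group contributes
#' `(L_i + 2) * (m_i + 1) / (m_i - 1)`, where `L_i` is the group's map
#' length in cM and `m_i` its marker count. Groups with a single marker
#' contribute `L_i + 2` with a warning (the multiplier is undefined at
#' `m = 1`).
#'
#' @param map A `genetic_map`.
#' @return Corrected length in cM.
#' @export
corrected_length <- function(map) {
  lg <- group_lengths(map)
  single <- lg$n_markers < 2L
  if (any(single)) {
    warning(sum(single), " single-marker group(s) contribute L + 2 without correction factor")
  }
  fac <- ifelse(single, 1, (lg$n_markers + 1) / (lg$n_markers - 1))
  sum((lg$length_cM + 2) * fac)
}

#' Genome coverage estimate
#'
#' Expected proportion of the genome within `d` cM of a marker:
#' `c = 1 - exp(-2 d n / L)`, with `d` the average intermarker distance
#' (cM), `n` the marker count and `L` the genome map length (cM).
#'
#' @param d Average intermarker distance in cM.
#' @param n Number of markers.
#' @param L Reference genome map length in cM.
#' @return Coverage in `[0, 1]`.
#' @export
coverage <- function(d, n, L) {
  if (any(c(d, n, L) <= 0)) stop("`d`, `n` and `L` must be positive")
  1 - exp(-2 * d * n / L)
}

#' Recombination rate and marker density
#'
#' @param map_length_cM Total (corrected) map length in cM.
#' @param genome_size_Mb Physical genome size in Mbp.
#' @param n_markers Number of markers.
#' @return List with `rate_cM_per_Mbp` (`map_length / genome_size`) and
#'   `density_Mbp_per_marker` (`genome_size / n_markers`).
#' @export
rate_and_density <- function(map_length_cM, genome_size_Mb, n_markers) {
  if (any(c(map_length_cM, genome_size_Mb, n_markers) <= 0)) {
    stop("all inputs must be positive")
  }
  list(rate_cM_per_Mbp = map_length_cM / genome_size_Mb,
       density_Mbp_per_marker = genome_size_Mb / n_markers)
}

#' Summary statistics for a genetic map
#'
#' Collects the standard descriptive statistics of a linkage map: marker
#' and group counts, summed and corrected length, intermarker distances,
#' genome coverage, recombination rate and marker density.
#'
#' Two coverage conventions are supported. `"external"` (default) uses
#' `d = summed_length / n` with an externally published reference map
#' length `reference_length_cM`; `"internal"` uses the mean intermarker
#' distance `d = summed_length / (n - n_groups)` with this map's own
#' corrected length as `L`. The two can differ noticeably on sparse maps.
#'
#' @param map A `genetic_map`.
#' @param genome_size_Mb Physical genome size (default 244.5 Mbp, the
#'   copepod haploid estimate the package's defaults emulate).
#' @param reference_length_cM Reference map length for the external
#'   coverage convention (default 484.8 cM, a previously published
#'   corrected map length for the same species).
#' @param coverage_convention `"external"` or `"internal"`.
#' @return List of class `map_summary`.
#' @export
map_summary <- function(map, genome_size_Mb = 244.5,
                        reference_length_cM = 484.8,
                        coverage_convention = c("external", "internal")) {
  coverage_convention <- match.arg(coverage_convention)
  im <- intermarker_stats(map)
  lt <- corrected_length(map)
  cov <- if (coverage_convention == "external") {
    coverage(im$summed_length_cM / im$n_markers, im$n_markers,
             reference_length_cM)
  } else {
    coverage(im$mean_cM, im$n_markers, lt)
  }
  rd <- rate_and_density(lt, genome_size_Mb, im$n_markers)
  structure(list(n_markers = im$n_markers, n_groups = im$n_groups,
                 summed_length_cM = im$summed_length_cM,
                 mean_intermarker_cM = im$mean_cM,
                 max_intermarker_cM = im$max_cM,
                 corrected_length_cM = lt,
                 coverage = cov,
                 coverage_convention = coverage_convention,
                 recomb_rate_cM_per_Mbp = rd$rate_cM_per_Mbp,
                 density_Mbp_per_marker = rd$density_Mbp_per_marker),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat("Linkage map summary\n")
  cat(sprintf("  markers:              %d in %d groups\n", x$n_markers, x$n_groups))
  cat(sprintf("  summed length:        %.1f cM\n", x$summed_length_cM))
  cat(sprintf("  intermarker distance: mean %.2f cM, max %.1f cM\n",
              x$mean_intermarker_cM, x$max_intermarker_cM))
  cat(sprintf("  corrected length:     %.1f cM\n", x$corrected_length_cM))
  cat(sprintf("  coverage (%s):  %.1f%%\n", x$coverage_convention, 100 * x$coverage))
  cat(sprintf("  recombination rate:   %.2f cM/Mbp\n", x$recomb_rate_cM_per_Mbp))
  cat(sprintf("  marker density:       %.2f Mbp/marker\n", x$density_Mbp_per_marker))
  invisible(x)
}
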
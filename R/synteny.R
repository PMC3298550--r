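#' Homolog table
#'
#' Marker-to-chromosome assignments for one reference genome: each row maps
#' a marker to its linkage-map chromosome and the chromosome (or scaffold)
#' of its best homolog in the reference genome. Markers without detected
#' homologs are simply absent.
#'
#' @param marker Marker ids (unique within a table).
#' @param map_chrom Linkage-map chromosome per marker.
#' @param ref_chrom Reference-genome chromosome or scaffold per marker.
#' @param ref_genome Label of the reference genome.
#' @param include_unanchored Whether unanchored scaffolds were retained
#'   (typical for scaffold-level assemblies) or discarded (typical for
#'   chromosome-level assemblies). Metadata only; filtering happens
#'   upstream.
#' @return Object of class `homolog_table` (a data frame).
#' @export
homolog_table <- function(marker, map_chrom, ref_chrom,
                          ref_genome = "reference",
                          include_unanchored = FALSE) {
  if (length(marker) != length(map_chrom) ||
      length(marker) != length(ref_chrom)) {
    stop("`marker`, `map_chrom` and `ref_chrom` must have equal length")
  }
  if (anyDuplicated(marker)) stop("one row per marker: duplicated marker id")
  tb <- data.frame(marker = as.character(marker),
                   map_chrom = as.character(map_chrom),
                   ref_chrom = as.character(ref_chrom),
                   stringsAsFactors = FALSE)
  attr(tb, "ref_genome") <- ref_genome
  attr(tb, "include_unanchored") <- include_unanchored
  class(tb) <- c("homolog_table", "data.frame")
  tb
}

#' Count syntenic units
#'
#' Groups homologs by (linkage-map chromosome, reference chromosome) cell;
#' a cell holding `k >= 2` colocalizing homologs contributes `k - 1`
#' syntenic units (a pair scores 1, a triple 2, and so on). The total is
#' the sum over cells.
#'
#' @param table A [homolog_table()] (or data frame with columns
#'   `map_chrom`, `ref_chrom`).
#' @return Integer count of syntenic units.
#' @export
count_syntenic_units <- function(table) {
  if (nrow(table) == 0L) stop("homolog table is empty")
  k <- table(paste(table$map_chrom, table$ref_chrom, sep = "\r"))
  sum(pmax(as.integer(k) - 1L, 0L))
}

#' Permutation test for macrosynteny
#'
#' Tests whether the observed number of syntenic units exceeds chance
#' expectation by randomly permuting the reference-genome chromosome
#' assignments against the fixed linkage-map assignments `n_perm` times and
#' recounting units each time. The p-value uses the add-one estimator
#' `p = (1 + #permuted >= observed) / (n_perm + 1)` (never exactly zero
#' from finite permutations). Significance is declared at the
#' Bonferroni-corrected level `alpha / n_tests`, and the matching empirical
#' quantile of the permutation distribution is reported as the threshold,
#' together with the permutation maximum.
#'
#' @param table A [homolog_table()] with at least 2 rows.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Nominal significance level.
#' @param n_tests Number of reference genomes tested (Bonferroni divisor,
#'   default 4).
#' @param rng_seed Optional seed for reproducible permutations.
#' @return Object of class `synteny_result`: list with `observed_units`,
#'   `n_alignments`, `permutation_units` (length `n_perm`), `p_value`,
#'   `alpha_corrected`, `threshold` (the `1 - alpha/n_tests` empirical
#'   quantile), `perm_max`, `significant` and `ref_genome`.
#' @export
permutation_test <- function(table, n_perm = 1000, alpha = 0.05,
                             n_tests = 4, rng_seed = NULL) {
  if (nrow(table) < 2L) stop("need at least 2 homolog rows")
  if (n_perm < 1L) stop("`n_perm` must be at least 1")
  obs <- count_syntenic_units(table)
  run <- function() {
    vapply(seq_len(n_perm), function(i) {
      perm <- table
      perm$ref_chrom <- sample(perm$ref_chrom)
      count_syntenic_units(perm)
    }, integer(1))
  }
  perm_units <- if (is.null(rng_seed)) run() else with_seed(rng_seed, run())
  p <- (1 + sum(perm_units >= obs)) / (n_perm + 1)
  a_corr <- alpha / n_tests
  thr <- as.numeric(stats::quantile(perm_units, probs = 1 - a_corr, type = 1))
  structure(list(observed_units = obs, n_alignments = nrow(table),
                 permutation_units = perm_units, p_value = p,
                 alpha_corrected = a_corr, threshold = thr,
                 perm_max = max(perm_units), significant = p < a_corr,
                 ref_genome = attr(table, "ref_genome")),
            class = "synteny_result")
}

#' @export
print.synteny_result <- function(x, ...) {
  cat(sprintf("synteny: %s, %d alignments, %d observed units (threshold %g, p = %.4g%s)\n",
              x$ref_genome %||% "reference", x$n_alignments, x$observed_units,
              x$threshold, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-genome synteny report
#'
#' One row per reference genome, mirroring the usual macrosynteny summary
#' table: number of alignments, observed syntenic units, permutation
#' threshold and maximum, p-value and a significance star at the
#' Bonferroni-corrected level.
#'
#' @param results List of `synteny_result` objects (see
#'   [permutation_test()]).
#' @return Data frame with columns `ref_genome`, `n_align`, `n_units`,
#'   `threshold`, `perm_max`, `p_value`, `significant`.
#' @export
multi_genome_report <- function(results) {
  if (length(results) == 0L) {
    return(data.frame(ref_genome = character(), n_align = integer(),
                      n_units = integer(), threshold = numeric(),
                      perm_max = integer(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(results, function(r) {
    data.frame(ref_genome = r$ref_genome %||% "reference",
               n_align = r$n_alignments, n_units = r$observed_units,
               threshold = r$threshold, perm_max = r$perm_max,
               p_value = r$p_value, significant = r$significant,
               stringsAsFactors = FALSE)
  }))
}
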
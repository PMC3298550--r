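#' Segregation-distortion test
#'
#' Per-marker chi-square test of the observed P1 versus P2 allele counts
#' (`2*AA + AB` vs `2*BB + AB`) against the Mendelian 1:1 expectation, with
#' 1 degree of freedom. A marker is flagged when its chi-square statistic
#' exceeds `chi2_flag_threshold` (default 14, a conservative screen beyond
#' the df = 1 critical value of 10.83 for p < 0.001). Bonferroni-corrected
#' p-values across all tested markers are also reported.
#'
#' A df = 2 genotype test against the 1:2:1 expectation is available with
#' `test = "genotype"`.
#'
#' @param matrix A [genotype_matrix()].
#' @param chi2_flag_threshold Chi-square value above which a marker is
#'   flagged.
#' @param test `"allele"` (default, df = 1) or `"genotype"` (df = 2).
#' @return Data frame with one row per marker: `marker`, `chi_square`, `df`,
#'   `p_value`, `bonferroni_p`, `flagged`. Markers with no non-missing
#'   calls get `NA` statistics and are not flagged.
#' @export
segregation_test <- function(matrix, chi2_flag_threshold = 14,
                             test = c("allele", "genotype")) {
  test <- match.arg(test)
  nAA <- rowSums(matrix == "AA", na.rm = TRUE)
  nAB <- rowSums(matrix == "AB", na.rm = TRUE)
  nBB <- rowSums(matrix == "BB", na.rm = TRUE)
  n <- nAA + nAB + nBB
  if (test == "allele") {
    a <- 2 * nAA + nAB
    b <- 2 * nBB + nAB
    chi2 <- ifelse(n > 0, (a - b)^2 / (a + b), NA_real_)
    df <- 1L
  } else {
    e <- cbind(n / 4, n / 2, n / 4)
    o <- cbind(nAA, nAB, nBB)
    chi2 <- ifelse(n > 0, rowSums((o - e)^2 / e), NA_real_)
    df <- 2L
  }
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  n_tested <- sum(!is.na(chi2))
  data.frame(marker = rownames(matrix),
             chi_square = chi2, df = df, p_value = p,
             bonferroni_p = pmin(1, p * n_tested),
             flagged = !is.na(chi2) & chi2 > chi2_flag_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Implied-female-recombination marker filter
#'
#' For each mapped marker, fits the sex-specific recombination model
#' ([estimate_r_sexspecific()]) against each of its nearest neighbours on
#' the map (both sides where defined). A marker is excluded when even its
#' best-supported neighbour implies female recombination above
#' `rf_threshold` — i.e. when the minimum over neighbours of the estimated
#' `r_f` exceeds the threshold. The rationale: female recombination in an
#' achiasmatic species does not occur at appreciable levels, so marker
#' states explicable only through high implied female recombination point
#' to genotyping artefacts such as cryptic polymorphism.
#'
#' @param map A `genetic_map` (see [build_map()]).
#' @param matrix The F2 [genotype_matrix()] the map was built from.
#' @param rf_threshold Exclusion threshold on the implied female
#'   recombination fraction (default 0.25).
#' @return Data frame with one row per marker: `marker`, `group`, `rf_hat`
#'   (minimum over nearest neighbours; `NA` for markers in single-marker
#'   groups, which are skipped), `excluded`.
#' @export
female_recomb_filter <- function(map, matrix, rf_threshold = 0.25) {
  stopifnot(inherits(map, "genetic_map"))
  out <- data.frame(marker = map$marker, group = map$group,
                    rf_hat = NA_real_, excluded = FALSE,
                    stringsAsFactors = FALSE)
  for (g in split(seq_len(nrow(map)), map$group)) {
    ord <- map$marker[g]
    if (length(ord) < 2L) next
    for (i in seq_along(ord)) {
      nb <- ord[c(i - 1L, i + 1L)]
      nb <- nb[!is.na(nb)]
      rf <- vapply(nb, function(m2) {
        estimate_r_sexspecific(count_pair_classes(matrix, ord[i], m2))$r_f
      }, numeric(1))
      out$rf_hat[g[i]] <- min(rf)
    }
  }
  out$excluded <- !is.na(out$rf_hat) & out$rf_hat > rf_threshold
  out
}
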
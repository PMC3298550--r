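PAIR_CLASSES <- c("AABB", "AABb", "AAbb", "AaBB", "AaBb", "Aabb",
                  "aaBB", "aaBb", "aabb")

#' Two-locus genotype class counts
#'
#' Tabulates the nine two-locus genotype classes for a marker pair,
#' excluding individuals missing at either marker. Locus 1 alleles are
#' written A/a and locus 2 alleles B/b, with the capital allele the P1
#' allele at each locus, so e.g. class `AAbb` means P1-homozygous at
#' `marker_i` and P2-homozygous at `marker_j`.
#'
#' @param matrix A [genotype_matrix()].
#' @param marker_i,marker_j Marker ids present in `matrix`.
#' @return Object of class `pair_counts`: named integer vector over the nine
#'   classes with attribute `n_complete`.
#' @export
count_pair_classes <- function(matrix, marker_i, marker_j) {
  for (m in c(marker_i, marker_j)) {
    if (!m %in% rownames(matrix)) stop("unknown marker id: ", m)
  }
  gi <- match(matrix[marker_i, ], GENO_CODES)   # 1 = AA, 2 = AB, 3 = BB
  gj <- match(matrix[marker_j, ], GENO_CODES)
  ok <- !is.na(gi) & !is.na(gj)
  cls <- tabulate((gi[ok] - 1L) * 3L + gj[ok], nbins = 9L)
  pair_counts(stats::setNames(cls, PAIR_CLASSES))
}

#' @rdname count_pair_classes
#' @param counts Named numeric vector with (a subset of) the nine class
#'   names; omitted classes are zero.
#' @export
pair_counts <- function(counts) {
  out <- stats::setNames(integer(9L), PAIR_CLASSES)
  if (is.null(names(counts)) || !all(names(counts) %in% PAIR_CLASSES)) {
    stop("counts must be named by two-locus classes: ",
         paste(PAIR_CLASSES, collapse = ", "))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  out[names(counts)] <- as.integer(counts)
  structure(out, n_complete = sum(out), class = "pair_counts")
}

#' Two-point recombination fraction under female achiasmy
#'
#' Maximum-likelihood estimate of the (male) recombination fraction for a
#' marker pair in an F2 intercross in which females do not recombine. The
#' maternal gamete is AB or ab with probability 1/2 each; the paternal
#' gamete is AB/ab with probability (1-r)/2 each and Ab/aB with probability
#' r/2 each, giving class probabilities
#' `P(AABB) = P(aabb) = (1-r)/4`, `P(AaBb) = (1-r)/2`,
#' `P(AABb) = P(AaBB) = P(Aabb) = P(aaBb) = r/4`, and
#' `P(AAbb) = P(aaBB) = 0`.
#'
#' Individuals in the two zero-probability classes (possible only through
#' genotyping error or female recombination) are excluded from the estimate
#' and reported as `n_impossible`. The closed-form MLE is the recombinant
#' fraction among the remaining individuals, clamped to `[0, 0.5]`; the LOD
#' score is the base-10 log likelihood ratio against r = 0.5.
#'
#' @param counts A `pair_counts` object (see [count_pair_classes()]).
#' @return Object of class `twopoint_estimate`: list with `r_hat`, `lod`,
#'   `n` (pairwise-complete sample size) and `n_impossible`.
#' @export
estimate_r_achiasmatic <- function(counts) {
  counts <- pair_counts(counts)
  n_imp <- sum(counts[c("AAbb", "aaBB")])
  n_rec <- sum(counts[c("AABb", "AaBB", "Aabb", "aaBb")])
  n_non <- sum(counts[c("AABB", "aabb", "AaBb")])
  n_eff <- n_rec + n_non
  if (n_eff == 0L) {
    stop("recombination fraction undefined: no individuals outside the impossible classes")
  }
  r <- min(max(n_rec / n_eff, 0), 0.5)
  lod <- .achias_lod(n_non, n_rec, r)
  structure(list(r_hat = r, lod = lod,
                 n = attr(counts, "n_complete"), n_impossible = n_imp),
            class = "twopoint_estimate")
}

# LOD of the achiasmatic likelihood at r versus the null r = 0.5;
# normalizing constants cancel, leaving count-weighted log10(2p) terms
.achias_lod <- function(n_non, n_rec, r) {
  lod <- 0
  if (n_non > 0) lod <- lod + n_non * log10(2 * (1 - r))
  if (n_rec > 0) lod <- lod + n_rec * log10(2 * r)
  max(lod, 0)
}

#' @export
print.twopoint_estimate <- function(x, ...) {
  cat(sprintf("two-point estimate: r = %.4f, LOD = %.2f (n = %d, impossible = %d)\n",
              x$r_hat, x$lod, x$n, x$n_impossible))
  invisible(x)
}

#' All pairwise two-point estimates
#'
#' Computes [estimate_r_achiasmatic()] for every marker pair of a genotype
#' matrix, via indicator-matrix cross-products (fast for hundreds of
#' markers).
#'
#' @param matrix A [genotype_matrix()].
#' @return Long-format data frame with columns `marker_i`, `marker_j`
#'   (i before j in matrix row order), `r_hat`, `lod`, `n`, `n_impossible`.
#' @export
pairwise_estimates <- function(matrix) {
  g <- base::matrix(match(matrix, GENO_CODES), nrow = nrow(matrix),
                    dimnames = dimnames(matrix))
  ind <- lapply(1:3, function(k) {
    x <- g == k
    x[is.na(x)] <- FALSE
    x * 1
  })
  cls <- vector("list", 9L)
  for (a in 1:3) for (b in 1:3) {
    cls[[(a - 1L) * 3L + b]] <- tcrossprod(ind[[a]], ind[[b]])
  }
  up <- upper.tri(cls[[1L]])
  ij <- which(up, arr.ind = TRUE)
  cc <- vapply(cls, function(m) m[up], numeric(sum(up)))
  colnames(cc) <- PAIR_CLASSES
  n_imp <- cc[, "AAbb"] + cc[, "aaBB"]
  n_rec <- cc[, "AABb"] + cc[, "AaBB"] + cc[, "Aabb"] + cc[, "aaBb"]
  n_non <- cc[, "AABB"] + cc[, "aabb"] + cc[, "AaBb"]
  n_eff <- n_rec + n_non
  r <- pmin(pmax(ifelse(n_eff > 0, n_rec / n_eff, NA_real_), 0), 0.5)
  lod <- mapply(function(nn, nr, rr) {
    if (is.na(rr)) NA_real_ else .achias_lod(nn, nr, rr)
  }, n_non, n_rec, r)
  data.frame(marker_i = rownames(matrix)[ij[, "row"]],
             marker_j = rownames(matrix)[ij[, "col"]],
             r_hat = r, lod = lod, n = rowSums(cc),
             n_impossible = n_imp, stringsAsFactors = FALSE)
}

# sex-specific two-locus log likelihood (up to additive constants).
# rf, rm may be vectors of equal length.
.sexspec_loglik <- function(counts, rf, rm) {
  nP <- sum(counts[c("AABB", "aabb")])
  nI <- sum(counts[c("AAbb", "aaBB")])
  nS <- sum(counts[c("AABb", "AaBB", "Aabb", "aaBb")])
  nH <- counts[["AaBb"]]
  pP <- (1 - rf) * (1 - rm)
  pI <- rf * rm
  pS <- rf * (1 - rm) + rm * (1 - rf)
  term <- function(n, p) if (n > 0) n * log(p) else rep(0, length(p))
  term(nP, pP) + term(nI, pI) + term(nS, pS) + term(nH, pP + pI)
}

#' Sex-specific recombination estimate
#'
#' Joint maximum-likelihood estimate of the female and male recombination
#' fractions `(r_f, r_m)` for a marker pair in an F2 intercross, dropping
#' the achiasmy assumption. With maternal gametes AB/ab at probability
#' `(1-r_f)/2` and Ab/aB at `r_f/2` (and likewise for the father with
#' `r_m`), the class probabilities are
#' `P(AABB) = P(aabb) = (1-r_f)(1-r_m)/4`,
#' `P(AAbb) = P(aaBB) = r_f r_m / 4`,
#' `P(AABb) = P(AaBB) = P(Aabb) = P(aaBb) = (r_f(1-r_m) + r_m(1-r_f))/4`,
#' `P(AaBb) = ((1-r_f)(1-r_m) + r_f r_m)/2`.
#' At `r_f = 0` this reduces exactly to the achiasmatic model.
#'
#' The likelihood is symmetric in `(r_f, r_m)`, so the labels are not
#' identifiable from F2 genotypes alone; the estimate is canonicalized with
#' `r_f <= r_m`, the biologically conservative assignment when female
#' recombination is the rare event under scrutiny.
#'
#' Maximization is by a bounded grid over `[0, 0.5]^2` followed by local
#' refinement; ties are broken toward smaller `r_f`.
#'
#' @param counts A `pair_counts` object.
#' @param grid_step Grid resolution for the initial search.
#' @return Object of class `sexspecific_estimate`: list with `r_f`, `r_m`
#'   and `log_likelihood` (up to a constant not depending on the rates).
#' @export
estimate_r_sexspecific <- function(counts, grid_step = 0.005) {
  counts <- pair_counts(counts)
  if (attr(counts, "n_complete") == 0L) stop("empty pair counts")
  grid <- seq(0, 0.5, by = grid_step)
  gg <- expand.grid(rf = grid, rm = grid)
  keep <- gg$rf <= gg$rm
  gg <- gg[keep, ]
  ll <- .sexspec_loglik(counts, gg$rf, gg$rm)
  ll[is.nan(ll)] <- -Inf
  # ties toward smaller r_f then smaller r_m (grid is ordered that way)
  best <- gg[which.max(ll), ]
  # keep the refinement box away from axes where a positive count would
  # make the log likelihood -Inf (L-BFGS-B needs finite values)
  n_imp <- sum(counts[c("AAbb", "aaBB")])
  floor_rf <- if (n_imp > 0) 1e-9 else 0
  fit <- try(stats::optim(
    pmax(c(best$rf, best$rm), floor_rf),
    function(p) -.sexspec_loglik(counts, p[1], p[2]),
    method = "L-BFGS-B",
    lower = pmax(c(best$rf, best$rm) - grid_step, floor_rf),
    upper = pmin(c(best$rf, best$rm) + grid_step, 0.5)
  ), silent = TRUE)
  if (!inherits(fit, "try-error") && is.finite(fit$value) &&
      -fit$value >= max(ll)) {
    est <- sort(fit$par)
    llmax <- -fit$value
  } else {
    est <- c(best$rf, best$rm)
    llmax <- max(ll)
  }
  structure(list(r_f = est[1], r_m = est[2], log_likelihood = llmax),
            class = "sexspecific_estimate")
}

#' @export
print.sexspecific_estimate <- function(x, ...) {
  cat(sprintf("sex-specific estimate: r_f = %.3f, r_m = %.3f (logL = %.3f)\n",
              x$r_f, x$r_m, x$log_likelihood))
  invisible(x)
}
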
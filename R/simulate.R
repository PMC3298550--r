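GENO_CODES <- c("AA", "AB", "BB")

#' Cross configuration
#'
#' Settings for the synthetic cross: sample sizes, noise layers and the
#' RNG seed that fully determines the output.
#'
#' Defaults follow the study design the package emulates: 250 F2 nauplii
#' genotyped from F1 x F1 pairs, plus 19 non-recombinant backcross adults.
#' Genotyping error and missingness default to zero; per-marker viability
#' selection is off by default (mapping on early-stage larvae showed no
#' segregation distortion).
#'
#' @param n_f2 Number of F2 individuals.
#' @param n_nrbc Number of non-recombinant backcross individuals.
#' @param genotyping_error_rate Probability that a call is replaced by one of
#'   the two other genotype codes, uniformly.
#' @param missing_rate Probability that a call is set missing.
#' @param viability_weights Optional numeric matrix (markers x 3, columns
#'   `AA`, `AB`, `BB`, rownames = marker ids) of multiplicative fitness
#'   weights applied to each surviving individual.
#' @param rng_seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return An object of class `cross_config`.
#' @export
cross_config <- function(n_f2 = 250, n_nrbc = 19,
                         genotyping_error_rate = 0, missing_rate = 0,
                         viability_weights = NULL, rng_seed = 1L) {
  stopifnot(is.numeric(n_f2), is.numeric(n_nrbc))
  for (p in c(genotyping_error_rate, missing_rate)) {
    if (is.na(p) || p < 0 || p > 1) stop("rates must lie in [0, 1]")
  }
  if (!is.null(viability_weights)) {
    vw <- as.matrix(viability_weights)
    if (ncol(vw) != 3L || any(vw < 0)) {
      stop("`viability_weights` must be a markers x 3 non-negative matrix")
    }
  }
  structure(list(n_f2 = as.integer(n_f2), n_nrbc = as.integer(n_nrbc),
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate,
                 viability_weights = viability_weights,
                 rng_seed = as.integer(rng_seed)),
            class = "cross_config")
}

#' Genotype matrix
#'
#' Markers x individuals character matrix with calls in `AA` (P1
#' homozygote), `AB` (heterozygote), `BB` (P2 homozygote) or `NA` (missing).
#'
#' @param calls Character matrix (markers in rows).
#' @param markers,individuals Optional dimension names.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, markers = rownames(calls),
                            individuals = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(markers)) markers <- sprintf("M%03d", seq_len(nrow(calls)))
  if (is.null(individuals)) individuals <- sprintf("I%03d", seq_len(ncol(calls)))
  if (length(markers) != nrow(calls) || length(individuals) != ncol(calls)) {
    stop("dimension names inconsistent with the call matrix")
  }
  bad <- !is.na(calls) & !(calls %in% GENO_CODES)
  if (any(bad)) {
    stop("unknown genotype code(s): ",
         paste(unique(calls[bad]), collapse = ", "))
  }
  dimnames(calls) <- list(marker = markers, individual = individuals)
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d individuals (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

# run `expr` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a single gamete
#'
#' Draws one gamete from a phased parent. Female meiosis is achiasmatic:
#' each chromosome is transmitted whole, so the gamete carries one of the two
#' parental haplotypes per chromosome with no within-chromosome switch
#' points. Male meiosis is a first-order Markov chain along each chromosome:
#' the parental-origin label switches between adjacent markers with
#' probability equal to the inverse-Kosambi transform of the intermarker
#' distance.
#'
#' Uses the current RNG stream; seed externally for reproducibility.
#'
#' @param genome A [genome_model()].
#' @param phase List with elements `hap1` and `hap2`: named character vectors
#'   of allele labels, one per marker in `genome`.
#' @param sex `"male"` or `"female"`.
#' @return Named character vector of transmitted alleles (one per marker).
#' @export
simulate_gamete <- function(genome, phase, sex = c("male", "female")) {
  if (!inherits(genome, "genome_model")) stop("`genome` must be a genome_model")
  sex <- match.arg(sex)
  for (h in c("hap1", "hap2")) {
    if (is.null(phase[[h]]) || !all(genome$marker %in% names(phase[[h]]))) {
      stop("`phase$", h, "` must be defined at every marker")
    }
  }
  out <- character(nrow(genome))
  names(out) <- genome$marker
  for (ch in .genome_split(genome)) {
    m <- length(ch$markers)
    if (sex == "female") {
      lab <- rep(sample(1:2, 1L), m)
    } else {
      r <- kosambi_inverse(diff(ch$pos))
      switches <- stats::runif(m - 1L) < r
      lab <- (sample(0:1, 1L) + c(0L, cumsum(switches))) %% 2L + 1L
    }
    hap <- ifelse(lab == 1L, phase$hap1[ch$markers], phase$hap2[ch$markers])
    out[ch$markers] <- hap
  }
  out
}

# vectorized origin labels for n gametes: list of per-chromosome m x n
# integer matrices in {1, 2}; female gametes carry whole chromosomes
.origin_labels <- function(genome, n, sex) {
  lapply(.genome_split(genome), function(ch) {
    m <- length(ch$markers)
    if (sex == "female") {
      matrix(rep(sample(1:2, n, replace = TRUE), each = m), nrow = m)
    } else {
      start <- sample(0:1, n, replace = TRUE)
      if (m == 1L) {
        lab <- matrix(start, nrow = 1L)
      } else {
        r <- kosambi_inverse(diff(ch$pos))
        sw <- matrix(stats::runif((m - 1L) * n) < r, nrow = m - 1L)
        cs <- apply(sw, 2L, cumsum)
        if (m == 2L) cs <- matrix(cs, nrow = 1L)
        lab <- rbind(start, sweep(cs, 2L, start, "+")) %% 2L
      }
      lab + 1L
    }
  })
}

# apply optional per-marker viability selection by rejection sampling
.viability_filter <- function(calls, weights) {
  w <- as.matrix(weights)
  colnames(w) <- GENO_CODES
  if (is.null(rownames(w)) && nrow(w) == nrow(calls)) rownames(w) <- rownames(calls)
  w <- w[rownames(calls), , drop = FALSE]
  logw <- log(w)
  idx <- match(calls, GENO_CODES)
  lw <- matrix(logw[cbind(rep(seq_len(nrow(calls)), ncol(calls)), idx)],
               nrow = nrow(calls))
  indw <- exp(colSums(lw) - sum(apply(logw, 1L, max)))
  stats::runif(ncol(calls)) < indw
}

#' Simulate an F2 intercross
#'
#' Each F2 individual is the union of a non-recombinant female F1 gamete and
#' a recombinant male F1 gamete (female achiasmy), after which optional
#' viability selection, genotyping error and missingness are applied.
#' Deterministic given `config$rng_seed`.
#'
#' @param genome A [genome_model()].
#' @param config A [cross_config()].
#' @return A [genotype_matrix()] of dimension markers x `n_f2`.
#' @export
simulate_f2 <- function(genome, config = cross_config()) {
  if (!inherits(genome, "genome_model")) stop("`genome` must be a genome_model")
  if (config$n_f2 <= 0L) stop("`n_f2` must be positive")
  with_seed(config$rng_seed, {
    calls <- .draw_f2(genome, config$n_f2)
    if (!is.null(config$viability_weights)) {
      keep <- .viability_filter(calls, config$viability_weights)
      calls <- calls[, keep, drop = FALSE]
      while (ncol(calls) < config$n_f2) {
        extra <- .draw_f2(genome, config$n_f2)
        keep <- .viability_filter(extra, config$viability_weights)
        calls <- cbind(calls, extra[, keep, drop = FALSE])
      }
      calls <- calls[, seq_len(config$n_f2), drop = FALSE]
    }
    colnames(calls) <- sprintf("F2_%04d", seq_len(ncol(calls)))
    gm <- genotype_matrix(calls)
    apply_noise(gm, config$genotyping_error_rate, config$missing_rate)
  })
}

.draw_f2 <- function(genome, n) {
  mat <- .origin_labels(genome, n, "female")
  pat <- .origin_labels(genome, n, "male")
  calls <- matrix(NA_character_, nrow(genome), n)
  rownames(calls) <- genome$marker
  chs <- .genome_split(genome)
  for (i in seq_along(chs)) {
    # origin 1 carries the P1 (A) allele, origin 2 the P2 (B) allele
    s <- mat[[i]] + pat[[i]]        # 2 = AA, 3 = AB, 4 = BB
    calls[chs[[i]]$markers, ] <- GENO_CODES[s - 1L]
  }
  calls
}

#' Simulate a non-recombinant backcross
#'
#' Emulates the (P1 female x P2 male) F1 female x P1 male design: the mother
#' is an achiasmatic F1, so each offspring inherits whole maternal
#' chromosomes, and the P1 father contributes only A alleles. With zero
#' noise, every individual is therefore all-`AA` or all-`AB` across each
#' chromosome, and `BB` never occurs.
#'
#' @inheritParams simulate_f2
#' @return A [genotype_matrix()] of dimension markers x `n_nrbc`.
#' @export
simulate_nrbc <- function(genome, config = cross_config()) {
  if (!inherits(genome, "genome_model")) stop("`genome` must be a genome_model")
  if (config$n_nrbc <= 0L) stop("`n_nrbc` must be positive")
  with_seed(config$rng_seed + 1L, {
    mat <- .origin_labels(genome, config$n_nrbc, "female")
    calls <- matrix(NA_character_, nrow(genome), config$n_nrbc)
    rownames(calls) <- genome$marker
    chs <- .genome_split(genome)
    for (i in seq_along(chs)) {
      calls[chs[[i]]$markers, ] <- c("AA", "AB")[mat[[i]]]
    }
    colnames(calls) <- sprintf("BC_%04d", seq_len(config$n_nrbc))
    gm <- genotype_matrix(calls)
    apply_noise(gm, config$genotyping_error_rate, config$missing_rate)
  })
}

#' Corrupt a genotype matrix with error and missingness
#'
#' Each call is independently replaced: with probability `error_rate` by one
#' of the two other genotype codes (chosen uniformly), then with probability
#' `missing_rate` by the missing code. Uses the current RNG stream.
#'
#' @param matrix A [genotype_matrix()].
#' @param error_rate,missing_rate Probabilities in `[0, 1]`.
#' @return A [genotype_matrix()] of the same dimension.
#' @export
apply_noise <- function(matrix, error_rate = 0, missing_rate = 0) {
  for (p in c(error_rate, missing_rate)) {
    if (is.na(p) || p < 0 || p > 1) stop("rates must lie in [0, 1]")
  }
  if (error_rate > 0) {
    hit <- which(!is.na(matrix) & stats::runif(length(matrix)) < error_rate)
    if (length(hit)) {
      cur <- match(matrix[hit], GENO_CODES)
      shift <- sample(1:2, length(hit), replace = TRUE)
      matrix[hit] <- GENO_CODES[(cur - 1L + shift) %% 3L + 1L]
    }
  }
  if (missing_rate > 0) {
    matrix[stats::runif(length(matrix)) < missing_rate] <- NA_character_
  }
  matrix
}
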
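# Independent oracles and fixture builders used across the test files.
# These deliberately avoid the package's own estimation code paths.

CLASS9 <- c("AABB", "AABb", "AAbb", "AaBB", "AaBb", "Aabb",
            "aaBB", "aaBb", "aabb")

full_counts <- function(...) {
  x <- stats::setNames(rep(0L, 9L), CLASS9)
  v <- c(...)
  x[names(v)] <- as.integer(v)
  x
}

# grid-search MLE of the achiasmatic model: maximize the multinomial
# log likelihood over r in [0, 0.5] by exhaustive grid
grid_r_achiasmatic <- function(cnt, step = 1e-4) {
  r <- seq(0, 0.5, by = step)
  n_non <- cnt[["AABB"]] + cnt[["aabb"]] + cnt[["AaBb"]]
  n_rec <- cnt[["AABb"]] + cnt[["AaBB"]] + cnt[["Aabb"]] + cnt[["aaBb"]]
  ll <- rep(0, length(r))
  if (n_non > 0) ll <- ll + n_non * log(1 - r)
  if (n_rec > 0) ll <- ll + n_rec * log(r)
  r[which.max(ll)]  # which.max takes the first max: ties go to smaller r
}

# grid-search MLE of the sex-specific model over [0, 0.5]^2,
# canonicalized to rf <= rm
grid_r_sexspecific <- function(cnt, step = 1e-3) {
  grid <- seq(0, 0.5, by = step)
  nP <- cnt[["AABB"]] + cnt[["aabb"]]
  nI <- cnt[["AAbb"]] + cnt[["aaBB"]]
  nS <- cnt[["AABb"]] + cnt[["AaBB"]] + cnt[["Aabb"]] + cnt[["aaBb"]]
  nH <- cnt[["AaBb"]]
  best <- list(ll = -Inf, rf = NA, rm = NA)
  for (rf in grid) {
    pP <- (1 - rf) * (1 - grid)
    pI <- rf * grid
    pS <- rf * (1 - grid) + grid * (1 - rf)
    ll <- rep(0, length(grid))
    if (nP > 0) ll <- ll + nP * log(pP)
    if (nI > 0) ll <- ll + nI * log(pI)
    if (nS > 0) ll <- ll + nS * log(pS)
    if (nH > 0) ll <- ll + nH * log(pP + pI)
    i <- which.max(ll)
    if (ll[i] > best$ll) best <- list(ll = ll[i], rf = rf, rm = grid[i])
  }
  c(rf = min(best$rf, best$rm), rm = max(best$rf, best$rm))
}

# random pair-count vector with n individuals spread over the classes a
# two-point dataset can produce (impossible classes optionally allowed)
random_counts <- function(n = 200, allow_impossible = FALSE) {
  probs <- stats::runif(9)
  if (!allow_impossible) probs[match(c("AAbb", "aaBB"), CLASS9)] <- 0
  stats::setNames(as.integer(stats::rmultinom(1, n, probs)), CLASS9)
}

# tiny two-marker genome at a given spacing
two_marker_genome <- function(d_cM = 10) {
  genome_model(chrom = c("c1", "c1"), marker = c("m1", "m2"),
               pos_cM = c(0, d_cM))
}

# pairwise-estimate table built by hand from (i, j, r, lod) triples
pw_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(x) {
    data.frame(marker_i = x[[1]], marker_j = x[[2]],
               r_hat = as.numeric(x[[3]]), lod = as.numeric(x[[4]]),
               n = 100L, n_impossible = 0L, stringsAsFactors = FALSE)
  }))
}

# all permutations of a small vector (for exhaustive permutation oracles)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# brute-force syntenic-unit count: enumerate colocalizing pairs and
# count k - 1 per cell via explicit pair counting on a spanning chain
brute_units <- function(map_chrom, ref_chrom) {
  cells <- table(paste(map_chrom, ref_chrom))
  sum(vapply(as.integer(cells), function(k) max(k - 1L, 0L), integer(1)))
}
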
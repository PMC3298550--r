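test_that("single-linkage grouping joins only pairs passing both thresholds", {
  pw <- pw_table(list("m1", "m2", 0.05, 10), list("m2", "m3", 0.05, 10),
                 list("m1", "m3", 0.05, 10), list("m4", "m5", 0.05, 10),
                 list("m1", "m4", 0.5, 0), list("m1", "m5", 0.5, 0),
                 list("m2", "m4", 0.5, 0), list("m2", "m5", 0.5, 0),
                 list("m3", "m4", 0.5, 0), list("m3", "m5", 0.5, 0))
  gr <- group_markers(pw)
  expect_equal(gr, list(c("m1", "m2", "m3"), c("m4", "m5")))

  # high LOD alone is not enough: r above the threshold keeps pairs apart
  pw2 <- pw_table(list("a", "b", 0.45, 2))
  expect_equal(length(group_markers(pw2)), 2L)

  # conjunction the other way: low r but LOD below threshold
  pw3 <- pw_table(list("a", "b", 0.1, 0.5))
  expect_equal(length(group_markers(pw3)), 2L)

  expect_equal(group_markers(pw_table(list("a", "b", 0.5, 0))[0, ]), list())
})

test_that("grouping is invariant to marker and row order", {
  f2 <- simulate_f2(default_genome(3, 15), cross_config(n_f2 = 120, rng_seed = 8))
  pw <- pairwise_estimates(f2)
  gr1 <- group_markers(pw, markers = rownames(f2))
  set.seed(9)
  pw_shuf <- pw[sample(nrow(pw)), ]
  swap <- pw_shuf$marker_i
  pw_shuf$marker_i <- pw_shuf$marker_j
  pw_shuf$marker_j <- swap
  gr2 <- group_markers(pw_shuf, markers = sample(rownames(f2)))
  expect_identical(gr1, gr2)
})

test_that("group ids go to larger groups first, ties to the smallest member", {
  pw <- pw_table(list("z1", "z2", 0.05, 10), list("a1", "a2", 0.05, 10))
  gr <- group_markers(pw)
  expect_equal(gr[[1]], c("a1", "a2"))  # equal size: smaller member first
  pw2 <- pw_table(list("z1", "z2", 0.05, 10), list("z2", "z3", 0.05, 10),
                  list("a1", "a2", 0.05, 10))
  expect_equal(group_markers(pw2)[[1]], c("z1", "z2", "z3"))
})

test_that("three-marker ordering agrees with exhaustive enumeration", {
  pw <- pw_table(list("m1", "m2", 0.05, 10), list("m2", "m3", 0.05, 10),
                 list("m1", "m3", 0.10, 10))
  ord <- order_group(c("m2", "m3", "m1"), pw)
  expect_equal(ord, c("m1", "m2", "m3"))
  # two markers: canonical orientation only
  expect_equal(order_group(c("b", "a"), pw_table(list("a", "b", 0.1, 5))),
               c("a", "b"))
})

test_that("ordering recovers the simulated arrangement at deep coverage", {
  g <- genome_model(rep("c1", 8), sprintf("m%d", 1:8), seq(0, 28, by = 4))
  hits <- 0L
  exhaustive_checked <- 0L
  for (seed in 1:100) {
    f2 <- simulate_f2(g, cross_config(n_f2 = 2000, rng_seed = 200 + seed))
    pw <- pairwise_estimates(f2)
    ord <- order_group(g$marker, pw)
    if (identical(ord, g$marker) || identical(ord, rev(g$marker))) {
      hits <- hits + 1L
    }
    if (seed <= 5) {
      # exhaustive-order oracle: returned order attains the minimum SARF
      D <- achiasmap:::.distance_matrix(g$marker, pw)
      best <- min(vapply(all_perms(g$marker), achiasmap:::.sarf,
                         numeric(1), D = D))
      expect_equal(achiasmap:::.sarf(ord, D), best, tolerance = 1e-9)
      exhaustive_checked <- exhaustive_checked + 1L
    }
  }
  expect_gte(hits, 95L)
  expect_equal(exhaustive_checked, 5L)
})

test_that("SARF of the returned order never exceeds the truth's SARF", {
  g <- default_genome(2, 16)
  f2 <- simulate_f2(g, cross_config(n_f2 = 300, rng_seed = 31))
  pw <- pairwise_estimates(f2)
  for (ch in unique(g$chrom)) {
    mk <- g$marker[g$chrom == ch]
    ord <- order_group(mk, pw)
    D <- achiasmap:::.distance_matrix(mk, pw)
    expect_lte(achiasmap:::.sarf(ord, D), achiasmap:::.sarf(mk, D) + 1e-9)
  }
})

test_that("map positions are cumulative Kosambi distances", {
  pw <- pw_table(list("m1", "m2", 0.05, 10), list("m2", "m3", 0.05, 10),
                 list("m1", "m3", 0.10, 10))
  map <- build_map(list(c("m1", "m2", "m3")), pw)
  expect_equal(map$pos_cM, c(0, 5.017, 10.034), tolerance = 1e-3)

  # single-marker group has length zero
  map1 <- build_map(list("solo"), pw)
  expect_equal(group_lengths(map1)$length_cM, 0)

  # unlinked adjacency is clamped with a warning
  pw2 <- pw_table(list("a", "b", 0.5, 0))
  expect_warning(map2 <- build_map(list(c("a", "b")), pw2), "clamped")
  expect_lt(max(map2$pos_cM), kosambi(0.49995))
})

test_that("map positions are mirror-symmetric under order reversal", {
  pw <- pw_table(list("m1", "m2", 0.1, 10), list("m2", "m3", 0.2, 10),
                 list("m1", "m3", 0.3, 10))
  fwd <- build_map(list(c("m1", "m2", "m3")), pw)
  rev_ <- build_map(list(c("m3", "m2", "m1")), pw)
  L <- max(fwd$pos_cM)
  expect_equal(rev_$pos_cM[match(fwd$marker, rev_$marker)],
               L - fwd$pos_cM, tolerance = 1e-10)
})

test_that("summed map length tracks the generating genome", {
  g <- default_genome(3, 30)
  f2 <- simulate_f2(g, cross_config(n_f2 = 1000, rng_seed = 77))
  pw <- pairwise_estimates(f2)
  groups <- group_markers(pw, markers = rownames(f2))
  map <- build_map(lapply(groups, order_group, pairwise = pw), pw)
  truth <- sum(tapply(g$pos_cM, g$chrom, max))
  est <- sum(group_lengths(map)$length_cM)
  expect_equal(est, truth, tolerance = 0.1)
})

test_that("non-recombinant backcross confirms clean linkage groups", {
  g <- default_genome(4, 32)
  f2 <- simulate_f2(g, cross_config(n_f2 = 250, rng_seed = 55))
  pw <- pairwise_estimates(f2)
  groups <- group_markers(pw, markers = rownames(f2))
  map <- build_map(lapply(groups, order_group, pairwise = pw), pw)
  bc <- simulate_nrbc(g, cross_config(n_nrbc = 19, rng_seed = 55))
  conf <- confirm_with_nrbc(map, bc)
  expect_true(conf$all_consistent)
  expect_equal(nrow(conf$flagged_pairs), 0L)

  # artificially split one group: the fragments co-segregate and are flagged
  groups_split <- c(list(groups[[1]][1:4], groups[[1]][-(1:4)]), groups[-1])
  map_split <- build_map(lapply(groups_split, order_group, pairwise = pw), pw)
  conf2 <- confirm_with_nrbc(map_split, bc)
  expect_true(conf2$all_consistent)  # fragments are internally consistent
  expect_equal(nrow(conf2$flagged_pairs), 1L)
  expect_equal(unlist(conf2$flagged_pairs, use.names = FALSE), c(1L, 2L))
})

test_that("a single discordant call breaks confirmation at zero tolerance", {
  g <- genome_model(rep("c1", 15), sprintf("m%02d", 1:15), seq(0, 28, 2))
  bc <- simulate_nrbc(g, cross_config(n_nrbc = 19, rng_seed = 66))
  map <- build_map(list(g$marker), pairwise_estimates(
    simulate_f2(g, cross_config(n_f2 = 200, rng_seed = 66))))
  flip <- function(x) if (x == "AA") "AB" else "AA"
  bc["m05", 3] <- flip(bc["m05", 3])
  conf <- confirm_with_nrbc(map, bc, max_mismatch_rate = 0)
  expect_false(conf$groups$consistent[1])
  # but a tolerant threshold accepts it
  conf2 <- confirm_with_nrbc(map, bc, max_mismatch_rate = 0.1)
  expect_true(conf2$groups$consistent[1])
})

test_that("BB calls in the backcross warn and count as mismatches", {
  g <- genome_model(rep("c1", 4), sprintf("m%d", 1:4), c(0, 2, 4, 6))
  bc <- simulate_nrbc(g, cross_config(n_nrbc = 10, rng_seed = 3))
  map <- build_map(list(g$marker), pairwise_estimates(
    simulate_f2(g, cross_config(n_f2 = 100, rng_seed = 3))))
  bc["m2", 1] <- "BB"
  expect_warning(conf <- confirm_with_nrbc(map, bc), "BB")
  expect_false(conf$groups$consistent[1])
})
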
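test_that("default genome has the configured shape", {
  g <- default_genome()
  lens <- tapply(g$pos_cM, g$chrom, max)
  expect_equal(nrow(g), 190)
  expect_equal(length(lens), 12L)
  expect_equal(unname(range(lens)), c(19, 32))
  expect_false(anyDuplicated(g$marker) > 0)
})

test_that("genome model validation rejects malformed input", {
  expect_error(genome_model("c1", c("a", "a"), c(0, 1)), "equal length")
  expect_error(genome_model(c("c1", "c1"), c("a", "a"), c(0, 1)), "unique")
  expect_error(genome_model(c("c1", "c1"), c("a", "b"), c(2, 1)),
               "non-decreasing")
})

test_that("simulation is bit-identical under a fixed seed", {
  g <- default_genome(4, 40)
  cc <- cross_config(n_f2 = 50, genotyping_error_rate = 0.02,
                     missing_rate = 0.05, rng_seed = 7)
  expect_identical(simulate_f2(g, cc), simulate_f2(g, cc))
  expect_identical(simulate_nrbc(g, cc), simulate_nrbc(g, cc))
  cc2 <- cross_config(n_f2 = 50, genotyping_error_rate = 0.02,
                      missing_rate = 0.05, rng_seed = 8)
  expect_false(identical(simulate_f2(g, cc), simulate_f2(g, cc2)))
})

test_that("female gametes carry whole parental chromosomes", {
  g <- genome_model(chrom = rep(c("c1", "c2"), each = 4),
                    marker = sprintf("m%d", 1:8),
                    pos_cM = rep(c(0, 5, 12, 30), 2))
  phase <- list(hap1 = stats::setNames(rep("A", 8), g$marker),
                hap2 = stats::setNames(rep("B", 8), g$marker))
  set.seed(11)
  for (i in 1:50) {
    gam <- simulate_gamete(g, phase, sex = "female")
    for (ch in unique(g$chrom)) {
      expect_length(unique(gam[g$marker[g$chrom == ch]]), 1L)
    }
  }
})

test_that("male switch frequency matches inverse-Kosambi of the spacing", {
  g <- two_marker_genome(10)
  phase <- list(hap1 = c(m1 = "A", m2 = "A"), hap2 = c(m1 = "B", m2 = "B"))
  set.seed(5)
  switches <- replicate(10000, {
    gam <- simulate_gamete(g, phase, sex = "male")
    gam["m1"] != gam["m2"]
  })
  expect_equal(mean(switches), 0.0987, tolerance = 0.01 / 0.0987)
})

test_that("markers at identical positions never separate in male meiosis", {
  g <- genome_model(c("c1", "c1"), c("m1", "m2"), c(3, 3))
  phase <- list(hap1 = c(m1 = "A", m2 = "A"), hap2 = c(m1 = "B", m2 = "B"))
  set.seed(2)
  for (i in 1:200) {
    gam <- simulate_gamete(g, phase, sex = "male")
    expect_identical(gam[["m1"]], gam[["m2"]])
  }
})

test_that("gamete simulation validates its inputs", {
  g <- two_marker_genome()
  phase <- list(hap1 = c(m1 = "A", m2 = "A"), hap2 = c(m1 = "B", m2 = "B"))
  expect_error(simulate_gamete(g, phase, sex = "hermaphrodite"))
  expect_error(simulate_gamete(g, list(hap1 = phase$hap1), "male"), "hap2")
  expect_error(simulate_f2(g, cross_config(n_f2 = 0)), "positive")
  expect_error(simulate_nrbc(g, cross_config(n_nrbc = -1)), "positive")
})

test_that("clean F2 never pairs opposite homozygotes at coincident markers", {
  g <- genome_model(c("c1", "c1", "c1"), c("m1", "m2", "m3"), c(0, 0, 20))
  f2 <- simulate_f2(g, cross_config(n_f2 = 400, rng_seed = 3))
  a <- f2["m1", ]; b <- f2["m2", ]
  expect_false(any((a == "AA" & b == "BB") | (a == "BB" & b == "AA")))
})

test_that("two-point estimates recover the simulation truth", {
  # adjacent markers at 1-30 cM: closed-form r-hat within 3 SE of
  # inverse-Kosambi truth at n = 10,000
  for (d in c(1, 10, 30)) {
    g <- two_marker_genome(d)
    f2 <- simulate_f2(g, cross_config(n_f2 = 10000, rng_seed = 40 + d))
    est <- estimate_r_achiasmatic(count_pair_classes(f2, "m1", "m2"))
    r_true <- kosambi_inverse(d)
    se <- sqrt(r_true * (1 - r_true) / 10000)
    expect_lt(abs(est$r_hat - r_true), 3 * se)
  }
  expect_equal(kosambi_inverse(10), 0.0987, tolerance = 1e-3)
})

test_that("markers on different chromosomes are estimated unlinked", {
  g <- genome_model(c("c1", "c2"), c("m1", "m2"), c(0, 0))
  f2 <- simulate_f2(g, cross_config(n_f2 = 10000, rng_seed = 9))
  est <- estimate_r_achiasmatic(count_pair_classes(f2, "m1", "m2"))
  expect_equal(est$r_hat, 0.5, tolerance = 0.02 / 0.5)
  # impossible classes arise at rate 1/8 for unlinked cross-chromosome pairs
  expect_gt(est$n_impossible, 0)
})

test_that("single-marker genotype frequencies segregate 1:2:1", {
  g <- default_genome(2, 10)
  flagged <- 0L
  for (seed in 1:20) {
    f2 <- simulate_f2(g, cross_config(n_f2 = 250, rng_seed = 100 + seed))
    seg <- segregation_test(f2, chi2_flag_threshold = qchisq(0.999, 1))
    flagged <- flagged + sum(seg$flagged)
  }
  # 200 marker-tests at alpha = 0.001: more than 2 flags would be surprising
  expect_lte(flagged, 2L)
})

test_that("non-recombinant backcross has the expected structure", {
  g <- default_genome(4, 40)
  bc <- simulate_nrbc(g, cross_config(n_nrbc = 1000, rng_seed = 12))
  expect_false(any(bc == "BB", na.rm = TRUE))
  for (ch in unique(g$chrom)) {
    sub <- bc[g$marker[g$chrom == ch], ]
    per_ind <- apply(sub, 2, function(x) length(unique(x)))
    expect_true(all(per_ind == 1L))
    frac_ab <- mean(sub[1, ] == "AB")
    expect_equal(frac_ab, 0.5, tolerance = 0.1 / 0.5)
  }
})

test_that("noise layers corrupt calls at the configured rates", {
  g <- default_genome()
  f2 <- simulate_f2(g, cross_config(n_f2 = 250, rng_seed = 21))
  set.seed(33)
  expect_identical(apply_noise(f2, 0, 0), f2)
  all_err <- apply_noise(f2, 1, 0)
  expect_true(all(all_err != f2, na.rm = TRUE))
  expect_equal(mean(is.na(all_err)), 0)
  miss <- apply_noise(f2, 0, 0.1)
  expect_equal(mean(is.na(miss)), 0.1, tolerance = 0.01 / 0.1)
  expect_error(apply_noise(f2, -0.1, 0), "\\[0, 1\\]")
  expect_error(apply_noise(f2, 0, 1.5), "\\[0, 1\\]")
})

test_that("viability selection shifts genotype frequencies", {
  g <- genome_model("c1", "m1", 0)
  w <- matrix(c(0.2, 1, 1), nrow = 1,
              dimnames = list("m1", c("AA", "AB", "BB")))
  f2 <- simulate_f2(g, cross_config(n_f2 = 2000, rng_seed = 5,
                                    viability_weights = w))
  expect_equal(ncol(f2), 2000L)
  tab <- table(factor(f2["m1", ], levels = c("AA", "AB", "BB")))
  # expected 0.2 : 2 : 1 after selection
  expect_lt(tab[["AA"]] / tab[["BB"]], 0.5)
})
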
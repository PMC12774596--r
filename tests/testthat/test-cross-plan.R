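test_that("expected_donor_fraction follows the analytic recurrence", {
  f1_only <- cross_plan("F1", "founder", 100, 1.5)
  expect_equal(expected_donor_fraction(f1_only), 0.5)
  expect_equal(expected_donor_fraction(fig_plan_iterative_backcross()),
               0.0234375)
  no_donor <- cross_plan(paste0("F", 1:6),
                         c("founder", rep("BY", 5)),
                         rep(100, 6), rep(1.5, 6))
  expect_equal(expected_donor_fraction(no_donor), 0.015625)
})

test_that("Monte-Carlo neutral lineages agree with the recurrence within 3 SE", {
  map <- small_map(500, seed = 1)
  plan <- cross_plan(paste0("F", 1:6), c("founder", rep("BY", 5)),
                     rep(10, 6), rep(1.5, 6))
  frac <- simulate_neutral_donor_fraction(plan, map, n_lineages = 2000,
                                          seed = 1)
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.015625), 3 * se)
})

test_that("cross plans are validated", {
  expect_error(cross_plan("F1", "BY", 10, 1.5), "founder")
  expect_error(cross_plan(c("F1", "F2"), c("founder", "founder"),
                          c(10, 10), c(1.5, 1.5)), "founder")
  expect_error(cross_plan("F1", "founder", 0, 1.5), "positive")
  expect_error(cross_plan(c("F1", "F2"), c("founder", "Sigma"),
                          c(10, 10), c(1.5, 1.5)))
})

test_that("genetic_value matches brute-force enumeration of genotypes", {
  map <- small_map(100, seed = 2)
  # empty locus list: 0 for every genotype
  t0 <- trait_model(NULL, noise_sd = 0)
  origins <- rbind(rep(0L, nrow(map)), rep(1L, nrow(map)))
  expect_equal(genetic_value(origins, map, t0, 1.5), c(0, 0))

  # single locus: BY-carrier minus CENPK-carrier difference is the effect
  l1 <- snap_locus_to_marker(map, "chrIV", 500000) |>
    dplyr::mutate(effect = 0.7, conc_scaling = 1)
  t1 <- trait_model(l1, noise_sd = 0)
  gv <- genetic_value(origins, map, t1, 1.0)
  expect_equal(gv[1] - gv[2], 0.7)

  # two loci: all four genotypes enumerate to the additive sums
  l2 <- dplyr::bind_rows(
    snap_locus_to_marker(map, "chrIV", 500000) |>
      dplyr::mutate(effect = 0.7, conc_scaling = 1),
    snap_locus_to_marker(map, "chrIX", 100000) |>
      dplyr::mutate(effect = -0.2, conc_scaling = 1))
  t2 <- trait_model(l2, noise_sd = 0)
  i4 <- which(map$chrom == l2$chrom[1] & map$pos == l2$pos[1])
  i9 <- which(map$chrom == l2$chrom[2] & map$pos == l2$pos[2])
  conc <- 2.0
  for (a in 0:1) {
    for (b in 0:1) {
      g <- rep(0L, nrow(map))
      g[i4] <- a; g[i9] <- b
      want <- (1 - a) * 0.7 * conc + (1 - b) * (-0.2) * conc
      expect_equal(genetic_value(g, map, t2, conc), want)
    }
  }
})

test_that("genetic_value rejects off-map loci and off-grid concentrations", {
  map <- small_map(50, seed = 3)
  bad <- trait_model(tibble::tibble(chrom = "chrIV", pos = 123L, effect = 1,
                                    conc_scaling = 1))
  g <- rep(0L, nrow(map))
  expect_error(genetic_value(g, map, bad, 1.5), "not on the marker map")
  ok <- major_only_trait(map)
  expect_error(genetic_value(g, map, ok, 0.33), "grid")
})

test_that("with zero noise the extreme segregant carries the superior allele", {
  map <- small_map(150, seed = 4)
  trait <- trait_model(default_trait_loci(map)[1, ], noise_sd = 0)
  plan <- cross_plan("F1", "founder", 50, 1.5)
  pop <- run_cross_plan(plan, map, trait, seed = 6)[[1]]
  locus <- trait$loci
  i <- which(map$chrom == locus$chrom & map$pos == locus$pos)
  expect_identical(pop$origins[pop$selected, i], 0L)  # BY allele (positive effect)
  conc_col <- which(pop$concentrations == 1.5)
  expect_equal(max(pop$phenotypes[, conc_col]),
               unname(pop$phenotypes[pop$selected, conc_col]))
})

test_that("run_cross_plan returns all generations with consistent shapes", {
  map <- small_map(120, seed = 5)
  trait <- trait_model(default_trait_loci(map), noise_sd = 0.1)
  plan <- desk_plan(n_offspring = 40)
  pops <- run_cross_plan(plan, map, trait, seed = 1)
  expect_named(pops, paste0("F", 1:7))
  for (pop in pops) {
    expect_s3_class(pop, "segregant_population")
    expect_equal(dim(pop$origins), c(40L, nrow(map)))
    expect_equal(dim(pop$phenotypes),
                 c(40L, length(trait$concentrations)))
  }
  td <- generics::tidy(pops$F1)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 40 * length(trait$concentrations))
  expect_true(all(donor_fraction(pops$F1) >= 0 &
                    donor_fraction(pops$F1) <= 1))
})

test_that("identical seeds reproduce the whole cross exactly", {
  map <- small_map(80, seed = 6)
  trait <- trait_model(default_trait_loci(map), noise_sd = 0.1)
  plan <- cross_plan(c("F1", "F2"), c("founder", "BY"), c(30, 30),
                     c(1.5, 1.5))
  a <- run_cross_plan(plan, map, trait, seed = 99)
  b <- run_cross_plan(plan, map, trait, seed = 99)
  expect_identical(a, b)
})
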
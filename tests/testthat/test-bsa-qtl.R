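fake_records <- function(n = 6) {
  tibble::tibble(
    CHROM = "chrI", POS = as.integer(seq(1000, by = 1000, length.out = n)),
    REF = "A", ALT = "T",
    AD_REF.LOW = 60L, AD_ALT.LOW = 60L,
    AD_REF.HIGH = 60L, AD_ALT.HIGH = 60L,
    DP = 240L, QD = 25, MQRankSum = 0)
}

test_that("filter_variants applies the depth and quality rules", {
  rec <- fake_records(5)
  rec$DP <- c(100L, 101L, 240L, 240L, 240L)      # depth must be > 100
  rec$QD <- c(25, 25, 1.9, 2.0, 25)              # keep QD >= 2.0
  rec$MQRankSum <- c(0, 0, 0, 0, -5.1)           # keep MQRankSum >= -5.0
  kept <- filter_variants(rec)
  expect_equal(kept$POS, c(2000L, 4000L))
  rej <- attr(kept, "rejections")
  expect_equal(rej[["depth"]], 1L)
  expect_equal(rej[["quality_by_depth"]], 1L)
  expect_equal(rej[["mq_rank_sum"]], 1L)
  # boundary values are kept
  rec2 <- fake_records(1)
  rec2$QD <- 2.0; rec2$MQRankSum <- -5.0
  expect_equal(nrow(filter_variants(rec2)), 1)
  # per-pool scope requires each pool to exceed the threshold
  rec3 <- fake_records(1)
  rec3$AD_REF.LOW <- 30L; rec3$AD_ALT.LOW <- 30L  # LOW depth 60
  rec3$DP <- 60L + 120L
  expect_equal(nrow(filter_variants(rec3, depth_scope = "per_pool")), 0)
  expect_equal(nrow(filter_variants(rec3, depth_scope = "combined")), 1)
})

test_that("allele_frequency handles the documented cases", {
  expect_equal(allele_frequency(30, 70), 0.7)
  expect_equal(allele_frequency(50, 50), 0.5)
  expect_equal(allele_frequency(0, 120), 1)
  expect_true(is.na(allele_frequency(0, 0)))
  expect_error(allele_frequency(-1, 10))
})

test_that("window medians use the fixed-window and median conventions", {
  rec <- tibble::tibble(
    CHROM = "chrI",
    POS = c(100L, 300L, 700L, 1500L, 3200L, 3300L, 3400L, 3500L),
    AD_REF.LOW = 50L, AD_ALT.LOW = 50L,
    AD_REF.HIGH = 0L, AD_ALT.HIGH = 0L)
  rec$freq_LOW <- c(0.2, 0.5, 0.9, 0.4, 0.2, 0.4, 0.6, 0.8)
  rec$freq_HIGH <- rec$freq_LOW
  med <- window_median_frequency(rec, window_bp = 1000)
  # window 1: odd-count median of {0.2, 0.5, 0.9} = 0.5
  expect_equal(med$median_freq_LOW[med$window_start == 1], 0.5)
  # window 2: single SNP keeps its own frequency
  expect_equal(med$median_freq_LOW[med$window_start == 1001], 0.4)
  # window 4: even-count mean-of-middle convention on {0.2,0.4,0.6,0.8} = 0.5
  expect_equal(med$median_freq_LOW[med$window_start == 3001], 0.5)
  # window 3 (2001-3000) has no SNPs: emitted as a gap
  expect_false(any(med$window_start == 2001))
})

test_that("g_statistic reproduces the hand-computed oracles", {
  expect_equal(g_statistic(20, 0, 0, 20), 80 * log(2), tolerance = 1e-12)
  expect_equal(g_statistic(15, 5, 5, 15), g_oracle(15, 5, 5, 15),
               tolerance = 1e-12)
  expect_equal(round(g_statistic(15, 5, 5, 15), 3), 10.465)
  # zero marginal -> G = 0 by convention
  expect_equal(g_statistic(50, 0, 70, 0), 0)
  expect_equal(suppressWarnings(g_statistic(0, 0, 0, 0)), 0)
  expect_error(g_statistic(-1, 2, 3, 4))
})

test_that("G equals the brute-force likelihood-ratio oracle on 1,000 random tables", {
  withr::with_seed(101, {
    tabs <- matrix(stats::rpois(4000, lambda = 30), ncol = 4)
  })
  tabs <- tabs[rowSums(tabs) > 0, , drop = FALSE]
  g <- g_statistic(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  ref <- g_oracle(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  expect_lt(max(abs(g - ref)), 1e-9)
  expect_true(all(g >= 0))
})

test_that("tricube_gprime matches a brute-force oracle and respects boundaries", {
  withr::with_seed(33, {
    track <- tibble::tibble(
      CHROM = rep(c("chrI", "chrII"), each = 40),
      POS = as.integer(c(sort(sample.int(100000, 40)),
                         sort(sample.int(100000, 40)))),
      G = stats::rexp(80))
  })
  out <- tricube_gprime(track, window_bp = 20000)
  for (ch in c("chrI", "chrII")) {
    d <- out[out$CHROM == ch, ]
    ref <- tricube_oracle(d$POS, d$G, 20000)
    expect_lt(max(abs(d$Gprime - ref)), 1e-12)
    # G' stays within the min/max of its window (weighted mean)
    expect_true(all(d$Gprime >= min(d$G) - 1e-12 &
                      d$Gprime <= max(d$G) + 1e-12))
  }
})

test_that("an isolated SNP gets its own G and constant windows stay constant", {
  iso <- tibble::tibble(CHROM = c("chrI", "chrII"), POS = c(500L, 500L),
                        G = c(3.2, 1.1))
  out <- tricube_gprime(iso, window_bp = 20000)
  expect_equal(out$Gprime, out$G)
  const <- tibble::tibble(CHROM = "chrI",
                          POS = as.integer(seq(1000, 30000, by = 500)),
                          G = 2.5)
  expect_equal(tricube_gprime(const, 20000)$Gprime,
               rep(2.5, nrow(const)))
})

test_that("estimate_null recovers lognormal parameters within 5%", {
  withr::with_seed(11, {
    g <- stats::rlnorm(10000, meanlog = 1, sdlog = 0.5)
  })
  null <- estimate_null(g)
  expect_lt(abs(null$meanlog - 1) / 1, 0.05)
  expect_lt(abs(null$sdlog - 0.5) / 0.5, 0.05)
  # robust to 2% contamination inflated 20x
  g2 <- g
  idx <- seq_len(200)
  g2[idx] <- g2[idx] * 20
  null2 <- estimate_null(g2)
  expect_lt(abs(null2$meanlog - 1) / 1, 0.05)
  expect_lt(abs(null2$sdlog - 0.5) / 0.5, 0.05)
  expect_gt(null2$n_trimmed, 0)
  expect_error(estimate_null(rep(2, 100)), "MAD|degenerate")
  expect_error(estimate_null(stats::rlnorm(10)), "50")
})

test_that("p_values implement the threshold arithmetic and calibration", {
  null <- structure(list(meanlog = 0.5, sdlog = 0.4, n_used = 1000L,
                         n_trimmed = 0L, hampel_c = 5.2),
                    class = "gprime_null")
  q95 <- stats::qlnorm(0.95, 0.5, 0.4)
  med <- stats::qlnorm(0.5, 0.5, 0.4)
  track <- tibble::tibble(CHROM = "chrI", POS = c(1000L, 2000L),
                          Gprime = c(q95, med))
  out <- p_values(track, null)
  expect_equal(out$p[1], 0.05, tolerance = 1e-12)
  expect_equal(round(out$neglog10p[1], 2), 1.30)
  expect_equal(out$neglog10p[2], -log10(0.5), tolerance = 1e-12)
  expect_true("q" %in% names(out))
  # marginal calibration: pure-null track at n = 5,000 is near-uniform
  withr::with_seed(17, {
    g <- stats::rlnorm(5000, 0.5, 0.4)
  })
  tr <- tibble::tibble(CHROM = "chrI",
                       POS = as.integer(seq_len(5000)), Gprime = g)
  fitted <- estimate_null(g)
  p <- p_values(tr, fitted)$p
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("interval calling reproduces block boundaries and merge behavior", {
  track <- block_track(list(
    list(chrom = "chrIV", start = 503000, end = 655000),
    list(chrom = "chrIX", start = 97000, end = 134000)))
  iv <- call_qtl_intervals(track)
  expect_equal(nrow(iv), 2)
  iv4 <- iv[iv$CHROM == "chrIV", ]
  expect_equal(iv4$start, 503000)
  expect_equal(iv4$end, 655000)
  expect_equal(iv4$width, 152000)
  expect_equal(iv[iv$CHROM == "chrIX", ]$width, 37000)

  # two blocks separated by more than merge_gap -> two intervals
  far <- block_track(list(
    list(chrom = "chrII", start = 100000, end = 110000),
    list(chrom = "chrII", start = 150000, end = 160000)))
  expect_equal(nrow(call_qtl_intervals(far)), 2)
  # separated by less than merge_gap -> one interval
  near <- block_track(list(
    list(chrom = "chrII", start = 100000, end = 110000),
    list(chrom = "chrII", start = 125000, end = 135000)))
  expect_equal(nrow(call_qtl_intervals(near)), 1)
  expect_equal(call_qtl_intervals(near)$width, 35000)

  # all SNPs below the threshold -> empty list
  none <- block_track(list())
  expect_equal(nrow(call_qtl_intervals(none)), 0)
  # an unreachable threshold empties any track
  expect_equal(nrow(call_qtl_intervals(track, neglog_threshold = 99)), 0)
})

test_that("the FDR cut suppresses isolated marginal SNPs but max_q = NULL keeps them", {
  track <- block_track(list(
    list(chrom = "chrIV", start = 503000, end = 655000)),
    background_n = 400)
  # one isolated SNP just past the raw threshold
  track <- dplyr::bind_rows(
    track, tibble::tibble(CHROM = "chrX", POS = 50000L,
                          neglog10p = 1.5, p = 10^-1.5))
  with_q <- call_qtl_intervals(track)
  expect_false("chrX" %in% with_q$CHROM)
  without_q <- call_qtl_intervals(track, max_q = NULL)
  expect_true("chrX" %in% without_q$CHROM)
})

test_that("gprime_scan runs end to end with the documented structure", {
  sim <- simulate_f1_pool_experiment(n_markers = 400, n_pop = 2000, seed = 5)
  scan <- gprime_scan(sim$pools)
  expect_s3_class(scan, "gprime_scan")
  expect_true(all(c("G", "Gprime", "p", "neglog10p", "q", "freq_LOW",
                    "freq_HIGH") %in% names(scan$track)))
  expect_true(all(scan$track$p > 0 & scan$track$p <= 1))
  expect_true(all(scan$track$G >= 0))
  gl <- generics::glance(scan)
  expect_equal(gl$n_snps, nrow(scan$track))
  td <- generics::tidy(scan)
  expect_s3_class(td, "tbl_df")
  # direction property: intervals carry the sign of the configured effects
  if (nrow(scan$intervals) > 0) {
    top <- scan$intervals[1, ]
    loci <- sim$trait$loci
    if (top$CHROM == loci$chrom[1]) expect_lt(top$mean_freq_shift, 0)
    if (top$CHROM == loci$chrom[2]) expect_gt(top$mean_freq_shift, 0)
  }
})
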
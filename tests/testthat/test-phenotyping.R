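test_that("relative_tolerance matches the normalization equation", {
  # test sizes equal to reference means on both plates -> exactly 1
  expect_equal(relative_tolerance(20, c(18, 22), 10, c(9, 11)), 1)
  # NaCl size half the reference mean with a YPD ratio of 1 -> 0.5
  expect_equal(relative_tolerance(10, c(20, 20), 10, c(10, 10)), 0.5)
  # direct arithmetic: (30/20) / (15/10) = 1
  expect_equal(relative_tolerance(30, c(20, 20), 15, c(10, 10)), 1)
})

test_that("relative_tolerance flags and validates degenerate inputs", {
  expect_warning(out <- relative_tolerance(10, c(20, 20), 0, c(10, 10)),
                 "zero")
  expect_true(is.na(out))
  expect_error(relative_tolerance(10, c(0, 0), 10, c(10, 10)), "positive")
  expect_error(relative_tolerance(10, numeric(), 10, c(10, 10)))
  expect_error(relative_tolerance(-1, c(20, 20), 10, c(10, 10)))
})

test_that("relative tolerance is invariant under per-plate scaling", {
  base <- relative_tolerance(13, c(17, 21), 8, c(9, 12))
  scaled_nacl <- relative_tolerance(13 * 3.7, c(17, 21) * 3.7, 8, c(9, 12))
  scaled_ypd <- relative_tolerance(13, c(17, 21), 8 * 0.2, c(9, 12) * 0.2)
  expect_equal(scaled_nacl, base)
  expect_equal(scaled_ypd, base)
})

test_that("assign_class implements the half-open right-closed 0.05 bins", {
  expect_identical(assign_class(1.0), 20L)
  expect_identical(assign_class(0.98), 20L)
  expect_identical(assign_class(0.05), 1L)
  expect_identical(assign_class(0.051), 2L)
  expect_identical(assign_class(0), 1L)
  # monotone non-decreasing over a dense grid
  v <- seq(0, 3, by = 0.001)
  expect_true(all(diff(assign_class(v)) >= 0))
  expect_error(assign_class(-0.1))
})

test_that("plate_tolerance joins plates and is invariant to plate effects", {
  nacl <- tibble::tibble(strain = c("ref", "ref", "a", "b"),
                         row = 1:4, col = 1L,
                         size = c(18, 22, 20, 10),
                         is_reference = c(TRUE, TRUE, FALSE, FALSE))
  ypd <- tibble::tibble(strain = c("ref", "ref", "a", "b"),
                        row = 1:4, col = 1L,
                        size = c(9, 11, 10, 10),
                        is_reference = c(TRUE, TRUE, FALSE, FALSE))
  tol <- plate_tolerance(nacl, ypd)
  expect_equal(tol$tolerance[tol$strain == "a"], 1)
  expect_equal(tol$class[tol$strain == "a"], 20L)
  scaled <- nacl
  scaled$size <- scaled$size * 5
  tol2 <- plate_tolerance(scaled, ypd)
  expect_equal(tol2$tolerance, tol$tolerance)
  # zero control size is flagged missing, not zero tolerance
  ypd0 <- ypd
  ypd0$size[3] <- 0
  tol3 <- plate_tolerance(nacl, ypd0)
  expect_true(is.na(tol3$tolerance[tol3$strain == "a"]))
  expect_equal(tol3$flag[tol3$strain == "a"], "zero_control")
})

test_that("class_histogram covers the observed range with zero counts", {
  h <- class_histogram(c(0.22, 0.23, 0.41))  # classes 5, 5, 9
  expect_equal(h$class, 5:9)
  expect_equal(h$count, c(2L, 0L, 0L, 0L, 1L))
})

test_that("a constant-zero curve yields all-zero growth parameters", {
  gp <- fit_growth_params(time = seq(0, 90, by = 10), size = rep(0, 10))
  expect_equal(gp$max_rate, 0)
  expect_equal(gp$auc, 0)
  expect_equal(gp$max_value, 0)
  expect_equal(gp$lag, 0)
})

test_that("logistic curves recover the analytic maximum rate r*K/4", {
  t <- seq(0, 2000, by = 10)
  r <- 0.01; K <- 2; t0 <- 1000
  y <- K / (1 + exp(-r * (t - t0)))
  gp <- fit_growth_params(t, y)
  expect_lt(abs(gp$max_rate - r * K / 4) / (r * K / 4), 0.05)
  expect_equal(gp$max_value, K, tolerance = 0.01)
})

test_that("lag is shift-equivariant within one sampling interval", {
  t <- seq(0, 3000, by = 10)
  r <- 0.01; K <- 2
  y1 <- K / (1 + exp(-r * (t - 1000)))
  y2 <- K / (1 + exp(-r * (t - 1200)))
  lag1 <- fit_growth_params(t, y1)$lag
  lag2 <- fit_growth_params(t, y2)$lag
  expect_lte(abs((lag2 - lag1) - 200), 10)
})

test_that("AUC is additive over time splits and max rate scales linearly", {
  t <- seq(0, 500, by = 10)
  withr::with_seed(21, {
    y <- cumsum(stats::runif(length(t)))
  })
  full <- fit_growth_params(t, y)$auc
  k <- 26
  left <- fit_growth_params(t[1:k], y[1:k])$auc
  right <- fit_growth_params(t[k:length(t)], y[k:length(t)])$auc
  expect_equal(left + right, full)
  # scaling the curve scales the maximum rate
  r1 <- fit_growth_params(t, y)$max_rate
  r3 <- fit_growth_params(t, 3 * y)$max_rate
  expect_equal(r3, 3 * r1)
})

test_that("fit_growth_params validates its inputs", {
  expect_error(fit_growth_params(1:3, 1:3), ">= 4")
  expect_error(fit_growth_params(c(1, 2, 2, 3), 1:4), "increasing")
  expect_error(fit_growth_params(1:5, c(1, 2, 3, 4, -1)))
  expect_error(fit_growth_params(1:5, 1:5, smoothing_window = 4), "odd")
})

test_that("nested_relative_params maps the wild type to exactly 1", {
  expect_equal(nested_relative_params(2, 4, 2, 4), 1)
  # a derivative at 1.65x the wild-type relative rate -> 1.65
  expect_equal(nested_relative_params(2 * 1.65, 4, 2, 4), 1.65)
  # common multiplicative plate effects cancel
  expect_equal(nested_relative_params(3 * 7, 5 * 2, 2 * 7, 4 * 2,
                                      grid_nacl = 7, grid_ypd = 2),
               nested_relative_params(3, 5, 2, 4))
  expect_warning(out <- nested_relative_params(2, 0, 2, 4), "zero")
  expect_true(is.na(out))
})

test_that("t_test_vs_reference matches the closed-form one-sample t", {
  tt <- t_test_vs_reference(c(1.2, 1.3, 1.4))
  expect_equal(tt$t, 0.3 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(tt$p, 2 * stats::pt(-abs(tt$t), df = 2), tolerance = 1e-10)
  # degenerate zero-variance samples
  same <- t_test_vs_reference(c(1, 1, 1))
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  diff <- t_test_vs_reference(c(1.4, 1.4, 1.4))
  expect_equal(diff$p, 0)
  expect_error(t_test_vs_reference(1))
})

test_that("significance stars follow the figure conventions", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.004, 4e-4, 4e-5)),
               c("", "*", "**", "***", "****"))
})

test_that("effect_estimates summarizes per strain and parameter", {
  vals <- tibble::tibble(
    strain = rep(c("d1", "d2"), each = 3),
    parameter = "max_rate",
    value = c(1.2, 1.3, 1.4, 1.0, 1.0, 1.0))
  est <- effect_estimates(vals)
  expect_equal(nrow(est), 2)
  d1 <- est[est$strain == "d1", ]
  expect_equal(d1$mean, 1.3)
  expect_equal(d1$stars, "*")
  d2 <- est[est$strain == "d2", ]
  expect_equal(d2$p, 1)
})
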
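#' Relative NaCl tolerance of a test colony
#'
#' Implements the within- and between-plate normalization
#' `(test_NaCl / mean(reference_NaCl)) / (test_YPD / mean(reference_YPD))`:
#' colony sizes are first normalized to the reference strain's mean size on the
#' same plate, then the salt-plate ratio is normalized to the control (YPD)
#' ratio. A value of 1 means the test strain is exactly as tolerant as the
#' reference strain; the statistic is invariant to multiplying all sizes on one
#' plate by a positive constant (plate effects cancel).
#'
#' @param test_nacl Test colony size(s) on the NaCl plate (>= 0).
#' @param ref_nacl Reference-strain colony sizes on the NaCl plate.
#' @param test_ypd Test colony size(s) on the YPD control plate.
#' @param ref_ypd Reference-strain colony sizes on the YPD plate.
#' @return Relative tolerance (dimensionless). Zero control-plate sizes yield
#'   `NA` (flagged missing rather than infinite) with a warning.
#' @export
#' @examples
#' relative_tolerance(30, c(20, 20), 15, c(10, 10))  # 1.0
relative_tolerance <- function(test_nacl, ref_nacl, test_ypd, ref_ypd) {
  if (length(ref_nacl) == 0 || length(ref_ypd) == 0) {
    abort("reference colony size lists must be non-empty")
  }
  mn <- mean(ref_nacl); my <- mean(ref_ypd)
  if (!is.finite(mn) || mn <= 0 || !is.finite(my) || my <= 0) {
    abort("reference mean colony sizes must be positive")
  }
  if (any(test_nacl < 0, na.rm = TRUE) || any(test_ypd < 0, na.rm = TRUE)) {
    abort("colony sizes must be non-negative")
  }
  out <- (test_nacl / mn) / (test_ypd / my)
  zero <- !is.na(test_ypd) & test_ypd == 0
  if (any(zero)) {
    warn("test colonies with zero control-plate size flagged as missing")
    out[zero] <- NA_real_
  }
  out
}

#' Tolerance class of a relative tolerance value
#'
#' Bins relative tolerance into classes of width 0.05, half-open right-closed:
#' class k covers `(0.05 (k - 1), 0.05 k]`, so the reference value 1.0 falls in
#' the 20th class by construction. Values of exactly 0 (no growth) are clamped
#' into class 1.
#'
#' @param value Relative tolerance value(s), >= 0.
#' @param width Class width (default 0.05).
#' @return Integer class index (>= 1).
#' @export
#' @examples
#' assign_class(1.0)   # 20
#' assign_class(0.98)  # 20
#' assign_class(0.05)  # 1
assign_class <- function(value, width = 0.05) {
  if (any(value < 0, na.rm = TRUE)) abort("tolerance values must be >= 0")
  # small guard against binary representation of the bin edges
  k <- as.integer(ceiling(value / width - 1e-9))
  pmax(k, 1L)
}

#' Per-colony relative tolerance from paired plate tables
#'
#' Joins a NaCl test plate to its YPD control plate by grid position,
#' normalizes each test colony to the reference strain's mean (or median) size
#' per plate, and assigns tolerance classes. Colonies with zero size on the
#' control plate are flagged missing, not treated as zero tolerance.
#'
#' @param nacl_plate,ypd_plate Tibbles with columns `strain`, `row`, `col`,
#'   `size`, `is_reference` ((row, col) unique per plate; at least one
#'   reference entry each).
#' @param summary `"mean"` (the default; the normalization's overline is a
#'   mean) or `"median"` for a robust reference summary.
#' @return Tibble with columns `strain`, `row`, `col`, `size_nacl`,
#'   `size_ypd`, `tolerance`, `class`, `flag`.
#' @export
plate_tolerance <- function(nacl_plate, ypd_plate,
                            summary = c("mean", "median")) {
  summary <- match.arg(summary)
  fun <- if (summary == "mean") mean else median
  for (p in list(nacl_plate, ypd_plate)) {
    stopifnot(all(c("strain", "row", "col", "size", "is_reference") %in%
                    names(p)))
    if (anyDuplicated(p[, c("row", "col")])) {
      abort("(row, col) must be unique within a plate")
    }
    if (!any(p$is_reference)) abort("each plate needs >= 1 reference entry")
    if (any(p$size < 0, na.rm = TRUE)) abort("colony sizes must be >= 0")
  }
  ref_nacl <- fun(nacl_plate$size[nacl_plate$is_reference], na.rm = TRUE)
  ref_ypd <- fun(ypd_plate$size[ypd_plate$is_reference], na.rm = TRUE)
  if (!is.finite(ref_nacl) || ref_nacl <= 0 || !is.finite(ref_ypd) ||
      ref_ypd <= 0) {
    abort("reference summary sizes must be positive")
  }
  joined <- dplyr::inner_join(
    nacl_plate |> dplyr::rename(size_nacl = "size"),
    ypd_plate |> dplyr::select("row", "col", size_ypd = "size"),
    by = c("row", "col"))
  joined |>
    dplyr::filter(!.data$is_reference) |>
    dplyr::mutate(
      tolerance = dplyr::if_else(
        !is.na(.data$size_ypd) & .data$size_ypd > 0,
        (.data$size_nacl / ref_nacl) / (.data$size_ypd / ref_ypd),
        NA_real_),
      class = dplyr::if_else(is.na(.data$tolerance), NA_integer_,
                             assign_class(pmax(.data$tolerance, 0))),
      flag = dplyr::case_when(
        is.na(.data$size_ypd) | is.na(.data$size_nacl) ~ "missing_size",
        .data$size_ypd == 0 ~ "zero_control",
        TRUE ~ NA_character_)) |>
    dplyr::select("strain", "row", "col", "size_nacl", "size_ypd",
                  "tolerance", "class", "flag")
}

#' Tolerance class histogram
#'
#' @param tolerances Tibble with a `class` column ([plate_tolerance()] output)
#'   or a numeric vector of tolerance values.
#' @return Tibble with columns `class`, `count`, covering the full observed
#'   class range (zero counts included).
#' @export
class_histogram <- function(tolerances) {
  cls <- if (is.data.frame(tolerances)) tolerances$class
         else assign_class(tolerances)
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0) return(tibble(class = integer(), count = integer()))
  rng <- seq(min(cls), max(cls))
  tibble(class = rng,
         count = vapply(rng, function(k) sum(cls == k), integer(1)))
}

#' Growth parameters of a colony-size time series
#'
#' Extracts the four standard growth-curve summaries from a size-vs-time
#' series: maximum growth rate (maximum of the moving-average-smoothed
#' finite-difference slope), maximum value reached (maximum smoothed size),
#' area under the curve (trapezoidal integral of the raw series), and lag
#' phase duration (time where the tangent at the maximum-slope point meets the
#' initial baseline, the mean of the first three points, clamped to >= 0).
#'
#' @param time Time points (minutes), strictly increasing, >= 4 points.
#' @param size Colony sizes (arbitrary units, >= 0), same length.
#' @param smoothing_window Odd moving-average window (points) for derivative
#'   estimation; default 5.
#' @return One-row tibble: `lag`, `max_rate`, `auc`, `max_value`.
#' @export
fit_growth_params <- function(time, size, smoothing_window = 5) {
  n <- length(time)
  if (n < 4 || length(size) != n) abort("need >= 4 matched (time, size) points")
  if (any(diff(time) <= 0)) abort("times must be strictly increasing")
  if (any(size < 0)) abort("sizes must be >= 0")
  w <- as.integer(smoothing_window)
  if (w < 1 || w %% 2 == 0) abort("smoothing_window must be odd and >= 1")
  w <- min(w, if (n %% 2 == 1) n else n - 1L)
  sm <- if (w == 1) size else {
    as.numeric(stats::filter(size, rep(1 / w, w), sides = 2))
  }
  # moving average is NA at the edges; fall back to the raw values there
  sm[is.na(sm)] <- size[is.na(sm)]
  slope <- diff(sm) / diff(time)
  i <- which.max(slope)
  max_rate <- slope[i]
  baseline <- mean(size[1:3])
  t_star <- (time[i] + time[i + 1]) / 2
  s_star <- (sm[i] + sm[i + 1]) / 2
  lag <- if (is.finite(max_rate) && max_rate > 0) {
    max(0, t_star - (s_star - baseline) / max_rate)
  } else 0
  tibble(lag = lag,
         max_rate = max(max_rate, 0),
         auc = sum(diff(time) * (head(size, -1) + tail(size, -1)) / 2),
         max_value = max(sm))
}

#' Growth parameters for many colonies
#'
#' @param curves Tibble with columns `colony`, `time`, `size`.
#' @param smoothing_window Passed to [fit_growth_params()].
#' @return Tibble with one row per colony.
#' @export
fit_growth_curves <- function(curves, smoothing_window = 5) {
  curves |>
    dplyr::group_by(.data$colony) |>
    dplyr::group_modify(~ fit_growth_params(.x$time, .x$size,
                                            smoothing_window)) |>
    dplyr::ungroup()
}

#' Nested isogenic normalization of a growth parameter
#'
#' Normalizes a derived strain's growth parameter first to the dispersed grid
#' control strains on each plate, then the salt-plate value to the control
#' (YPD) plate value, and finally to the same doubly normalized value of the
#' wild-type isogenic source strain:
#' `((derived_NaCl/grid_NaCl) / (derived_YPD/grid_YPD)) /`
#' `((wt_NaCl/grid_NaCl) / (wt_YPD/grid_YPD))`.
#' The wild type maps to exactly 1, and any multiplicative plate effect common
#' to all colonies on a plate cancels.
#'
#' @param derived_nacl,derived_ypd Derived-strain parameter on the NaCl and
#'   YPD plates.
#' @param wt_nacl,wt_ypd Wild-type source-strain parameter on the same plates.
#' @param grid_nacl,grid_ypd Grid-control reference values per plate
#'   (default 1, i.e. already grid-normalized inputs).
#' @return Relative value (dimensionless; wild type = 1). Zero normalizers are
#'   flagged missing (`NA`) with a warning.
#' @export
nested_relative_params <- function(derived_nacl, derived_ypd, wt_nacl, wt_ypd,
                                   grid_nacl = 1, grid_ypd = 1) {
  denom_zero <- derived_ypd == 0 | wt_nacl == 0 | wt_ypd == 0 |
    grid_nacl == 0 | grid_ypd == 0
  if (any(denom_zero, na.rm = TRUE)) {
    warn("zero normalizer flagged as missing")
  }
  out <- ((derived_nacl / grid_nacl) / (derived_ypd / grid_ypd)) /
    ((wt_nacl / grid_nacl) / (wt_ypd / grid_ypd))
  out[denom_zero] <- NA_real_
  out
}

#' One-sample two-tailed t-test against a reference value
#'
#' Used to compare relative growth parameters of strain derivatives to the
#' isogenic wild type, whose relative value is 1 by construction. With zero
#' sample variance the test is degenerate: p is 0 if the mean differs from the
#' reference and 1 otherwise, and the result is flagged.
#'
#' @param values Relative values (n >= 2).
#' @param reference Reference constant (default 1).
#' @return One-row tibble: `n`, `mean`, `sd`, `t`, `df`, `p`, `degenerate`.
#' @export
#' @examples
#' t_test_vs_reference(c(1.2, 1.3, 1.4))
t_test_vs_reference <- function(values, reference = 1) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) abort("need at least 2 finite values for a t-test")
  m <- mean(values); s <- sd(values)
  if (s == 0) {
    return(tibble(n = n, mean = m, sd = s,
                  t = if (m == reference) 0 else Inf * sign(m - reference),
                  df = n - 1,
                  p = if (m == reference) 1 else 0, degenerate = TRUE))
  }
  tt <- t.test(values, mu = reference)
  tibble(n = n, mean = m, sd = s, t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
}

#' Two-sample two-tailed t-test
#'
#' @param x,y Numeric samples (each n >= 2 with nonzero pooled variance).
#' @param var_equal Use the pooled-variance Student form (default `FALSE`,
#'   i.e. Welch's unequal-variance form).
#' @return One-row tibble: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
t_test_two_sample <- function(x, y, var_equal = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) abort("each group needs >= 2 values")
  if (sd(x) == 0 && sd(y) == 0) {
    eq <- mean(x) == mean(y)
    return(tibble(t = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                  df = NA_real_, p = if (eq) 1 else 0,
                  mean_x = mean(x), mean_y = mean(y)))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
         mean_x = mean(x), mean_y = mean(y))
}

#' Significance stars
#'
#' @param p P-value(s).
#' @return `"****"` for p < 0.0001, `"***"` < 0.001, `"**"` < 0.01, `"*"` <
#'   0.05, otherwise `""`.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(p < 1e-4 ~ "****", p < 1e-3 ~ "***",
                   p < 1e-2 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Per-derivative effect table
#'
#' Summarizes replicate relative growth values per strain derivative and
#' parameter: mean, SD, n, a two-tailed one-sample t-test against the
#' wild-type reference value of 1, and significance stars.
#'
#' @param relative_values Tibble with columns `strain`, `parameter`, `value`
#'   (relative values from [nested_relative_params()]), and optionally further
#'   grouping columns such as `concentration`.
#' @param reference Reference constant (default 1).
#' @return Tibble with one row per group: `mean`, `sd`, `n`, `t`, `p`,
#'   `stars`.
#' @export
effect_estimates <- function(relative_values, reference = 1) {
  extra <- setdiff(names(relative_values), c("strain", "parameter", "value"))
  relative_values |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("strain", "parameter",
                                                  extra)))) |>
    dplyr::group_modify(function(d, key) {
      tt <- t_test_vs_reference(d$value, reference)
      tibble(mean = tt$mean, sd = tt$sd, n = tt$n, t = tt$t, p = tt$p,
             stars = significance_stars(tt$p))
    }) |>
    dplyr::ungroup()
}
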
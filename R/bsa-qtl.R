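#' Hard-filter variant records on depth and quality annotations
#'
#' Keeps records with combined sequencing depth > `min_depth` (default 100),
#' quality-by-depth >= 2.0 and mapping-quality rank-sum >= -5.0, the standard
#' hard-filter thresholds; records failing any rule are removed. Missing
#' annotations are treated as passing (and counted). Rejection counts per rule
#' are attached as attribute `"rejections"` and logged.
#'
#' @param records Pool variant table (see [simulate_pools()] /
#'   [read_pool_table()]). Depth is taken from `DP` if present, else from the
#'   sum of the four allele-depth columns.
#' @param min_depth Depth must be strictly greater than this (default 100).
#' @param min_qd Minimum quality-by-depth (default 2.0).
#' @param min_mqranksum Minimum mapping-quality rank-sum (default -5.0).
#' @param depth_scope `"combined"` (default) applies the depth rule to the
#'   combined record depth; `"per_pool"` requires each pool to exceed
#'   `min_depth` on its own.
#' @return The filtered tibble, with attribute `rejections` (named counts).
#' @export
filter_variants <- function(records, min_depth = 100, min_qd = 2.0,
                            min_mqranksum = -5.0,
                            depth_scope = c("combined", "per_pool")) {
  depth_scope <- match.arg(depth_scope)
  ad <- records[c("AD_REF.LOW", "AD_ALT.LOW", "AD_REF.HIGH", "AD_ALT.HIGH")]
  dp_low <- ad$AD_REF.LOW + ad$AD_ALT.LOW
  dp_high <- ad$AD_REF.HIGH + ad$AD_ALT.HIGH
  dp <- if ("DP" %in% names(records)) records$DP else dp_low + dp_high
  pass_dp <- if (depth_scope == "combined") dp > min_depth
             else dp_low > min_depth & dp_high > min_depth
  qd <- if ("QD" %in% names(records)) records$QD else NA_real_
  mq <- if ("MQRankSum" %in% names(records)) records$MQRankSum else NA_real_
  pass_qd <- is.na(qd) | qd >= min_qd
  pass_mq <- is.na(mq) | mq >= min_mqranksum
  keep <- pass_dp & pass_qd & pass_mq
  rej <- c(depth = sum(!pass_dp), quality_by_depth = sum(!pass_qd),
           mq_rank_sum = sum(!pass_mq),
           missing_annotation = sum(is.na(qd) | is.na(mq)))
  out <- records[keep, , drop = FALSE]
  attr(out, "rejections") <- rej
  log_info("filter_variants: kept %d / %d (depth %d, QD %d, MQRankSum %d rejections)",
           nrow(out), nrow(records), rej[["depth"]],
           rej[["quality_by_depth"]], rej[["mq_rank_sum"]])
  out
}

#' Alternative (CEN.PK) allele frequency from allele depths
#'
#' @param ref_depth,alt_depth Read counts supporting the reference (BY-origin)
#'   and alternative (CEN.PK-origin) allele.
#' @return `alt / (ref + alt)`; `NA` (missing, excluded from profiles) where
#'   the total depth is zero. 0.50 is the neutral expectation in a biparental
#'   pool.
#' @export
#' @examples
#' allele_frequency(30, 70)  # 0.7
allele_frequency <- function(ref_depth, alt_depth) {
  if (any(ref_depth < 0, na.rm = TRUE) || any(alt_depth < 0, na.rm = TRUE)) {
    abort("allele depths must be >= 0")
  }
  tot <- ref_depth + alt_depth
  dplyr::if_else(tot > 0, alt_depth / tot, NA_real_)
}

#' Add per-pool allele frequencies to a pool variant table
#'
#' @param records Pool variant table.
#' @return The table with `freq_LOW` and `freq_HIGH` columns (CEN.PK-allele
#'   frequency in the reference and selected pool).
#' @export
add_allele_frequencies <- function(records) {
  records |>
    dplyr::mutate(
      freq_LOW = allele_frequency(.data$AD_REF.LOW, .data$AD_ALT.LOW),
      freq_HIGH = allele_frequency(.data$AD_REF.HIGH, .data$AD_ALT.HIGH))
}

#' Median allele frequency in non-overlapping genomic windows
#'
#' Summarizes per-SNP allele frequencies as medians within fixed windows
#' `[(k-1) w + 1, k w]` per chromosome (default 1 kbp), the representation
#' used for pool frequency profiles. Windows without diverging sites are
#' omitted (gaps). Even-count medians use the mean-of-middle-values
#' convention of [stats::median()].
#'
#' @param records Pool variant table (frequencies added if absent).
#' @param window_bp Window width in bp (default 1000).
#' @return Tibble: `CHROM`, `window_start`, `window_end`, `n_snps`,
#'   `median_freq_LOW`, `median_freq_HIGH`.
#' @export
window_median_frequency <- function(records, window_bp = 1000) {
  if (!all(c("freq_LOW", "freq_HIGH") %in% names(records))) {
    records <- add_allele_frequencies(records)
  }
  records |>
    dplyr::mutate(.win = (.data$POS - 1) %/% window_bp) |>
    dplyr::group_by(.data$CHROM, .data$.win) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      median_freq_LOW = median(.data$freq_LOW, na.rm = TRUE),
      median_freq_HIGH = median(.data$freq_HIGH, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(window_start = .data$.win * window_bp + 1,
                  window_end = (.data$.win + 1) * window_bp) |>
    dplyr::select("CHROM", "window_start", "window_end", "n_snps",
                  "median_freq_LOW", "median_freq_HIGH")
}

#' G statistic of a two-pool allele-count table
#'
#' Likelihood-ratio G statistic on the 2x2 table of reference/alternative read
#' counts in the two pools at one SNP: `G = 2 sum(n * ln(n / nhat))` over the
#' four cells, with expected counts `nhat` from the row/column marginals and
#' the convention `0 ln 0 = 0`. A zero marginal (e.g. no alternative reads in
#' either pool) gives G = 0 by convention. Vectorized over SNPs.
#'
#' @param ref_low,alt_low Reference-pool allele depths.
#' @param ref_high,alt_high Selected-pool allele depths.
#' @return Non-negative G value(s).
#' @export
#' @examples
#' g_statistic(20, 0, 0, 20)  # 80 log(2)
g_statistic <- function(ref_low, alt_low, ref_high, alt_high) {
  o <- cbind(ref_low, alt_low, ref_high, alt_high)
  if (any(o < 0, na.rm = TRUE)) abort("allele depths must be >= 0")
  n <- ref_low + alt_low + ref_high + alt_high
  if (any(n == 0, na.rm = TRUE)) warn("sites with zero total depth: G set to 0")
  row_low <- ref_low + alt_low
  row_high <- ref_high + alt_high
  col_ref <- ref_low + ref_high
  col_alt <- alt_low + alt_high
  e <- cbind(row_low * col_ref, row_low * col_alt,
             row_high * col_ref, row_high * col_alt) / n
  term <- o * log(o / e)
  term[!is.finite(term)] <- 0  # 0 ln 0 = 0; zero marginals give G = 0
  g <- 2 * rowSums(term)
  pmax(g, 0)
}

#' Tricube-smoothed G statistic (G')
#'
#' For each focal SNP, G' is the tricube-kernel weighted mean of the raw G
#' values of all SNPs within half a window (`window_bp / 2`, default 10 kbp to
#' each side) on the same chromosome: weights `(1 - (d / D)^3)^3` with
#' `D = window_bp / 2`. Windows never span chromosome boundaries; an isolated
#' SNP gets its own G.
#'
#' @param track Tibble with `CHROM`, `POS`, `G`, sorted by position within
#'   chromosome.
#' @param window_bp Full window width in bp (default 20000).
#' @return The track with a `Gprime` column.
#' @export
tricube_gprime <- function(track, window_bp = 20000) {
  half <- window_bp / 2
  track |>
    dplyr::group_by(.data$CHROM) |>
    dplyr::group_modify(function(d, key) {
      if (is.unsorted(d$POS)) abort("positions must be sorted within chromosome")
      pos <- d$POS; g <- d$G
      lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
      hi <- findInterval(pos + half, pos)
      gp <- vapply(seq_along(pos), function(i) {
        j <- lo[i]:hi[i]
        w <- (1 - (abs(pos[j] - pos[i]) / half)^3)^3
        sum(w * g[j]) / sum(w)
      }, numeric(1))
      d$Gprime <- gp
      d
    }) |>
    dplyr::ungroup()
}

#' Robust lognormal null model for G'
#'
#' Non-parametric estimation of the null distribution of G': outliers (the
#' signal) are removed by Hampel's rule on `ln G'` (median +/- c * MAD,
#' default c = 5.2), then a lognormal null is fitted to the trimmed set with a
#' median-based location and MAD-based scale.
#'
#' @param gprime G' values (>= 50 finite positive values after trimming
#'   zeros).
#' @param hampel_c Hampel constant (default 5.2).
#' @return A `gprime_null`: list with `meanlog`, `sdlog`, `n_used`,
#'   `n_trimmed`, `hampel_c`.
#' @export
estimate_null <- function(gprime, hampel_c = 5.2) {
  g <- gprime[is.finite(gprime) & gprime > 0]
  if (length(g) < 50) abort("need >= 50 positive G' values to fit the null")
  lg <- log(g)
  med <- median(lg)
  s <- mad(lg)
  if (s == 0) abort("degenerate G' track: zero MAD")
  keep <- abs(lg - med) <= hampel_c * s
  lg_t <- lg[keep]
  structure(list(meanlog = median(lg_t), sdlog = mad(lg_t),
                 n_used = length(lg_t), n_trimmed = sum(!keep),
                 hampel_c = hampel_c),
            class = "gprime_null")
}

#' @export
print.gprime_null <- function(x, ...) {
  cat(sprintf("<gprime_null> lognormal(meanlog = %.4f, sdlog = %.4f), %d used, %d trimmed\n",
              x$meanlog, x$sdlog, x$n_used, x$n_trimmed))
  invisible(x)
}

#' Upper-tail p-values for G' under the fitted null
#'
#' @param track Tibble with a `Gprime` column.
#' @param null A `gprime_null` from [estimate_null()].
#' @param bh Also append Benjamini-Hochberg q-values (default `TRUE`).
#' @return The track with `p`, `neglog10p` and optionally `q` columns.
#'   `-log10(0.05)` is 1.30 to two decimals, the QTL-discovery threshold.
#' @export
p_values <- function(track, null, bh = TRUE) {
  stopifnot(inherits(null, "gprime_null"))
  p <- plnorm(track$Gprime, null$meanlog, null$sdlog, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p[!is.finite(track$Gprime) | track$Gprime <= 0] <- 1
  track$p <- p
  track$neglog10p <- -log10(p)
  if (bh) track$q <- p.adjust(p, method = "BH")
  track
}

#' Call QTL intervals from a significance track
#'
#' Finds maximal runs of SNPs with `-log10(P)` at or above the threshold
#' (default 1.30, i.e. P <= 0.05) per chromosome, merges runs separated by
#' less than `merge_gap_bp`, and reports 1-based inclusive intervals whose
#' boundaries are the outermost significant SNP positions, with peak
#' statistics and the mean pool frequency shift.
#'
#' By default a SNP must also pass a Benjamini-Hochberg false-discovery cut
#' (`q <= max_q`) to seed an interval: with thousands of SNPs per genome, a
#' per-SNP P < 0.05 rule alone would flag ~5% of the genome in a pure-noise
#' scan, whereas the FDR cut keeps genome-wide false calls near zero while
#' real QTL peaks (whose q-values are orders of magnitude smaller) are
#' unaffected. Set `max_q = NULL` to call on the raw threshold alone.
#'
#' @param track Tibble with `CHROM`, `POS`, `neglog10p` and optionally
#'   `freq_LOW` / `freq_HIGH`, `q`.
#' @param neglog_threshold Significance threshold on `-log10(P)` (default
#'   1.30).
#' @param merge_gap_bp Runs closer than this are merged (default 20000).
#' @param max_q BH q-value cut for genome-wide calling (default 0.05);
#'   `NULL` disables it. If the track lacks a `q` column it is computed from
#'   the p-values.
#' @return Tibble of intervals: `CHROM`, `start`, `end`, `width`, `n_snps`,
#'   `peak_neglog10p`, `peak_pos`, `mean_freq_shift`.
#' @export
call_qtl_intervals <- function(track, neglog_threshold = 1.30,
                               merge_gap_bp = 20000, max_q = 0.05) {
  stopifnot("neglog10p" %in% names(track))
  has_freq <- all(c("freq_LOW", "freq_HIGH") %in% names(track))
  if (!is.null(max_q)) {
    if (!"q" %in% names(track)) {
      track$q <- p.adjust(10^(-track$neglog10p), method = "BH")
    }
  } else {
    track$q <- -Inf  # q filter disabled: every SNP passes it
  }
  track |>
    dplyr::group_by(.data$CHROM) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$POS), ]
      sig <- which(d$neglog10p >= neglog_threshold &
                     d$q <= (max_q %||% Inf))
      if (length(sig) == 0) {
        return(tibble(start = integer(), end = integer(), width = integer(),
                      n_snps = integer(), peak_neglog10p = numeric(),
                      peak_pos = integer(), mean_freq_shift = numeric()))
      }
      # group significant SNPs: a new interval starts when the bp gap to the
      # previous significant SNP is at least merge_gap_bp
      gap <- c(Inf, diff(d$POS[sig]))
      grp <- cumsum(gap >= merge_gap_bp)
      purrr::map_dfr(split(sig, grp), function(idx) {
        seg <- d[idx, ]
        peak <- which.max(seg$neglog10p)
        tibble(start = min(seg$POS), end = max(seg$POS),
               width = max(seg$POS) - min(seg$POS),
               n_snps = nrow(seg),
               peak_neglog10p = seg$neglog10p[peak],
               peak_pos = seg$POS[peak],
               mean_freq_shift = if (has_freq) {
                 mean(seg$freq_HIGH - seg$freq_LOW, na.rm = TRUE)
               } else NA_real_)
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$peak_neglog10p))
}

#' Full bulk-segregant G' QTL scan
#'
#' End-to-end scan of a two-pool variant table: hard filtering, per-pool
#' allele frequencies, per-SNP G, tricube-smoothed G' in physical-distance
#' windows, robust lognormal null, upper-tail p-values with -log10 transform
#' and BH q-values, 1-kbp median frequency profiles, and QTL interval calls.
#'
#' @param records Pool variant table ([simulate_pools()] or
#'   [read_pool_table()] output).
#' @param window_bp G' smoothing window (default 20000 bp).
#' @param median_window_bp Frequency-profile window (default 1000 bp).
#' @param neglog_threshold Interval-calling threshold on -log10(P) (default
#'   1.30).
#' @param hampel_c Hampel trimming constant (default 5.2).
#' @param min_depth,depth_scope Passed to [filter_variants()].
#' @param merge_gap_bp Interval merge gap (default 20000 bp).
#' @param max_q BH q-value cut for interval calling (default 0.05; see
#'   [call_qtl_intervals()]).
#' @return A `gprime_scan`: list with `track` (per-SNP tibble), `medians`,
#'   `null`, `intervals`, `params`, `filter_rejections`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_f1_pool_experiment(n_markers = 500, n_pop = 500, seed = 2)
#' scan <- gprime_scan(sim$pools)
#' scan$intervals
#' }
gprime_scan <- function(records, window_bp = 20000, median_window_bp = 1000,
                        neglog_threshold = 1.30, hampel_c = 5.2,
                        min_depth = 100,
                        depth_scope = c("combined", "per_pool"),
                        merge_gap_bp = 20000, max_q = 0.05) {
  depth_scope <- match.arg(depth_scope)
  kept <- filter_variants(records, min_depth = min_depth,
                          depth_scope = depth_scope)
  rej <- attr(kept, "rejections")
  track <- kept |>
    add_allele_frequencies() |>
    dplyr::mutate(G = g_statistic(.data$AD_REF.LOW, .data$AD_ALT.LOW,
                                  .data$AD_REF.HIGH, .data$AD_ALT.HIGH)) |>
    tricube_gprime(window_bp = window_bp)
  null <- estimate_null(track$Gprime, hampel_c = hampel_c)
  track <- p_values(track, null)
  structure(list(
    track = track,
    medians = window_median_frequency(kept, median_window_bp),
    null = null,
    intervals = call_qtl_intervals(track, neglog_threshold, merge_gap_bp,
                                   max_q),
    params = list(window_bp = window_bp, median_window_bp = median_window_bp,
                  neglog_threshold = neglog_threshold, hampel_c = hampel_c,
                  min_depth = min_depth, depth_scope = depth_scope,
                  merge_gap_bp = merge_gap_bp, max_q = max_q),
    filter_rejections = rej),
    class = "gprime_scan")
}

#' @export
print.gprime_scan <- function(x, ...) {
  cat(sprintf("<gprime_scan> %d SNPs, %d QTL interval(s) at -log10(P) >= %.2f\n",
              nrow(x$track), nrow(x$intervals), x$params$neglog_threshold))
  if (nrow(x$intervals)) print(x$intervals)
  invisible(x)
}

#' @describeIn gprime_scan Per-SNP track as a tibble.
#' @param x A `gprime_scan`.
#' @param ... Unused.
#' @method tidy gprime_scan
#' @export
tidy.gprime_scan <- function(x, ...) {
  as_tibble(x$track)
}

#' @describeIn gprime_scan One-row scan summary.
#' @method glance gprime_scan
#' @export
glance.gprime_scan <- function(x, ...) {
  tibble(n_snps = nrow(x$track), n_intervals = nrow(x$intervals),
         meanlog = x$null$meanlog, sdlog = x$null$sdlog,
         n_trimmed = x$null$n_trimmed,
         threshold = x$params$neglog_threshold)
}
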
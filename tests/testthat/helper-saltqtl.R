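# Shared fixtures for the test suite. All randomness is seeded.

# a small marker map on the real karyotype
small_map <- function(n = 200, seed = 1) {
  build_marker_map(n, yeast_chromosomes(), seed = seed)
}

# n equal-length chromosomes
equal_chroms <- function(n = 16, len = 1e5) {
  stats::setNames(rep(len, n), paste0("c", seq_len(n)))
}

# single-locus trait on the marker of `map` nearest the default major locus
major_only_trait <- function(map, noise_sd = 0.1) {
  trait_model(default_trait_loci(map)[1, ], noise_sd = noise_sd)
}

# independent brute-force 2x2 likelihood-ratio oracle for the G statistic:
# G = 2 * (sum o ln o - sum rows r ln r - sum cols c ln c + N ln N)
g_oracle <- function(a, b, c, d) {
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  n <- a + b + c + d
  2 * (xlx(a) + xlx(b) + xlx(c) + xlx(d) -
         xlx(a + b) - xlx(c + d) - xlx(a + c) - xlx(b + d) + xlx(n))
}

# brute-force tricube smoother (direct double loop)
tricube_oracle <- function(pos, g, window_bp) {
  half <- window_bp / 2
  vapply(seq_along(pos), function(i) {
    d <- abs(pos - pos[i])
    j <- which(d <= half)
    w <- (1 - (d[j] / half)^3)^3
    sum(w * g[j]) / sum(w)
  }, numeric(1))
}

# brute-force longest-run oracle over all substrings
homorepeat_oracle <- function(s, residue = "N") {
  ch <- strsplit(toupper(s), "")[[1]]
  best <- 0L
  run <- 0L
  for (x in ch) {
    run <- if (identical(x, residue)) run + 1L else 0L
    best <- max(best, run)
  }
  best
}

# a minimal synthetic significance track for interval-calling tests:
# background SNPs at p ~ 0.63 plus blocks of strongly significant SNPs
block_track <- function(blocks, background_chrom = "chrI",
                        background_n = 50, neglog_block = 6) {
  bg <- tibble::tibble(CHROM = background_chrom,
                       POS = as.integer(seq(5000, by = 25000,
                                            length.out = background_n)),
                       neglog10p = 0.2)
  sig <- purrr::map_dfr(blocks, function(b) {
    tibble::tibble(CHROM = b$chrom,
                   POS = as.integer(seq(b$start, b$end, by = b$step %||% 1000)),
                   neglog10p = neglog_block)
  })
  out <- dplyr::bind_rows(bg, sig)
  out$p <- 10^(-out$neglog10p)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
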
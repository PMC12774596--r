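#' Sequencing model for pooled bulk sequencing
#'
#' @param mean_depth Mean per-site per-pool sequencing depth (> 0).
#' @param dispersion Optional negative-binomial size parameter for depth
#'   overdispersion; `NULL` (default) draws depths Poisson.
#' @param base_error Optional flat base-error rate mixing reads toward the
#'   other allele.
#' @return A `sequencing_model` list.
#' @export
sequencing_model <- function(mean_depth = 100, dispersion = NULL,
                             base_error = 0) {
  stopifnot(mean_depth > 0, base_error >= 0, base_error < 0.5)
  structure(list(mean_depth = mean_depth, dispersion = dispersion,
                 base_error = base_error),
            class = "sequencing_model")
}

#' Simulate two-pool bulk sequencing of a segregant population
#'
#' The reference (LOW) pool is the whole population, grown without salt; the
#' selected (HIGH) pool is the top `survival_fraction` of the population by
#' phenotype at `concentration` (truncation selection, emulating growth under
#' high salt where only ~1% of segregants survive). Per marker, the true
#' CEN.PK-allele frequency of each pool is computed from pool membership, then
#' read depths are drawn at the sequencing model's depth and allele counts
#' binomially at the true frequency.
#'
#' @param pop A `segregant_population` from [run_cross_plan()].
#' @param survival_fraction Fraction of the population surviving selection,
#'   in (0, 1].
#' @param concentration Selection concentration (mol/L), on the trait grid.
#' @param sequencing A [sequencing_model()].
#' @param seed Integer seed.
#' @return A pool variant table: tibble with columns `CHROM`, `POS`, `REF`,
#'   `ALT`, `AD_REF.LOW`, `AD_ALT.LOW`, `AD_REF.HIGH`, `AD_ALT.HIGH`, plus
#'   quality annotations `DP` (combined depth), `QD`, `MQRankSum` and the true
#'   pool frequencies `freq_true_LOW`, `freq_true_HIGH` (simulation truth,
#'   dropped by the writers).
#' @export
simulate_pools <- function(pop, survival_fraction = 0.01, concentration = 1.5,
                           sequencing = sequencing_model(), seed = 1L) {
  stopifnot(inherits(pop, "segregant_population"),
            survival_fraction > 0, survival_fraction <= 1)
  n <- nrow(pop$origins)
  n_sel <- floor(n * survival_fraction)
  if (n_sel < 1) abort("survival_fraction leaves an empty selected pool")
  ci <- which(abs(pop$concentrations - concentration) < 1e-12)
  if (length(ci) != 1L) abort("selection concentration is off the trait grid")
  withr::with_seed(seed, {
    ph <- pop$phenotypes[, ci]
    sel <- order(ph, decreasing = TRUE)[seq_len(n_sel)]
    freq_low <- colMeans(pop$origins)                 # CEN.PK = alt frequency
    freq_high <- colMeans(pop$origins[sel, , drop = FALSE])
    m <- ncol(pop$origins)
    draw_depth <- function() {
      if (is.null(sequencing$dispersion)) {
        rpois(m, sequencing$mean_depth)
      } else {
        stats::rnbinom(m, size = sequencing$dispersion,
                       mu = sequencing$mean_depth)
      }
    }
    e <- sequencing$base_error
    obs_freq <- function(f) f * (1 - e) + (1 - f) * e
    dp_low <- draw_depth(); dp_high <- draw_depth()
    alt_low <- rbinom(m, dp_low, obs_freq(freq_low))
    alt_high <- rbinom(m, dp_high, obs_freq(freq_high))
    # synthetic alleles and pass-by-default quality annotations
    nt <- c("A", "C", "G", "T")
    ref <- sample(nt, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
    tibble(
      CHROM = pop$map$chrom, POS = pop$map$pos, REF = ref, ALT = alt,
      AD_REF.LOW = dp_low - alt_low, AD_ALT.LOW = alt_low,
      AD_REF.HIGH = dp_high - alt_high, AD_ALT.HIGH = alt_high,
      DP = dp_low + dp_high,
      QD = round(25 + rnorm(m, sd = 3), 2),
      MQRankSum = round(rnorm(m, sd = 1), 3),
      freq_true_LOW = freq_low, freq_true_HIGH = freq_high
    )
  })
}

#' One-call desk-scale simulation of a selected F1 pool experiment
#'
#' Convenience wrapper that builds a marker map, the default two-locus trait,
#' simulates an F1 segregant population, and sequences the reference and
#' salt-selected pools. This is the default scenario used throughout the test
#' suite and examples.
#'
#' @param n_markers Markers on the map.
#' @param n_pop F1 population size (default ~10^4 segregants per pool, the
#'   study's bulk size; 1% truncation then leaves ~100 survivors, which sets
#'   the drift-noise floor of the scan).
#' @param survival_fraction Truncation-selection survival (default 1%).
#' @param concentration Selection concentration (mol/L).
#' @param depth Mean per-pool sequencing depth.
#' @param loci Trait loci (default [default_trait_loci()]); pass a zero-row
#'   tibble for a null (no-trait) experiment.
#' @param noise_sd Environmental noise SD.
#' @param seed Integer seed.
#' @return List with `map`, `trait`, `pop` (the F1 `segregant_population`) and
#'   `pools` (the pool variant table).
#' @export
simulate_f1_pool_experiment <- function(n_markers = 2000, n_pop = 10000,
                                        survival_fraction = 0.01,
                                        concentration = 1.5, depth = 100,
                                        loci = NULL, noise_sd = 0.1,
                                        seed = 1L) {
  map <- build_marker_map(n_markers, yeast_chromosomes(), seed = seed)
  if (is.null(loci)) loci <- default_trait_loci(map)
  trait <- trait_model(loci, noise_sd = noise_sd)
  plan <- cross_plan("F1", "founder", n_pop, concentration)
  pop <- run_cross_plan(plan, map, trait, seed = seed)[[1]]
  pools <- simulate_pools(pop, survival_fraction, concentration,
                          sequencing_model(depth), seed = seed + 1L)
  list(map = map, trait = trait, pop = pop, pools = pools)
}
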
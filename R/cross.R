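#' Founder haplotypes
#'
#' Founders are idealized as fully homozygous and opposite at every diverging
#' marker: the BY founder carries origin 0 everywhere, the CEN.PK founder
#' origin 1 everywhere.
#'
#' @param map A `marker_map`.
#' @param parent `"BY"` or `"CENPK"`.
#' @return Integer origin vector over the map's markers.
#' @export
founder_haplotype <- function(map, parent = c("BY", "CENPK")) {
  parent <- match.arg(parent)
  rep(if (parent == "BY") 0L else 1L, nrow(map))
}

#' Simulate meiotic gametes of a diploid parent
#'
#' Per chromosome, the crossover count is Poisson with mean
#' `length_kb * recomb_rate / 100` (no interference), breakpoints are uniform,
#' and the starting chromatid is chosen with probability 1/2 independently per
#' chromosome. Gametes are sampled independently (tetrad structure is ignored,
#' as segregants are picked independently).
#'
#' @param h1,h2 Integer origin vectors of the parent's two haplotypes.
#' @param map The `marker_map`.
#' @param n Number of gametes.
#' @param recomb_rate Recombination rate in cM per kb (default 0.35,
#'   yeast-typical).
#' @return For `meiosis_batch`, an integer matrix of `n` gamete origin vectors
#'   (rows); for `meiosis_gamete`, a single origin vector.
#' @export
meiosis_batch <- function(h1, h2, map, n, recomb_rate = 0.35) {
  stopifnot(length(h1) == nrow(map), length(h2) == nrow(map),
            recomb_rate >= 0, n >= 1)
  meiosis_batch_cpp(as.integer(n), as.integer(h1), as.integer(h2),
                    marker_chrom_index(map), as.numeric(map$pos),
                    as.numeric(chrom_lengths(map)), recomb_rate)
}

#' @rdname meiosis_batch
#' @export
meiosis_gamete <- function(h1, h2, map, recomb_rate = 0.35) {
  drop(meiosis_batch(h1, h2, map, 1L, recomb_rate))
}

#' Build a crossing plan
#'
#' A plan is an ordered tibble of steps. The first step must cross the two
#' founders (`cross_to = "founder"`); each later step crosses the previous
#' step's selected extreme segregant to a founder parent (`"BY"` or
#' `"CENPK"`). `select_conc` is the NaCl concentration (mol/L) at which the
#' extreme segregant of that generation is picked.
#'
#' @param generation Character labels (e.g. `"F1"`).
#' @param cross_to `"founder"` for the first step, else `"BY"`/`"CENPK"`.
#' @param n_offspring Offspring per step (> 0).
#' @param select_conc Selection concentration per step (mol/L).
#' @return A `cross_plan` tibble.
#' @export
cross_plan <- function(generation, cross_to, n_offspring, select_conc) {
  plan <- tibble(generation = generation, cross_to = cross_to,
                 n_offspring = as.integer(n_offspring),
                 select_conc = select_conc)
  validate_cross_plan(plan)
  class(plan) <- c("cross_plan", class(plan))
  plan
}

validate_cross_plan <- function(plan) {
  if (nrow(plan) < 1) abort("a cross plan needs at least one step")
  if (plan$cross_to[1] != "founder") {
    abort("the first step must cross the two founder parents")
  }
  if (nrow(plan) > 1 && any(plan$cross_to[-1] == "founder")) {
    abort("only the first step may be a founder x founder cross")
  }
  if (!all(plan$cross_to %in% c("founder", "BY", "CENPK"))) {
    abort("cross_to must be 'founder', 'BY' or 'CENPK'")
  }
  if (any(plan$n_offspring <= 0)) abort("offspring counts must be positive")
  invisible(plan)
}

#' The study's seven-generation crossing plan
#'
#' F1: BY x CEN.PK founders (2,156 segregants phenotyped); F2: the extreme F1
#' segregant crossed back to CEN.PK; F3-F7: the extreme segregant of each
#' generation backcrossed to BY (1,232 segregants per generation). Selection of
#' the extreme individual is at high salt (1.50 M by default).
#'
#' @param n_f1 F1 population size.
#' @param n_later Population size for F2-F7.
#' @param select_conc Selection concentration (mol/L).
#' @return A `cross_plan`.
#' @export
fig_plan_iterative_backcross <- function(n_f1 = 2156, n_later = 1232,
                                         select_conc = 1.5) {
  cross_plan(
    generation = paste0("F", 1:7),
    cross_to = c("founder", "CENPK", rep("BY", 5)),
    n_offspring = c(n_f1, rep(n_later, 6)),
    select_conc = rep(select_conc, 7)
  )
}

#' Desk-scale crossing plan
#'
#' The same seven-step design at a reduced population size for fast simulation.
#'
#' @param n_offspring Offspring per generation.
#' @param select_conc Selection concentration (mol/L).
#' @return A `cross_plan`.
#' @export
desk_plan <- function(n_offspring = 500, select_conc = 1.5) {
  cross_plan(
    generation = paste0("F", 1:7),
    cross_to = c("founder", "CENPK", rep("BY", 5)),
    n_offspring = rep(n_offspring, 7),
    select_conc = rep(select_conc, 7)
  )
}

#' Expected donor-genome fraction under neutrality
#'
#' Analytic recurrence for the expected fraction of the CEN.PK (donor) genome
#' carried by the selected lineage after each step, under neutrality and no
#' selection: the F1 segregant carries 1/2; crossing the current segregant to
#' the donor parent maps f to (f + 1)/2; crossing to the recurrent BY parent
#' maps f to f/2. For the seven-step study plan this yields 0.75 / 32 =
#' 0.0234375, i.e. 2.34% of the donor variation remaining.
#'
#' @param plan A `cross_plan`.
#' @return Expected donor (CEN.PK) fraction after the last step.
#' @export
#' @examples
#' expected_donor_fraction(fig_plan_iterative_backcross())  # 0.0234375
expected_donor_fraction <- function(plan) {
  validate_cross_plan(plan)
  f <- 0.5
  for (step in plan$cross_to[-1]) {
    f <- if (step == "CENPK") (f + 1) / 2 else f / 2
  }
  f
}

#' Run an iterative crossing and selection plan
#'
#' Executes the plan step by step: cross, draw offspring gametes (haploid
#' segregants), evaluate genetic values on the trait model's concentration
#' grid, add Gaussian environmental noise per individual and concentration,
#' and select the extreme individual (maximum phenotype at the step's
#' selection concentration; ties broken by lowest index) to seed the next
#' cross.
#'
#' @param plan A `cross_plan`.
#' @param map A `marker_map`.
#' @param trait A [trait_model()].
#' @param recomb_rate Recombination rate (cM/kb).
#' @param seed Integer seed.
#' @return A list of `segregant_population` objects, one per step, each with
#'   elements `generation`, `origins` (n x markers integer matrix),
#'   `phenotypes` (n x concentrations matrix), `genetic` (same shape),
#'   `selected` (index of the extreme segregant), `map`, `concentrations`.
#' @export
run_cross_plan <- function(plan, map, trait, recomb_rate = 0.35, seed = 1L) {
  validate_cross_plan(plan)
  concs <- trait$concentrations
  withr::with_seed(seed, {
    by <- founder_haplotype(map, "BY")
    cenpk <- founder_haplotype(map, "CENPK")
    parent1 <- by
    parent2 <- cenpk
    out <- vector("list", nrow(plan))
    for (s in seq_len(nrow(plan))) {
      n <- plan$n_offspring[s]
      origins <- meiosis_batch(parent1, parent2, map, n, recomb_rate)
      genetic <- vapply(concs, function(cc) genetic_value(origins, map, trait, cc),
                        numeric(n))
      genetic <- matrix(genetic, nrow = n)
      noise <- matrix(rnorm(n * length(concs), sd = trait$noise_sd), nrow = n)
      phenotypes <- genetic + noise
      colnames(phenotypes) <- colnames(genetic) <- paste0("M", concs)
      sc <- plan$select_conc[s]
      ci <- which(abs(concs - sc) < 1e-12)
      if (length(ci) != 1L) {
        abort(sprintf("selection concentration %.3g is off the trait grid", sc))
      }
      selected <- which.max(phenotypes[, ci])  # which.max: lowest index wins ties
      out[[s]] <- structure(
        list(generation = plan$generation[s], origins = origins,
             genetic = genetic, phenotypes = phenotypes,
             selected = selected, map = map, concentrations = concs),
        class = "segregant_population")
      if (s < nrow(plan)) {
        parent1 <- origins[selected, ]
        parent2 <- if (plan$cross_to[s + 1] == "BY") by else cenpk
      }
    }
    names(out) <- plan$generation
    out
  })
}

#' @export
print.segregant_population <- function(x, ...) {
  cat(sprintf("<segregant_population> %s: %d segregants x %d markers, %d concentrations\n",
              x$generation, nrow(x$origins), ncol(x$origins),
              length(x$concentrations)))
  invisible(x)
}

#' Tidy a segregant population's phenotypes
#'
#' @param x A `segregant_population`.
#' @param ... Unused.
#' @return Tibble with columns `generation`, `segregant`, `concentration`,
#'   `phenotype`, `genetic`.
#' @method tidy segregant_population
#' @export
tidy.segregant_population <- function(x, ...) {
  n <- nrow(x$origins)
  tidyr::expand_grid(segregant = seq_len(n),
                     concentration = x$concentrations) |>
    dplyr::mutate(generation = x$generation,
                  phenotype = as.vector(t(x$phenotypes)),
                  genetic = as.vector(t(x$genetic))) |>
    dplyr::select("generation", "segregant", "concentration",
                  "phenotype", "genetic")
}

#' Donor-genome fraction of each segregant
#'
#' @param pop A `segregant_population`.
#' @return Numeric vector: per-segregant fraction of markers of CEN.PK origin.
#' @export
donor_fraction <- function(pop) {
  rowMeans(pop$origins)
}

#' Monte-Carlo donor fraction of neutral lineages
#'
#' Simulates `n_lineages` independent selected lineages through the plan with
#' no trait and no selection (a random offspring carries the lineage forward)
#' and returns each lineage's final donor-genome fraction. Used as the
#' simulation oracle for [expected_donor_fraction()].
#'
#' @param plan A `cross_plan`.
#' @param map A `marker_map`.
#' @param n_lineages Number of independent lineages.
#' @param recomb_rate Recombination rate (cM/kb).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_lineages`.
#' @export
simulate_neutral_donor_fraction <- function(plan, map, n_lineages = 10000,
                                            recomb_rate = 0.35, seed = 1L) {
  validate_cross_plan(plan)
  withr::with_seed(seed, {
    by <- founder_haplotype(map, "BY")
    cenpk <- founder_haplotype(map, "CENPK")
    # all lineages share the F1 parents; one gamete per lineage per step
    state <- meiosis_batch(by, cenpk, map, n_lineages, recomb_rate)
    for (s in seq_len(nrow(plan))[-1]) {
      other <- if (plan$cross_to[s] == "BY") by else cenpk
      for (i in seq_len(n_lineages)) {
        state[i, ] <- meiosis_gamete(state[i, ], other, map, recomb_rate)
      }
    }
    rowMeans(state)
  })
}
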
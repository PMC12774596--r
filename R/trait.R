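#' Define an additive trait model over marker loci
#'
#' Each causative locus contributes `effect * conc_scaling * concentration`
#' phenotype units when the segregant carries the BY allele at that marker, and
#' 0 when it carries the CEN.PK allele. Effects are therefore per molar NaCl:
#' genetic effects vanish on salt-free control plates and grow with the salt
#' concentration, mirroring how relative tolerance is normalized against the
#' control medium. Signs follow the cross: the sodium-pump cluster's BY allele
#' raises tolerance (positive effect) while the stress-regulator BY allele
#' lowers it (negative effect).
#'
#' @param loci Tibble with columns `chrom`, `pos` (must be marker positions on
#'   the map used downstream), `effect` (phenotype units per molar for the BY
#'   allele) and optionally `conc_scaling` (default 1).
#' @param noise_sd Environmental noise standard deviation (>= 0), in phenotype
#'   units.
#' @param concentrations Numeric grid of NaCl concentrations (mol/L) at which
#'   phenotypes are evaluated.
#' @return A `trait_model` list.
#' @export
#' @examples
#' map <- build_marker_map(100, yeast_chromosomes(), seed = 1)
#' tm <- trait_model(default_trait_loci(map), noise_sd = 0.1)
trait_model <- function(loci,
                        noise_sd = 0.1,
                        concentrations = seq(0.25, 2.5, by = 0.25)) {
  if (is.null(loci) || nrow(loci) == 0) {
    loci <- tibble(chrom = character(), pos = integer(),
                   effect = numeric(), conc_scaling = numeric())
  }
  if (!"conc_scaling" %in% names(loci)) loci$conc_scaling <- 1
  stopifnot(noise_sd >= 0, all(concentrations >= 0))
  structure(list(loci = as_tibble(loci), noise_sd = noise_sd,
                 concentrations = concentrations),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> %d loci, noise SD %.3g, %d concentrations\n",
              nrow(x$loci), x$noise_sd, length(x$concentrations)))
  print(x$loci)
  invisible(x)
}

#' Default two-locus trait architecture for the NaCl cross
#'
#' A major-effect locus on chrIV (sodium-efflux-pump-like, BY allele +1.0 per
#' molar) and a minor-effect locus on chrIX (stress-regulator-like, BY allele
#' -0.2 per molar), each snapped to the nearest marker on `map`.
#'
#' @param map A `marker_map`.
#' @param major_effect,minor_effect Per-molar effects of the BY allele.
#' @param major_pos,minor_pos Intended bp coordinates (snapped to markers).
#' @return Tibble of loci suitable for [trait_model()].
#' @export
default_trait_loci <- function(map, major_effect = 1.0, minor_effect = -0.2,
                               major_pos = 530000, minor_pos = 115000) {
  dplyr::bind_rows(
    snap_locus_to_marker(map, "chrIV", major_pos) |>
      dplyr::mutate(effect = major_effect, conc_scaling = 1),
    snap_locus_to_marker(map, "chrIX", minor_pos) |>
      dplyr::mutate(effect = minor_effect, conc_scaling = 1)
  )
}

#' Snap an intended locus coordinate to the nearest marker
#'
#' @param map A `marker_map`.
#' @param chrom Chromosome name.
#' @param pos Intended position (bp).
#' @return One-row tibble with `chrom` and the nearest marker `pos`.
#' @export
snap_locus_to_marker <- function(map, chrom, pos) {
  cand <- map$pos[map$chrom == chrom]
  if (length(cand) == 0) abort(sprintf("no markers on %s", chrom))
  tibble(chrom = chrom, pos = cand[which.min(abs(cand - pos))])
}

# internal: marker column index for each trait locus; error if off the map
trait_marker_index <- function(trait, map) {
  if (nrow(trait$loci) == 0) return(integer())
  idx <- purrr::map2_int(trait$loci$chrom, trait$loci$pos, function(ch, p) {
    i <- which(map$chrom == ch & map$pos == p)
    if (length(i) != 1L) {
      abort(sprintf("trait locus %s:%d is not on the marker map", ch, p))
    }
    i
  })
  idx
}

#' Additive genetic value of segregant haplotypes
#'
#' Sums, over trait loci, `effect * conc_scaling * concentration` for
#' individuals carrying the BY allele (origin 0) at each locus. Deterministic;
#' no noise is added here.
#'
#' @param origins Integer vector (one haplotype) or matrix (individuals in
#'   rows) of marker origins, 0 = BY, 1 = CENPK.
#' @param map The `marker_map` the haplotypes are defined on.
#' @param trait A [trait_model()].
#' @param concentration NaCl concentration (mol/L); must lie on the model grid.
#' @return Numeric vector of genetic values, one per individual.
#' @export
genetic_value <- function(origins, map, trait, concentration) {
  if (!isTRUE(any(abs(trait$concentrations - concentration) < 1e-12))) {
    abort(sprintf("concentration %.3g is not on the trait model grid",
                  concentration))
  }
  if (is.null(dim(origins))) origins <- matrix(origins, nrow = 1)
  if (nrow(trait$loci) == 0) return(rep(0, nrow(origins)))
  idx <- trait_marker_index(trait, map)
  w <- trait$loci$effect * trait$loci$conc_scaling * concentration
  # BY allele indicator is (1 - origin)
  drop((1 - origins[, idx, drop = FALSE]) %*% w)
}
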
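#' Nuclear chromosome lengths of the S288C reference genome
#'
#' Lengths of the 16 nuclear chromosomes of the *Saccharomyces cerevisiae*
#' S288C reference assembly (R64), in bp. The total is 12,071,326 bp.
#'
#' @return Named numeric vector of chromosome lengths (bp), chrI..chrXVI.
#' @export
#' @examples
#' sum(yeast_chromosomes())
yeast_chromosomes <- function() {
  c(chrI = 230218, chrII = 813184, chrIII = 316620, chrIV = 1531933,
    chrV = 576874, chrVI = 270161, chrVII = 1090940, chrVIII = 562643,
    chrIX = 439888, chrX = 745751, chrXI = 666816, chrXII = 1078177,
    chrXIII = 924431, chrXIV = 784333, chrXV = 1091291, chrXVI = 948066)
}

#' Build a map of diverging marker sites
#'
#' Distributes `n_markers` biallelic diverging sites across chromosomes
#' proportionally to chromosome length (largest-remainder apportionment), with
#' uniform random positions within each chromosome, sorted and without
#' duplicates. This is the coordinate backbone for the biparental cross
#' simulator, scaled down from the ~21,100 diverging SNVs that separate the BY
#' and CEN.PK genomes.
#'
#' @param n_markers Total number of marker sites (>= 1).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param seed Integer seed; the map is deterministic given the seed.
#' @return A `marker_map`: a tibble with columns `chrom` (character) and `pos`
#'   (integer, 1-based), sorted by chromosome then position, carrying the
#'   chromosome lengths as attribute `chrom_lengths`.
#' @export
#' @examples
#' map <- build_marker_map(200, yeast_chromosomes(), seed = 1)
#' marker_density(map)
build_marker_map <- function(n_markers, chrom_lengths = yeast_chromosomes(),
                             seed = 1L) {
  stopifnot(length(n_markers) == 1L, n_markers >= 1)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (any(chrom_lengths <= 0)) abort("chromosome lengths must be positive")
  total <- sum(chrom_lengths)
  if (n_markers > total) {
    abort("n_markers exceeds the total genome length in bp")
  }
  # largest-remainder apportionment proportional to length
  quota <- n_markers * chrom_lengths / total
  alloc <- floor(quota)
  left <- n_markers - sum(alloc)
  if (left > 0) {
    take <- order(quota - alloc, decreasing = TRUE)[seq_len(left)]
    alloc[take] <- alloc[take] + 1
  }
  # an allocation can exceed a tiny chromosome's bp count; shift the excess
  over <- alloc > chrom_lengths
  while (any(over)) {
    excess <- sum(alloc[over] - chrom_lengths[over])
    alloc[over] <- chrom_lengths[over]
    room <- which(alloc < chrom_lengths)
    alloc[room[seq_len(excess)]] <- alloc[room[seq_len(excess)]] + 1
    over <- alloc > chrom_lengths
  }
  withr::with_seed(seed, {
    markers <- purrr::map2_dfr(names(chrom_lengths), seq_along(chrom_lengths),
      function(nm, i) {
        k <- alloc[i]
        if (k == 0) return(tibble(chrom = character(), pos = integer()))
        tibble(chrom = nm, pos = sort(sample.int(chrom_lengths[i], k)))
      })
  })
  new_marker_map(markers, chrom_lengths)
}

new_marker_map <- function(markers, chrom_lengths) {
  out <- as_tibble(markers)
  attr(out, "chrom_lengths") <- chrom_lengths
  class(out) <- c("marker_map", class(out))
  out
}

#' @export
print.marker_map <- function(x, ...) {
  cl <- chrom_lengths(x)
  cat(sprintf("<marker_map> %d markers over %d chromosomes (%s bp)\n",
              nrow(x), length(cl), format(sum(cl), big.mark = ",")))
  NextMethod()
}

#' Chromosome lengths stored on a marker map
#' @param map A `marker_map`.
#' @return Named numeric vector of lengths (bp).
#' @export
chrom_lengths <- function(map) {
  attr(map, "chrom_lengths")
}

#' Per-bp marker density of a map
#'
#' The number of diverging sites divided by the total genome length; for the
#' full BY/CEN.PK catalogue (21,100 sites over 12,071,326 bp) this is the
#' between-parent heterozygosity, 0.002 to one significant digit.
#'
#' @param map A `marker_map`.
#' @return Density in markers per bp.
#' @export
marker_density <- function(map) {
  nrow(map) / sum(chrom_lengths(map))
}

# internal: 0-based chromosome index per marker, in chrom_lengths order
marker_chrom_index <- function(map) {
  match(map$chrom, names(chrom_lengths(map))) - 1L
}

#' Convert a marker-origin vector to breakpoint segments
#'
#' The two views of a haplotype — per-marker parental origin and a per-chromosome
#' breakpoint list of (start position, origin) runs — must reconstruct each
#' other exactly; [breakpoints_to_origin()] is the inverse.
#'
#' @param origin Integer vector over the map's markers, 0 = BY, 1 = CENPK.
#' @param map The `marker_map` the haplotype is defined on.
#' @return Tibble with columns `chrom`, `start_pos` (first marker of the run),
#'   `end_pos` (last marker of the run), `origin`.
#' @export
haplotype_breakpoints <- function(origin, map) {
  stopifnot(length(origin) == nrow(map))
  df <- tibble(chrom = map$chrom, pos = map$pos, origin = as.integer(origin))
  df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      r <- rle(d$origin)
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      tibble(start_pos = d$pos[starts], end_pos = d$pos[ends],
             origin = r$values)
    }) |>
    dplyr::ungroup()
}

#' Reconstruct a marker-origin vector from breakpoint segments
#'
#' @param segments Tibble as returned by [haplotype_breakpoints()].
#' @param map The `marker_map`.
#' @return Integer origin vector over the map's markers.
#' @export
breakpoints_to_origin <- function(segments, map) {
  origin <- rep(NA_integer_, nrow(map))
  for (i in seq_len(nrow(segments))) {
    sel <- map$chrom == segments$chrom[i] &
      map$pos >= segments$start_pos[i] & map$pos <= segments$end_pos[i]
    origin[sel] <- as.integer(segments$origin[i])
  }
  if (anyNA(origin)) abort("segments do not cover every marker")
  origin
}
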
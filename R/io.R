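POOL_COLUMNS <- c("CHROM", "POS", "REF", "ALT",
                  "AD_REF.LOW", "AD_ALT.LOW", "AD_REF.HIGH", "AD_ALT.HIGH")

#' Read a two-pool variant table
#'
#' Reads per-site allele depths of the reference (LOW) and selected (HIGH)
#' pool, either from a tab-separated table with columns `CHROM`, `POS`, `REF`,
#' `ALT`, `AD_REF.LOW`, `AD_ALT.LOW`, `AD_REF.HIGH`, `AD_ALT.HIGH` (plus any
#' annotation columns), or from a minimal two-sample VCF whose samples are
#' named `LOW` and `HIGH` and carry `AD` in FORMAT. Records are returned
#' sorted by (chromosome, position); unsorted input is sorted with a warning.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return Pool variant tibble.
#' @export
read_pool_table <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  out <- if (format == "vcf") read_pool_vcf(path) else read_pool_tsv(path)
  ad <- out[grep("^AD_", names(out))]
  if (any(as.matrix(ad) < 0, na.rm = TRUE)) {
    abort("negative allele depth in input")
  }
  # chromosome order = order of first appearance (karyotype order is not
  # alphabetical), so a karyotype-sorted file is accepted as sorted
  ch <- factor(out$CHROM, levels = unique(out$CHROM))
  o <- order(ch, out$POS)
  if (!identical(o, seq_len(nrow(out)))) {
    warn("input records were not sorted by (CHROM, POS); sorting")
    out <- out[o, ]
  }
  out
}

read_pool_tsv <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(POOL_COLUMNS, names(out))
  if (length(missing)) {
    abort(paste0("missing required columns: ", paste(missing, collapse = ", ")))
  }
  out
}

read_pool_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  for (s in c("LOW", "HIGH")) {
    if (!s %in% samples) abort(sprintf("VCF is missing sample '%s'", s))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  for (s in c("LOW", "HIGH")) {
    if (all(is.na(ad[, s]))) {
      abort(sprintf("VCF sample '%s' carries no AD field", s))
    }
  }
  split_ad <- function(x) {
    parts <- stringr::str_split_fixed(x, ",", 2)
    cbind(as.integer(parts[, 1]), as.integer(parts[, 2]))
  }
  low <- split_ad(ad[, "LOW"]); high <- split_ad(ad[, "HIGH"])
  fix <- as_tibble(vcfR::getFIX(v))
  out <- tibble(CHROM = fix$CHROM, POS = as.integer(fix$POS),
                REF = fix$REF, ALT = fix$ALT,
                AD_REF.LOW = low[, 1], AD_ALT.LOW = low[, 2],
                AD_REF.HIGH = high[, 1], AD_ALT.HIGH = high[, 2])
  info <- vcfR::extract.info(v, element = "QD", as.numeric = TRUE)
  if (!all(is.na(info))) out$QD <- info
  mq <- vcfR::extract.info(v, element = "MQRankSum", as.numeric = TRUE)
  if (!all(is.na(mq))) out$MQRankSum <- mq
  out$DP <- out$AD_REF.LOW + out$AD_ALT.LOW + out$AD_REF.HIGH +
    out$AD_ALT.HIGH
  out
}

#' Write a two-pool variant table
#'
#' Writes the standard columns (plus `DP`, `QD`, `MQRankSum` when present) as
#' TSV, or a minimal VCF 4.2 with two samples `LOW` and `HIGH` carrying
#' `GT:AD:DP`. Simulation-truth columns (`freq_true_*`) are dropped. Numeric
#' annotation output uses 6 significant digits.
#'
#' @param records Pool variant tibble.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param chrom_lengths Optional named lengths for VCF contig headers.
#' @param seed Optional seed recorded in the header line.
#' @return `path`, invisibly.
#' @export
write_pool_table <- function(records, path, format = c("auto", "tsv", "vcf"),
                             chrom_lengths = NULL, seed = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    keep <- intersect(c(POOL_COLUMNS, "DP", "QD", "MQRankSum"), names(records))
    header <- sprintf("# saltqtl pool variant table%s",
                      if (is.null(seed)) "" else sprintf(" (seed %d)", seed))
    writeLines(header, path)
    out <- records[keep]
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], signif, digits = 6)
    readr::write_tsv(out, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    write_pool_vcf(records, path, chrom_lengths, seed)
  }
  invisible(path)
}

write_pool_vcf <- function(records, path, chrom_lengths = NULL, seed = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=saltqtl%s", if (is.null(seed)) ""
            else sprintf(" (seed %d)", seed)),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Combined depth">',
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">')
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                          as.integer(chrom_lengths)))
  } else {
    hdr <- c(hdr, sprintf("##contig=<ID=%s>", unique(records$CHROM)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", "LOW", "HIGH"), collapse = "\t"))
  dp_low <- records$AD_REF.LOW + records$AD_ALT.LOW
  dp_high <- records$AD_REF.HIGH + records$AD_ALT.HIGH
  info <- sprintf("DP=%d", dp_low + dp_high)
  if ("QD" %in% names(records)) {
    info <- paste0(info, ";QD=", signif(records$QD, 6))
  }
  if ("MQRankSum" %in% names(records)) {
    info <- paste0(info, ";MQRankSum=", signif(records$MQRankSum, 6))
  }
  body <- paste(records$CHROM, records$POS, ".", records$REF, records$ALT,
                ".", "PASS", info, "GT:AD:DP",
                sprintf("0/1:%d,%d:%d", records$AD_REF.LOW,
                        records$AD_ALT.LOW, dp_low),
                sprintf("0/1:%d,%d:%d", records$AD_REF.HIGH,
                        records$AD_ALT.HIGH, dp_high),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write QTL intervals as BED and TSV
#'
#' The BED file is 0-based half-open; the TSV mirror is 1-based inclusive.
#' Each file states its coordinate convention in a header line.
#'
#' @param intervals Interval tibble from [call_qtl_intervals()].
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_intervals <- function(intervals, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    lines <- c("# QTL intervals, BED: 0-based half-open [start, end)",
               sprintf("%s\t%d\t%d\tpeak=%s;neglog10p=%s",
                       intervals$CHROM, intervals$start - 1L, intervals$end,
                       intervals$peak_pos,
                       signif(intervals$peak_neglog10p, 6)))
    writeLines(lines, bed_path)
  }
  if (!is.null(tsv_path)) {
    writeLines("# QTL intervals, TSV: 1-based inclusive [start, end]",
               tsv_path)
    out <- intervals
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], signif, digits = 6)
    readr::write_tsv(out, tsv_path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Write and read a population genotype matrix
#'
#' Tab-separated strain x marker table with values `BY` / `CENPK`.
#'
#' @param pop A `segregant_population`.
#' @param path Output TSV.
#' @return `path` (writer) or an integer origin matrix with marker column
#'   names `chrom:pos` (reader), strains in rows.
#' @export
write_genotypes <- function(pop, path) {
  m <- pop$origins
  lab <- matrix(c("BY", "CENPK")[m + 1L], nrow = nrow(m))
  df <- as.data.frame(lab)
  names(df) <- paste0(pop$map$chrom, ":", pop$map$pos)
  df <- cbind(strain = sprintf("%s_%04d", pop$generation, seq_len(nrow(m))),
              df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1])
  out <- matrix(match(m, c("BY", "CENPK")) - 1L, nrow = nrow(m),
                dimnames = list(df$strain, colnames(m)))
  out
}

#' Write per-strain phenotypes of a population
#'
#' @param pop A `segregant_population`.
#' @param path Output TSV (columns: strain, one column per concentration).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pop, path) {
  df <- as_tibble(signif(pop$phenotypes, 6))
  names(df) <- sprintf("M%.2f", pop$concentrations)
  df <- dplyr::bind_cols(
    tibble(strain = sprintf("%s_%04d", pop$generation,
                            seq_len(nrow(pop$origins)))), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read and write run configuration
#'
#' A run configuration is a sectioned plain-text file (`[section]` headers,
#' `key = value` lines, `#` comments). Sections: `[genome]` (`n_markers`,
#' `recomb_rate`, optional `chrom_lengths` as comma-separated `name:bp`),
#' `[trait]` (`noise_sd`, `loci` as semicolon-separated
#' `chrom:pos:effect:scaling`, `concentrations` comma-separated), `[plan]`
#' (`steps` as semicolon-separated `generation:cross_to:n:select_conc`),
#' `[sequencing]` (`depth`, `survival_fraction`, `selection_conc`), `[scan]`
#' (`window_bp`, `median_window_bp`, `threshold`, `hampel_c`, `min_depth`,
#' `merge_gap_bp`), `[seed]` (`seed`).
#'
#' @param path Config file.
#' @return Nested named list of sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) abort("config entries must appear inside a section")
      kv <- stringr::str_split_fixed(ln, "=", 2)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      num <- suppressWarnings(as.numeric(val))
      cfg[[section]][[key]] <- if (!is.na(num) && !grepl("[:;,]", val)) num
                               else val
    } else {
      abort(sprintf("cannot parse config line: '%s'", ln))
    }
  }
  cfg
}

#' @rdname read_run_config
#' @param cfg Nested named list of sections.
#' @return For the writer, `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  lines <- unlist(purrr::imap(cfg, function(sec, nm) {
    c(sprintf("[%s]", nm),
      purrr::imap_chr(sec, function(v, k) sprintf("%s = %s", k, v)), "")
  }))
  writeLines(lines, path)
  invisible(path)
}

# internal: turn a parsed config into simulator inputs
config_to_inputs <- function(cfg) {
  g <- cfg$genome %||% list()
  lens <- if (!is.null(g$chrom_lengths)) {
    parts <- stringr::str_split_fixed(
      stringr::str_split_1(g$chrom_lengths, ","), ":", 2)
    setNames(as.numeric(parts[, 2]), trimws(parts[, 1]))
  } else yeast_chromosomes()
  seed <- as.integer(cfg$seed$seed %||% 1)
  map <- build_marker_map(as.integer(g$n_markers %||% 2000), lens,
                          seed = seed)
  tr <- cfg$trait %||% list()
  loci <- if (!is.null(tr$loci)) {
    parts <- stringr::str_split_fixed(stringr::str_split_1(tr$loci, ";"),
                                      ":", 4)
    tibble(chrom = trimws(parts[, 1]), pos = as.integer(parts[, 2]),
           effect = as.numeric(parts[, 3]),
           conc_scaling = as.numeric(parts[, 4]))
  } else default_trait_loci(map)
  concs <- if (!is.null(tr$concentrations)) {
    as.numeric(stringr::str_split_1(as.character(tr$concentrations), ","))
  } else seq(0.25, 2.5, by = 0.25)
  trait <- trait_model(loci, noise_sd = as.numeric(tr$noise_sd %||% 0.1),
                       concentrations = concs)
  p <- cfg$plan %||% list()
  plan <- if (!is.null(p$steps)) {
    parts <- stringr::str_split_fixed(stringr::str_split_1(p$steps, ";"),
                                      ":", 4)
    cross_plan(trimws(parts[, 1]), trimws(parts[, 2]),
               as.integer(parts[, 3]), as.numeric(parts[, 4]))
  } else desk_plan()
  sq <- cfg$sequencing %||% list()
  list(map = map, trait = trait, plan = plan, seed = seed,
       recomb_rate = as.numeric(g$recomb_rate %||% 0.35),
       depth = as.numeric(sq$depth %||% 100),
       survival_fraction = as.numeric(sq$survival_fraction %||% 0.01),
       selection_conc = as.numeric(sq$selection_conc %||% 1.5),
       scan = cfg$scan %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
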
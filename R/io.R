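#' Write a synthetic dataset to plain-text fixtures
#'
#' Emits BED files (OCRs, genes, origins) and headered TSVs (genotypes,
#' counts, SNP calls, hotness track, truth tables) that round-trip losslessly
#' through the package readers.
#'
#' @param dataset List from [simulate_dataset()].
#' @param ocrs OCR tibble.
#' @param genotypes Wide genotype tibble.
#' @param layout A `genome_layout`.
#' @param truth A `cross_truth`.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector: the manifest of written paths.
#' @export
write_fixtures <- function(dataset, ocrs, genotypes, layout, truth, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory: %s", out_dir))
  }
  p <- function(f) file.path(out_dir, f)
  manifest <- c(
    ocrs = p("ocrs.bed"), genes = p("genes.bed"), origins = p("origins.bed"),
    genotypes = p("genotypes.tsv"), counts = p("counts.tsv"),
    snp_calls = p("snp_calls.tsv"), parental_snp_calls = p("parental_snp_calls.tsv"),
    hotness = p("hotness.tsv"), chromosomes = p("chromosomes.tsv"),
    library_sizes = p("library_sizes.tsv"),
    truth_cis = p("truth_cis.tsv"), truth_trans = p("truth_trans.tsv")
  )
  write_bed(dplyr::transmute(ocrs, .data$chrom, .data$start, .data$end,
                             name = .data$ocr), manifest["ocrs"])
  write_bed(dplyr::transmute(layout$genes, .data$chrom, .data$start, .data$end,
                             name = .data$name, score = 0L,
                             strand = .data$strand), manifest["genes"])
  write_bed(layout$origins, manifest["origins"])
  readr::write_tsv(genotypes, manifest["genotypes"])
  readr::write_tsv(dataset$counts, manifest["counts"])
  readr::write_tsv(dataset$snp_profiles, manifest["snp_calls"])
  readr::write_tsv(dataset$parental_profiles, manifest["parental_snp_calls"])
  readr::write_tsv(layout$hotness, manifest["hotness"])
  readr::write_tsv(layout$chromosomes, manifest["chromosomes"])
  readr::write_tsv(tibble::tibble(strain = names(dataset$library_sizes),
                                  total_reads = unname(dataset$library_sizes)),
                   manifest["library_sizes"])
  readr::write_tsv(truth$cis_effects, manifest["truth_cis"])
  readr::write_tsv(truth$trans_effects, manifest["truth_trans"])
  manifest
}

#' Read/write BED intervals (0-based half-open) as tidy tibbles
#'
#' Headerless tab-separated BED with 3-6 columns; extra columns beyond the
#' ones present are dropped on write.
#'
#' @param path File path.
#' @return `read_bed()`: tibble with `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  names(df) <- cols[seq_len(ncol(df))]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

#' @rdname read_bed
#' @param x Tibble with `chrom`, `start`, `end` and optional BED columns.
#' @export
write_bed <- function(x, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  readr::write_tsv(x[, keep], path, col_names = FALSE)
  invisible(path)
}

#' Read a headered TSV matrix or table written by [write_fixtures()]
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
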
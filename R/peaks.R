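#' Consolidate per-strain peak calls into a unified OCR set
#'
#' Peaks shorter than `min_len` are symmetrically extended to exactly
#' `min_len` (an odd deficit puts the extra base on the right), clipped at
#' chromosome bounds, then the union across all strains is computed:
#' overlapping and bookended intervals (`[a,b)`, `[b,c)`) are merged, the
#' standard BED-merge semantics at distance 0. Output is sorted with ids
#' assigned left-to-right per chromosome.
#'
#' @param per_strain_peaks A tibble of intervals (`chrom`, `start`, `end`;
#'   0-based half-open) pooled over strains, or a list of such tibbles.
#' @param chrom_lengths Named integer vector of chromosome lengths, or a
#'   tibble with `name`/`length` columns (e.g. `layout$chromosomes`).
#' @param min_len Minimum peak length in bp after extension.
#' @return OCR tibble: `ocr`, `chrom`, `start`, `end`, `size`.
#' @export
extend_and_merge_peaks <- function(per_strain_peaks, chrom_lengths, min_len = 15) {
  if (is.list(per_strain_peaks) && !is.data.frame(per_strain_peaks)) {
    per_strain_peaks <- purrr::list_rbind(
      purrr::map(per_strain_peaks, tibble::as_tibble))
  }
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- stats::setNames(chrom_lengths$length, chrom_lengths$name)
  }
  pk <- tibble::as_tibble(per_strain_peaks)
  .check_intervals(pk, "peak")
  .assert(all(pk$chrom %in% names(chrom_lengths)),
          "peak on a chromosome absent from chrom_lengths")
  len <- unname(chrom_lengths[pk$chrom])
  .assert(all(pk$end <= len), "peak exceeds chromosome bounds")

  deficit <- pmax(0L, min_len - (pk$end - pk$start))
  start <- pk$start - deficit %/% 2L
  end <- pk$end + (deficit - deficit %/% 2L)
  # clip, pushing the lost extension to the other side where room remains
  shift_r <- pmax(0L, -start)
  shift_l <- pmax(0L, end - len)
  start <- pmax(0L, start - shift_l)
  end <- pmin(len, end + shift_r)

  merged <- purrr::map_dfr(split(tibble::tibble(chrom = pk$chrom, start = start,
                                                end = end), pk$chrom),
    function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end),
                            min.gapwidth = 1L)
      tibble::tibble(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
                     end = IRanges::end(ir))
    })
  merged %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::mutate(ocr = sprintf("ocr%04d", dplyr::row_number()),
                  size = .data$end - .data$start) %>%
    dplyr::select("ocr", "chrom", "start", "end", "size")
}

#' Count reads per OCR per strain by midpoint containment
#'
#' A read is assigned to an OCR when its midpoint (`floor((start+end)/2)`)
#' falls inside the OCR's half-open interval, so no read is double-counted.
#'
#' @param reads Long tibble `strain`, `chrom`, `start`, `end` of read
#'   placements (BED intervals).
#' @param ocrs OCR tibble.
#' @return Wide counts tibble: `ocr` plus one integer column per strain.
#' @export
count_reads_in_ocrs <- function(reads, ocrs) {
  .check_intervals(reads, "read")
  strains <- sort(unique(reads$strain))
  counts <- matrix(0L, nrow = nrow(ocrs), ncol = length(strains),
                   dimnames = list(ocrs$ocr, strains))
  mids <- tibble::tibble(strain = reads$strain, chrom = reads$chrom,
                         mid = (reads$start + reads$end) %/% 2L)
  for (cn in unique(ocrs$chrom)) {
    oc <- ocrs[ocrs$chrom == cn, ]
    md <- mids[mids$chrom == cn, ]
    if (nrow(md) == 0) next
    hit <- IRanges::findOverlaps(IRanges::IRanges(md$mid + 1L, md$mid + 1L),
                                 IRanges::IRanges(oc$start + 1L, oc$end))
    if (length(hit) == 0) next
    tab <- table(ocr = oc$ocr[S4Vectors::subjectHits(hit)],
                 strain = md$strain[S4Vectors::queryHits(hit)])
    counts[rownames(tab), colnames(tab)] <- counts[rownames(tab), colnames(tab)] +
      matrix(as.integer(tab), nrow = nrow(tab))
  }
  dplyr::bind_cols(tibble::tibble(ocr = ocrs$ocr), tibble::as_tibble(counts))
}

#' Normalize a counts matrix to standardized peak densities
#'
#' Chain: density = count / (OCR size in kb x library size in millions)
#' (reads per kb per million); log2, with zero densities mapped to -Inf;
#' ceiling (all negative values set to 0); finally each strain column scaled
#' to zero mean and unit variance. `stage` picks where to stop.
#'
#' @param counts Wide counts tibble (`ocr` + strain columns).
#' @param ocrs OCR tibble (for sizes).
#' @param library_sizes Named numeric vector of per-strain read totals, or a
#'   tibble with `strain`/`total_reads`.
#' @param stage One of `"density"`, `"log2-ceiled"`, `"standardized"`.
#' @return Wide tibble, same shape as `counts`, with attribute `stage`.
#' @export
normalize_density <- function(counts, ocrs, library_sizes,
                              stage = c("standardized", "log2-ceiled", "density")) {
  stage <- match.arg(stage)
  if (is.data.frame(library_sizes)) {
    library_sizes <- stats::setNames(library_sizes$total_reads, library_sizes$strain)
  }
  strains <- strain_cols(counts)
  .assert(all(strains %in% names(library_sizes)),
          "strain missing from library_sizes")
  .assert(all(library_sizes[strains] > 0), "library sizes must be positive")
  size_kb <- ocrs$size[match(counts$ocr, ocrs$ocr)] / 1000
  .assert(all(size_kb > 0) && !anyNA(size_kb), "OCR sizes must be positive")

  m <- as.matrix(counts[, strains])
  m <- m / outer(size_kb, unname(library_sizes[strains]) / 1e6)
  if (stage != "density") {
    m <- log2(m)          # zero density -> -Inf
    m[m < 0] <- 0         # ceiling
    if (stage == "standardized") m <- scale(m)
  }
  out <- dplyr::bind_cols(tibble::tibble(ocr = counts$ocr), tibble::as_tibble(m))
  attr(out, "stage") <- stage
  out
}

#' Quantify reads over OCRs and normalize in one step
#'
#' @inheritParams count_reads_in_ocrs
#' @inheritParams normalize_density
#' @return Standardized density tibble (see [normalize_density()]).
#' @export
quantify_and_normalize <- function(reads, ocrs, library_sizes) {
  normalize_density(count_reads_in_ocrs(reads, ocrs), ocrs, library_sizes)
}

#' Classify OCRs by genomic context
#'
#' Labels each OCR promoter / TTS / ORF / other with priority
#' promoter > TTS > ORF, and independently flags replication-origin overlap.
#' Promoters are the `promoter_window` bp upstream of the TSS (strand-aware);
#' the TTS window extends `tts_window` bp to both sides of the termination
#' site. Any base-pair overlap counts.
#'
#' @param ocrs OCR tibble.
#' @param genes Gene tibble (`chrom`, `start`, `end`, `strand`).
#' @param origins Origin interval tibble (may be empty).
#' @param promoter_window Promoter size upstream of TSS, bp.
#' @param tts_window Half-width of the TTS window, bp.
#' @return List: `labels` (per-OCR tibble with `context` and `on_origin`),
#'   `summary` (one-row tibble of fractions, incl. the fraction of genes with
#'   a promoter OCR).
#' @export
classify_ocr_context <- function(ocrs, genes, origins = NULL,
                                 promoter_window = 500, tts_window = 200) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  prom <- tibble::tibble(chrom = genes$chrom,
                         start = ifelse(genes$strand == "+", tss - promoter_window, tss),
                         end = ifelse(genes$strand == "+", tss, tss + promoter_window),
                         gene = genes$name)
  ttsw <- tibble::tibble(chrom = genes$chrom, start = tts - tts_window,
                         end = tts + tts_window)
  orf <- genes[, c("chrom", "start", "end")]

  ov <- function(feat) .overlaps_any(ocrs, feat)
  is_prom <- ov(prom); is_tts <- ov(ttsw); is_orf <- ov(orf)
  on_origin <- if (is.null(origins) || nrow(origins) == 0)
    rep(FALSE, nrow(ocrs)) else ov(origins)

  context <- dplyr::case_when(is_prom ~ "promoter", is_tts ~ "TTS",
                              is_orf ~ "ORF", TRUE ~ "other")
  labels <- tibble::tibble(ocr = ocrs$ocr, context = context,
                           on_origin = on_origin)
  genes_with_prom <- .overlaps_any(prom, ocrs)
  summary <- tibble::tibble(
    frac_promoter = mean(context == "promoter"),
    frac_tts = mean(context == "TTS"),
    frac_orf = mean(context == "ORF"),
    frac_other = mean(context == "other"),
    frac_on_origin = mean(on_origin),
    frac_genes_with_promoter_ocr = mean(genes_with_prom)
  )
  list(labels = labels, summary = summary)
}

# TRUE for each row of `x` overlapping any interval of `feat` (>= 1 bp).
.overlaps_any <- function(x, feat) {
  out <- logical(nrow(x))
  for (cn in unique(x$chrom)) {
    xi <- which(x$chrom == cn)
    fi <- feat[feat$chrom == cn & feat$end > feat$start, ]
    if (nrow(fi) == 0) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(x$start[xi] + 1L, x$end[xi]),
      IRanges::IRanges(fi$start + 1L, fi$end))
    out[xi[unique(S4Vectors::queryHits(hit))]] <- TRUE
  }
  out
}
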
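#' Gene density around OCRs
#'
#' Counts the genes overlapping a window extending `window` bp beyond both
#' peak boundaries and divides by the peak size, giving genes per kb of peak.
#' OCRs in the top decile of density are flagged gene-rich; those in the
#' bottom 5% gene-poor.
#'
#' @param ocrs OCR tibble.
#' @param genes Gene tibble (`chrom`, `start`, `end`).
#' @param window Flank beyond each boundary, bp (default 50 kb).
#' @param rich_quantile,poor_quantile Classification quantiles.
#' @return Tibble: `ocr`, `n_genes`, `density` (genes/kb), `gene_rich`,
#'   `gene_poor`.
#' @export
gene_density <- function(ocrs, genes, window = 5e4,
                         rich_quantile = 0.9, poor_quantile = 0.05) {
  n <- integer(nrow(ocrs))
  for (cn in unique(ocrs$chrom)) {
    oi <- which(ocrs$chrom == cn)
    gn <- genes[genes$chrom == cn, ]
    if (nrow(gn) == 0) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(pmax(0L, ocrs$start[oi] - window) + 1L,
                       ocrs$end[oi] + window),
      IRanges::IRanges(gn$start + 1L, gn$end))
    cnt <- table(factor(S4Vectors::queryHits(hit), levels = seq_along(oi)))
    n[oi] <- as.integer(cnt)
  }
  density <- n / (ocrs$size / 1000)
  tibble::tibble(ocr = ocrs$ocr, n_genes = n, density = density,
                 gene_rich = density >= stats::quantile(density, rich_quantile),
                 gene_poor = density <= stats::quantile(density, poor_quantile))
}

#' Telomere-distance profile of a per-OCR statistic
#'
#' Each OCR's distance from the chromosome ends is `min(start, length - end)`.
#' The statistic is averaged in sliding windows of `window` bp placed every
#' `step` bp along the distance axis, and OCRs closer than `near` to an end
#' are compared with the rest by a two-sample t test.
#'
#' @param values Named numeric vector keyed by OCR id (e.g.
#'   [trans_variation()] output).
#' @param ocrs OCR tibble.
#' @param layout A `genome_layout` (for chromosome lengths).
#' @param window Sliding-window width, bp (default 2 kb).
#' @param step Window step, bp (default 1 kb).
#' @param near Distance cutoff for the near-telomere group (default 10 kb).
#' @return List: `distances` (tibble ocr/distance/value), `profile` (tibble
#'   `bin_start`, `mid`, `mean`, `n`), `test` (one-row tibble `t`, `p`,
#'   `n_near`, `n_far`, `mean_near`, `mean_far`).
#' @export
telomere_profile <- function(values, ocrs, layout, window = 2e3, step = 1e3,
                             near = 1e4) {
  oc <- ocrs[ocrs$ocr %in% names(values), ]
  len <- layout$chromosomes$length[match(oc$chrom, layout$chromosomes$name)]
  dist <- pmin(oc$start, len - oc$end)
  v <- unname(values[oc$ocr])
  distances <- tibble::tibble(ocr = oc$ocr, distance = dist, value = v)

  starts <- seq(0, max(dist), by = step)
  profile <- purrr::map_dfr(starts, function(s) {
    inb <- dist >= s & dist < s + window
    tibble::tibble(bin_start = s, mid = s + window / 2,
                   mean = if (any(inb)) mean(v[inb]) else NA_real_,
                   n = sum(inb))
  })
  near_g <- v[dist < near]; far_g <- v[dist >= near]
  test <- if (length(near_g) >= 2 && length(far_g) >= 2) {
    tt <- .two_sample_t(near_g, far_g, var_equal = FALSE)
    tibble::tibble(t = tt$t, p = tt$p, n_near = length(near_g),
                   n_far = length(far_g), mean_near = mean(near_g),
                   mean_far = mean(far_g))
  } else {
    tibble::tibble(t = NA_real_, p = NA_real_, n_near = length(near_g),
                   n_far = length(far_g), mean_near = NA_real_,
                   mean_far = NA_real_)
  }
  list(distances = distances, profile = profile, test = test)
}

#' Recombination hotness of an OCR set
#'
#' Assigns each OCR the mean log2 hotness score of track loci within
#' `assign_window` bp of the OCR interval (falling back to the nearest locus
#' when none is that close), then tests the assigned scores against zero with
#' a one-sample t test.
#'
#' @param ocr_set OCR tibble (must be non-empty).
#' @param track Hotness tibble (`chrom`, `pos`, `score`).
#' @param assign_window Assignment window, bp (default 5 kb).
#' @param alternative t-test alternative (`"two.sided"`, `"less"`,
#'   `"greater"`).
#' @return List: `scores` (tibble ocr/score), `mean`, `t`, `p`, `n`.
#' @export
recombination_hotness <- function(ocr_set, track, assign_window = 5e3,
                                  alternative = "two.sided") {
  .assert(nrow(ocr_set) > 0, "empty OCR set")
  .assert(nrow(track) > 0, "empty hotness track")
  score <- purrr::pmap_dbl(ocr_set[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      tr <- track[track$chrom == chrom, ]
      if (nrow(tr) == 0) return(NA_real_)
      gap <- .interval_gap(start, end, tr$pos, tr$pos + 1L)
      inw <- gap <= assign_window
      if (any(inw)) mean(tr$score[inw]) else tr$score[which.min(gap)]
    })
  keep <- !is.na(score)
  score <- score[keep]
  .assert(length(score) > 0, "no OCR could be assigned a hotness score")
  if (length(score) < 2 || stats::sd(score) == 0) {
    m <- mean(score)
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0   # degenerate zero-variance limit
  } else {
    ht <- stats::t.test(score, mu = 0, alternative = alternative)
    t <- unname(ht$statistic); p <- ht$p.value; m <- mean(score)
  }
  list(scores = tibble::tibble(ocr = ocr_set$ocr[keep], score = score),
       mean = mean(score), t = t, p = p, n = length(score))
}

#' Scan a sequence for poly-A/T tracts
#'
#' Finds maximal runs of bases in \{A, T\} (mixed runs count by default; set
#' `mode = "homopolymer"` to require a single base) of length at least
#' `min_run`.
#'
#' @param sequence DNA string over A/C/G/T/N (case-insensitive).
#' @param min_run Minimum run length (default 5).
#' @param mode `"mixed"` or `"homopolymer"`.
#' @return List: `flag` (any qualifying run) and `runs` (tibble `start`,
#'   `end`, 0-based half-open).
#' @export
poly_at_scan <- function(sequence, min_run = 5, mode = c("mixed", "homopolymer")) {
  mode <- match.arg(mode)
  s <- toupper(sequence)
  .assert(grepl("^[ACGTN]*$", s), "sequence must be over {A,C,G,T,N}")
  pat <- if (mode == "mixed") sprintf("[AT]{%d,}", min_run)
         else sprintf("A{%d,}|T{%d,}", min_run, min_run)
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(list(flag = FALSE, runs = tibble::tibble(start = integer(),
                                                    end = integer())))
  }
  st <- as.integer(m) - 1L
  en <- st + attr(m, "match.length")
  list(flag = TRUE, runs = tibble::tibble(start = st, end = en))
}

#' Enrichment of cis-association among motif-polymorphic OCRs
#'
#' An OCR is motif-polymorphic when at least one SNP position falls inside at
#' least one TF-motif occurrence within the OCR (half-open intervals: a SNP
#' at the interval start is inside, at the end coordinate outside). Builds
#' the 2x2 table of motif-polymorphic by cis-associated and returns the
#' sample odds ratio with a two-sided Fisher exact p.
#'
#' @param ocrs OCR tibble.
#' @param motif_occurrences Motif interval tibble (`chrom`, `start`, `end`,
#'   0-based half-open; produced externally).
#' @param snp_positions Tibble (`chrom`, `pos`) with `pos` on the same
#'   0-based scale as the intervals (subtract 1 from 1-based SNP calls).
#' @param cis_flags Logical vector along `ocrs` rows: cis-associated or not.
#' @return List: `table` (2x2 matrix), `odds_ratio` (ad/bc), `p`,
#'   `degenerate` (TRUE when a zero margin makes the odds ratio undefined;
#'   then `p = 1`), `polymorphic` (per-OCR flag tibble).
#' @export
motif_polymorphism_enrichment <- function(ocrs, motif_occurrences,
                                          snp_positions, cis_flags) {
  .assert(length(cis_flags) == nrow(ocrs), "cis_flags must match ocrs rows")
  snp_in_motif <- rep(FALSE, nrow(snp_positions))
  for (cn in unique(snp_positions$chrom)) {
    si <- which(snp_positions$chrom == cn)
    mo <- motif_occurrences[motif_occurrences$chrom == cn, ]
    if (nrow(mo) == 0) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(snp_positions$pos[si] + 1L, snp_positions$pos[si] + 1L),
      IRanges::IRanges(mo$start + 1L, mo$end))
    snp_in_motif[si[unique(S4Vectors::queryHits(hit))]] <- TRUE
  }
  hits <- snp_positions[snp_in_motif, , drop = FALSE]
  poly <- logical(nrow(ocrs))
  if (nrow(hits) > 0) {
    for (cn in unique(ocrs$chrom)) {
      oi <- which(ocrs$chrom == cn)
      hp <- hits[hits$chrom == cn, ]
      if (nrow(hp) == 0) next
      hit <- IRanges::findOverlaps(
        IRanges::IRanges(ocrs$start[oi] + 1L, ocrs$end[oi]),
        IRanges::IRanges(hp$pos + 1L, hp$pos + 1L))
      poly[oi[unique(S4Vectors::queryHits(hit))]] <- TRUE
    }
  }
  tab <- matrix(c(sum(poly & cis_flags), sum(poly & !cis_flags),
                  sum(!poly & cis_flags), sum(!poly & !cis_flags)),
                nrow = 2, byrow = TRUE,
                dimnames = list(motif_poly = c("yes", "no"),
                                cis = c("yes", "no")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    or <- NA_real_; p <- 1
  } else {
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    p <- stats::fisher.test(tab)$p.value
  }
  list(table = tab, odds_ratio = or, p = p, degenerate = degenerate,
       polymorphic = tibble::tibble(ocr = ocrs$ocr, motif_polymorphic = poly))
}
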
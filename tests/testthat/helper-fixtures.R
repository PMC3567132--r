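# Shared small synthetic fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Compact 4-chromosome pipeline world: cross, OCRs, injected effects, dataset.
small_world <- function() {
  with_cache("small_world", {
    layout <- simulate_genome_layout(n_chrom = 4, seed = 11)
    geno <- simulate_cross(layout, default_marker_positions(layout, 200),
                           n_strains = 96, seed = 12)
    ocrs <- simulate_ocrs(layout, n_ocrs = 400, seed = 13)
    truth <- cross_truth(ocrs, geno, n_cis = 20, cis_effect = 1.2,
                         n_hotspots = 1, targets_per_hotspot = 40,
                         trans_effect = 1.0, seed = 14)
    ds <- simulate_dataset(layout, geno, ocrs, truth, seed = 15)
    dens <- normalize_density(ds$counts, ocrs, ds$library_sizes)
    list(layout = layout, geno = geno, ocrs = ocrs, truth = truth,
         ds = ds, dens = dens)
  })
}

# Random interval set on one chromosome, for union-oracle checks.
random_peaks <- function(n, chrom_len, min_size = 1, max_size = 60) {
  start <- sample.int(chrom_len - max_size, n, replace = TRUE) - 1L
  size <- sample.int(max_size - min_size + 1, n, replace = TRUE) + min_size - 1L
  tibble::tibble(chrom = "chrU", start = start, end = start + size)
}

# Brute-force interval union via a per-base boolean vector (half-open coords).
boolean_union_oracle <- function(intervals, chrom_len) {
  v <- logical(chrom_len)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (e > s) v[(s + 1):e] <- TRUE
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# Minimal hand-built SNP world for genotyping rules: one OCR, two sites.
toy_snp_world <- function(strain_alleles, by = c("A", "C"), rm = c("G", "T")) {
  k <- length(by)
  ocrs <- tibble::tibble(ocr = "ocrX", chrom = "chr1", start = 100L,
                         end = 200L, size = 100L)
  pos <- seq(110L, length.out = k, by = 10L)
  parent <- function(name, al) {
    tibble::tibble(strain = name, chrom = "chr1", pos = pos, allele = al,
                   depth = 30L, major_fraction = 1)
  }
  prof <- purrr::imap_dfr(strain_alleles, function(al, s) {
    tibble::tibble(strain = s, chrom = "chr1", pos = pos[seq_along(al)],
                   allele = al, depth = 10L, major_fraction = 1)
  })
  list(ocrs = ocrs, by = parent("BY", by), rm = parent("RM", rm), prof = prof)
}
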
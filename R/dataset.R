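#' Place synthetic open chromatin regions on a genome layout
#'
#' OCRs are dropped at gene-promoter-biased positions, non-overlapping,
#' sorted, with ids assigned left-to-right per chromosome. Sizes emulate
#' merged FAIRE peaks (median ~236 bp).
#'
#' @param layout A `genome_layout`.
#' @param n_ocrs Number of OCRs to place.
#' @param size_range Min/max OCR size in bp.
#' @param seed Integer seed.
#' @return Tibble `ocr`, `chrom`, `start`, `end`, `size` (bp, 0-based
#'   half-open), non-overlapping and sorted.
#' @export
simulate_ocrs <- function(layout, n_ocrs = 2000, size_range = c(100, 500), seed = 1L) {
  restore <- .local_seed(seed)
  on.exit(restore(), add = TRUE)
  total <- sum(layout$chromosomes$length)
  per_chrom <- pmax(1L, round(n_ocrs * layout$chromosomes$length / total))
  out <- purrr::pmap(list(layout$chromosomes$name, layout$chromosomes$length, per_chrom),
    function(cn, len, k) {
      sizes <- as.integer(round(stats::runif(k, size_range[1], size_range[2])))
      # lay OCRs on a jittered grid so they cannot overlap
      slots <- seq(0, len - max(sizes) - 1, length.out = max(k, 2))
      starts <- as.integer(sort(sample(round(slots), k)) +
                             round(stats::runif(k, 0, 50)))
      tibble::tibble(chrom = cn, start = starts, end = starts + sizes)
    }) %>% purrr::list_rbind()
  out <- out %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::mutate(ocr = sprintf("ocr%04d", dplyr::row_number()),
                  size = .data$end - .data$start) %>%
    dplyr::select("ocr", "chrom", "start", "end", "size")
  # enforce non-overlap defensively (jitter could collide on tiny chromosomes)
  out %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::filter(dplyr::row_number() == 1 | .data$start >= dplyr::lag(.data$end)) %>%
    dplyr::ungroup()
}

#' Ground-truth effect table for a synthetic cross dataset
#'
#' Defines which OCRs carry a local-sequence (cis) effect, which marker acts
#' as a trans hotspot and which OCRs it targets, per-OCR baseline log2
#' densities, the strain-level noise, and per-strain library sizes. Effects
#' are shifts on the log2 density scale attributed to the BY allele; defaults
#' keep the per-strain column standard deviation near 1 so a log2-scale shift
#' of e lands as a group-mean difference of ~e after standardization.
#'
#' @param ocrs OCR tibble from [simulate_ocrs()].
#' @param genotypes Wide genotype tibble from [simulate_cross()].
#' @param n_cis Number of OCRs given a cis effect.
#' @param cis_effect Log2-scale density shift for the BY allele at cis OCRs.
#' @param n_hotspots Number of trans hotspot marker loci.
#' @param targets_per_hotspot OCRs targeted by each hotspot.
#' @param trans_effect Log2-scale shift per hotspot target.
#' @param baseline_log2 Mean baseline log2 density (reads/kb/million).
#' @param baseline_sd SD of per-OCR baselines.
#' @param noise_sd SD of strain-by-OCR Gaussian noise on the log2 scale.
#' @param library_size Mean per-strain read total; actual totals jittered 10%.
#' @param seed Integer seed.
#' @return `cross_truth` list: `cis_effects`, `trans_effects`, `baseline`
#'   tibbles, `ocr_marker` (OCR to nearest-marker map), `noise_sd`,
#'   `library_sizes`, `seed`.
#' @export
cross_truth <- function(ocrs, genotypes, n_cis = 100, cis_effect = 1.0,
                        n_hotspots = 1, targets_per_hotspot = 80,
                        trans_effect = 1.0, baseline_log2 = 6,
                        baseline_sd = 0.6, noise_sd = 0.8,
                        library_size = 5e6, seed = 1L) {
  .assert(noise_sd >= 0 && baseline_sd >= 0, "negative sd parameter")
  .assert(library_size > 0, "library_size must be positive")
  restore <- .local_seed(seed)
  on.exit(restore(), add = TRUE)

  strains <- strain_cols(genotypes)
  ocr_marker <- nearest_marker(ocrs, genotypes)

  cis_ids <- sample(ocrs$ocr, min(n_cis, nrow(ocrs)))
  cis_effects <- tibble::tibble(ocr = sort(cis_ids), effect = cis_effect)

  trans_effects <- tibble::tibble(marker = character(), ocr = character(),
                                  effect = numeric())
  if (n_hotspots > 0) {
    hot_markers <- sample(genotypes$marker, n_hotspots)
    trans_effects <- purrr::map_dfr(hot_markers, function(mk) {
      mk_chrom <- genotypes$chrom[genotypes$marker == mk]
      # targets are distal OCRs (other chromosomes) so injected links are trans
      pool <- setdiff(ocrs$ocr[ocrs$chrom != mk_chrom], cis_ids)
      tibble::tibble(marker = mk,
                     ocr = sort(sample(pool, min(targets_per_hotspot, length(pool)))),
                     effect = trans_effect)
    })
  }

  baseline <- tibble::tibble(
    ocr = ocrs$ocr,
    baseline = stats::rnorm(nrow(ocrs), baseline_log2, baseline_sd)
  )
  lib <- round(library_size * stats::runif(length(strains), 0.9, 1.1))

  structure(list(cis_effects = cis_effects, trans_effects = trans_effects,
                 baseline = baseline, ocr_marker = ocr_marker,
                 noise_sd = noise_sd,
                 library_sizes = stats::setNames(lib, strains), seed = seed),
            class = "cross_truth")
}

#' Nearest marker to each OCR (same chromosome)
#'
#' @param ocrs OCR tibble.
#' @param genotypes Wide genotype tibble.
#' @return Tibble `ocr`, `marker` mapping each OCR to the marker whose
#'   position is closest to the OCR midpoint on its chromosome.
#' @export
nearest_marker <- function(ocrs, genotypes) {
  purrr::map_dfr(split(ocrs, ocrs$chrom), function(oc) {
    mk <- genotypes[genotypes$chrom == oc$chrom[1], ]
    if (nrow(mk) == 0) return(NULL)
    mid <- (oc$start + oc$end) / 2
    idx <- vapply(mid, function(x) which.min(abs(mk$start - x)), integer(1))
    tibble::tibble(ocr = oc$ocr, marker = mk$marker[idx])
  }) %>% dplyr::arrange(.data$ocr)
}

# True OCR-level genotype (0/1) of each strain: the genotype at the marker
# nearest the OCR. Rows OCRs, columns strains.
.true_ocr_genotypes <- function(ocrs, genotypes, ocr_marker) {
  strains <- strain_cols(genotypes)
  g <- as.matrix(genotypes[, strains])
  rownames(g) <- genotypes$marker
  m <- g[ocr_marker$marker[match(ocrs$ocr, ocr_marker$ocr)], , drop = FALSE]
  rownames(m) <- ocrs$ocr
  m
}

#' Simulate FAIRE-seq style counts and SNP profiles for a cross
#'
#' Expected read count of OCR i in strain s is
#' `lib_s/1e6 * size_kb_i * 2^(baseline_i + cis_i g_is + sum trans g_s(source) + noise)`
#' with the realized count drawn Poisson, so that downstream reads-per-kb-
#' per-million normalization recovers the log2 densities. SNP profiles place
#' `snps_per_ocr` biallelic sites uniformly inside each profiled OCR with the
#' true inherited parental allele, per-site read depth Poisson(`depth_mean`),
#' and a per-read error rate `error_rate` flipping alleles.
#'
#' @param layout A `genome_layout`.
#' @param genotypes Wide genotype tibble from [simulate_cross()].
#' @param ocrs OCR tibble.
#' @param truth A `cross_truth`.
#' @param profiled_ocrs OCR ids to receive SNP profiles; default the
#'   cis-effect OCRs, `"all"` profiles every OCR.
#' @param snps_per_ocr SNPs placed inside each profiled OCR (default 2).
#' @param depth_mean Mean per-site read depth (Poisson).
#' @param error_rate Per-read allele-flip probability.
#' @param seed Integer seed.
#' @return List: `counts` (wide tibble OCR rows, strain columns),
#'   `snp_profiles` (long tibble strain/chrom/pos/allele/depth/major_fraction),
#'   `parental_profiles` (same shape, strains `"BY"`/`"RM"`),
#'   `true_genotypes` (OCR-by-strain 0/1 matrix), `library_sizes`.
#' @export
simulate_dataset <- function(layout, genotypes, ocrs, truth,
                             profiled_ocrs = NULL, snps_per_ocr = 2,
                             depth_mean = 20, error_rate = 0, seed = 1L) {
  .assert(depth_mean >= 0, "negative depth parameter")
  .assert(error_rate >= 0 && error_rate <= 1, "error_rate must be in [0,1]")
  .assert(all(truth$cis_effects$ocr %in% ocrs$ocr) &&
            all(truth$trans_effects$ocr %in% ocrs$ocr),
          "truth references unknown OCRs")
  .assert(all(truth$trans_effects$marker %in% genotypes$marker),
          "truth references unknown markers")
  restore <- .local_seed(seed)
  on.exit(restore(), add = TRUE)

  strains <- strain_cols(genotypes)
  n_s <- length(strains)
  g_ocr <- .true_ocr_genotypes(ocrs, genotypes, truth$ocr_marker)

  logdens <- matrix(truth$baseline$baseline[match(ocrs$ocr, truth$baseline$ocr)],
                    nrow = nrow(ocrs), ncol = n_s)
  rownames(logdens) <- ocrs$ocr; colnames(logdens) <- strains

  ce <- truth$cis_effects
  if (nrow(ce) > 0) {
    logdens[ce$ocr, ] <- logdens[ce$ocr, , drop = FALSE] +
      ce$effect * g_ocr[ce$ocr, , drop = FALSE]
  }
  te <- truth$trans_effects
  if (nrow(te) > 0) {
    g_mk <- as.matrix(genotypes[match(te$marker, genotypes$marker), strains])
    logdens[te$ocr, ] <- logdens[te$ocr, , drop = FALSE] + te$effect * g_mk
  }
  if (truth$noise_sd > 0) {
    logdens <- logdens + matrix(stats::rnorm(length(logdens), 0, truth$noise_sd),
                                nrow = nrow(logdens))
  }

  lib <- truth$library_sizes[strains]
  size_kb <- ocrs$size / 1000
  mu <- 2^logdens * outer(size_kb, lib / 1e6)
  counts <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu),
                   dimnames = dimnames(logdens))
  counts_tbl <- dplyr::bind_cols(tibble::tibble(ocr = ocrs$ocr),
                                 tibble::as_tibble(counts))

  if (is.null(profiled_ocrs)) profiled_ocrs <- truth$cis_effects$ocr
  if (identical(profiled_ocrs, "all")) profiled_ocrs <- ocrs$ocr
  snp <- .simulate_snp_profiles(ocrs[ocrs$ocr %in% profiled_ocrs, ], g_ocr,
                                strains, snps_per_ocr, depth_mean, error_rate)

  list(counts = counts_tbl, snp_profiles = snp$strains,
       parental_profiles = snp$parents, true_genotypes = g_ocr,
       library_sizes = lib)
}

.simulate_snp_profiles <- function(ocrs, g_ocr, strains, k, depth_mean, eps) {
  if (nrow(ocrs) == 0) {
    empty <- tibble::tibble(strain = character(), chrom = character(),
                            pos = integer(), allele = character(),
                            depth = integer(), major_fraction = numeric())
    return(list(strains = empty, parents = empty))
  }
  bases <- c("A", "C", "G", "T")
  sites <- purrr::pmap_dfr(ocrs[, c("ocr", "chrom", "start", "end")],
    function(ocr, chrom, start, end) {
      pos <- sort(sample(seq(start + 1L, end), min(k, end - start)))
      al <- replicate(length(pos), sample(bases, 2), simplify = FALSE)
      tibble::tibble(ocr = ocr, chrom = chrom, pos = pos,
                     by_allele = purrr::map_chr(al, 1),
                     rm_allele = purrr::map_chr(al, 2))
    })

  parents <- dplyr::bind_rows(
    tibble::tibble(strain = "BY", chrom = sites$chrom, pos = sites$pos,
                   allele = sites$by_allele, depth = 30L, major_fraction = 1),
    tibble::tibble(strain = "RM", chrom = sites$chrom, pos = sites$pos,
                   allele = sites$rm_allele, depth = 30L, major_fraction = 1))

  per_strain <- purrr::map_dfr(strains, function(s) {
    g <- g_ocr[sites$ocr, s]
    true_al <- ifelse(g == 1, sites$by_allele, sites$rm_allele)
    other_al <- ifelse(g == 1, sites$rm_allele, sites$by_allele)
    depth <- stats::rpois(nrow(sites), depth_mean)
    err <- stats::rbinom(nrow(sites), depth, eps)
    maj_is_true <- err <= depth - err  # ties go to the true allele
    allele <- ifelse(maj_is_true, true_al, other_al)
    major_n <- pmax(err, depth - err)
    keep <- depth > 0
    tibble::tibble(strain = s, chrom = sites$chrom[keep], pos = sites$pos[keep],
                   allele = allele[keep], depth = depth[keep],
                   major_fraction = major_n[keep] / depth[keep])
  })
  list(strains = per_strain, parents = parents)
}
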
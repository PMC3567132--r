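#' Combine associated markers into regulatory loci and flag hotspots
#'
#' Markers lying less than `gap` bp apart (between covered regions) that
#' share at least one common target trait are combined into one locus,
#' transitively. A locus's target set is the union of its member markers'
#' targets; it is a hotspot when the number of distinct targets exceeds
#' `hotspot_threshold`.
#'
#' @param assocs Association tibble (`marker`, `trait`; typically the
#'   trans-labelled significant set).
#' @param markers Wide marker tibble with coordinates.
#' @param gap Distance below which adjacent markers may merge (default 10 kb).
#' @param hotspot_threshold Targets required (exclusive) for the hotspot flag
#'   (default 65).
#' @return Locus tibble: `locus`, `chrom`, `start`, `end`, `members` and
#'   `targets` list-columns, `n_targets`, `hotspot`.
#' @export
build_regulatory_loci <- function(assocs, markers, gap = 1e4,
                                  hotspot_threshold = 65) {
  .assert(all(assocs$marker %in% markers$marker),
          "associations reference unknown markers")
  used <- markers[markers$marker %in% assocs$marker, ]
  if (nrow(used) == 0) {
    return(tibble::tibble(locus = character(), chrom = character(),
                          start = integer(), end = integer(),
                          members = list(), targets = list(),
                          n_targets = integer(), hotspot = logical()))
  }
  targets_of <- split(assocs$trait, assocs$marker)

  out <- purrr::map(split(used, used$chrom), function(d) {
    d <- dplyr::arrange(d, .data$start)
    parent <- seq_len(nrow(d))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nrow(d))) {
      j <- i + 1L
      while (j <= nrow(d) &&
             .interval_gap(d$start[i], d$end[i], d$start[j], d$end[j]) < gap) {
        if (length(intersect(targets_of[[d$marker[i]]],
                             targets_of[[d$marker[j]]])) > 0) {
          parent[find(j)] <- find(i)
        }
        j <- j + 1L
      }
    }
    comp <- vapply(seq_len(nrow(d)), find, integer(1))
    purrr::map_dfr(split(seq_len(nrow(d)), comp), function(idx) {
      tg <- sort(unique(unlist(targets_of[d$marker[idx]])))
      tibble::tibble(chrom = d$chrom[1], start = min(d$start[idx]),
                     end = max(d$end[idx]), members = list(d$marker[idx]),
                     targets = list(tg), n_targets = length(tg))
    })
  }) %>% purrr::list_rbind()

  out %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::mutate(locus = sprintf("L%03d", dplyr::row_number()), .before = 1) %>%
    dplyr::mutate(hotspot = .data$n_targets > hotspot_threshold)
}

#' Annotate regulatory loci with candidate regulator genes
#'
#' A locus is annotated with every regulator gene overlapping the locus
#' interval extended by `flank` on both sides. Adjacent loci sharing at least
#' one regulator are then merged (automating the by-hand merge rule), and
#' loci with no regulator are flagged unannotated.
#'
#' @param loci Locus tibble from [build_regulatory_loci()].
#' @param regulators Gene tibble (`chrom`, `start`, `end`, `name`).
#' @param flank Search window around the locus, bp (default 10 kb).
#' @param hotspot_threshold Re-applied after regulator-based merging.
#' @return Locus tibble with `regulators` list-column and `annotated` flag.
#' @export
annotate_loci <- function(loci, regulators, flank = 1e4,
                          hotspot_threshold = 65) {
  if (nrow(loci) == 0) {
    return(dplyr::mutate(loci, regulators = list(), annotated = logical()))
  }
  regs <- purrr::map(seq_len(nrow(loci)), function(i) {
    r <- regulators[regulators$chrom == loci$chrom[i] &
                      regulators$end > loci$start[i] - flank &
                      regulators$start < loci$end[i] + flank, ]
    sort(unique(r$name))
  })
  loci$regulators <- regs

  # merge adjacent loci (same chromosome, in positional order) sharing a regulator
  out <- purrr::map(split(loci, loci$chrom), function(d) {
    d <- dplyr::arrange(d, .data$start)
    grp <- cumsum(c(1L, vapply(seq_len(nrow(d))[-1], function(i) {
      as.integer(length(intersect(d$regulators[[i - 1]],
                                  d$regulators[[i]])) == 0)
    }, integer(1))))
    purrr::map_dfr(split(seq_len(nrow(d)), grp), function(idx) {
      tg <- sort(unique(unlist(d$targets[idx])))
      tibble::tibble(chrom = d$chrom[1], start = min(d$start[idx]),
                     end = max(d$end[idx]),
                     members = list(sort(unique(unlist(d$members[idx])))),
                     targets = list(tg), n_targets = length(tg),
                     regulators = list(sort(unique(unlist(d$regulators[idx])))))
    })
  }) %>% purrr::list_rbind()

  out %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::mutate(locus = sprintf("L%03d", dplyr::row_number()), .before = 1) %>%
    dplyr::mutate(hotspot = .data$n_targets > hotspot_threshold,
                  annotated = purrr::map_lgl(.data$regulators, ~ length(.x) > 0))
}

#' Regulatory-architecture report
#'
#' Summarizes the mapped trans-regulatory structure: how many loci target
#' each trait, how many traits each locus targets, the fraction of total
#' trans-variation carried by trans-associated OCRs, the per-trait R-squared
#' of a multiple regression of trait values on all associated locus genotype
#' profiles, and (when annotation is present) an annotated-vs-unannotated
#' comparison of hotspot target counts.
#'
#' @param assocs Labelled association tibble (needs `label`).
#' @param loci Locus tibble (optionally annotated).
#' @param variation An `ocr_variation` tibble covering the trait universe.
#' @param traits Wide trait tibble (for the R-squared fits); optional.
#' @param markers Wide marker tibble (for locus genotype profiles); optional.
#' @return List: `per_trait` (trait, n_trans_loci), `mean_loci_per_trait`,
#'   `per_locus` (locus, n_targets), `explained_trans_fraction`,
#'   `r_squared` (trait, r2, n_loci), `mean_r_squared`,
#'   `annotation_test` (t/p or NULL).
#' @export
regulatory_architecture <- function(assocs, loci, variation,
                                    traits = NULL, markers = NULL) {
  trans_tr <- unique(assocs$trait[assocs$label == "trans"])
  locus_of_trait <- tidyr::unnest(loci[, c("locus", "targets")],
                                  "targets") %>%
    dplyr::rename(trait = "targets")
  per_trait <- locus_of_trait %>%
    dplyr::filter(.data$trait %in% trans_tr) %>%
    dplyr::count(.data$trait, name = "n_trans_loci")

  tv <- trans_variation(variation)
  denom <- sum(tv)
  explained <- if (denom > 0)
    sum(tv[names(tv) %in% trans_tr]) / denom else 0

  r2 <- NULL
  if (!is.null(traits) && !is.null(markers) && nrow(per_trait) > 0) {
    strains <- intersect(strain_cols(markers), strain_cols(traits))
    locus_profile <- function(lc) {
      mem <- loci$members[[match(lc, loci$locus)]]
      colMeans(as.matrix(markers[markers$marker %in% mem, strains,
                                 drop = FALSE]))
    }
    r2 <- purrr::map_dfr(per_trait$trait, function(tr) {
      lcs <- locus_of_trait$locus[locus_of_trait$trait == tr]
      y <- as.numeric(traits[traits[[1]] == tr, strains])
      if (length(lcs) >= length(strains)) {
        inform(sprintf("skipping R^2 fit for %s: more predictors than strains", tr))
        return(NULL)
      }
      X <- vapply(lcs, locus_profile, numeric(length(strains)))
      fit <- stats::lm(y ~ X)
      tibble::tibble(trait = tr, n_loci = length(lcs),
                     r2 = summary(fit)$r.squared)
    })
  }

  annotation_test <- NULL
  if ("annotated" %in% names(loci) && any(loci$hotspot)) {
    hs <- loci[loci$hotspot, ]
    if (length(unique(hs$annotated)) == 2) {
      tt <- .two_sample_t(hs$n_targets[hs$annotated],
                          hs$n_targets[!hs$annotated], var_equal = FALSE)
      annotation_test <- tibble::tibble(
        mean_annotated = mean(hs$n_targets[hs$annotated]),
        mean_unannotated = mean(hs$n_targets[!hs$annotated]),
        t = tt$t, p = tt$p)
    }
  }

  list(per_trait = per_trait,
       mean_loci_per_trait = if (nrow(per_trait)) mean(per_trait$n_trans_loci)
         else NA_real_,
       per_locus = loci[, c("locus", "n_targets", "hotspot")],
       explained_trans_fraction = explained,
       r_squared = r2,
       mean_r_squared = if (!is.null(r2) && nrow(r2)) mean(r2$r2) else NA_real_,
       annotation_test = annotation_test)
}
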
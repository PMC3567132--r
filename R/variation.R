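#' Decompose per-OCR accessibility variation into cis and trans components
#'
#' For each OCR with at least `min_per_group` strains carrying each parental
#' allele, computes the sequence-independent (trans) variation as the
#' within-group standard deviations of normalized density (one per parental
#' group), and the sequence-dependent (cis) signal as a two-sample t test on
#' the BY vs RM group means.
#'
#' @param density Standardized density tibble (`ocr` + strain columns).
#' @param genotypes Wide OCR-genotype tibble from [genotype_ocrs()]
#'   (`"BY"`/`"RM"`/`NA` entries).
#' @param min_per_group Minimum strains per genotype group for eligibility
#'   (default 10).
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return `ocr_variation` object: a tibble with one row per eligible OCR
#'   (`ocr`, `n_by`, `n_rm`, `sd_by`, `sd_rm`, `mean_diff` (BY - RM),
#'   `t`, `p`).
#' @export
estimate_variation <- function(density, genotypes, min_per_group = 10,
                               var_equal = FALSE) {
  strains <- intersect(strain_cols(density), strain_cols(genotypes))
  .assert(length(strains) > 0, "density and genotypes share no strains")
  shared <- intersect(density$ocr, genotypes$ocr)
  d <- as.matrix(density[match(shared, density$ocr), strains])
  g <- as.matrix(genotypes[match(shared, genotypes$ocr), strains])

  rows <- purrr::map(seq_along(shared), function(i) {
    by_v <- d[i, g[i, ] == "BY" & !is.na(g[i, ])]
    rm_v <- d[i, g[i, ] == "RM" & !is.na(g[i, ])]
    if (length(by_v) < min_per_group || length(rm_v) < min_per_group) return(NULL)
    tt <- .two_sample_t(by_v, rm_v, var_equal)
    tibble::tibble(ocr = shared[i], n_by = length(by_v), n_rm = length(rm_v),
                   sd_by = stats::sd(by_v), sd_rm = stats::sd(rm_v),
                   mean_diff = mean(by_v) - mean(rm_v), t = tt$t, p = tt$p)
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) {
    warn("no OCR passed the per-group eligibility threshold")
    out <- tibble::tibble(ocr = character(), n_by = integer(), n_rm = integer(),
                          sd_by = numeric(), sd_rm = numeric(),
                          mean_diff = numeric(), t = numeric(), p = numeric())
  }
  structure(out, class = c("ocr_variation", class(out)),
            min_per_group = min_per_group, var_equal = var_equal)
}

# Two-sample t with the zero-variance edge handled: both groups constant and
# equal means -> t = 0, p = 1.
.two_sample_t <- function(x, y, var_equal) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Summarize a variation decomposition
#'
#' Reports the fraction of eligible OCRs whose cis test is significant at
#' each alpha, and the agreement (Pearson correlation) of the two per-group
#' trans-variation measures across OCRs.
#'
#' @param estimates An `ocr_variation` tibble from [estimate_variation()].
#' @param alphas Significance levels for the cis-test fractions.
#' @return One-row tibble: `n_eligible`, one `frac_sig_<alpha>` column per
#'   alpha, and `sd_correlation`.
#' @export
summarize_variation <- function(estimates, alphas = c(0.05, 0.01)) {
  .assert(nrow(estimates) > 0, "empty variation estimate set")
  fr <- purrr::map_dbl(alphas, ~ mean(estimates$p < .x))
  out <- tibble::tibble(n_eligible = nrow(estimates))
  for (i in seq_along(alphas)) {
    out[[sprintf("frac_sig_%g", alphas[i])]] <- fr[i]
  }
  out$sd_correlation <- if (nrow(estimates) > 2)
    stats::cor(estimates$sd_by, estimates$sd_rm) else NA_real_
  out
}

#' Per-OCR trans-variation magnitude
#'
#' The single-number summary used by positional profiles and the
#' explained-variation fraction: the mean of the BY-group and RM-group
#' standard deviations.
#'
#' @param estimates An `ocr_variation` tibble.
#' @return Named numeric vector keyed by OCR id.
#' @export
trans_variation <- function(estimates) {
  stats::setNames((estimates$sd_by + estimates$sd_rm) / 2, estimates$ocr)
}

#' @method glance ocr_variation
#' @export
glance.ocr_variation <- function(x, ...) summarize_variation(x)

#' @method tidy ocr_variation
#' @export
tidy.ocr_variation <- function(x, ...) tibble::as_tibble(x)
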
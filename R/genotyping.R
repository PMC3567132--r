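#' Filter SNP calls by depth and major-allele frequency
#'
#' Calls covered by fewer than `min_depth` reads are discarded. Heterogeneous
#' calls are kept (as the major allele) only when the major-allele fraction
#' exceeds `major_frac`, and dropped otherwise.
#'
#' @param profile Long SNP-call tibble: `strain`, `chrom`, `pos` (1-based),
#'   `allele`, `depth`, `major_fraction`.
#' @param min_depth Minimum read depth to keep a call (default 5).
#' @param major_frac Major-allele fraction that must be exceeded (default 0.8).
#' @return Filtered tibble, same columns.
#' @export
filter_snp_calls <- function(profile, min_depth = 5, major_frac = 0.8) {
  dplyr::filter(profile, .data$depth >= min_depth,
                .data$major_fraction > major_frac)
}

#' Genotype OCRs from SNP profiles against the parental strains
#'
#' For each OCR and strain, the strain's filtered alleles are compared with
#' the two parents at sites where the parents disagree (other sites are
#' uninformative). Under `mode = "strict"` the strain is assigned a parent
#' only when every compared site matches that parent; under `"relaxed"` when
#' more than half of the compared sites match exactly one parent. Ties, no
#' informative sites, or no surviving coverage give a missing call. Sites
#' with no call in the strain are ignored, not counted as mismatches.
#'
#' @param profiles Long filtered SNP-call tibble over all strains
#'   (see [filter_snp_calls()]).
#' @param by_profile,rm_profile Parental SNP-call tibbles (strain column
#'   ignored).
#' @param ocrs OCR tibble.
#' @param mode `"strict"` (perfect match) or `"relaxed"` (majority match).
#' @param min_informative_sites Minimum compared sites required to assign a
#'   genotype (default 1).
#' @return Wide OCR-genotype tibble: `ocr` plus one character column per
#'   strain with entries `"BY"`, `"RM"` or `NA` (missing).
#' @export
genotype_ocrs <- function(profiles, by_profile, rm_profile, ocrs,
                          mode = c("strict", "relaxed"),
                          min_informative_sites = 1) {
  mode <- match.arg(mode)
  par <- dplyr::inner_join(
    dplyr::select(by_profile, "chrom", "pos", by_allele = "allele"),
    dplyr::select(rm_profile, "chrom", "pos", rm_allele = "allele"),
    by = c("chrom", "pos")) %>%
    dplyr::filter(.data$by_allele != .data$rm_allele)
  par$ocr <- .site_to_ocr(par, ocrs)
  par <- dplyr::filter(par, !is.na(.data$ocr))

  strains <- sort(unique(profiles$strain))
  geno <- matrix(NA_character_, nrow = nrow(ocrs), ncol = length(strains),
                 dimnames = list(ocrs$ocr, strains))
  if (nrow(par) > 0) {
    cmp <- dplyr::inner_join(profiles, par, by = c("chrom", "pos")) %>%
      dplyr::mutate(match_by = .data$allele == .data$by_allele,
                    match_rm = .data$allele == .data$rm_allele) %>%
      dplyr::group_by(.data$strain, .data$ocr) %>%
      dplyr::summarise(n = dplyr::n(), n_by = sum(.data$match_by),
                       n_rm = sum(.data$match_rm), .groups = "drop") %>%
      dplyr::filter(.data$n >= min_informative_sites)
    call <- if (mode == "strict") {
      dplyr::case_when(cmp$n_by == cmp$n ~ "BY", cmp$n_rm == cmp$n ~ "RM",
                       TRUE ~ NA_character_)
    } else {
      dplyr::case_when(cmp$n_by > cmp$n / 2 ~ "BY", cmp$n_rm > cmp$n / 2 ~ "RM",
                       TRUE ~ NA_character_)
    }
    geno[cbind(match(cmp$ocr, ocrs$ocr), match(cmp$strain, strains))] <- call
  }
  dplyr::bind_cols(tibble::tibble(ocr = ocrs$ocr), tibble::as_tibble(geno))
}

# Map 1-based site positions to the id of the (non-overlapping) OCR
# containing them; NA when outside every OCR.
.site_to_ocr <- function(sites, ocrs) {
  .assert(is.data.frame(ocrs) && all(c("ocr", "chrom", "start", "end") %in%
                                       names(ocrs)), "malformed OCR set")
  out <- rep(NA_character_, nrow(sites))
  for (cn in unique(sites$chrom)) {
    si <- which(sites$chrom == cn)
    oc <- ocrs[ocrs$chrom == cn, ]
    if (nrow(oc) == 0) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[si], sites$pos[si]),
      IRanges::IRanges(oc$start + 1L, oc$end))
    out[si[S4Vectors::queryHits(hit)]] <- oc$ocr[S4Vectors::subjectHits(hit)]
  }
  out
}

#' Accuracy of an OCR genotype call set against simulation truth
#'
#' Fraction of assigned (non-missing) calls that equal the true inherited
#' parent; abstentions do not count against accuracy.
#'
#' @param geno Wide OCR-genotype tibble from [genotype_ocrs()].
#' @param true_genotypes OCR-by-strain 0/1 matrix (1 = BY) from
#'   [simulate_dataset()].
#' @return One-row tibble: `n_assigned`, `n_correct`, `accuracy`,
#'   `call_rate`.
#' @export
genotype_accuracy <- function(geno, true_genotypes) {
  strains <- strain_cols(geno)
  g <- as.matrix(geno[, strains])
  truth <- true_genotypes[geno$ocr, strains, drop = FALSE]
  assigned <- !is.na(g)
  correct <- assigned & ((g == "BY") == (truth == 1))
  tibble::tibble(n_assigned = sum(assigned), n_correct = sum(correct),
                 accuracy = ifelse(sum(assigned) == 0, NA_real_,
                                   sum(correct) / sum(assigned)),
                 call_rate = mean(assigned))
}
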
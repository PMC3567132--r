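#' Simulate haploid segregants of a two-parent cross
#'
#' Each strain is an independent haploid recombinant of the BY and RM
#' parents. The first marker of each chromosome is BY with probability 1/2;
#' between adjacent markers at genetic distance d Morgans the allele switches
#' with the Haldane (no-interference) probability r = (1 - exp(-2d)) / 2.
#'
#' Genotypes are coded as in the field's convention for this cross:
#' 0 = RM, 1 = BY (0.5 marks a missing call; the simulator itself produces
#' none — inject missingness downstream if needed).
#'
#' @param layout A `genome_layout` (for chromosome names/bounds).
#' @param marker_positions Named list per chromosome of strictly increasing
#'   bp positions; see [default_marker_positions()].
#' @param n_strains Number of segregants (>= 2).
#' @param cM_per_kb Genetic map density, centimorgans per kilobase
#'   (yeast-like default 0.35).
#' @param seed Integer seed.
#' @return A wide genotype tibble: columns `marker`, `chrom`, `start`, `end`
#'   (the marker's covered region; a point for raw markers) then one column
#'   per strain with values in \{0, 1\}.
#' @export
simulate_cross <- function(layout, marker_positions = default_marker_positions(layout),
                           n_strains = 96, cM_per_kb = 0.35, seed = 1L) {
  .assert(n_strains >= 2, "n_strains must be >= 2")
  restore <- .local_seed(seed)
  on.exit(restore(), add = TRUE)

  purrr::imap(marker_positions, function(pos, cn) {
    .assert(all(diff(pos) > 0), "marker positions must be strictly increasing")
    d_morgan <- diff(pos) / 1000 * cM_per_kb / 100
    r <- haldane_r(d_morgan)
    m <- length(pos)
    g <- matrix(0L, nrow = m, ncol = n_strains)
    g[1, ] <- stats::rbinom(n_strains, 1, 0.5)
    if (m > 1) {
      for (i in 2:m) {
        switch_ <- stats::rbinom(n_strains, 1, r[i - 1])
        g[i, ] <- ifelse(switch_ == 1, 1L - g[i - 1, ], g[i - 1, ])
      }
    }
    out <- tibble::tibble(chrom = cn, start = as.integer(pos), end = as.integer(pos) + 1L)
    cbind(out, as.data.frame(g) |>
            stats::setNames(sprintf("strain%03d", seq_len(n_strains))))
  }) %>%
    purrr::list_rbind() %>%
    dplyr::mutate(marker = sprintf("m%04d", dplyr::row_number()), .before = 1) %>%
    tibble::as_tibble()
}

#' Haldane map function
#'
#' Recombination fraction for a genetic distance under no interference:
#' r(d) = (1 - exp(-2d)) / 2, d in Morgans.
#'
#' @param d_morgan Genetic distance in Morgans (vectorized).
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d_morgan) {
  .assert(all(d_morgan >= 0), "genetic distance must be nonnegative")
  (1 - exp(-2 * d_morgan)) / 2
}
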
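#' Simulate a compact yeast-like genome layout
#'
#' Builds the positional scaffolding used by the synthetic cross: a set of
#' chromosomes with telomeres at both ends, non-overlapping genes with strand,
#' replication origins, and a recombination-hotness track (log2 enrichment
#' scores at regularly spaced loci). Defaults emulate the S. cerevisiae genome
#' scaled to one tenth of its physical length: 16 chromosomes, ~one gene per
#' 2 kb, origins every ~30 kb.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_lengths Integer vector of chromosome lengths in bp (recycled
#'   or generated if `NULL`: 20-150 kb, roughly the yeast spread / 10).
#' @param gene_every Mean spacing between gene starts, bp.
#' @param gene_len_range Range of gene lengths, bp.
#' @param origin_every Mean spacing between replication origins, bp.
#' @param hotness_step Spacing of hotness-track loci, bp.
#' @param seed Integer seed; the layout is deterministic given it.
#' @return An object of class `genome_layout`: a list of tibbles
#'   `chromosomes` (name, length), `telomeres` (chrom, pos), `genes`
#'   (chrom, start, end, strand, name), `origins` (chrom, start, end) and
#'   `hotness` (chrom, pos, score).
#' @export
simulate_genome_layout <- function(n_chrom = 16,
                                   chrom_lengths = NULL,
                                   gene_every = 2000,
                                   gene_len_range = c(300, 1500),
                                   origin_every = 30000,
                                   hotness_step = 2000,
                                   seed = 1L) {
  .assert(n_chrom >= 1, "n_chrom must be >= 1")
  withr_seed <- .local_seed(seed)
  on.exit(withr_seed(), add = TRUE)

  if (is.null(chrom_lengths)) {
    chrom_lengths <- round(seq(150000, 20000, length.out = n_chrom) +
                             stats::runif(n_chrom, -5000, 5000))
  }
  chrom_lengths <- as.integer(rep_len(chrom_lengths, n_chrom))
  chroms <- tibble::tibble(
    name = sprintf("chr%02d", seq_len(n_chrom)),
    length = chrom_lengths
  )

  genes <- purrr::map2_dfr(chroms$name, chroms$length, function(cn, len) {
    starts <- seq(1000, len - max(gene_len_range) - 1000, by = gene_every)
    if (length(starts) == 0) return(NULL)
    starts <- starts + round(stats::runif(length(starts), 0, gene_every * 0.3))
    lens <- round(stats::runif(length(starts), gene_len_range[1], gene_len_range[2]))
    tibble::tibble(chrom = cn, start = as.integer(starts),
                   end = as.integer(pmin(starts + lens, len)),
                   strand = sample(c("+", "-"), length(starts), replace = TRUE))
  })
  genes$name <- sprintf("gene%05d", seq_len(nrow(genes)))

  origins <- purrr::map2_dfr(chroms$name, chroms$length, function(cn, len) {
    pos <- seq(origin_every / 2, len, by = origin_every)
    if (length(pos) == 0) return(NULL)
    tibble::tibble(chrom = cn, start = as.integer(pos),
                   end = as.integer(pmin(pos + 500, len)))
  })

  # Hotness: smooth log2 signal, hotter away from telomeres (recombination
  # coldspots at chromosome ends), plus noise.
  hotness <- purrr::map2_dfr(chroms$name, chroms$length, function(cn, len) {
    pos <- seq(hotness_step / 2, len, by = hotness_step)
    dist_end <- pmin(pos, len - pos)
    base <- 0.6 * tanh(dist_end / 15000) - 0.3
    tibble::tibble(chrom = cn, pos = as.integer(pos),
                   score = base + stats::rnorm(length(pos), 0, 0.4))
  })

  telomeres <- tibble::tibble(
    chrom = rep(chroms$name, each = 2),
    pos = as.integer(rbind(0L, chroms$length))
  )

  structure(list(chromosomes = chroms, telomeres = telomeres, genes = genes,
                 origins = origins, hotness = hotness),
            class = "genome_layout")
}

# Save/restore RNG state so generators are pure given their seed argument.
.local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosomes, %d genes, %d origins, %d hotness loci\n",
              nrow(x$chromosomes), nrow(x$genes), nrow(x$origins), nrow(x$hotness)))
  invisible(x)
}

#' Marker positions evenly spread over a genome layout
#'
#' @param layout A `genome_layout`.
#' @param n_markers Total marker count, apportioned by chromosome length.
#' @return Named list (per chromosome) of strictly increasing bp positions.
#' @export
default_marker_positions <- function(layout, n_markers = 1500) {
  total <- sum(layout$chromosomes$length)
  purrr::map2(layout$chromosomes$name, layout$chromosomes$length, function(cn, len) {
    k <- max(2L, round(n_markers * len / total))
    as.integer(round(seq(1, len - 1, length.out = k)))
  }) %>% stats::setNames(layout$chromosomes$name)
}
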
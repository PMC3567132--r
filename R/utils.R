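#' @importFrom rlang abort warn inform .data
#' @importFrom dplyr %>%
NULL

# Metadata columns that precede strain columns in wide matrix tibbles.
.marker_meta <- c("marker", "chrom", "start", "end", "members")
.ocr_meta <- c("ocr", "trait", "gene", "chrom", "start", "end", "size")

#' Strain columns of a wide matrix tibble
#'
#' Wide tibbles in this package carry feature metadata columns (marker or OCR
#' id and coordinates) followed by one numeric column per strain. This helper
#' returns the strain column names, i.e. everything that is not metadata.
#'
#' @param x A wide tibble (genotype, count, or density matrix).
#' @return Character vector of strain column names.
#' @export
strain_cols <- function(x) {
  setdiff(names(x), c(.marker_meta, .ocr_meta, "stage"))
}

# Extract the numeric strains-by-features matrix (strains in rows) from a
# tibble whose first column is the feature id and remaining columns strains.
.strain_matrix <- function(x) {
  m <- t(as.matrix(x[, -1]))
  colnames(m) <- x[[1]]
  m
}

.assert <- function(ok, msg) if (!ok) abort(msg)

.check_intervals <- function(df, what = "interval") {
  .assert(all(df$end > df$start), sprintf("malformed %s: end must exceed start", what))
  .assert(all(df$start >= 0), sprintf("malformed %s: negative start", what))
  invisible(df)
}

# Minimum gap between two half-open intervals on the same sequence; 0 if they
# overlap or are bookended.
.interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}
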
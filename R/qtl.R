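#' Merge adjacent genetic markers with near-identical genotype profiles
#'
#' Scans each chromosome left to right and extends the current run while the
#' next raw marker differs from the run's first member at no more than
#' `max_mismatch` strains (positions where either profile is 0.5/missing are
#' excluded from the comparison). Each run is emitted as one merged marker
#' whose profile is the element-wise mean of its members and whose covered
#' region spans them.
#'
#' @param raw Wide genotype tibble (`marker`, `chrom`, `start`, `end` +
#'   strain columns with values in \{0, 0.5, 1\}), sorted by position.
#' @param max_mismatch Maximum tolerated genotypic mismatches (default 2).
#' @return Wide merged-marker tibble with a `members` list-column recording
#'   the raw marker ids of each run.
#' @export
merge_markers <- function(raw, max_mismatch = 2) {
  strains <- strain_cols(raw)
  .assert(all(unlist(raw[, strains]) %in% c(0, 0.5, 1)),
          "genotype values must be in {0, 0.5, 1}")
  out <- purrr::map(split(raw, raw$chrom), function(d) {
    .assert(!is.unsorted(d$start), "markers must be sorted by position")
    g <- as.matrix(d[, strains])
    runs <- integer(nrow(d))
    run_id <- 1L; anchor <- 1L
    runs[1] <- 1L
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        cmp <- g[anchor, ] != 0.5 & g[i, ] != 0.5
        mm <- sum(g[anchor, cmp] != g[i, cmp])
        if (mm > max_mismatch) { run_id <- run_id + 1L; anchor <- i }
        runs[i] <- run_id
      }
    }
    purrr::map_dfr(split(seq_len(nrow(d)), runs), function(idx) {
      prof <- colMeans(g[idx, , drop = FALSE])
      dplyr::bind_cols(
        tibble::tibble(chrom = d$chrom[1], start = min(d$start[idx]),
                       end = max(d$end[idx]),
                       members = list(d$marker[idx])),
        tibble::as_tibble(as.list(prof)))
    })
  }) %>% purrr::list_rbind()
  out %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::mutate(marker = sprintf("M%04d", dplyr::row_number()), .before = 1)
}

#' Map QTLs by marker-trait correlation with a permutation FDR
#'
#' Computes the Pearson correlation of every (marker genotype profile, trait
#' vector) pair; builds an empirical null by permuting the strain labels of
#' the trait matrix as whole sample vectors (columns move together, so
#' trait-trait correlation is preserved) `B` times; converts observed |r| to
#' empirical p with add-one smoothing, `p = (1 + k) / (N_null + 1)` where `k`
#' counts null values at least as extreme (null pooled across all pairs by
#' default); adjusts p over all pairs by Benjamini-Hochberg. Works identically
#' for chromatin (OCR density) and expression trait matrices. Missing
#' genotypes participate as the numeric value 0.5.
#'
#' @param traits Wide trait tibble: id column (first) + strain columns
#'   (standardized density or expression).
#' @param markers Wide marker tibble (`marker`, coordinates, strain columns).
#' @param B Number of permutations (ignored when `exhaustive`).
#' @param fdr FDR threshold for the significant set (default 0.01).
#' @param null `"pooled"` (null shared across pairs) or `"pairwise"`.
#' @param exhaustive Use all n! strain orderings (requires n <= 8).
#' @param seed Integer seed for the permutations.
#' @return A `qtl_map` object: list with `associations` (all pairs:
#'   `marker`, `trait`, `r`, `p`, `q`, `sign`), `significant` (q <= fdr),
#'   `n_strains`, `B`, `fdr`, `null`, and `dropped` (zero-variance ids).
#' @export
map_qtl <- function(traits, markers, B = 1000, fdr = 0.01,
                    null = c("pooled", "pairwise"), exhaustive = FALSE,
                    seed = 1L) {
  null <- match.arg(null)
  .assert(B >= 1, "B must be >= 1")
  strains <- intersect(strain_cols(markers), strain_cols(traits))
  .assert(length(strains) >= 3, "need >= 3 shared strains")
  n <- length(strains)

  X <- .strain_matrix(markers[, c("marker", strains)])   # strains x markers
  Y <- .strain_matrix(traits[, c(names(traits)[1], strains)])
  drop_x <- colnames(X)[apply(X, 2, stats::sd) == 0]
  drop_y <- colnames(Y)[apply(Y, 2, stats::sd) == 0]
  if (length(drop_x) + length(drop_y) > 0) {
    inform(sprintf("skipping %d zero-variance marker(s)/trait(s)",
                   length(drop_x) + length(drop_y)))
    X <- X[, setdiff(colnames(X), drop_x), drop = FALSE]
    Y <- Y[, setdiff(colnames(Y), drop_y), drop = FALSE]
  }
  .assert(ncol(X) > 0 && ncol(Y) > 0, "no usable marker/trait pairs")

  Xs <- scale(X); Ys <- scale(Y)
  r_obs <- crossprod(Xs, Ys) / (n - 1)     # markers x traits
  obs <- abs(as.vector(r_obs))
  P <- length(obs)

  perms <- if (exhaustive) {
    .assert(n <= 8, "exhaustive permutations require <= 8 strains")
    .all_perms(n)
  } else {
    restore <- .local_seed(seed)
    on.exit(restore(), add = TRUE)
    replicate(B, sample.int(n), simplify = FALSE)
  }
  nB <- length(perms)

  if (null == "pooled") {
    ord <- order(obs)
    k <- numeric(P)
    for (pm in perms) {
      s <- sort(abs(as.vector(crossprod(Xs[pm, , drop = FALSE], Ys) / (n - 1))))
      k[ord] <- k[ord] + (length(s) - findInterval(obs[ord], s, left.open = TRUE))
    }
    p <- (1 + k) / (nB * P + 1)
  } else {
    k <- numeric(P)
    for (pm in perms) {
      rp <- abs(as.vector(crossprod(Xs[pm, , drop = FALSE], Ys) / (n - 1)))
      k <- k + (rp >= obs - 1e-12)
    }
    p <- (1 + k) / (nB + 1)
  }

  assoc <- tibble::tibble(
    marker = rep(rownames(r_obs), times = ncol(r_obs)),
    trait = rep(colnames(r_obs), each = nrow(r_obs)),
    r = as.vector(r_obs), p = p,
    q = stats::p.adjust(p, method = "BH"),
    sign = ifelse(as.vector(r_obs) >= 0, "BY", "RM"))

  structure(list(associations = assoc,
                 significant = dplyr::filter(assoc, .data$q <= fdr),
                 n_strains = n, B = nB, fdr = fdr, null = null,
                 dropped = c(drop_x, drop_y)),
            class = "qtl_map")
}

# All permutations of 1..n, list of integer vectors (n! entries).
.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_perms(n - 1L)
  purrr::flatten(purrr::map(seq_len(n), function(i) {
    purrr::map(sub, function(p) c(i, p + (p >= i)))
  }))
}

#' @export
print.qtl_map <- function(x, ...) {
  cat(sprintf("<qtl_map> %d pairs, %d strains, B = %d (%s null); %d associations at q <= %g\n",
              nrow(x$associations), x$n_strains, x$B, x$null,
              nrow(x$significant), x$fdr))
  invisible(x)
}

#' @method tidy qtl_map
#' @export
tidy.qtl_map <- function(x, ...) x$significant

#' @method glance qtl_map
#' @export
glance.qtl_map <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$associations), n_strains = x$n_strains,
                 B = x$B, null = x$null, fdr = x$fdr,
                 n_significant = nrow(x$significant),
                 min_p = min(x$associations$p))
}

#' Label associations as cis or trans and report parametric concordance
#'
#' An association is cis when the marker's covered region and the trait's
#' genomic interval are on the same chromosome and at most `distance` apart
#' (overlap counts as gap 0); otherwise trans. Also reports the fraction of
#' associations whose single-predictor linear-regression p value falls below
#' each parametric cutoff; when the `traits` matrix is supplied the p comes
#' from an actual [stats::lm()] fit, otherwise from the closed form
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 df.
#'
#' @param assocs Association tibble (e.g. `tidy(qtl_map)`).
#' @param trait_positions Tibble with trait id (first column), `chrom`,
#'   `start`, `end` for every trait in `assocs`.
#' @param markers Wide marker tibble used in the mapping.
#' @param distance Cis distance threshold in bp (default 100 kb).
#' @param n_strains Strain count (needed for the closed-form p when `traits`
#'   is absent).
#' @param traits Optional wide trait tibble for regression-based concordance.
#' @param parametric_cutoffs Parametric p cutoffs for the concordance report.
#' @return List: `associations` (input + `label` column),
#'   `concordance` (tibble cutoff / fraction_below).
#' @export
classify_associations <- function(assocs, trait_positions, markers,
                                  distance = 1e5, n_strains = NULL,
                                  traits = NULL,
                                  parametric_cutoffs = c(1e-3, 1e-5)) {
  tp_id <- names(trait_positions)[1]
  idx <- match(assocs$trait, trait_positions[[tp_id]])
  .assert(!anyNA(idx), "coordinates required for every trait")
  mk <- match(assocs$marker, markers$marker)
  .assert(!anyNA(mk), "unknown marker in associations")

  same <- markers$chrom[mk] == trait_positions$chrom[idx]
  gap <- .interval_gap(markers$start[mk], markers$end[mk],
                       trait_positions$start[idx], trait_positions$end[idx])
  out <- dplyr::mutate(assocs,
                       label = ifelse(same & gap <= distance, "cis", "trans"))

  if (!is.null(traits)) {
    strains <- intersect(strain_cols(markers), strain_cols(traits))
    reg_p <- purrr::map2_dbl(assocs$marker, assocs$trait, function(m, tr) {
      x <- as.numeric(markers[markers$marker == m, strains])
      y <- as.numeric(traits[traits[[1]] == tr, strains])
      stats::coef(summary(stats::lm(y ~ x)))["x", "Pr(>|t|)"]
    })
  } else {
    .assert(!is.null(n_strains), "n_strains required without a traits matrix")
    tstat <- abs(assocs$r) * sqrt((n_strains - 2) / pmax(1 - assocs$r^2, 1e-300))
    reg_p <- 2 * stats::pt(-tstat, n_strains - 2)
  }
  concordance <- tibble::tibble(
    cutoff = parametric_cutoffs,
    fraction_below = purrr::map_dbl(parametric_cutoffs, ~ mean(reg_p < .x)))
  list(associations = dplyr::mutate(out, regression_p = reg_p),
       concordance = concordance)
}

#' Overlap between chromatin and expression QTL marker sets
#'
#' Reports the fraction of chromatin-QTL markers that are also
#' expression-QTL markers (and vice versa), and, among such dual markers, the
#' fraction whose linked chromatin and expression traits come within
#' `same_locus_window` bp of each other.
#'
#' @param chrom_assocs,expr_assocs Labelled association tibbles with trait
#'   coordinates attached (`trait`, `marker`, `trait_chrom`, `trait_start`,
#'   `trait_end`); see [attach_trait_positions()].
#' @param same_locus_window Max gap between trait intervals to call the same
#'   locus (default 100 kb, the cis-distance convention).
#' @param markers Optional marker tibble defining the shared universe; both
#'   association lists must draw from it.
#' @return One-row tibble: `frac_chrom_also_expr`, `frac_expr_also_chrom`,
#'   `n_dual`, `frac_dual_same_locus`.
#' @export
dual_qtl_overlap <- function(chrom_assocs, expr_assocs,
                             same_locus_window = 1e5, markers = NULL) {
  if (!is.null(markers)) {
    .assert(all(c(chrom_assocs$marker, expr_assocs$marker) %in% markers$marker),
            "association marker outside the shared marker universe")
  }
  cm <- unique(chrom_assocs$marker); em <- unique(expr_assocs$marker)
  dual <- intersect(cm, em)
  same_locus <- purrr::map_lgl(dual, function(m) {
    ct <- chrom_assocs[chrom_assocs$marker == m, ]
    et <- expr_assocs[expr_assocs$marker == m, ]
    any(outer(seq_len(nrow(ct)), seq_len(nrow(et)), Vectorize(function(i, j) {
      ct$trait_chrom[i] == et$trait_chrom[j] &&
        .interval_gap(ct$trait_start[i], ct$trait_end[i],
                      et$trait_start[j], et$trait_end[j]) <= same_locus_window
    })))
  })
  tibble::tibble(
    frac_chrom_also_expr = if (length(cm)) length(dual) / length(cm) else 0,
    frac_expr_also_chrom = if (length(em)) length(dual) / length(em) else 0,
    n_dual = length(dual),
    frac_dual_same_locus = if (length(dual)) mean(same_locus) else NA_real_)
}

#' Attach trait genomic coordinates to an association table
#'
#' @param assocs Association tibble with a `trait` column.
#' @param trait_positions Tibble: trait id (first column), `chrom`, `start`,
#'   `end`.
#' @return `assocs` with `trait_chrom`, `trait_start`, `trait_end` columns.
#' @export
attach_trait_positions <- function(assocs, trait_positions) {
  idx <- match(assocs$trait, trait_positions[[1]])
  .assert(!anyNA(idx), "coordinates required for every trait")
  dplyr::mutate(assocs, trait_chrom = trait_positions$chrom[idx],
                trait_start = trait_positions$start[idx],
                trait_end = trait_positions$end[idx])
}
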
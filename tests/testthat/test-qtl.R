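# Small wide marker/trait tibbles from matrices (strains in columns).
wide_from_matrix <- function(id_col, ids, m, chrom = "chr1",
                             start = seq_along(ids) * 1000L) {
  out <- tibble::tibble(id = ids, chrom = chrom,
                        start = as.integer(start),
                        end = as.integer(start + 1L))
  names(out)[1] <- id_col
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

test_that("identical adjacent markers merge and mismatch counting respects the cutoff", {
  n <- 96
  strains <- sprintf("s%03d", 1:n)
  base <- rep(c(0, 1), length.out = n)
  mk3 <- base; mk3[1:3] <- 1 - mk3[1:3]          # 3 mismatches
  m <- rbind(base, base, mk3)
  colnames(m) <- strains
  raw <- wide_from_matrix("marker", c("m1", "m2", "m3"), m)
  merged <- merge_markers(raw)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$members[[1]], c("m1", "m2"))
  expect_equal(as.numeric(merged[1, strains]), base)   # mean of identical profiles
  expect_equal(merged$start[1], 1000L)
  expect_equal(merged$end[1], 2001L)
  # missing (0.5) entries are excluded from the comparison
  mk2 <- base; mk2[1:3] <- 0.5
  m2 <- rbind(base, mk2); colnames(m2) <- strains
  raw2 <- wide_from_matrix("marker", c("m1", "m2"), m2)
  expect_equal(nrow(merge_markers(raw2)), 1)
})

test_that("marker merging equals a brute-force implementation of the run rule", {
  brute_merge <- function(profiles, max_mismatch) {
    runs <- list(); current <- 1
    for (i in seq_len(nrow(profiles))[-1]) {
      a <- profiles[current[1], ]; b <- profiles[i, ]
      cmp <- a != 0.5 & b != 0.5
      if (sum(a[cmp] != b[cmp]) <= max_mismatch) current <- c(current, i)
      else { runs <- c(runs, list(current)); current <- i }
    }
    c(runs, list(current))
  }
  set.seed(77)
  for (rep in 1:10) {
    n <- 30
    m <- matrix(sample(c(0, 0.5, 1), 20 * n, replace = TRUE,
                       prob = c(0.45, 0.1, 0.45)), nrow = 20)
    colnames(m) <- sprintf("s%03d", 1:n)
    raw <- wide_from_matrix("marker", sprintf("m%02d", 1:20), m)
    merged <- merge_markers(raw, max_mismatch = 2)
    oracle <- brute_merge(m, 2)
    expect_equal(length(oracle), nrow(merged))
    expect_equal(merged$members,
                 purrr::map(oracle, ~ sprintf("m%02d", .x)))
    for (j in seq_along(oracle)) {
      expect_equal(as.numeric(merged[j, colnames(m)]),
                   unname(colMeans(m[oracle[[j]], , drop = FALSE])))
    }
  }
})

test_that("a trait identical to a marker profile has correlation one and minimal p", {
  set.seed(5)
  n <- 20
  g <- matrix(sample(c(0, 1), n * 3, replace = TRUE), ncol = n,
              dimnames = list(NULL, sprintf("s%03d", 1:n)))
  markers <- wide_from_matrix("marker", c("m1", "m2", "m3"), g)
  traits <- dplyr::bind_cols(tibble::tibble(trait = "t1"),
                             tibble::as_tibble(g[1, , drop = FALSE]))
  qm <- map_qtl(traits, markers, B = 200, seed = 6)
  a <- qm$associations
  expect_equal(a$r[a$marker == "m1"], 1)
  expect_equal(a$p[a$marker == "m1"], min(a$p))
  expect_true(all(a$p > 0))
  expect_equal(a$sign[a$marker == "m1"], "BY")
})

test_that("exhaustive pairwise permutation p equals full enumeration", {
  set.seed(8)
  n <- 5
  g <- matrix(c(0, 1, 0, 1, 1, 1, 1, 0, 0, 1), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, sprintf("s%03d", 1:n)))
  y <- matrix(rnorm(3 * n), nrow = 3, dimnames = list(NULL, colnames(g)))
  markers <- wide_from_matrix("marker", c("m1", "m2"), g)
  traits <- dplyr::bind_cols(tibble::tibble(trait = c("t1", "t2", "t3")),
                             tibble::as_tibble(y))
  qm <- map_qtl(traits, markers, null = "pairwise", exhaustive = TRUE)
  expect_equal(qm$B, 120)

  # independent enumeration oracle: next_perm-style iteration + cor()
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == n), ]
  expect_equal(nrow(perms), 120)
  for (i in 1:2) for (j in 1:3) {
    r_obs <- abs(cor(g[i, ], y[j, ]))
    k <- sum(apply(perms, 1, function(pm) {
      abs(cor(g[i, ], y[j, pm])) >= r_obs - 1e-12
    }))
    p_oracle <- (1 + k) / (120 + 1)
    got <- qm$associations$p[qm$associations$marker == paste0("m", i) &
                               qm$associations$trait == paste0("t", j)]
    expect_equal(got, p_oracle)
  }
})

test_that("flipping the allele coding flips r and sign but not p or q", {
  set.seed(15)
  n <- 30
  g <- matrix(sample(c(0, 1), n * 4, replace = TRUE), ncol = n,
              dimnames = list(NULL, sprintf("s%03d", 1:n)))
  y <- matrix(rnorm(5 * n), nrow = 5, dimnames = list(NULL, colnames(g)))
  markers <- wide_from_matrix("marker", sprintf("m%d", 1:4), g)
  markers_f <- wide_from_matrix("marker", sprintf("m%d", 1:4), 1 - g)
  traits <- dplyr::bind_cols(tibble::tibble(trait = sprintf("t%d", 1:5)),
                             tibble::as_tibble(y))
  a <- map_qtl(traits, markers, B = 100, seed = 3)$associations
  b <- map_qtl(traits, markers_f, B = 100, seed = 3)$associations
  expect_equal(a$r, -b$r)
  expect_equal(a$p, b$p)
  expect_equal(a$q, b$q)
  expect_true(all(a$sign != b$sign | a$r == 0))
})

test_that("zero-variance traits are skipped with a notice", {
  n <- 10
  g <- matrix(sample(c(0, 1), n * 2, replace = TRUE), ncol = n,
              dimnames = list(NULL, sprintf("s%03d", 1:n)))
  markers <- wide_from_matrix("marker", c("m1", "m2"), g)
  y <- rbind(rnorm(n), rep(1, n))
  colnames(y) <- colnames(g)
  traits <- dplyr::bind_cols(tibble::tibble(trait = c("t1", "t2")),
                             tibble::as_tibble(y))
  expect_message(qm <- map_qtl(traits, markers, B = 50, seed = 2),
                 "zero-variance")
  expect_equal(qm$dropped, "t2")
  expect_equal(nrow(qm$associations), 2)
})

test_that("cis/trans labels follow the 100 kb same-chromosome rule", {
  markers <- tibble::tibble(marker = c("mA", "mB", "mC"),
                            chrom = c("chr1", "chr1", "chr2"),
                            start = c(1000L, 250000L, 1000L),
                            end = c(2000L, 251000L, 2000L))
  tp <- tibble::tibble(ocr = "o1", chrom = "chr1", start = 1500L, end = 1700L)
  assocs <- tibble::tibble(marker = c("mA", "mB", "mC"), trait = "o1",
                           r = c(0.9, 0.5, 0.4))
  cl <- classify_associations(assocs, tp, markers, n_strains = 96)
  # overlap -> cis; 248 kb away same chrom -> trans; other chrom -> trans
  expect_equal(cl$associations$label, c("cis", "trans", "trans"))
  gap_edge <- dplyr::mutate(markers[2, ], start = 101700L, end = 102000L)
  cl2 <- classify_associations(assocs[2, ], tp, gap_edge, n_strains = 96)
  expect_equal(cl2$associations$label, "cis")   # gap exactly 100 kb
  expect_error(classify_associations(assocs, tp[0, ], markers, n_strains = 96),
               "coordinates")
})

test_that("regression p equals the correlation t-distribution p", {
  set.seed(91)
  n <- 25
  strains <- sprintf("s%03d", 1:n)
  g <- matrix(runif(n), ncol = n, dimnames = list(NULL, strains))
  y <- matrix(rnorm(n), ncol = n, dimnames = list(NULL, strains))
  markers <- wide_from_matrix("marker", "m1", g)
  traits <- dplyr::bind_cols(tibble::tibble(trait = "t1"), tibble::as_tibble(y))
  r <- cor(g[1, ], y[1, ])
  assocs <- tibble::tibble(marker = "m1", trait = "t1", r = r)
  tp <- tibble::tibble(trait = "t1", chrom = "chr1", start = 1L, end = 2L)
  cl_lm <- classify_associations(assocs, tp, markers, traits = traits)
  t_r <- abs(r) * sqrt((n - 2) / (1 - r^2))
  expect_equal(cl_lm$associations$regression_p, 2 * stats::pt(-t_r, n - 2),
               tolerance = 1e-12)
})

test_that("dual QTL overlap fractions match hand enumeration", {
  pos <- tibble::tibble(id = c("c1", "c2", "c3", "c4", "e1", "e2"),
                        chrom = c("chr1", "chr1", "chr2", "chr2", "chr1", "chr3"),
                        start = c(100L, 5000L, 100L, 900L, 200L, 100L),
                        end = c(300L, 5200L, 300L, 1100L, 400L, 300L))
  ca <- tibble::tibble(marker = c("M1", "M2", "M3", "M4"),
                       trait = c("c1", "c2", "c3", "c4"))
  ea <- tibble::tibble(marker = c("M1", "M5"), trait = c("e1", "e2"))
  ca <- attach_trait_positions(ca, dplyr::rename(pos, trait = id))
  ea <- attach_trait_positions(ea, dplyr::rename(pos, trait = id))
  ov <- dual_qtl_overlap(ca, ea, same_locus_window = 1000)
  # dual markers: M1 only -> 1/4 and 1/2; c1 and e1 are 0 bp apart on chr1
  expect_equal(ov$frac_chrom_also_expr, 0.25)
  expect_equal(ov$frac_expr_also_chrom, 0.5)
  expect_equal(ov$frac_dual_same_locus, 1)
  # identical lists give 1 everywhere; disjoint give 0
  same <- dual_qtl_overlap(ca, ca)
  expect_equal(same$frac_chrom_also_expr, 1)
  expect_equal(same$frac_dual_same_locus, 1)
  disj <- dual_qtl_overlap(ca, dplyr::mutate(ea, marker = c("M8", "M9")))
  expect_equal(disj$frac_chrom_also_expr, 0)
  expect_true(is.na(disj$frac_dual_same_locus))
  expect_error(dual_qtl_overlap(ca, ea, markers = tibble::tibble(marker = "M1")),
               "universe")
})
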
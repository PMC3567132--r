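test_that("gene density divides the +/-50 kb gene count by the peak size in kb", {
  ocrs <- tibble::tibble(ocr = c("o1", "o2"), chrom = "chr1",
                         start = c(100000L, 300000L), end = c(100200L, 300500L),
                         size = c(200L, 500L))
  genes <- tibble::tibble(chrom = "chr1",
                          start = as.integer(seq(60000, 141000, by = 9000)),
                          end = as.integer(seq(60000, 141000, by = 9000)) + 500L)
  gd <- gene_density(ocrs, genes)
  expect_equal(gd$n_genes, c(10L, 0L))
  expect_equal(gd$density, c(10 / 0.2, 0))   # 50 genes per kb
  expect_true(gd$gene_rich[1])
  expect_true(gd$gene_poor[2])
})

test_that("gene counting matches a per-interval brute-force oracle", {
  set.seed(61)
  for (i in 1:20) {
    oc <- random_peaks(10, 5000L)
    oc <- dplyr::mutate(oc, ocr = sprintf("o%02d", dplyr::row_number()),
                        size = end - start)
    gn <- random_peaks(15, 5000L)
    gd <- gene_density(oc, gn, window = 300)
    oracle <- vapply(seq_len(nrow(oc)), function(j) {
      sum(vapply(seq_len(nrow(gn)), function(k) {
        max(oc$start[j] - 300, gn$start[k]) < min(oc$end[j] + 300, gn$end[k])
      }, logical(1)))
    }, integer(1))
    expect_equal(gd$n_genes, oracle)
  }
})

test_that("telomere distance is the minimum gap to either chromosome end", {
  layout <- list(chromosomes = tibble::tibble(name = "chr1", length = 10000L))
  ocrs <- tibble::tibble(ocr = c("a", "b"), chrom = "chr1",
                         start = c(0L, 4000L), end = c(200L, 4200L),
                         size = 200L)
  tp <- telomere_profile(c(a = 1, b = 2), ocrs, layout)
  expect_equal(tp$distances$distance, c(0, 4000))   # min(4000, 5800) = 4000
  expect_true(all(tp$distances$distance <= 10000 / 2))
})

test_that("a constant statistic gives a flat profile and p = 1 near vs far", {
  layout <- list(chromosomes = tibble::tibble(name = "chr1", length = 60000L))
  set.seed(3)
  starts <- as.integer(seq(500, 55000, by = 1500))
  ocrs <- tibble::tibble(ocr = sprintf("o%02d", seq_along(starts)),
                         chrom = "chr1", start = starts, end = starts + 200L,
                         size = 200L)
  vals <- stats::setNames(rep(0.7, nrow(ocrs)), ocrs$ocr)
  tp <- telomere_profile(vals, ocrs, layout)
  expect_true(all(tp$profile$mean[!is.na(tp$profile$mean)] == 0.7))
  expect_equal(tp$test$p, 1)
  # elevated near-telomere values are detected
  vals2 <- vals + ifelse(pmin(ocrs$start, 60000 - ocrs$end) < 10000, 1, 0) +
    rnorm(length(vals), 0, 0.05)
  names(vals2) <- ocrs$ocr
  tp2 <- telomere_profile(vals2, ocrs, layout)
  expect_lt(tp2$test$p, 1e-6)
  expect_gt(tp2$test$mean_near, tp2$test$mean_far)
})

test_that("hotness assignment averages nearby loci and the one-sample t is exact", {
  track <- tibble::tibble(chrom = "chr1",
                          pos = as.integer(c(1000, 2000, 50000)),
                          score = c(0.5, -0.2, 3))
  ocr1 <- tibble::tibble(ocr = "o1", chrom = "chr1", start = 1500L,
                         end = 1700L, size = 200L)
  rh <- recombination_hotness(ocr1, track, assign_window = 1000)
  expect_equal(rh$scores$score, mean(c(0.5, -0.2)))  # both within 1 kb
  # no locus within the window: nearest is used
  far <- tibble::tibble(ocr = "o2", chrom = "chr1", start = 20000L,
                        end = 20200L, size = 200L)
  expect_equal(recombination_hotness(far, track, assign_window = 1000)$scores$score,
               -0.2)
  # frozen one-sample t example
  tr5 <- tibble::tibble(chrom = "chr1", pos = as.integer(1:5 * 1000),
                        score = c(0.5, -0.2, 0.8, 0.1, 0.4))
  oc5 <- tibble::tibble(ocr = sprintf("o%d", 1:5), chrom = "chr1",
                        start = as.integer(1:5 * 1000 - 100),
                        end = as.integer(1:5 * 1000 + 100), size = 200L)
  rh5 <- recombination_hotness(oc5, tr5, assign_window = 200)
  expect_equal(rh5$mean, 0.32)
  expect_equal(rh5$t, 1.866278, tolerance = 1e-6)
  expect_equal(rh5$p, 0.135413, tolerance = 1e-5)
  # degenerate zero-variance edge
  const <- dplyr::mutate(tr5, score = 1)
  rhc <- recombination_hotness(oc5, const, assign_window = 200)
  expect_equal(rhc$mean, 1)
  expect_true(is.infinite(rhc$t) && rhc$t > 0)
  expect_equal(rhc$p, 0)
  zero <- dplyr::mutate(tr5, score = 0)
  rh0 <- recombination_hotness(oc5, zero, assign_window = 200)
  expect_equal(rh0$t, 0)
  expect_equal(rh0$p, 1)
  expect_error(recombination_hotness(oc5[0, ], tr5), "empty")
})

test_that("poly-A/T scanning finds maximal runs with half-open coordinates", {
  r1 <- poly_at_scan("GGAAAAAGG")
  expect_true(r1$flag)
  expect_equal(c(r1$runs$start, r1$runs$end), c(2L, 7L))
  r2 <- poly_at_scan("GATATATG")           # mixed A/T run of 6
  expect_true(r2$flag)
  expect_equal(c(r2$runs$start, r2$runs$end), c(1L, 7L))
  expect_false(poly_at_scan("GATATATG", mode = "homopolymer")$flag)
  expect_false(poly_at_scan("ACGTACGT")$flag)
  expect_error(poly_at_scan("ACGX"), "A,C,G,T,N")
})

test_that("poly-A/T flags are invariant under A<->T swap and mirror under reverse complement", {
  set.seed(71)
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    a <- poly_at_scan(s)
    swapped <- poly_at_scan(chartr("AT", "TA", s))
    expect_equal(a$runs, swapped$runs)
    rc <- poly_at_scan(revcomp(s))
    expect_equal(a$flag, rc$flag)
    expect_equal(rc$runs$start, sort(60L - a$runs$end))
    expect_equal(rc$runs$end, sort(60L - a$runs$start))
  }
})

test_that("motif-polymorphism enrichment builds the 2x2 table with exact boundary rules", {
  ocrs <- tibble::tibble(ocr = c("o1", "o2", "o3"), chrom = "chr1",
                         start = c(100L, 300L, 500L), end = c(200L, 400L, 600L),
                         size = 100L)
  motifs <- tibble::tibble(chrom = "chr1", start = c(150L, 350L),
                           end = c(160L, 360L))
  # SNP at motif start (inside), at motif end (outside), none in o3
  snps <- tibble::tibble(chrom = "chr1", pos = c(150L, 360L))
  res <- motif_polymorphism_enrichment(ocrs, motifs, snps,
                                       cis_flags = c(TRUE, FALSE, FALSE))
  expect_equal(res$polymorphic$motif_polymorphic, c(TRUE, FALSE, FALSE))
  expect_equal(as.vector(res$table), c(1, 0, 0, 2))
  # degenerate margins are flagged with p = 1
  none <- motif_polymorphism_enrichment(ocrs, motifs, snps[0, ],
                                        cis_flags = c(TRUE, FALSE, FALSE))
  expect_true(none$degenerate)
  expect_equal(none$p, 1)
  expect_true(is.na(none$odds_ratio))
})

test_that("the Fisher test on the frozen contingency table matches hypergeometric enumeration", {
  # counts: 10 poly-cis, 90 poly-noncis, 5 nonpoly-cis, 895 nonpoly-noncis
  set.seed(81)
  build <- function(a, b, c, d) {
    n <- a + b + c + d
    ocrs <- tibble::tibble(ocr = sprintf("x%04d", 1:n), chrom = "chr1",
                           start = as.integer((1:n) * 1000),
                           end = as.integer((1:n) * 1000 + 100), size = 100L)
    poly <- rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d))
    cis <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d))
    motifs <- dplyr::transmute(ocrs[poly, ], chrom, start = start + 10L,
                               end = start + 20L)
    snps <- tibble::tibble(chrom = "chr1", pos = motifs$start + 2L)
    list(ocrs = ocrs, motifs = motifs, snps = snps, cis = cis)
  }
  w <- build(10, 90, 5, 895)
  res <- motif_polymorphism_enrichment(w$ocrs, w$motifs, w$snps, w$cis)
  expect_equal(res$odds_ratio, 10 * 895 / (90 * 5))   # 19.89
  # independent oracle: hypergeometric tail enumeration
  m <- 100; k <- 15; N <- 1000
  probs <- stats::dhyper(0:k, m, N - m, k)
  p_oracle <- sum(probs[probs <= stats::dhyper(10, m, N - m, k) * (1 + 1e-7)])
  expect_equal(res$p, p_oracle, tolerance = 1e-9)
  expect_lt(res$p, 1e-6)
})
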
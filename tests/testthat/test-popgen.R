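test_that("allele binning snaps to the repeat ladder and flags ties", {
  b <- bin_alleles(c(200.1, 202.0, 203.9), motif_length = 2,
                   reference_size = 200)
  expect_equal(b$allele, c(200, 202, 204))
  expect_false(any(b$ambiguous))

  # single size snaps to its nearest rung
  expect_equal(bin_alleles(198.8, 2, 200)$allele, 198)

  tie <- bin_alleles(201, 2, 200)
  expect_true(tie$ambiguous)
  expect_true(is.na(tie$allele))
  expect_error(bin_alleles(-5, 2, 200), "positive")
  expect_error(bin_alleles(200, 0, 200), "motif_length")
})

test_that("diploid allele counting: 14/24 vs 10/24 and degenerate cases", {
  g <- generate_panel(panel_spec(
    loci = list(list(name = "L", motif_length = 2, ref_size = 200,
                     counts = c(14, 10))),
    populations = c(p = 12), mode = "counts", seed = 1))
  f <- allele_frequencies(g, "L")
  expect_equal(sum(f$counts), 24L)
  expect_equal(unname(sort(f$counts, decreasing = TRUE)), c(14L, 10L))
  expect_equal(unname(sort(round(f$freqs, 4), decreasing = TRUE)),
               c(0.5833, 0.4167))

  hom <- genotype_matrix(matrix(200, 5, 1, dimnames = list(NULL, "L")),
                         matrix(200, 5, 1, dimnames = list(NULL, "L")))
  fh <- allele_frequencies(hom, "L")
  expect_equal(unname(fh$freqs), 1)
  expect_equal(fh$n_het, 0L)

  miss <- genotype_matrix(matrix(NA_real_, 3, 1,
                                 dimnames = list(NULL, "L")),
                          matrix(NA_real_, 3, 1,
                                 dimnames = list(NULL, "L")))
  expect_error(allele_frequencies(miss, "L"), "missing")
})

test_that("closed-form checks: equifrequent and monomorphic loci", {
  g2 <- generate_panel(panel_spec(
    loci = list(list(name = "L", motif_length = 2, ref_size = 200,
                     counts = c(12, 12))),
    populations = c(p = 12), mode = "counts", seed = 1))
  st <- locus_stats(allele_frequencies(g2, "L"))
  expect_equal(st$Ne, 2)
  expect_equal(st$I, log(2))
  expect_equal(st$PIC, 0.375)

  g1 <- generate_panel(panel_spec(
    loci = list(list(name = "L", motif_length = 2, ref_size = 200,
                     counts = c(24))),
    populations = c(p = 12), mode = "counts", seed = 1))
  m <- locus_stats(allele_frequencies(g1, "L"))
  expect_equal(m$Ne, 1)
  expect_equal(m$I, 0)
  expect_equal(m$He, 0)
  expect_equal(m$PIC, 0)
})

test_that("reference panel rows reproduce all four statistics jointly to 4 dp", {
  g <- reference_panel_genotypes()
  st <- panel_stats(g)
  rp <- reference_panel()
  m <- merge(st, rp$expected, by = "locus", suffixes = c("", ".ref"))
  expect_equal(nrow(m), 28L)
  expect_equal(m$Na, m$Na.ref)
  expect_equal(round(m$Ne, 4), m$Ne.ref)
  expect_equal(round(m$I, 4), m$I.ref)
  expect_equal(round(m$He, 4), m$He.ref)
  expect_equal(round(m$PIC, 4), m$PIC.ref)
  # the legacy "observed heterozygosity" column is the He complement
  expect_equal(m$Ho_compat, 1 - m$He)
})

test_that("panel summary: totals, means, spread and PIC classes", {
  g <- reference_panel_genotypes()
  ps <- summarize_panel(panel_stats(g))
  expect_equal(ps$total_alleles, 81)
  expect_equal(round(ps$statistics["Na", "mean"], 4), 2.8929)
  expect_equal(round(ps$statistics["Ne", "mean"], 4), 2.0281)
  expect_equal(round(ps$statistics["I", "mean"], 4), 0.7600)
  expect_equal(round(ps$statistics["He", "mean"], 4), 0.4732)
  expect_equal(round(ps$statistics["PIC", "mean"], 4), 0.3863)
  expect_equal(unname(ps$pic_classes["low"]), 7L)
  expect_equal(unname(ps$pic_classes["high"]), 6L)
  expect_equal(sum(ps$pic_classes), 28L)

  single <- summarize_panel(panel_stats(g)[1, ])
  expect_equal(single$statistics["Ne", "sd"], 0)
  expect_equal(single$statistics["Ne", "mean"],
               single$statistics["Ne", "min"])
})

test_that("statistics are invariant to allele relabeling and He correction vanishes as n grows", {
  g <- reference_panel_genotypes()
  f <- allele_frequencies(g, "SSR522")
  st <- locus_stats(f)
  # permute allele labels/order: the frequency multiset is unchanged
  f2 <- f
  f2$counts <- rev(f2$counts)
  f2$freqs <- rev(f2$freqs)
  st2 <- locus_stats(f2)
  expect_equal(st2[c("Ne", "I", "He", "PIC")], st[c("Ne", "I", "He", "PIC")])

  p <- c(0.6, 0.3, 0.1)
  gd <- 1 - sum(p^2)
  he_n <- vapply(c(10, 100, 1000, 1e5), function(n)
    (2 * n / (2 * n - 1)) * gd, numeric(1))
  expect_true(all(diff(abs(he_n - gd)) < 0))
  expect_equal(he_n[4], gd, tolerance = 1e-4)
  # PIC never exceeds the gene diversity bound
  set.seed(9)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    cts <- as.vector(stats::rmultinom(1, 24, runif(k) + 0.1))
    cts <- cts[cts > 0]
    if (length(cts) < 2) next
    gg <- generate_panel(panel_spec(
      loci = list(list(name = "L", motif_length = 2, ref_size = 100,
                       counts = cts)),
      populations = c(p = 12), mode = "counts", seed = 1))
    s <- locus_stats(allele_frequencies(gg, "L"))
    pvec <- cts / 24
    expect_lte(s$PIC, 1 - sum(pvec^2) + 1e-12)
    expect_lte(s$Ne, s$Na)
    expect_gte(s$Ne, 1)
  }
})

test_that("within-population diversity: clonal and fixed-difference panels", {
  mk <- function(vals) {
    a <- matrix(vals, ncol = 2,
                dimnames = list(paste0("s", seq_len(length(vals) / 2)),
                                c("L1", "L2")))
    genotype_matrix(a, a)
  }
  # two clonal populations (every individual homozygous, identical)
  g <- mk(rep(c(200, 300), each = 6))
  pops <- setNames(rep(c("A", "B"), each = 3), g$samples)
  wp <- within_population_diversity(g, pops)
  expect_equal(wp$Hs, 0)

  # populations fixed for different alleles: Hs = 0, total diversity > 0
  a1 <- matrix(c(rep(200, 3), rep(204, 3)), ncol = 1,
               dimnames = list(paste0("s", 1:6), "L1"))
  gf <- genotype_matrix(a1, a1)
  wpf <- within_population_diversity(gf, setNames(rep(c("A", "B"),
                                                      each = 3),
                                                  gf$samples))
  expect_equal(wpf$Hs, 0)
  expect_gt(locus_stats(allele_frequencies(gf, "L1"))$He, 0)

  expect_warning(
    within_population_diversity(gf, setNames(c("A", "A", "A", "A", "A",
                                               "B"), gf$samples)),
    "size 1")

  # corrected estimator exceeds the uncorrected one when diversity > 0
  set.seed(12)
  gp <- generate_panel(panel_spec(
    loci = list(list(name = "L1", motif_length = 2, ref_size = 100,
                     freqs = c(0.6, 0.4))),
    populations = c(A = 10, B = 10), mode = "hw", seed = 4))
  w0 <- within_population_diversity(gp, attr(gp, "populations"))
  w1 <- within_population_diversity(gp, attr(gp, "populations"),
                                    corrected = TRUE)
  expect_gte(w1$Hs, w0$Hs)
})

test_that("genotype tables round-trip through the text dialect", {
  g <- reference_panel_genotypes()
  path <- tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path)
  expect_equal(g2$a1, g$a1)
  expect_equal(g2$a2, g$a2)
  expect_equal(g2$samples, g$samples)
})
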
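# a genotype matrix from explicit homozygous calls (one band per marker)
panel_from_codes <- function(codes) {
  # codes: samples x markers integer matrix of allele indices
  a <- 200 + 2 * codes
  rownames(a) <- paste0("s", seq_len(nrow(codes)))
  colnames(a) <- paste0("M", seq_len(ncol(codes)))
  genotype_matrix(a, a)
}

test_that("marker subsets distinguish iff all pairwise patterns differ", {
  g <- panel_from_codes(cbind(c(1, 2, 3, 4), c(1, 1, 2, 2)))
  fp <- fingerprint_profile(g)
  expect_true(distinguishes("M1", fp))
  expect_false(distinguishes("M2", fp))
  expect_true(distinguishes(c("M1", "M2"), fp))
  expect_error(distinguishes("M9", fp), "unknown")
  expect_error(distinguishes(character(0), fp), "non-empty")

  # duplicated samples: no subset can ever discriminate
  dup <- panel_from_codes(cbind(c(1, 1, 2), c(3, 3, 4)))
  fdup <- fingerprint_profile(dup)
  expect_false(distinguishes(c("M1", "M2"), fdup))
})

test_that("engineered anchor structure: two fixed markers plus any one of five", {
  # M1 and M2 jointly split the panel into groups; each of M3..M7 resolves
  # the one remaining ambiguous pair, and no other pair of markers does
  codes <- cbind(
    M1 = c(1, 1, 2, 2, 3, 3),
    M2 = c(1, 2, 1, 2, 1, 1),
    M3 = c(1, 1, 1, 1, 1, 2),
    M4 = c(2, 2, 2, 2, 2, 1),
    M5 = c(1, 1, 1, 1, 2, 1),
    M6 = c(1, 1, 1, 1, 3, 2),
    M7 = c(2, 2, 2, 2, 1, 3))
  g <- panel_from_codes(codes)
  fp <- fingerprint_profile(g)
  # {M1, M2} leaves exactly the pair (s5, s6) unresolved
  expect_false(distinguishes(c("M1", "M2"), fp))
  for (m in paste0("M", 3:7))
    expect_true(distinguishes(c("M1", "M2", m), fp))
  core <- find_core_sets(fp, max_size = 3)
  with_anchors <- Filter(function(s) all(c("M1", "M2") %in% s), core$sets)
  expect_length(with_anchors, 5L)
  expect_setequal(vapply(with_anchors, function(s)
    setdiff(s, c("M1", "M2")), character(1)), paste0("M", 3:7))
  # exhaustive confirmation against unpruned brute force
  expect_equal(core$sets, oracle_core_sets(g, 3))
})

test_that("core-set search matches brute force on random panels", {
  set.seed(55)
  for (i in 1:6) {
    codes <- matrix(sample(1:3, 12 * 8, replace = TRUE), 12, 8)
    g <- panel_from_codes(codes)
    core <- find_core_sets(fingerprint_profile(g), max_size = 3)
    expect_equal(core$sets, oracle_core_sets(g, 3))
  }
})

test_that("monotonicity and minimality of reported sets", {
  set.seed(66)
  codes <- matrix(sample(1:4, 10 * 6, replace = TRUE), 10, 6)
  g <- panel_from_codes(codes)
  fp <- fingerprint_profile(g)
  core <- find_core_sets(fp, max_size = 3)
  all_markers <- unique(fp$markers)
  for (s in core$sets) {
    # supersets still discriminate
    extra <- setdiff(all_markers, s)
    if (length(extra) > 0)
      expect_true(distinguishes(c(s, extra[1]), fp))
    # removing any member breaks discrimination
    if (length(s) > 1)
      for (m in s) expect_false(distinguishes(setdiff(s, m), fp))
  }
})

test_that("single all-distinct marker, duplicates diagnostic, missing data", {
  g1 <- panel_from_codes(cbind(c(1, 2, 3, 4, 5)))
  core1 <- find_core_sets(fingerprint_profile(g1), max_size = 2)
  expect_equal(core1$sets, list("M1"))

  dup <- panel_from_codes(cbind(c(1, 1, 2), c(2, 2, 3)))
  core_dup <- find_core_sets(fingerprint_profile(dup), max_size = 2)
  expect_length(core_dup$sets, 0L)
  expect_equal(core_dup$unresolved_pairs, "s1|s2")

  # a missing call makes the pair indeterminate at that marker
  a <- matrix(c(200, 202, 204, NA), ncol = 2,
              dimnames = list(c("s1", "s2"), c("M1", "M2")))
  gm <- genotype_matrix(a, a)
  fpm <- fingerprint_profile(gm)
  expect_true(distinguishes("M1", fpm))
  expect_false(distinguishes("M2", fpm))
})

test_that("fingerprint report: band counts and stable patterns", {
  codes <- cbind(M1 = c(1, 2, 3, 4, 5, 6), M2 = c(1, 1, 1, 1, 1, 1))
  g <- panel_from_codes(codes)
  rep <- fingerprint_report(fingerprint_profile(g))
  expect_equal(unname(rep$band_counts[c("M1", "M2")]), c(6L, 1L))
  # a monomorphic marker contributes nothing to discrimination
  expect_false(distinguishes("M2", fingerprint_profile(g)))
  expect_length(rep$patterns, 6L)
  expect_equal(length(unique(rep$patterns)), 6L)
})

test_that("strict genotype mode separates heterozygote pairs that share bands", {
  # s1 = A/B het; s2 = A/A hom; s3 = B/B hom: band view and genotype view
  # agree here, but an A/B vs A/B comparison with phase-identical bands is
  # still equal in both modes; verify modes run and agree on this panel
  a1 <- matrix(c(200, 200, 202), ncol = 1,
               dimnames = list(paste0("s", 1:3), "M1"))
  a2 <- matrix(c(202, 200, 202), ncol = 1,
               dimnames = list(paste0("s", 1:3), "M1"))
  g <- genotype_matrix(a1, a2)
  fp <- fingerprint_profile(g)
  expect_true(distinguishes("M1", fp, mode = "bands"))
  expect_true(distinguishes("M1", fp, mode = "genotype"))
})
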
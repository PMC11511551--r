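test_that("flank extraction round-trips the genomic span", {
  set.seed(8)
  genome <- c(chr1 = paste0(random_dna(100), strrep("AT", 10),
                            random_dna(120)))
  ssr <- data.frame(seq_id = "chr1", start = 101, end = 120)
  fl <- extract_flanks(ssr, genome, flank_length = 100)
  expect_equal(fl$left_flank, unname(substr(genome, 1, 100)))
  expect_equal(fl$right_flank, unname(substr(genome, 121, 220)))
  expect_equal(paste0(fl$left_flank, fl$ssr_seq, fl$right_flank),
               unname(substr(genome, 1, 220)))
  expect_false(fl$truncated)

  near_start <- data.frame(seq_id = "chr1", start = 5, end = 20)
  expect_warning(fl2 <- extract_flanks(near_start, genome, 100),
                 "truncated")
  expect_equal(fl2$left_flank, unname(substr(genome, 1, 4)))
  expect_error(extract_flanks(data.frame(seq_id = "chr1", start = 500,
                                         end = 520), genome, 10),
               "bounds")
})

test_that("Wallace rule and nearest-neighbor Tm behave as specified", {
  # 10 AT + 10 GC -> 2*10 + 4*10 = 60
  expect_equal(compute_tm("ATATATATATGCGCGCGCGC", method = "wallace"), 60)
  expect_error(compute_tm(""), "empty")
  expect_error(compute_tm("ACGTN"), "ambiguous")
  # frozen oracle: independent nearest-neighbor calculation with the
  # SantaLucia unified table, 50 nM primer, 50 mM Na+, entropy salt
  # correction (computed with an external thermodynamics implementation)
  expect_equal(compute_tm("GCGTCTGTAGTAGCAGTTCA"), 51.686304,
               tolerance = 1e-6)
  expect_equal(compute_tm("ATGCATGCATGCATGCATGC"), 55.497937,
               tolerance = 1e-6)
  expect_equal(compute_tm("ACGTACGTACGTACGTAC"), 48.310512,
               tolerance = 1e-6)
})

test_that("primer pair validation reports each violated rule", {
  ok <- structure(list(forward = strrep("A", 20), reverse = strrep("A", 20),
                       product_size = 200,
                       tm = c(forward = 60, reverse = 60),
                       gc = c(forward = 50, reverse = 50)),
                  class = "primer_pair")
  res <- check_primer_pair(ok)
  expect_true(res$pass)
  expect_length(res$reasons, 0)

  short_fwd <- ok; short_fwd$forward <- strrep("A", 17)
  expect_equal(check_primer_pair(short_fwd)$reasons, "forward length")

  hot_gc <- ok; hot_gc$gc["reverse"] <- 65
  expect_equal(check_primer_pair(hot_gc)$reasons, "reverse GC-content")

  big <- ok; big$product_size <- 500
  expect_equal(check_primer_pair(big)$reasons, "product size")
})

test_that("validation is monotone: relaxing ranges never fails a passer", {
  set.seed(30)
  base <- primer_constraints()
  for (i in 1:25) {
    p <- structure(list(forward = strrep("A", sample(15:30, 1)),
                        reverse = strrep("A", sample(15:30, 1)),
                        product_size = runif(1, 80, 500),
                        tm = c(forward = runif(1, 50, 70),
                               reverse = runif(1, 50, 70)),
                        gc = c(forward = runif(1, 20, 80),
                               reverse = runif(1, 20, 80))),
                   class = "primer_pair")
    relaxed <- primer_constraints(length = base$length + c(-2, 2),
                                  tm = base$tm + c(-5, 5),
                                  product = base$product + c(-50, 50),
                                  gc = base$gc + c(-10, 10))
    # contrapositive form so every iteration asserts something
    expect_true(!check_primer_pair(p, base)$pass ||
                check_primer_pair(p, relaxed)$pass)
  }
})

test_that("M13 tailing prepends once and shifts sizes by the tail length", {
  tail <- m13_tail()
  expect_equal(tail$sequence, "TGTAAAAACGACGGCCAGT")
  expect_equal(m13_tail(variant = "canonical")$sequence,
               "TGTAAAACGACGGCCAGT")
  expect_equal(nchar(m13_tail(variant = "canonical")$sequence), 18L)

  primer <- "GCGTCTGTAGTAGCAGTTCA"
  tailed <- apply_m13_tail(primer, tail)
  expect_equal(nchar(tailed), nchar(primer) + nchar(tail$sequence))
  expect_equal(as.character(substr(tailed, 1, nchar(tail$sequence))),
               tail$sequence)
  expect_error(apply_m13_tail(tailed, tail), "already")
  expect_equal(tailed_product_size(200, tail), 200 + 19)
  expect_error(m13_tail(dye = "CY5"), "dye")
})

test_that("candidate enumeration returns only constraint-satisfying pairs", {
  set.seed(77)
  # flanks rich in balanced GC so candidates exist
  left <- random_dna(120, gc = 0.5)
  right <- random_dna(120, gc = 0.5)
  cons <- primer_constraints(tm = c(45, 65), product = c(60, 300))
  cand <- enumerate_primer_candidates(left, right, ssr_length = 20,
                                      constraints = cons, max_pairs = 20)
  expect_gt(nrow(cand), 0)
  if (nrow(cand) > 0) {
    expect_true(all(cand$forward_gc >= 40 & cand$forward_gc <= 60))
    expect_true(all(cand$forward_tm >= 45 & cand$forward_tm <= 65))
    expect_true(all(cand$product_size >= 60 & cand$product_size <= 300))
    expect_true(all(nchar(cand$forward) >= 18 & nchar(cand$forward) <= 25))
    # reverse primer must be a revcomp substring of the right flank
    expect_true(all(vapply(cand$reverse, function(r)
      grepl(reverse_complement(r), right, fixed = TRUE), logical(1))))
  }
})
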
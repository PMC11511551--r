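test_that("threshold boundary: AT x 6 is reported, AT x 5 is not", {
  hit <- find_perfect_ssrs(strrep("AT", 6))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "AT")
  expect_equal(hit$repeats, 6L)
  expect_equal(c(hit$start, hit$end), c(1L, 12L))
  expect_equal(nrow(find_perfect_ssrs(strrep("AT", 5))), 0L)
})

test_that("scanner basics: empty input, invalid characters, N truncation", {
  expect_equal(nrow(find_perfect_ssrs("")), 0L)
  expect_error(find_perfect_ssrs("ACGTX"), "invalid character")
  split_run <- find_perfect_ssrs(paste0(strrep("AT", 7), "N", strrep("AT", 7)))
  expect_equal(nrow(split_run), 2L)
  expect_equal(split_run$repeats, c(7L, 7L))
  expect_false(any(grepl("N", split_run$motif)))
})

test_that("runs divisible by a shorter period are reported at that period", {
  hit <- find_perfect_ssrs(strrep("AT", 10))
  expect_equal(hit$motif, "AT")
  expect_equal(hit$motif_length, 2L)
  # phase preserved even after a discarded homopolymer context
  hit2 <- find_perfect_ssrs(paste0(strrep("A", 12), strrep("TA", 8)))
  expect_equal(hit2$motif, "AT")
  expect_equal(hit2$start, 12L)
})

test_that("planted SSRs are recovered exactly; spacers yield no false hits", {
  sp <- plant_spec(plants = data.frame(
    motif = c("AT", "GA", "CAG", "AAT", "TACA", "CGAGC", "TATACA",
              "CT", "GGC", "AC", "TTG", "CATA"),
    repeats = c(8, 7, 6, 6, 5, 5, 5, 9, 7, 6, 5, 6)), seed = 11)
  gg <- generate_genome(sp)
  found <- find_perfect_ssrs(gg$genome[[1]], sp$config, seq_id = "chr1")
  expect_equal(nrow(found), 12L)
  expect_equal(found$start, gg$truth$start)
  expect_equal(found$end, gg$truth$end)
  expect_equal(found$motif, gg$truth$motif)
  expect_equal(found$repeats, gg$truth$repeats)
})

test_that("scanner agrees with the exhaustive position-by-period oracle", {
  set.seed(101)
  cfg <- mining_config()
  adversarial <- c(
    paste0(strrep("A", 30), strrep("TA", 9), strrep("A", 30)),
    paste0(strrep("ATAT", 8), "G", strrep("CAG", 12)),
    paste0(strrep("AAT", 10), strrep("ATA", 10)),
    strrep("ACGT", 25),
    paste0(strrep("CACACG", 6), strrep("CA", 10)))
  for (s in adversarial)
    expect_same_ssrs(find_perfect_ssrs(s, cfg), oracle_find_ssrs(s, cfg))
  for (i in 1:20) {
    # low-GC random sequence sprinkled with injected repeats
    s <- paste0(random_dna(2000, gc = runif(1, 0.3, 0.7)),
                strrep(random_dna(sample(2:6, 1)), sample(5:12, 1)),
                random_dna(1000))
    expect_same_ssrs(find_perfect_ssrs(s, cfg), oracle_find_ssrs(s, cfg))
  }
})

test_that("compound merging follows the linker bound transitively", {
  mk <- function(starts, lens) {
    d <- data.frame(seq_id = "s", start = starts, end = starts + lens - 1L,
                    motif = "AT", motif_length = 2L, repeats = lens / 2,
                    length = lens)
    class(d) <- c("ssr_table", "data.frame"); d
  }
  cfg <- mining_config(max_linker = 100)

  # zero-nt junction -> one compound of two members
  two <- merge_compound(mk(c(1, 13), c(12, 12)), cfg)
  expect_equal(two$type, "compound")
  expect_equal(two$n_members, 2L)
  expect_equal(two$linkers[[1]], 0L)

  # gap of max_linker merges, max_linker + 1 does not
  at_bound <- merge_compound(mk(c(1, 113), c(12, 12)), cfg)
  expect_equal(at_bound$type, "compound")
  over <- merge_compound(mk(c(1, 114), c(12, 12)), cfg)
  expect_equal(over$type, c("perfect", "perfect"))

  # chaining is transitive: gaps 5 and 40 -> one 3-member compound
  three <- merge_compound(mk(c(1, 18, 70), c(12, 12, 12)), cfg)
  expect_equal(three$n_members, 3L)
  expect_equal(three$linkers[[1]], c(5L, 40L))

  expect_error(merge_compound(mk(c(1, 5), c(12, 12)), cfg), "overlap")
})

test_that("merging is idempotent and conserves member counts", {
  set.seed(42)
  cfg <- mining_config()
  for (rep in 1:5) {
    n <- 15
    gaps <- sample(c(0:5, 50, 101, 150, 300), n, replace = TRUE)
    lens <- sample(seq(12, 30, by = 2), n, replace = TRUE)
    starts <- cumsum(c(1, (lens + gaps + 1)[-n]))
    d <- data.frame(seq_id = "s", start = starts, end = starts + lens - 1L,
                    motif = "GA", motif_length = 2L, repeats = lens / 2,
                    length = lens)
    merged <- merge_compound(d, cfg)
    expect_equal(sum(merged$n_members), n)
    flat <- do.call(rbind, merged$members)
    remerged <- merge_compound(flat[order(flat$start), ], cfg)
    expect_equal(remerged$start, merged$start)
    expect_equal(remerged$end, merged$end)
    expect_equal(remerged$n_members, merged$n_members)
  }
})

test_that("motif classes pair reverse complements and preserve phase", {
  expect_equal(canonical_motif_class("GA"), "GA/TC")
  expect_equal(canonical_motif_class("CT"), "AG/CT")
  expect_equal(canonical_motif_class("AT"), "AT/AT")
  expect_equal(canonical_motif_class("CCG"), "CCG/CGG")
  # rotations are distinct classes
  expect_false(canonical_motif_class("GA") == canonical_motif_class("AG"))
  expect_error(canonical_motif_class("AN"), "ambiguous")
  # closure under reverse complement for all dimers/trimers
  set.seed(1)
  for (k in 2:3) {
    motifs <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1,
                    paste, collapse = "")
    expect_equal(canonical_motif_class(motifs),
                 canonical_motif_class(reverse_complement(motifs)))
  }
})

test_that("mining summary arithmetic: frequency per Mb and proportions", {
  # genome-screen scale check on the published magnitude
  expect_equal(round(231789 / 2813.5, 1), 82.4)

  sp <- plant_spec(plants = data.frame(
    motif = c(rep("AT", 6), rep("CAG", 3), "TACA"),
    repeats = c(rep(7, 6), rep(6, 3), 5)), seed = 3)
  gg <- generate_genome(sp)
  mining <- mine_ssrs(gg$genome, sp$config)
  sm <- mining$summary
  expect_equal(sm$n_total, 10L)
  expect_equal(sm$n_motifs, 10L)
  bl <- sm$by_motif_length
  expect_equal(bl$proportion[match(c("2", "3", "4"), bl$key)],
               c(0.6, 0.3, 0.1))
  expect_equal(sum(bl$proportion), 1)
  expect_equal(sm$frequency_per_mb,
               10 / (nchar(gg$genome[[1]]) / 1e6))
  expect_error(summarize_mining(mining$records, 0), "genome_length")

  empty <- summarize_mining(find_perfect_ssrs("ACGT"), 1e6)
  expect_equal(empty$n_total, 0L)
  expect_equal(empty$frequency_per_mb, 0)
})
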
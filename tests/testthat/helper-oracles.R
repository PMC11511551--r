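# Independent oracles used across the suite. These deliberately use
# different mechanics from the package implementation.

random_dna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# Exhaustive O(n * k * L) scan: tests every start position and period,
# extending character by character, and applies the same reporting rules
# (left/right maximality, shortest-period-only, longer-span-wins overlap
# resolution) by direct definition.
oracle_find_ssrs <- function(seq, config = mining_config()) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  ok <- chars %in% c("A", "C", "G", "T")
  cand <- list()
  for (k in as.integer(names(config$min_repeats))) {
    minrep <- config$min_repeats[[as.character(k)]]
    if (n < k * minrep) next
    for (i in seq_len(n - k * minrep + 1L)) {
      if (!all(ok[i:(i + k - 1L)])) next
      j <- i + k
      while (j <= n && ok[j] && chars[j] == chars[j - k]) j <- j + 1L
      reps <- (j - i) %/% k
      if (reps < minrep) next
      # left-maximal: the previous base must not extend the periodicity
      if (i > 1L && ok[i - 1L] && chars[i - 1L] == chars[i - 1L + k]) next
      motif <- paste(chars[i:(i + k - 1L)], collapse = "")
      power <- FALSE
      for (d in seq_len(k - 1L)) {
        if (k %% d == 0L &&
            paste(rep(chars[i:(i + d - 1L)], k %/% d), collapse = "") ==
              motif) { power <- TRUE; break }
      }
      if (power) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = i, end = i + reps * k - 1L, motif = motif,
        motif_length = k, repeats = reps, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), motif_length = integer(),
                      repeats = integer(), stringsAsFactors = FALSE))
  cand <- do.call(rbind, cand)
  # iterative overlap resolution: longest span wins, tie -> shorter period,
  # tie -> leftmost
  chosen <- list()
  while (nrow(cand) > 0L) {
    len <- cand$end - cand$start + 1L
    best <- which(len == max(len))
    best <- best[cand$motif_length[best] == min(cand$motif_length[best])]
    best <- best[which.min(cand$start[best])]
    pick <- cand[best, , drop = FALSE]
    chosen[[length(chosen) + 1L]] <- pick
    cand <- cand[cand$end < pick$start | cand$start > pick$end, ,
                 drop = FALSE]
  }
  out <- do.call(rbind, chosen)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_same_ssrs <- function(found, oracle) {
  expect_equal(nrow(found), nrow(oracle))
  if (nrow(found) == nrow(oracle) && nrow(found) > 0) {
    expect_equal(found$start, oracle$start)
    expect_equal(found$end, oracle$end)
    expect_equal(found$motif, oracle$motif)
    expect_equal(found$repeats, oracle$repeats)
  }
}

# Unpruned brute force over all marker subsets up to max_size, comparing
# full pattern strings directly.
oracle_core_sets <- function(g, max_size, fp_mode = "bands") {
  fp <- fingerprint_profile(g)
  markers <- unique(fp$markers)
  ns <- length(fp$samples)
  pattern_of <- function(sample_i, set) {
    paste(vapply(set, function(m) {
      cols <- which(fp$markers == m)
      v <- fp$bands[sample_i, cols]
      if (anyNA(v)) NA_character_ else paste(v, collapse = "")
    }, character(1)), collapse = "|")
  }
  discriminates <- function(set) {
    for (i in seq_len(ns - 1)) {
      for (j in seq(i + 1, ns)) {
        sep <- FALSE
        for (m in set) {
          a <- pattern_of(i, m); b <- pattern_of(j, m)
          if (!is.na(a) && !is.na(b) && a != b) { sep <- TRUE; break }
        }
        if (!sep) return(FALSE)
      }
    }
    TRUE
  }
  all_sets <- list()
  for (size in seq_len(min(max_size, length(markers)))) {
    for (set in utils::combn(markers, size, simplify = FALSE)) {
      if (discriminates(set)) all_sets[[length(all_sets) + 1L]] <- set
    }
  }
  # keep minimal ones only
  minimal <- Filter(function(s) {
    !any(vapply(all_sets, function(o)
      length(o) < length(s) && all(o %in% s), logical(1)))
  }, all_sets)
  minimal[order(lengths(minimal),
                vapply(minimal, paste, character(1), collapse = "\r"))]
}
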
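#' Mining configuration for microsatellite detection
#'
#' Bundles the per-motif-length minimum repeat counts and the compound-SSR
#' linker bound used throughout the mining stage.
#'
#' @param min_repeats Named integer vector mapping motif length (as character
#'   names `"1"`..`"6"`) to the minimum number of tandem repeats required to
#'   report a perfect SSR. Defaults to the classic MISA-style genome screen:
#'   dinucleotides at least 6 times, tri- to hexanucleotides at least 5 times.
#' @param max_linker Maximum spacing, in nucleotides, between two consecutive
#'   perfect SSRs for them to be merged into one compound SSR (inclusive
#'   bound).
#' @param include_mono Report mononucleotide runs as well. Off by default;
#'   when enabled and no `"1"` entry is present in `min_repeats`, a minimum
#'   of 10 repeats is used.
#'
#' @return An object of class `mining_config`.
#' @examples
#' cfg <- mining_config()
#' cfg$min_repeats
#' @export
mining_config <- function(min_repeats = c("2" = 6L, "3" = 5L, "4" = 5L,
                                          "5" = 5L, "6" = 5L),
                          max_linker = 100L,
                          include_mono = FALSE) {
  if (is.null(names(min_repeats)) || any(!nzchar(names(min_repeats))))
    stop("'min_repeats' must be named by motif length")
  lens <- suppressWarnings(as.integer(names(min_repeats)))
  if (anyNA(lens) || any(lens < 1L) || any(lens > 6L))
    stop("motif lengths in 'min_repeats' must be integers in 1..6")
  min_repeats <- as.integer(min_repeats)
  names(min_repeats) <- as.character(lens)
  if (any(min_repeats < 2L)) stop("minimum repeat counts must be >= 2")
  if (include_mono && !"1" %in% names(min_repeats))
    min_repeats <- c("1" = 10L, min_repeats)
  if (!include_mono) min_repeats <- min_repeats[names(min_repeats) != "1"]
  max_linker <- as.integer(max_linker)
  if (is.na(max_linker) || max_linker < 0L) stop("'max_linker' must be >= 0")
  structure(list(min_repeats = min_repeats[order(as.integer(names(min_repeats)))],
                 max_linker = max_linker,
                 include_mono = include_mono),
            class = "mining_config")
}

#' @export
print.mining_config <- function(x, ...) {
  cat("SSR mining configuration\n")
  cat("  min repeats:",
      paste(sprintf("%s-mer>=%d", names(x$min_repeats), x$min_repeats),
            collapse = ", "), "\n")
  cat("  max compound linker:", x$max_linker, "nt\n")
  invisible(x)
}

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

.check_sequence <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L) stop("'sequence' must be a single string")
  bad <- regmatches(sequence, regexpr(sprintf("[^%s]", IUPAC_CHARS), sequence))
  if (length(bad) > 0L)
    stop("invalid character in sequence (outside IUPAC set): '", bad, "'")
  sequence
}

# smallest period d (dividing k) such that the motif is d-periodic
.motif_period <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k)) {
    if (k %% d != 0L) next
    if (strrep(substr(motif, 1L, d), k %/% d) == motif) return(d)
  }
  k
}

.empty_ssr_table <- function() {
  structure(
    data.frame(seq_id = character(), start = integer(), end = integer(),
               motif = character(), motif_length = integer(),
               repeats = integer(), length = integer(),
               stringsAsFactors = FALSE),
    class = c("ssr_table", "data.frame"))
}

#' Detect perfect microsatellites in a nucleotide sequence
#'
#' Scans one sequence for maximal uninterrupted tandem repeats of 1-6 nt
#' motifs meeting the configured per-motif-length repeat thresholds.
#' Coordinates are 1-based inclusive. The reported motif is the first
#' occurring phase of the run (so `GA...` runs and `AG...` runs keep distinct
#' motifs). A run whose motif is itself a repetition of a shorter word (e.g.
#' `ATAT` as a tetramer) is reported at the shortest period only, and
#' overlapping candidate runs of different periods are resolved by keeping
#' the longer span (ties broken toward the shorter period). Ambiguity codes
#' terminate runs and never appear inside a reported SSR.
#'
#' @param sequence A single nucleotide string (IUPAC characters allowed).
#' @param config A [mining_config()].
#' @param seq_id Identifier recorded in the output table.
#'
#' @return A data frame of class `ssr_table` with columns `seq_id`, `start`,
#'   `end`, `motif`, `motif_length`, `repeats`, `length`, sorted by start.
#' @examples
#' find_perfect_ssrs(strrep("AT", 6))
#' @export
find_perfect_ssrs <- function(sequence, config = mining_config(),
                              seq_id = "seq1") {
  stopifnot(inherits(config, "mining_config"))
  sequence <- .check_sequence(sequence)
  if (nchar(sequence) == 0L) return(.empty_ssr_table())

  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  acgt <- chars %in% c("A", "C", "G", "T")
  cand <- list()
  for (k in as.integer(names(config$min_repeats))) {
    mreps <- config$min_repeats[[as.character(k)]]
    if (n < k * mreps) next
    # a position i continues a period-k tract iff base i equals base i+k;
    # maximal TRUE runs of length L give repeat tracts of L+k nt
    idx <- seq_len(n - k)
    eq <- (chars[idx] == chars[idx + k]) & acgt[idx] & acgt[idx + k]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    hits <- which(r$values & r$lengths >= k * (mreps - 1L))
    for (j in hits) {
      i0 <- run_start[j]
      reps <- (r$lengths[j] + k) %/% k
      motif <- substr(sequence, i0, i0 + k - 1L)
      if (.motif_period(motif) < k) next  # reported at the shorter period
      cand[[length(cand) + 1L]] <- data.frame(
        start = i0, motif = motif, motif_length = k, repeats = reps,
        length = reps * k, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) return(.empty_ssr_table())
  cand <- do.call(rbind, cand)
  cand$end <- cand$start + cand$length - 1L

  # overlap resolution across periods: longer span wins, ties -> shorter period
  ord <- order(-cand$length, cand$motif_length, cand$start)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  covered_start <- integer(0); covered_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(s <= covered_end & e >= covered_start)) {
      keep[i] <- TRUE
      covered_start <- c(covered_start, s)
      covered_end <- c(covered_end, e)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  out <- data.frame(seq_id = seq_id, start = cand$start, end = cand$end,
                    motif = cand$motif, motif_length = cand$motif_length,
                    repeats = cand$repeats, length = cand$length,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("ssr_table", "data.frame"))
}

#' Merge nearby perfect SSRs into compound SSRs
#'
#' Consecutive perfect SSRs on the same sequence separated by at most
#' `max_linker` nucleotides are chained (transitively) into compound SSRs;
#' isolated SSRs pass through unchanged.
#'
#' @param ssrs An `ssr_table` of perfect SSRs (sorted, non-overlapping per
#'   sequence); typically from [find_perfect_ssrs()].
#' @param config A [mining_config()]; only `max_linker` is used.
#' @param sequence Optional named character vector (or single string) of the
#'   source sequence(s); when supplied, linker sequences are recorded and a
#'   MISA-style compound notation with lowercase linkers is produced.
#'
#' @return A data frame of class `ssr_records` with columns `seq_id`,
#'   `start`, `end`, `type` ("perfect"/"compound"), `ssr` (notation string),
#'   `n_members`, `size`, and list columns `members` (data frames of member
#'   perfect SSRs) and `linkers` (integer gap lengths per junction).
#' @examples
#' s <- paste0(strrep("AT", 6), strrep("GA", 7))
#' merge_compound(find_perfect_ssrs(s), sequence = s)
#' @export
merge_compound <- function(ssrs, config = mining_config(), sequence = NULL) {
  stopifnot(inherits(config, "mining_config"))
  ssrs <- as.data.frame(ssrs)
  if (nrow(ssrs) == 0L) {
    out <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), type = character(), ssr = character(),
                      n_members = integer(), size = integer(),
                      stringsAsFactors = FALSE)
    out$members <- list(); out$linkers <- list()
    return(structure(out, class = c("ssr_records", "data.frame")))
  }
  if (!is.null(sequence) && is.null(names(sequence)) &&
      length(sequence) == 1L)
    names(sequence) <- unique(ssrs$seq_id)[1]

  res <- lapply(split(ssrs, ssrs$seq_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("input perfect SSRs overlap; merge_compound requires ",
           "non-overlapping records")
    gaps <- if (nrow(d) > 1L) d$start[-1] - d$end[-nrow(d)] - 1L else integer(0)
    grp <- cumsum(c(1L, as.integer(gaps > config$max_linker)))
    lapply(split(seq_len(nrow(d)), grp), function(idx) {
      mem <- d[idx, , drop = FALSE]
      lk <- if (length(idx) > 1L)
        mem$start[-1] - mem$end[-nrow(mem)] - 1L else integer(0)
      notation <- .ssr_notation(mem, lk, sequence)
      data.frame(seq_id = mem$seq_id[1], start = mem$start[1],
                 end = mem$end[nrow(mem)],
                 type = if (nrow(mem) > 1L) "compound" else "perfect",
                 ssr = notation, n_members = nrow(mem),
                 size = mem$end[nrow(mem)] - mem$start[1] + 1L,
                 members = I(list(mem)), linkers = I(list(lk)),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, unlist(res, recursive = FALSE))
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ssr_records", "data.frame"))
}

.ssr_notation <- function(members, linkers, sequence) {
  units <- sprintf("(%s)%d", members$motif, members$repeats)
  if (nrow(members) == 1L) return(units)
  if (!is.null(sequence) && members$seq_id[1] %in% names(sequence)) {
    s <- sequence[[members$seq_id[1]]]
    link_seq <- vapply(seq_along(linkers), function(j) {
      if (linkers[j] == 0L) return("")
      tolower(substr(s, members$end[j] + 1L, members$start[j + 1L] - 1L))
    }, character(1))
  } else {
    link_seq <- vapply(linkers, function(g)
      if (g == 0L) "" else sprintf("+%d+", g), character(1))
  }
  paste0(units[1], paste0(link_seq, units[-1], collapse = ""))
}

#' Reverse complement of nucleotide words
#'
#' @param x Character vector of unambiguous nucleotide words.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement(c("GA", "CCG"))
#' @export
reverse_complement <- function(x) {
  x <- toupper(x)
  if (any(grepl("[^ACGT]", x)))
    stop("reverse_complement: ambiguous or invalid base")
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Canonical motif class label
#'
#' Pairs each motif with its reverse complement into an equivalence-class
#' label `"X/Y"`, with `X` the lexicographically smaller member. The phase of
#' the motif is preserved: cyclic rotations map to different classes, so
#' `GA/TC` and `AG/CT` stay distinct, as in MISA motif tallies.
#'
#' @param motif Character vector of motifs (1-6 nt, unambiguous bases).
#' @return Character vector of class labels.
#' @examples
#' canonical_motif_class(c("GA", "CT", "AT"))
#' @export
canonical_motif_class <- function(motif) {
  motif <- toupper(motif)
  if (any(nchar(motif) < 1L | nchar(motif) > 6L))
    stop("motif length must be 1..6")
  rc <- reverse_complement(motif)
  ifelse(motif <= rc, paste0(motif, "/", rc), paste0(rc, "/", motif))
}

#' Summarize a microsatellite mining run
#'
#' Computes genome-wide composition tables: totals by category (standalone
#' perfect, compound, all records, and the motif tally counting every perfect
#' run including compound members), counts and proportions by motif length
#' and by canonical motif class, repeat-count histograms per motif length,
#' compound member-count and linker-length histograms, per-sequence counts,
#' and the overall SSR frequency per Mb.
#'
#' @param records An `ssr_records` table from [merge_compound()], or an
#'   `ssr_table` of perfect SSRs (then every record is standalone).
#' @param genome_length Total genome length in bp (> 0).
#' @return An object of class `mining_summary`.
#' @export
summarize_mining <- function(records, genome_length) {
  genome_length <- as.numeric(genome_length)
  if (is.na(genome_length) || genome_length <= 0)
    stop("'genome_length' must be > 0")
  if (is.null(records$members)) {
    standalone <- as.data.frame(records)
    compounds <- standalone[0, , drop = FALSE]
    n_perfect <- nrow(standalone); n_compound <- 0L
    all_members <- standalone
    member_counts <- integer(0); linker_lens <- integer(0)
  } else {
    records <- as.data.frame(records)
    standalone <- records[records$type == "perfect", , drop = FALSE]
    compounds <- records[records$type == "compound", , drop = FALSE]
    n_perfect <- nrow(standalone); n_compound <- nrow(compounds)
    all_members <- do.call(rbind, c(records$members,
                                    list(.empty_ssr_table())))
    member_counts <- compounds$n_members
    linker_lens <- unlist(compounds$linkers)
  }
  n_total <- n_perfect + n_compound
  n_motifs <- nrow(all_members)

  prop_tab <- function(x) {
    tb <- table(x)
    data.frame(key = names(tb), count = as.integer(tb),
               proportion = if (sum(tb) > 0) as.numeric(tb) / sum(tb)
                            else numeric(length(tb)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  by_len <- prop_tab(all_members$motif_length)
  by_class <- if (n_motifs > 0)
    prop_tab(canonical_motif_class(all_members$motif)) else prop_tab(character(0))
  rep_hist <- if (n_motifs > 0)
    lapply(split(all_members$repeats, all_members$motif_length), table)
  else list()
  per_seq <- if (n_total > 0) {
    rec_all <- rbind(
      data.frame(seq_id = standalone$seq_id, stringsAsFactors = FALSE),
      data.frame(seq_id = if (n_compound) compounds$seq_id else character(0),
                 stringsAsFactors = FALSE))
    prop_tab(rec_all$seq_id)
  } else prop_tab(character(0))

  structure(list(
    n_perfect = n_perfect, n_compound = n_compound, n_total = n_total,
    n_motifs = n_motifs,
    by_motif_length = by_len, by_class = by_class,
    repeat_histograms = rep_hist,
    member_count_histogram = table(member_counts),
    linker_length_histogram = table(linker_lens),
    per_sequence = per_seq,
    genome_length = genome_length,
    frequency_per_mb = n_total / (genome_length / 1e6)),
    class = "mining_summary")
}

#' @export
print.mining_summary <- function(x, ...) {
  cat("SSR mining summary\n")
  cat(sprintf("  records: %d (perfect %d, compound %d); motif tally %d\n",
              x$n_total, x$n_perfect, x$n_compound, x$n_motifs))
  cat(sprintf("  genome length: %.1f Mb; frequency: %.1f SSR/Mb\n",
              x$genome_length / 1e6, x$frequency_per_mb))
  if (nrow(x$by_motif_length)) {
    cat("  by motif length:\n")
    print(x$by_motif_length, row.names = FALSE)
  }
  invisible(x)
}

#' Mine a genome for perfect and compound SSRs
#'
#' Convenience wrapper running [find_perfect_ssrs()] on every sequence of a
#' genome, merging compounds with [merge_compound()], and summarizing with
#' [summarize_mining()].
#'
#' @param genome A named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param config A [mining_config()].
#' @return A list of class `ssr_mining` with elements `perfect`
#'   (`ssr_table`), `records` (`ssr_records`), `summary` (`mining_summary`)
#'   and `genome_length`.
#' @export
mine_ssrs <- function(genome, config = mining_config()) {
  seqs <- .as_named_sequences(genome)
  perfect <- do.call(rbind, lapply(names(seqs), function(id)
    find_perfect_ssrs(seqs[[id]], config, seq_id = id)))
  if (is.null(perfect)) perfect <- .empty_ssr_table()
  class(perfect) <- c("ssr_table", "data.frame")
  records <- merge_compound(perfect, config, sequence = seqs)
  glen <- sum(nchar(seqs))
  structure(list(perfect = perfect, records = records,
                 summary = summarize_mining(records, glen),
                 genome_length = glen),
            class = "ssr_mining")
}

#' @export
print.ssr_mining <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
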
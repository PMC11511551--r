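#' Primer design constraints
#'
#' The constraint set used to screen SSR primer candidates: primer length
#' 18-25 nt, melting temperature 57-62 degrees C, PCR product size
#' 120-400 bp and GC content 40-60 percent by default.
#'
#' @param length Length range in nt, `c(min, max)`.
#' @param tm Melting temperature range in degrees C.
#' @param product Product size range in bp.
#' @param gc GC-content range in percent.
#' @return An object of class `primer_constraints`.
#' @export
primer_constraints <- function(length = c(18, 25), tm = c(57, 62),
                               product = c(120, 400), gc = c(40, 60)) {
  for (r in list(length = length, tm = tm, product = product, gc = gc)) {
    if (length(r) != 2L || r[1] > r[2])
      stop("each constraint must be a non-empty range c(min, max)")
  }
  structure(list(length = length, tm = tm, product = product, gc = gc),
            class = "primer_constraints")
}

#' Extract SSR flanking sequences
#'
#' Returns, for each SSR, the upstream and downstream flanks of the
#' requested length, truncated (with a warning) at sequence ends. The
#' concatenation `left + ssr + right` always equals the corresponding
#' genomic span.
#'
#' @param ssrs Data frame with `seq_id`, `start`, `end` (1-based inclusive).
#' @param genome Named character vector / `DNAStringSet` / FASTA path.
#' @param flank_length Flank length in nt (default 200).
#' @return A data frame with `seq_id`, `start`, `end`, `left_flank`,
#'   `ssr_seq`, `right_flank`, `truncated`.
#' @export
extract_flanks <- function(ssrs, genome, flank_length = 200L) {
  seqs <- .as_named_sequences(genome)
  ssrs <- as.data.frame(ssrs)
  out <- lapply(seq_len(nrow(ssrs)), function(i) {
    id <- ssrs$seq_id[i]
    if (!id %in% names(seqs)) stop("SSR on unknown sequence: ", id)
    s <- seqs[[id]]; n <- nchar(s)
    if (ssrs$start[i] < 1L || ssrs$end[i] > n)
      stop("SSR span outside sequence bounds on ", id)
    ls <- max(1L, ssrs$start[i] - flank_length)
    re <- min(n, ssrs$end[i] + flank_length)
    data.frame(seq_id = id, start = ssrs$start[i], end = ssrs$end[i],
               left_flank = substr(s, ls, ssrs$start[i] - 1L),
               ssr_seq = substr(s, ssrs$start[i], ssrs$end[i]),
               right_flank = substr(s, ssrs$end[i] + 1L, re),
               truncated = (ls > ssrs$start[i] - flank_length) ||
                           (re < ssrs$end[i] + flank_length),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (any(out$truncated))
    warning(sum(out$truncated), " flank(s) truncated at sequence ends")
  out
}

# SantaLucia unified nearest-neighbor parameters
# (dH kcal/mol, dS cal/(mol K))
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Primer melting temperature
#'
#' Default method is nearest-neighbor thermodynamics (SantaLucia unified
#' parameter set; terminal initiation terms; entropy salt correction
#' `0.368 * (L-1) * ln([Na+])`), with
#' `Tm = dH * 1000 / (dS + R * ln(C/4)) - 273.15` where `C` is the total
#' primer concentration and `R = 1.987 cal/(mol K)`. The classic Wallace
#' rule `2(A+T) + 4(G+C)` is available as a fallback mode.
#'
#' @param primer Primer sequence, 5'->3', unambiguous bases.
#' @param method `"nn"` (nearest-neighbor, default) or `"wallace"`.
#' @param primer_conc Total primer concentration in mol/L (default 50 nM).
#' @param na_conc Monovalent cation concentration in mol/L (default 50 mM).
#' @return Melting temperature in degrees C.
#' @examples
#' compute_tm("ATATATATATGCGCGCGCGC", method = "wallace")  # 60
#' @export
compute_tm <- function(primer, method = c("nn", "wallace"),
                       primer_conc = 50e-9, na_conc = 50e-3) {
  method <- match.arg(method)
  primer <- toupper(primer)
  if (nchar(primer) == 0L) stop("empty primer")
  if (grepl("[^ACGT]", primer)) stop("ambiguous base in primer")
  b <- strsplit(primer, "")[[1]]
  if (method == "wallace")
    return(2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C")))
  if (length(b) < 2L) stop("nearest-neighbor Tm needs >= 2 bases")
  steps <- paste0(b[-length(b)], b[-1])
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  for (term in b[c(1, length(b))]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (length(b) - 1) * log(na_conc)
  dh * 1000 / (ds + 1.987 * log(primer_conc / 4)) - 273.15
}

.gc_percent <- function(primer) {
  b <- strsplit(toupper(primer), "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

#' A primer pair for one SSR locus
#'
#' @param forward,reverse Primer sequences, each written 5'->3' on its own
#'   strand.
#' @param product_size Expected amplicon length in bp (must contain the
#'   target SSR; not re-derivable from the sequences alone).
#' @param tm_method,primer_conc,na_conc Passed to [compute_tm()].
#' @return An object of class `primer_pair` with per-primer Tm and GC.
#' @export
primer_pair <- function(forward, reverse, product_size,
                        tm_method = "nn", primer_conc = 50e-9,
                        na_conc = 50e-3) {
  structure(list(
    forward = toupper(forward), reverse = toupper(reverse),
    product_size = as.numeric(product_size),
    tm = c(forward = compute_tm(forward, tm_method, primer_conc, na_conc),
           reverse = compute_tm(reverse, tm_method, primer_conc, na_conc)),
    gc = c(forward = .gc_percent(forward), reverse = .gc_percent(reverse))),
    class = "primer_pair")
}

#' Validate a primer pair against the constraint set
#'
#' Checks primer length, melting temperature and GC content for both
#' primers, plus the product size; the pair passes iff every rule holds.
#'
#' @param pair A [primer_pair()].
#' @param constraints A [primer_constraints()].
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   violated rules, e.g. `"forward length"`, `"product size"`).
#' @export
check_primer_pair <- function(pair, constraints = primer_constraints()) {
  stopifnot(inherits(pair, "primer_pair"),
            inherits(constraints, "primer_constraints"))
  inr <- function(x, r) x >= r[1] & x <= r[2]
  reasons <- character(0)
  for (side in c("forward", "reverse")) {
    p <- pair[[side]]
    if (!inr(nchar(p), constraints$length))
      reasons <- c(reasons, paste(side, "length"))
    if (!inr(pair$tm[[side]], constraints$tm))
      reasons <- c(reasons, paste(side, "Tm"))
    if (!inr(pair$gc[[side]], constraints$gc))
      reasons <- c(reasons, paste(side, "GC-content"))
  }
  if (!inr(pair$product_size, constraints$product))
    reasons <- c(reasons, "product size")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' M13 tail definition for TP-M13 genotyping
#'
#' The three-primer TP-M13 assay prepends a universal M13 sequence to the
#' locus-specific forward primer so that a dye-labelled universal M13
#' primer fluorescently labels the amplicons. The `"printed"` default is
#' the 19-letter tail sequence as published in common protocols; the
#' `"canonical"` variant is the classic 18-nt M13(-21) sequence.
#'
#' @param variant `"printed"` (TGTAAAAACGACGGCCAGT) or `"canonical"`
#'   (TGTAAAACGACGGCCAGT), or a custom sequence via `sequence`.
#' @param dye Dye label for the universal primer: ROX, HEX, TET or FAM.
#' @param sequence Optional custom tail sequence overriding `variant`.
#' @return An object of class `m13_tail`.
#' @export
m13_tail <- function(variant = c("printed", "canonical"), dye = "FAM",
                     sequence = NULL) {
  variant <- match.arg(variant)
  if (!dye %in% c("ROX", "HEX", "TET", "FAM")) stop("unknown dye: ", dye)
  seq <- if (!is.null(sequence)) toupper(sequence)
         else if (variant == "printed") "TGTAAAAACGACGGCCAGT"
         else "TGTAAAACGACGGCCAGT"
  structure(list(sequence = seq, dye = dye, variant = variant),
            class = "m13_tail")
}

#' Apply an M13 tail to a forward primer
#'
#' Prepends the tail exactly once; re-tailing an already tailed primer is an
#' error. The expected amplicon size for allele binning increases by the
#' tail length (see [tailed_product_size()]).
#'
#' @param forward_primer Forward primer sequence.
#' @param tail An [m13_tail()].
#' @return The tailed primer (character) with attribute `m13_tailed = TRUE`
#'   and `tail_length`.
#' @export
apply_m13_tail <- function(forward_primer, tail = m13_tail()) {
  stopifnot(inherits(tail, "m13_tail"))
  if (isTRUE(attr(forward_primer, "m13_tailed")))
    stop("primer already carries an M13 tail")
  out <- paste0(tail$sequence, toupper(forward_primer))
  attr(out, "m13_tailed") <- TRUE
  attr(out, "tail_length") <- nchar(tail$sequence)
  out
}

#' Expected raw fragment size of an M13-tailed amplicon
#'
#' @param product_size Untailed amplicon size in bp.
#' @param tail An [m13_tail()].
#' @return `product_size + nchar(tail)`.
#' @export
tailed_product_size <- function(product_size, tail = m13_tail()) {
  stopifnot(inherits(tail, "m13_tail"))
  product_size + nchar(tail$sequence)
}

#' Enumerate constraint-satisfying primer candidates around one SSR
#'
#' Scans every window of the allowed length range in the left flank (forward
#' primers) and in the reverse complement of the right flank (reverse
#' primers), keeps windows passing the per-primer rules, and pairs them
#' when the implied product size is in range. Full primer optimization
#' (penalty weighting, dimer and hairpin screening) is deliberately out of
#' scope and left to dedicated designers; this enumerates the valid search
#' space under the constraint set.
#'
#' @param left_flank,right_flank Flank sequences from [extract_flanks()].
#' @param ssr_length Length of the SSR tract between the flanks.
#' @param constraints A [primer_constraints()].
#' @param max_pairs Stop after this many passing pairs (default 100).
#' @param tm_method Passed to [compute_tm()].
#' @return A data frame of candidate pairs with positions, Tm, GC and
#'   product size; zero rows when no pair satisfies the constraints.
#' @export
enumerate_primer_candidates <- function(left_flank, right_flank, ssr_length,
                                        constraints = primer_constraints(),
                                        max_pairs = 100L,
                                        tm_method = "nn") {
  inr <- function(x, r) x >= r[1] & x <= r[2]
  scan_side <- function(seqchr) {
    n <- nchar(seqchr)
    res <- list()
    for (len in seq(constraints$length[1], constraints$length[2])) {
      if (n < len) next
      for (s in seq_len(n - len + 1L)) {
        p <- substr(seqchr, s, s + len - 1L)
        if (grepl("[^ACGT]", p)) next
        gc <- .gc_percent(p)
        if (!inr(gc, constraints$gc)) next
        tm <- compute_tm(p, tm_method)
        if (!inr(tm, constraints$tm)) next
        res[[length(res) + 1L]] <- data.frame(
          seq = p, start = s, end = s + len - 1L, tm = tm, gc = gc,
          stringsAsFactors = FALSE)
      }
    }
    if (length(res) == 0L) return(NULL)
    do.call(rbind, res)
  }
  fw <- scan_side(toupper(left_flank))
  rv_template <- reverse_complement(toupper(right_flank))
  rv <- scan_side(rv_template)
  out <- list()
  if (!is.null(fw) && !is.null(rv)) {
    nl <- nchar(left_flank); nr <- nchar(right_flank)
    for (i in seq_len(nrow(fw))) {
      for (j in seq_len(nrow(rv))) {
        # product: forward start .. reverse primer 3' end on the template
        prod <- (nl - fw$start[i] + 1L) + ssr_length + (nr - rv$start[j] + 1L)
        if (!inr(prod, constraints$product)) next
        out[[length(out) + 1L]] <- data.frame(
          forward = fw$seq[i], reverse = rv$seq[j],
          forward_tm = fw$tm[i], reverse_tm = rv$tm[j],
          forward_gc = fw$gc[i], reverse_gc = rv$gc[j],
          product_size = prod, stringsAsFactors = FALSE)
        if (length(out) >= max_pairs) break
      }
      if (length(out) >= max_pairs) break
    }
  }
  if (length(out) == 0L)
    return(data.frame(forward = character(), reverse = character(),
                      forward_tm = numeric(), reverse_tm = numeric(),
                      forward_gc = numeric(), reverse_gc = numeric(),
                      product_size = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
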
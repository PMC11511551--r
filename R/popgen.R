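#' Co-dominant genotype matrix
#'
#' Container for diploid, co-dominant SSR genotypes: an unordered pair of
#' allele identifiers (fragment sizes in bp) per sample and locus, with
#' missing calls marked `NA` in both allele slots.
#'
#' @param a1,a2 Numeric matrices (samples x loci, identical dimnames) holding
#'   the two allele calls. The pair is unordered; it is stored sorted so
#'   `A/B` and `B/A` are the same genotype.
#' @param motif_length Optional named integer vector of repeat-unit lengths
#'   per locus (used for allele binning and band labels).
#' @return An object of class `genotype_matrix` with elements `samples`,
#'   `loci` (data frame `name`, `motif_length`), `a1`, `a2`.
#' @export
genotype_matrix <- function(a1, a2, motif_length = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2)))
    stop("'a1' and 'a2' must have identical dimensions")
  if (is.null(colnames(a1))) stop("allele matrices need locus column names")
  if (is.null(rownames(a1))) rownames(a1) <- paste0("S", seq_len(nrow(a1)))
  if (xor(is.na(a1), is.na(a2)) |> any())
    stop("half-missing calls are not allowed: mark both alleles NA")
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  ml <- rep(NA_integer_, ncol(a1))
  names(ml) <- colnames(a1)
  if (!is.null(motif_length)) ml[names(motif_length)] <- motif_length
  structure(list(samples = rownames(a1),
                 loci = data.frame(name = colnames(a1), motif_length = ml,
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
                 a1 = lo, a2 = hi),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$a1))
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d missing calls)\n",
              length(x$samples), nrow(x$loci), n_missing))
  invisible(x)
}

#' Snap raw fragment sizes onto a repeat-unit allele ladder
#'
#' Capillary fragment sizes rarely land exactly on integers; true alleles at
#' one SSR differ by whole multiples of the repeat unit. Each raw size is
#' assigned to the nearest ladder rung `reference_size + k * motif_length`;
#' a size exactly half a repeat unit from two rungs is flagged ambiguous
#' rather than silently assigned.
#'
#' @param raw_sizes Numeric vector of observed fragment sizes (bp, > 0).
#' @param motif_length Repeat unit length in nt (>= 1).
#' @param reference_size Anchor rung of the ladder, in bp.
#' @return A data frame with columns `raw`, `allele` (the binned size;
#'   `NA` when ambiguous) and `ambiguous`; attribute `bins` maps each ladder
#'   allele to its member raw sizes.
#' @examples
#' bin_alleles(c(200.1, 202.0, 203.9), motif_length = 2, reference_size = 200)
#' @export
bin_alleles <- function(raw_sizes, motif_length, reference_size) {
  if (motif_length < 1) stop("'motif_length' must be >= 1")
  if (any(raw_sizes <= 0)) stop("raw sizes must be positive")
  k <- (raw_sizes - reference_size) / motif_length
  ambiguous <- abs(k - floor(k) - 0.5) < 1e-9
  allele <- reference_size + round(k) * motif_length
  allele[ambiguous] <- NA_real_
  out <- data.frame(raw = raw_sizes, allele = allele, ambiguous = ambiguous)
  attr(out, "bins") <- split(raw_sizes[!ambiguous], allele[!ambiguous])
  out
}

#' Allele counts and frequencies at one locus
#'
#' Diploid counting over non-missing calls: every genotype contributes two
#' gene copies (a homozygote contributes two copies of one allele). The
#' number of heterozygous individuals is recorded for observed
#' heterozygosity.
#'
#' @param g A [genotype_matrix()].
#' @param locus Locus name.
#' @return An object of class `allele_freqs`: list with `locus`, `counts`
#'   (named integer, names = allele sizes), `freqs`, `n` (non-missing
#'   individuals), `n_het`.
#' @export
allele_frequencies <- function(g, locus) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!locus %in% g$loci$name) stop("unknown locus: ", locus)
  a1 <- g$a1[, locus]; a2 <- g$a2[, locus]
  ok <- !is.na(a1)
  if (!any(ok)) stop("all calls missing at locus ", locus)
  copies <- c(a1[ok], a2[ok])
  counts <- table(copies)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(locus = locus, counts = counts,
                 freqs = counts / sum(counts),
                 n = sum(ok), n_het = sum(a1[ok] != a2[ok])),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat(sprintf("locus %s: n = %d individuals, %d alleles\n",
              x$locus, x$n, length(x$counts)))
  print(round(x$freqs, 4))
  invisible(x)
}

#' Per-locus diversity statistics
#'
#' Computes the standard co-dominant marker panel statistics from allele
#' frequencies `p` over `2n` gene copies (`n` non-missing diploid
#' individuals):
#' \itemize{
#' \item `Na`, observed number of alleles;
#' \item `Ne = 1 / sum(p^2)`, effective number of alleles;
#' \item `I = -sum(p * log(p))`, Shannon's information index (natural log);
#' \item `Ho`, observed heterozygosity = fraction of non-missing individuals
#'   that are heterozygous;
#' \item `He = (2n / (2n - 1)) * (1 - sum(p^2))`, Nei's unbiased expected
#'   heterozygosity;
#' \item `PIC = 1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2`, Botstein's
#'   polymorphic information content.
#' }
#' `Ho_compat = 1 - He` is also reported: some legacy population-genetics
#' programs print average homozygosity complement under the "Ho" heading,
#' and this column reproduces that convention.
#'
#' @param freqs An [allele_frequencies()] result.
#' @return A one-row data frame of class `locus_stats` with columns `locus`,
#'   `n`, `Na`, `Ne`, `I`, `Ho`, `Ho_compat`, `He`, `PIC` (full precision;
#'   round at report time).
#' @examples
#' g <- generate_panel(panel_spec(
#'   loci = list(list(name = "L1", motif_length = 2, ref_size = 200,
#'               counts = c(14, 10))),
#'   populations = c(all = 12), mode = "counts", seed = 1))
#' locus_stats(allele_frequencies(g, "L1"))
#' @export
locus_stats <- function(freqs) {
  stopifnot(inherits(freqs, "allele_freqs"))
  p <- as.numeric(freqs$freqs)
  n <- freqs$n
  if (n <= 1L) stop("unbiased He undefined for n <= 1")
  sp2 <- sum(p^2)
  na <- length(p)
  ne <- 1 / sp2
  i_idx <- -sum(ifelse(p > 0, p * log(p), 0))
  he <- (2 * n / (2 * n - 1)) * (1 - sp2)
  p2 <- p^2
  pic <- 1 - sp2 - (sum(outer(p2, p2))[1] - sum(p2^2)) # 2*sum_{i<j} pi^2 pj^2
  ho <- freqs$n_het / n
  out <- data.frame(locus = freqs$locus, n = n, Na = na, Ne = ne, I = i_idx,
                    Ho = ho, Ho_compat = 1 - he, He = he, PIC = pic,
                    stringsAsFactors = FALSE)
  class(out) <- c("locus_stats", "data.frame")
  out
}

#' @export
print.locus_stats <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Diversity statistics for every locus of a panel
#'
#' @param g A [genotype_matrix()].
#' @return A `locus_stats` data frame, one row per locus.
#' @export
panel_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  out <- do.call(rbind, lapply(g$loci$name, function(l)
    locus_stats(allele_frequencies(g, l))))
  class(out) <- c("locus_stats", "data.frame")
  out
}

#' Summarize a panel of per-locus statistics
#'
#' Mean, standard deviation, minimum and maximum per statistic, the total
#' allele count, and the number of loci in the conventional PIC
#' informativeness classes (low `< 0.25`, intermediate `0.25--0.5`, high
#' `> 0.5`; strict inequalities).
#'
#' @param stats A `locus_stats` data frame (from [panel_stats()]), or any
#'   data frame with columns `Na`, `Ne`, `I`, `Ho`, `He`, `PIC`.
#' @return An object of class `panel_summary`.
#' @export
summarize_panel <- function(stats) {
  stats <- as.data.frame(stats)
  if (nrow(stats) < 1L) stop("need at least one locus")
  cols <- intersect(c("Na", "Ne", "I", "Ho", "Ho_compat", "He", "PIC"),
                    colnames(stats))
  tab <- t(vapply(stats[cols], function(v)
    c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v)),
    numeric(4)))
  if (nrow(stats) == 1L) tab[, "sd"] <- 0
  structure(list(
    n_loci = nrow(stats),
    statistics = as.data.frame(tab),
    total_alleles = sum(stats$Na),
    pic_classes = c(low = sum(stats$PIC < 0.25),
                    intermediate = sum(stats$PIC >= 0.25 & stats$PIC <= 0.5),
                    high = sum(stats$PIC > 0.5))),
    class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, digits = 4, ...) {
  cat(sprintf("panel of %d loci, %d alleles in total\n",
              x$n_loci, x$total_alleles))
  print(round(x$statistics, digits))
  cat(sprintf("PIC classes: %d low (<0.25), %d intermediate, %d high (>0.5)\n",
              x$pic_classes["low"], x$pic_classes["intermediate"],
              x$pic_classes["high"]))
  invisible(x)
}

#' Within-population gene diversity (Hs)
#'
#' Computes, for each population with at least two individuals, per-locus
#' gene diversity from that population's allele frequencies, and averages
#' over loci and populations to give Hs. The uncorrected estimator
#' `1 - sum(p^2)` is the default; `corrected = TRUE` applies the
#' small-sample factor `2n/(2n - 1)` per population and locus.
#'
#' @param g A [genotype_matrix()].
#' @param populations Named character/factor vector assigning each sample to
#'   a population (names = sample ids), or an unnamed vector in sample
#'   order.
#' @param corrected Use the unbiased per-population estimator.
#' @return An object of class `within_pop_diversity`: `Hs`, `per_population`
#'   (data frame of mean Na/Ne/I/He per population), `per_locus` matrix of
#'   within-population gene diversities.
#' @export
within_population_diversity <- function(g, populations, corrected = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(names(populations))) {
    if (length(populations) != length(g$samples))
      stop("'populations' must cover every sample")
    names(populations) <- g$samples
  }
  pops <- as.character(populations[g$samples])
  sizes <- table(pops)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding populations of size 1: ",
            paste(small, collapse = ", "))
    keep_pops <- setdiff(names(sizes), small)
  } else keep_pops <- names(sizes)
  if (length(keep_pops) == 0) stop("no population with >= 2 individuals")

  per_locus <- matrix(NA_real_, length(keep_pops), nrow(g$loci),
                      dimnames = list(keep_pops, g$loci$name))
  per_pop <- list()
  for (pp in keep_pops) {
    idx <- which(pops == pp)
    sub <- genotype_matrix(g$a1[idx, , drop = FALSE],
                           g$a2[idx, , drop = FALSE])
    st <- panel_stats(sub)
    gd <- vapply(g$loci$name, function(l) {
      f <- allele_frequencies(sub, l)
      d <- 1 - sum(as.numeric(f$freqs)^2)
      if (corrected) d <- d * (2 * f$n) / (2 * f$n - 1)
      d
    }, numeric(1))
    per_locus[pp, ] <- gd
    per_pop[[pp]] <- data.frame(population = pp, n = length(idx),
                                Na = mean(st$Na), Ne = mean(st$Ne),
                                I = mean(st$I), He = mean(st$He),
                                stringsAsFactors = FALSE)
  }
  structure(list(Hs = mean(per_locus),
                 per_population = do.call(rbind, per_pop),
                 per_locus = per_locus,
                 corrected = corrected),
            class = "within_pop_diversity")
}

#' @export
print.within_pop_diversity <- function(x, digits = 4, ...) {
  cat(sprintf("within-population gene diversity Hs = %.4f (%s estimator)\n",
              x$Hs, if (x$corrected) "bias-corrected" else "uncorrected"))
  y <- x$per_population
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
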
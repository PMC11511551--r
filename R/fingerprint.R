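#' DNA fingerprint profile of a sample panel
#'
#' Per sample and marker, the set of present fragment sizes — a view of the
#' presence/absence band matrix organized by marker, used for core-marker
#' search and fingerprint reporting.
#'
#' @param x A [genotype_matrix()] or a `band_matrix` from
#'   [bands_from_genotypes()].
#' @return An object of class `fingerprint_profile`: list with `bands`
#'   (0/1/NA matrix), `markers` (locus of each band column), `samples`, and
#'   `genotypes` (retained when built from a genotype matrix, for the
#'   strict-genotype discrimination mode).
#' @export
fingerprint_profile <- function(x) {
  if (inherits(x, "genotype_matrix")) {
    bands <- bands_from_genotypes(x)
    g <- x
  } else if (inherits(x, "band_matrix")) {
    bands <- x
    g <- NULL
  } else stop("need a genotype_matrix or band_matrix")
  structure(list(bands = unclass(bands), markers = attr(bands, "locus"),
                 samples = rownames(bands), genotypes = g),
            class = "fingerprint_profile")
}

#' @export
print.fingerprint_profile <- function(x, ...) {
  cat(sprintf("fingerprint profile: %d samples, %d markers, %d bands\n",
              length(x$samples), length(unique(x$markers)),
              ncol(x$bands)))
  invisible(x)
}

# per-marker pattern strings; NA for a sample whose calls at the marker are
# missing (indeterminate pattern)
.marker_patterns <- function(fp, markers) {
  vapply(markers, function(m) {
    cols <- which(fp$markers == m)
    if (length(cols) == 0L) stop("unknown marker: ", m)
    apply(fp$bands[, cols, drop = FALSE], 1, function(v)
      if (anyNA(v)) NA_character_ else paste(v, collapse = ""))
  }, character(length(fp$samples)))
}

# logical matrix: sample pairs x markers, TRUE iff the marker separates the
# pair (both patterns observed and different); missing pattern on either
# side is conservatively non-separating
.pair_separation <- function(fp, mode = c("bands", "genotype")) {
  mode <- match.arg(mode)
  markers <- unique(fp$markers)
  ns <- length(fp$samples)
  if (mode == "bands") {
    pat <- .marker_patterns(fp, markers)
  } else {
    if (is.null(fp$genotypes))
      stop("genotype mode requires a profile built from a genotype_matrix")
    g <- fp$genotypes
    pat <- vapply(markers, function(m)
      ifelse(is.na(g$a1[, m]), NA_character_,
             paste(g$a1[, m], g$a2[, m], sep = "/")),
      character(ns))
  }
  pairs <- utils::combn(ns, 2)
  sep <- matrix(FALSE, ncol(pairs), length(markers),
                dimnames = list(paste(fp$samples[pairs[1, ]],
                                      fp$samples[pairs[2, ]], sep = "|"),
                                markers))
  for (k in seq_len(ncol(pairs))) {
    a <- pat[pairs[1, k], ]; b <- pat[pairs[2, k], ]
    sep[k, ] <- !is.na(a) & !is.na(b) & a != b
  }
  sep
}

#' Does a marker subset distinguish every sample pair?
#'
#' TRUE iff, restricted to the given markers, all pairwise sample band
#' patterns are distinct. A missing call makes the affected pair
#' comparison indeterminate at that marker, which conservatively counts as
#' non-separating.
#'
#' @param markers Non-empty character vector of marker (locus) names.
#' @param fingerprint A [fingerprint_profile()].
#' @param mode `"bands"` compares presence/absence band patterns (the
#'   fingerprint-gel view); `"genotype"` compares diploid allele pairs.
#' @return Logical scalar.
#' @export
distinguishes <- function(markers, fingerprint, mode = "bands") {
  stopifnot(inherits(fingerprint, "fingerprint_profile"))
  if (length(markers) == 0L) stop("'markers' must be non-empty")
  if (!all(markers %in% fingerprint$markers))
    stop("unknown marker(s): ",
         paste(setdiff(markers, fingerprint$markers), collapse = ", "))
  sep <- .pair_separation(fingerprint, mode)
  all(rowSums(sep[, markers, drop = FALSE]) > 0L)
}

#' Find all minimal core-marker sets
#'
#' Enumerates marker subsets in increasing size, keeping those whose
#' combined band patterns give every sample a unique fingerprint and that
#' contain no smaller discriminating subset (minimality). Enumeration is
#' pruned through the pair-separation matrix: a subset is only retained if
#' it covers every sample pair, and supersets of reported sets are skipped.
#'
#' @param fingerprint A [fingerprint_profile()].
#' @param max_size Largest subset size to consider (>= 1).
#' @param mode See [distinguishes()].
#' @return An object of class `core_sets`: list with `sets` (list of
#'   character vectors, sorted by size then labels), and when no set exists
#'   within `max_size`, `unresolved_pairs` naming the sample pairs no
#'   marker separates (or that remain unseparated at `max_size`).
#' @export
find_core_sets <- function(fingerprint, max_size = 3L, mode = "bands") {
  stopifnot(inherits(fingerprint, "fingerprint_profile"))
  if (max_size < 1L) stop("'max_size' must be >= 1")
  sep <- .pair_separation(fingerprint, mode)
  markers <- colnames(sep)
  found <- list()
  for (size in seq_len(min(max_size, length(markers)))) {
    for (idx in utils::combn(length(markers), size, simplify = FALSE)) {
      set <- markers[idx]
      # skip supersets of an already-found (hence smaller, minimal) set
      if (length(found) > 0 &&
          any(vapply(found, function(f) all(f %in% set), logical(1))))
        next
      if (all(rowSums(sep[, set, drop = FALSE]) > 0L))
        found[[length(found) + 1L]] <- set
    }
  }
  ord <- order(lengths(found),
               vapply(found, function(s) paste(s, collapse = "\r"),
                      character(1)))
  found <- found[ord]
  unresolved <- character(0)
  if (length(found) == 0L)
    unresolved <- rownames(sep)[rowSums(sep) == 0L]
  structure(list(sets = found, max_size = max_size,
                 unresolved_pairs = unresolved),
            class = "core_sets")
}

#' @export
print.core_sets <- function(x, ...) {
  if (length(x$sets) == 0L) {
    cat("no discriminating marker set up to size", x$max_size, "\n")
    if (length(x$unresolved_pairs))
      cat("sample pairs no marker separates:",
          paste(x$unresolved_pairs, collapse = "; "), "\n")
  } else {
    cat(length(x$sets), "minimal core-marker set(s):\n")
    for (s in x$sets) cat("  {", paste(s, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Fingerprint report: band counts and pattern strings
#'
#' @param fingerprint A [fingerprint_profile()].
#' @return A list of class `fingerprint_report` with `band_counts` (distinct
#'   fragment sizes observed per marker) and `patterns` (per-sample
#'   delimited band pattern strings, stable across runs).
#' @export
fingerprint_report <- function(fingerprint) {
  stopifnot(inherits(fingerprint, "fingerprint_profile"))
  bc <- vapply(split(seq_along(fingerprint$markers), fingerprint$markers),
               function(cols) sum(colSums(
                 fingerprint$bands[, cols, drop = FALSE] == 1L,
                 na.rm = TRUE) > 0L),
               integer(1))
  pats <- apply(fingerprint$bands, 1, function(v)
    paste(ifelse(is.na(v), "?", v), collapse = ""))
  structure(list(band_counts = bc[order(-bc, names(bc))],
                 patterns = pats,
                 band_names = colnames(fingerprint$bands)),
            class = "fingerprint_report")
}

#' @export
print.fingerprint_report <- function(x, ...) {
  cat("bands per marker (descending):\n")
  print(x$band_counts)
  invisible(x)
}

#' Write fingerprint table and core-set listing
#'
#' @param fingerprint A [fingerprint_profile()].
#' @param core A [find_core_sets()] result (optional).
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_fingerprint <- function(fingerprint, core = NULL, dir = ".") {
  fp_path <- file.path(dir, "fingerprint.tsv")
  d <- data.frame(sample = fingerprint$samples,
                  fingerprint$bands, check.names = FALSE)
  .write_tsv(d, fp_path)
  paths <- fp_path
  if (!is.null(core)) {
    cs_path <- file.path(dir, "core_sets.tsv")
    if (length(core$sets) > 0) {
      .write_tsv(data.frame(
        set = seq_along(core$sets),
        size = lengths(core$sets),
        markers = vapply(core$sets, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE), cs_path)
    } else {
      .write_tsv(data.frame(unresolved_pair = core$unresolved_pairs,
                            stringsAsFactors = FALSE), cs_path)
    }
    paths <- c(paths, cs_path)
  }
  invisible(paths)
}
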
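#' @importFrom GenomicRanges GRanges reduce setdiff findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

REGION_CATEGORIES <- c("five_prime_UTR", "three_prime_UTR", "exon",
                       "intron", "intergenic", "multi_mapped")

#' Build a genomic region index from GFF3 annotation
#'
#' Derives the five annotated interval sets used for six-way SSR region
#' assignment: 5'UTR, 3'UTR, exon, intron and gene spans (everything outside
#' gene spans is intergenic). Introns are derived per transcript as the gaps
#' between its exons; because a UTR is also an exon in GFF3, UTR intervals
#' take precedence and are subtracted from the exon category. Categories are
#' unioned across transcripts. Strand is ignored: region identity is
#' strand-independent in this scheme.
#'
#' @param annotation Path to a GFF3 file, or GFF3 content as a single string
#'   / character vector of lines.
#' @param seq_lengths Optional named integer vector of sequence lengths;
#'   taken from `##sequence-region` pragmas when absent.
#' @return An object of class `region_index`: list of `GRanges` components
#'   `five_prime_UTR`, `three_prime_UTR`, `exon`, `intron`, `gene`, plus
#'   `seq_lengths` and `gene_ids`.
#' @export
build_region_index <- function(annotation, seq_lengths = NULL) {
  path <- annotation
  if (length(annotation) > 1L || grepl("\n", annotation[1]) ||
      !file.exists(annotation[1])) {
    path <- tempfile(fileext = ".gff3")
    writeLines(unlist(strsplit(annotation, "\n")), path)
    on.exit(unlink(path))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3: ",
                                          conditionMessage(e)))
  if (is.null(seq_lengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    seq_lengths <- sl[!is.na(sl)]
    # sequence-region pragmas are authoritative even without features
    pr <- grep("^##sequence-region", readLines(path), value = TRUE)
    if (length(pr) > 0) {
      f <- strsplit(trimws(pr), "\\s+")
      pl <- stats::setNames(vapply(f, function(x) as.integer(x[4]),
                                   integer(1)),
                            vapply(f, `[`, character(1), 2))
      seq_lengths <- c(seq_lengths,
                       pl[setdiff(names(pl), names(seq_lengths))])
    }
    if (length(seq_lengths) == 0) seq_lengths <- NULL
  }

  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  tx <- gr[typ %in% c("mRNA", "transcript")]
  exons <- gr[typ == "exon"]
  utr5 <- gr[typ == "five_prime_UTR"]
  utr3 <- gr[typ == "three_prime_UTR"]

  # exon escaping its gene span -> warn and clip (annotation hygiene)
  if (length(exons) > 0 && length(genes) > 0) {
    gspan <- GenomicRanges::reduce(GenomicRanges::granges(genes),
                                   ignore.strand = TRUE)
    contained <- IRanges::overlapsAny(exons, gspan, type = "within",
                                      ignore.strand = TRUE)
    if (any(!contained)) {
      warning(sum(!contained),
              " exon interval(s) extend outside gene spans; clipped")
      ov <- GenomicRanges::findOverlaps(exons, gspan, ignore.strand = TRUE)
      exons <- GenomicRanges::pintersect(
        exons[S4Vectors::queryHits(ov)],
        gspan[S4Vectors::subjectHits(ov)], ignore.strand = TRUE)
    }
  }

  # introns: per transcript, gaps between that transcript's exons
  introns <- GenomicRanges::GRanges()
  if (length(tx) > 0 && length(exons) > 0) {
    parent <- vapply(exons$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    tx_ids <- as.character(tx$ID)
    by_tx <- split(seq_along(exons), parent)
    intr <- lapply(names(by_tx), function(txid) {
      ex <- GenomicRanges::reduce(exons[by_tx[[txid]]], ignore.strand = TRUE)
      if (length(ex) < 2L) return(NULL)
      GenomicRanges::setdiff(range(ex), ex, ignore.strand = TRUE)
    })
    intr <- intr[!vapply(intr, is.null, logical(1))]
    if (length(intr) > 0)
      introns <- GenomicRanges::reduce(do.call(c, intr), ignore.strand = TRUE)
  } else if (length(genes) > 0 && length(exons) > 0) {
    # no transcript features: derive introns within each gene span
    introns <- GenomicRanges::setdiff(
      GenomicRanges::reduce(genes, ignore.strand = TRUE),
      GenomicRanges::reduce(exons, ignore.strand = TRUE),
      ignore.strand = TRUE)
  }

  utr <- GenomicRanges::reduce(c(GenomicRanges::granges(utr5),
                                 GenomicRanges::granges(utr3)),
                               ignore.strand = TRUE)
  exon_cat <- GenomicRanges::setdiff(
    GenomicRanges::reduce(GenomicRanges::granges(exons),
                          ignore.strand = TRUE),
    utr, ignore.strand = TRUE)

  gene_spans <- if (length(genes) > 0)
    GenomicRanges::reduce(GenomicRanges::granges(genes), ignore.strand = TRUE)
  else GenomicRanges::GRanges()

  structure(list(
    five_prime_UTR = GenomicRanges::reduce(GenomicRanges::granges(utr5),
                                           ignore.strand = TRUE),
    three_prime_UTR = GenomicRanges::reduce(GenomicRanges::granges(utr3),
                                            ignore.strand = TRUE),
    exon = exon_cat,
    intron = introns,
    gene = gene_spans,
    gene_features = genes,
    seq_lengths = seq_lengths,
    seq_ids = unique(c(names(seq_lengths),
                       as.character(GenomicRanges::seqnames(gr))))),
    class = "region_index")
}

#' @export
print.region_index <- function(x, ...) {
  cat("region index over", length(x$seq_ids), "sequence(s)\n")
  for (cat_name in c("five_prime_UTR", "three_prime_UTR", "exon", "intron",
                     "gene"))
    cat(sprintf("  %-16s %d interval(s), %d bp\n", cat_name,
                length(x[[cat_name]]),
                sum(GenomicRanges::width(x[[cat_name]]))))
  invisible(x)
}

#' Assign SSRs to genomic region categories
#'
#' Each SSR span receives exactly one of six categories: `five_prime_UTR`,
#' `three_prime_UTR`, `exon`, `intron`, `intergenic`, or `multi_mapped` when
#' the span overlaps two or more distinct categories (any overlap of at
#' least 1 bp counts; an SSR need not be contained). Spans on sequences
#' unknown to the index are reported as `unplaced` and counted separately.
#'
#' @param ssrs An `ssr_table`/`ssr_records` data frame (columns `seq_id`,
#'   `start`, `end`) or a `GRanges`.
#' @param index A [build_region_index()] result.
#' @return A data frame with the input coordinates plus `category` and
#'   `overlapped_genes` (comma-separated gene IDs).
#' @export
assign_region <- function(ssrs, index) {
  stopifnot(inherits(index, "region_index"))
  if (methods::is(ssrs, "GRanges")) {
    ssrs <- data.frame(seq_id = as.character(GenomicRanges::seqnames(ssrs)),
                       start = GenomicRanges::start(ssrs),
                       end = GenomicRanges::end(ssrs),
                       stringsAsFactors = FALSE)
  }
  ssrs <- as.data.frame(ssrs)
  n <- nrow(ssrs)
  category <- character(n)
  genes_hit <- character(n)
  if (n == 0L)
    return(cbind(ssrs, category = character(0),
                 overlapped_genes = character(0)))

  unplaced <- !(ssrs$seq_id %in% index$seq_ids)
  q <- GenomicRanges::GRanges(ssrs$seq_id,
                              IRanges::IRanges(ssrs$start, ssrs$end))
  cats <- c("five_prime_UTR", "three_prime_UTR", "exon", "intron")
  hit_mat <- vapply(cats, function(cc)
    suppressWarnings(IRanges::overlapsAny(q, index[[cc]])), logical(n))
  hit_mat <- matrix(hit_mat, nrow = n,
                    dimnames = list(NULL, cats))
  # intergenic: any part of the span outside reduced gene spans
  if (length(index$gene) > 0) {
    ov <- suppressWarnings(GenomicRanges::findOverlaps(q, index$gene))
    covered <- rep(0L, n)
    if (length(ov) > 0) {
      pi_ <- GenomicRanges::pintersect(q[S4Vectors::queryHits(ov)],
                                       index$gene[S4Vectors::subjectHits(ov)])
      covered <- as.integer(tapply(GenomicRanges::width(pi_),
        factor(S4Vectors::queryHits(ov), levels = seq_len(n)), sum,
        default = 0L))
    }
    intergenic <- covered < GenomicRanges::width(q)
  } else intergenic <- rep(TRUE, n)
  hit_mat <- cbind(hit_mat, intergenic = intergenic)

  n_cats <- rowSums(hit_mat)
  category[unplaced] <- "unplaced"
  category[!unplaced & n_cats >= 2] <- "multi_mapped"
  single <- !unplaced & n_cats == 1
  category[single] <- colnames(hit_mat)[apply(
    hit_mat[single, , drop = FALSE], 1, which)]
  # span fully inside a gene lacking exon annotation: non-exonic gene
  # interior, report as intron
  category[!unplaced & n_cats == 0] <- "intron"

  if (length(index$gene_features) > 0) {
    ovg <- suppressWarnings(
      GenomicRanges::findOverlaps(q, index$gene_features))
    ids <- as.character(index$gene_features$ID)
    genes_hit <- vapply(seq_len(n), function(i) {
      j <- S4Vectors::subjectHits(ovg)[S4Vectors::queryHits(ovg) == i]
      paste(unique(ids[j]), collapse = ",")
    }, character(1))
  }
  out <- cbind(as.data.frame(ssrs), category = category,
               overlapped_genes = genes_hit, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tabulate SSR region assignments
#'
#' @param assignments Output of [assign_region()].
#' @param per_sequence Also tabulate per `seq_id`.
#' @return A data frame of counts and proportions per category (proportions
#'   over placed SSRs; `unplaced` listed separately).
#' @export
region_distribution <- function(assignments, per_sequence = FALSE) {
  lev <- c(REGION_CATEGORIES, "unplaced")
  tab_one <- function(d) {
    tb <- table(factor(d$category, levels = lev))
    placed <- sum(tb[REGION_CATEGORIES])
    data.frame(category = lev, count = as.integer(tb),
               proportion = ifelse(lev == "unplaced", NA,
                 if (placed > 0) as.integer(tb) / placed else 0),
               stringsAsFactors = FALSE)
  }
  if (!per_sequence) return(tab_one(assignments))
  do.call(rbind, lapply(split(assignments, assignments$seq_id), function(d)
    cbind(seq_id = d$seq_id[1], tab_one(d))))
}
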
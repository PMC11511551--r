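#' @importFrom Biostrings readDNAStringSet DNAStringSet writeXStringSet
NULL

# Normalize genome input (path / DNAStringSet / named character) to a named
# character vector of uppercase sequences.
.as_named_sequences <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    # FASTA headers: keep the first token as the sequence id
    names(out) <- sub("\\s.*$", "", names(out))
    return(toupper(out))
  }
  if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- paste0("seq", seq_along(genome))
    return(toupper(genome))
  }
  stop("cannot interpret 'genome' as sequences")
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) .as_named_sequences(path)

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a MISA-compatible SSR table
#'
#' Writes the classic tab-delimited columns `ID`, `SSR nr.`, `SSR type`,
#' `SSR`, `size`, `start`, `end`. Perfect records get type `p<k>` (k = motif
#' length); compound records get type `c`.
#'
#' @param records An `ssr_records` table from [merge_compound()] or
#'   [mine_ssrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_misa_table <- function(records, path) {
  records <- as.data.frame(records)
  type <- ifelse(records$type == "compound", "c",
                 paste0("p", vapply(records$members,
                                    function(m) m$motif_length[1], numeric(1))))
  nr <- stats::ave(seq_len(nrow(records)), records$seq_id, FUN = seq_along)
  d <- data.frame(ID = records$seq_id, `SSR nr.` = nr, `SSR type` = type,
                  SSR = records$ssr, size = records$size,
                  start = records$start, end = records$end,
                  check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(d, path)
}

#' Write the native SSR record table
#'
#' A richer flat table than the MISA format: one row per member perfect SSR,
#' with the compound record id, member index and linker to the previous
#' member, so compound membership round-trips through plain text.
#'
#' @inheritParams write_misa_table
#' @export
write_ssr_table <- function(records, path) {
  records <- as.data.frame(records)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    mem <- records$members[[i]]
    lk <- records$linkers[[i]]
    data.frame(record_id = i, seq_id = records$seq_id[i],
               type = records$type[i], member = seq_len(nrow(mem)),
               motif = mem$motif, repeats = mem$repeats,
               start = mem$start, end = mem$end,
               linker_before = c(NA_integer_, lk),
               stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}

#' Read a co-dominant genotype table
#'
#' The dialect is a tab-separated file with a header
#' `sample<TAB>locus1.A1<TAB>locus1.A2<TAB>...`; allele calls are fragment
#' sizes in bp and missing calls are `NA` (both alleles).
#'
#' @param path Path to the genotype table.
#' @param motif_length Optional named integer vector of motif lengths per
#'   locus.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, motif_length = NULL) {
  d <- .read_tsv(path)
  if (colnames(d)[1] != "sample") stop("first column must be 'sample'")
  cn <- colnames(d)[-1]
  loci <- unique(sub("\\.A[12]$", "", cn))
  need <- as.vector(rbind(paste0(loci, ".A1"), paste0(loci, ".A2")))
  if (!identical(cn, need))
    stop("genotype columns must come in <locus>.A1/<locus>.A2 pairs")
  a1 <- as.matrix(d[paste0(loci, ".A1")]); colnames(a1) <- loci
  a2 <- as.matrix(d[paste0(loci, ".A2")]); colnames(a2) <- loci
  rownames(a1) <- rownames(a2) <- d$sample
  genotype_matrix(a1, a2, motif_length = motif_length)
}

#' Write a co-dominant genotype table
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotypes <- function(g, path) {
  loci <- g$loci$name
  out <- data.frame(sample = g$samples, stringsAsFactors = FALSE)
  for (l in loci) {
    out[[paste0(l, ".A1")]] <- g$a1[, l]
    out[[paste0(l, ".A2")]] <- g$a2[, l]
  }
  .write_tsv(out, path)
}
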
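#' Pipeline run configuration
#'
#' Collects every stage parameter of the genome-to-fingerprint workflow in
#' one validated object; all parameters are echoed into the run manifest
#' for provenance. Unknown arguments are rejected.
#'
#' @param fasta Path to the genome FASTA (or named character vector of
#'   sequences). Optional; mining/region/primer stages run only when
#'   present.
#' @param gff Optional path to (or text of) a GFF3 annotation.
#' @param genotypes Optional path to a genotype table (see
#'   [read_genotypes()]) or a [genotype_matrix()].
#' @param populations Optional named vector of population assignments.
#' @param mining A [mining_config()].
#' @param constraints A [primer_constraints()].
#' @param flank_length Flank length for primer extraction (nt).
#' @param motif_length Optional named vector of locus motif lengths for the
#'   genotype table.
#' @param max_core_size Largest core-marker set size to search.
#' @param max_primer_ssrs Cap on the number of SSRs taken into the primer
#'   candidate stage.
#' @param seed Seed echoed into the manifest (the pipeline itself is
#'   deterministic).
#' @return An object of class `run_config`.
#' @export
run_config <- function(fasta = NULL, gff = NULL, genotypes = NULL,
                       populations = NULL, mining = mining_config(),
                       constraints = primer_constraints(),
                       flank_length = 200L, motif_length = NULL,
                       max_core_size = 3L, max_primer_ssrs = 10L,
                       seed = 1L) {
  stopifnot(inherits(mining, "mining_config"),
            inherits(constraints, "primer_constraints"))
  if (is.null(fasta) && is.null(genotypes))
    stop("nothing to do: provide 'fasta' and/or 'genotypes'")
  if (flank_length < 1L) stop("'flank_length' must be >= 1")
  if (max_core_size < 1L) stop("'max_core_size' must be >= 1")
  structure(list(fasta = fasta, gff = gff, genotypes = genotypes,
                 populations = populations, mining = mining,
                 constraints = constraints,
                 flank_length = as.integer(flank_length),
                 motif_length = motif_length,
                 max_core_size = as.integer(max_core_size),
                 max_primer_ssrs = as.integer(max_primer_ssrs),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the genome-to-fingerprint pipeline
#'
#' Executes the stages in dependency order — SSR mining, region mapping,
#' primer flank extraction and candidate validation, diversity statistics,
#' similarity clustering, fingerprint and core-set search — writing each
#' stage's tables under `out_dir` and a machine-readable `manifest.json`
#' listing every artifact with its md5 checksum plus the full parameter
#' echo. Stages whose inputs are absent are skipped; re-running with the
#' same inputs and configuration reproduces identical checksums.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list with `artifacts` and `config`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  note <- function(p) artifacts <<- c(artifacts, p)

  if (!is.null(config$fasta)) {
    seqs <- .as_named_sequences(config$fasta)
    mining <- mine_ssrs(seqs, config$mining)
    note(write_misa_table(mining$records,
                          file.path(out_dir, "ssr_misa.tsv")))
    note(write_ssr_table(mining$records,
                         file.path(out_dir, "ssr_records.tsv")))
    sm <- mining$summary
    .write_tsv(sm$by_motif_length,
               file.path(out_dir, "summary_by_motif_length.tsv"))
    note(file.path(out_dir, "summary_by_motif_length.tsv"))
    .write_tsv(sm$by_class, file.path(out_dir, "summary_by_class.tsv"))
    note(file.path(out_dir, "summary_by_class.tsv"))

    if (!is.null(config$gff)) {
      idx <- build_region_index(config$gff)
      assn <- assign_region(mining$perfect, idx)
      # list columns are not serializable; flat coordinates only
      flat <- assn[c("seq_id", "start", "end", "motif", "category",
                     "overlapped_genes")]
      .write_tsv(flat, file.path(out_dir, "ssr_regions.tsv"))
      note(file.path(out_dir, "ssr_regions.tsv"))
      .write_tsv(region_distribution(assn),
                 file.path(out_dir, "region_distribution.tsv"))
      note(file.path(out_dir, "region_distribution.tsv"))
    }

    take <- utils::head(seq_len(nrow(mining$perfect)),
                        config$max_primer_ssrs)
    if (length(take) > 0) {
      fl <- extract_flanks(mining$perfect[take, , drop = FALSE], seqs,
                           config$flank_length)
      .write_tsv(fl, file.path(out_dir, "ssr_flanks.tsv"))
      note(file.path(out_dir, "ssr_flanks.tsv"))
      cand <- lapply(seq_len(nrow(fl)), function(i) {
        cc <- enumerate_primer_candidates(
          fl$left_flank[i], fl$right_flank[i],
          nchar(fl$ssr_seq[i]), config$constraints, max_pairs = 5L)
        if (nrow(cc) > 0)
          cbind(seq_id = fl$seq_id[i], ssr_start = fl$start[i], cc)
        else NULL
      })
      cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
      if (is.null(cand))
        cand <- data.frame(seq_id = character(), ssr_start = integer())
      .write_tsv(cand, file.path(out_dir, "primer_candidates.tsv"))
      note(file.path(out_dir, "primer_candidates.tsv"))
    }
  }

  if (!is.null(config$genotypes)) {
    g <- if (inherits(config$genotypes, "genotype_matrix")) config$genotypes
         else read_genotypes(config$genotypes, config$motif_length)
    st <- panel_stats(g)
    .write_tsv(as.data.frame(st), file.path(out_dir, "locus_stats.tsv"))
    note(file.path(out_dir, "locus_stats.tsv"))
    ps <- summarize_panel(st)
    .write_tsv(cbind(statistic = rownames(ps$statistics), ps$statistics),
               file.path(out_dir, "panel_summary.tsv"))
    note(file.path(out_dir, "panel_summary.tsv"))
    if (!is.null(config$populations)) {
      wp <- within_population_diversity(g, config$populations)
      .write_tsv(wp$per_population,
                 file.path(out_dir, "within_population.tsv"))
      note(file.path(out_dir, "within_population.tsv"))
    }

    bands <- bands_from_genotypes(g)
    s <- similarity_matrix(bands)
    .write_tsv(data.frame(sample = rownames(s), as.data.frame(unclass(s)),
                          check.names = FALSE),
               file.path(out_dir, "similarity_sm.tsv"))
    note(file.path(out_dir, "similarity_sm.tsv"))
    if (nrow(s) >= 2) {
      tree <- upgma(s)
      note(write_newick(tree, file.path(out_dir, "upgma.nwk")))
      if (nrow(s) >= 3) {
        r <- cophenetic_correlation(tree, s)
        writeLines(sprintf("cophenetic_r\t%.6f", r),
                   file.path(out_dir, "cophenetic.tsv"))
        note(file.path(out_dir, "cophenetic.tsv"))
      }
    }

    fp <- fingerprint_profile(g)
    core <- find_core_sets(fp, config$max_core_size)
    note(write_fingerprint(fp, core, out_dir))
  }

  manifest <- list(
    tool = sprintf("ssrkit %s",
                   as.character(utils::packageVersion("ssrkit"))),
    config = .echo_config(config),
    artifacts = lapply(unique(artifacts), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.echo_config <- function(config) {
  list(mining = list(min_repeats = as.list(config$mining$min_repeats),
                     max_linker = config$mining$max_linker),
       constraints = unclass(config$constraints),
       flank_length = config$flank_length,
       max_core_size = config$max_core_size,
       max_primer_ssrs = config$max_primer_ssrs,
       seed = config$seed,
       inputs = list(
         fasta = if (is.character(config$fasta) &&
                     length(config$fasta) == 1L &&
                     file.exists(config$fasta))
           list(path = config$fasta,
                md5 = unname(tools::md5sum(config$fasta)))
           else if (!is.null(config$fasta)) "in-memory" else NULL,
         gff = if (is.character(config$gff) && length(config$gff) == 1L &&
                   file.exists(config$gff))
           list(path = config$gff, md5 = unname(tools::md5sum(config$gff)))
           else if (!is.null(config$gff)) "in-memory" else NULL,
         genotypes = if (is.character(config$genotypes) &&
                         file.exists(config$genotypes))
           list(path = config$genotypes,
                md5 = unname(tools::md5sum(config$genotypes)))
           else if (!is.null(config$genotypes)) "in-memory" else NULL))
}
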
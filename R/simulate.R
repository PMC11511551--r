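#' Specification of a synthetic genome with planted SSRs
#'
#' Declares the ground truth for a generated test genome: which perfect
#' SSRs to plant (optionally grouped into compound SSRs with fixed linker
#' gaps), which gene models to lay out, and the composition of the
#' repeat-free spacer sequence between them.
#'
#' @param plants Data frame with columns `motif`, `repeats`; optional
#'   columns `group` (integer; members sharing a group id are planted
#'   adjacently, forming a compound SSR), `linker` (gap in nt before a
#'   member within its group, default 10), `gene` (index into `genes`) and
#'   `region` (`"intergenic"` default, or `"five_prime_UTR"`, `"exon"`,
#'   `"intron"`, `"three_prime_UTR"`; requires `gene`).
#' @param genes Optional list of gene models, each a list with `utr5`,
#'   `exons` (vector of exon lengths), `introns` (lengths, one fewer than
#'   exons), `utr3`.
#' @param spacer_length Length of the repeat-free spacers separating planted
#'   elements; must exceed the compound linker bound so independent plants
#'   never merge.
#' @param spacer_gc GC fraction of spacer sequence.
#' @param seed Random seed (drives all randomness of the generator).
#' @param config [mining_config()] the spacers are verified repeat-free
#'   against.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(plants, genes = NULL, spacer_length = 300L,
                       spacer_gc = 0.5, seed = 1L,
                       config = mining_config()) {
  plants <- as.data.frame(plants)
  stopifnot(all(c("motif", "repeats") %in% colnames(plants)))
  nr <- nrow(plants)
  if (is.null(plants$group)) plants$group <- rep(NA_integer_, nr)
  if (is.null(plants$linker)) plants$linker <- rep(10L, nr)
  if (is.null(plants$gene)) plants$gene <- rep(NA_integer_, nr)
  if (is.null(plants$region)) plants$region <- rep("intergenic", nr)
  plants$region[is.na(plants$region)] <- "intergenic"
  if (any(plants$region != "intergenic" & is.na(plants$gene)))
    stop("genic plants need a 'gene' index")
  if (spacer_length <= config$max_linker)
    stop("'spacer_length' must exceed the compound linker bound (",
         config$max_linker, " nt) so that independent plants never merge")
  structure(list(plants = plants, genes = genes,
                 spacer_length = as.integer(spacer_length),
                 spacer_gc = spacer_gc, seed = as.integer(seed),
                 config = config),
            class = "plant_spec")
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_dna <- function(len, gc = 0.5) {
  if (len <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# rejection-sample a spacer until it contains no reportable SSR; boundary
# bases can be constrained so the spacer cannot continue the periodicity of
# an adjacent planted repeat (a single blocked base breaks the period-k
# equality chain across the junction)
.clean_dna <- function(len, gc, config, tries = 200L,
                       forbid_first = NULL, forbid_last = NULL) {
  if (len <= 0L) return("")
  for (i in seq_len(tries)) {
    s <- .random_dna(len, gc)
    if (!is.null(forbid_first) && substr(s, 1L, 1L) %in% forbid_first) next
    if (!is.null(forbid_last) && substr(s, len, len) %in% forbid_last) next
    if (nrow(find_perfect_ssrs(s, config)) == 0L) return(s)
  }
  stop("could not generate a repeat-free spacer of length ", len)
}

# boundary constraints for a spacer between two plants: its last base must
# not equal the last motif base of the following plant (blocks leftward
# extension / phase shift) and its first base must not equal the first
# motif base of the preceding plant (blocks rightward extension)
.forbid_last_of <- function(motif) substr(motif, nchar(motif), nchar(motif))
.forbid_first_of <- function(motif) substr(motif, 1L, 1L)

#' Generate a synthetic genome with planted SSRs and annotation
#'
#' Assembles one chromosome from repeat-free spacers, the planted SSRs of
#' the specification (compound groups planted with their declared linker
#' gaps) and the declared gene models (genic SSRs embedded in the middle of
#' the requested region). The result is verified: mining the assembled
#' sequence at the specification's thresholds must return exactly the
#' planted truth, otherwise the assembly is resampled; an infeasible layout
#' errors out. Deterministic for a given seed.
#'
#' @param spec A [plant_spec()].
#' @param seq_id Name of the generated sequence.
#' @return A list of class `synthetic_genome`: `genome` (named character),
#'   `truth` (data frame of planted SSRs with coordinates, group id and
#'   region category), `gff` (GFF3 text lines, `NULL` without genes),
#'   `spec`.
#' @export
generate_genome <- function(spec, seq_id = "chr1") {
  stopifnot(inherits(spec, "plant_spec"))
  .with_seed(spec$seed, {
    for (attempt in 1:25) {
      res <- .assemble_genome(spec, seq_id)
      mined <- find_perfect_ssrs(res$genome[[seq_id]], spec$config,
                                 seq_id = seq_id)
      truth <- res$truth
      ok <- nrow(mined) == nrow(truth) &&
        all(mined$start == truth$start & mined$end == truth$end &
            mined$motif == truth$motif & mined$repeats == truth$repeats)
      if (ok) return(structure(res, class = "synthetic_genome"))
    }
    stop("infeasible layout: junction artifacts persist across resampling")
  })
}

.assemble_genome <- function(spec, seq_id) {
  cfg <- spec$config
  plants <- spec$plants
  plants$motif <- toupper(plants$motif)
  pieces <- character(0)
  pos <- 0L
  truth <- list()
  gff <- NULL
  gene_rows <- list()

  add <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  plant_one <- function(row, region) {
    s <- strrep(row$motif, row$repeats)
    start <- pos + 1L
    add(s)
    truth[[length(truth) + 1L]] <<- data.frame(
      seq_id = seq_id, start = start, end = pos,
      motif = row$motif, motif_length = nchar(row$motif),
      repeats = row$repeats, length = nchar(s),
      group = row$group, region = region, stringsAsFactors = FALSE)
  }
  plant_group <- function(rows, region) {
    for (k in seq_len(nrow(rows))) {
      if (k > 1L)
        add(.clean_dna(rows$linker[k], spec$spacer_gc, cfg,
                       forbid_first = .forbid_first_of(rows$motif[k - 1L]),
                       forbid_last = .forbid_last_of(rows$motif[k])))
      plant_one(rows[k, ], region)
    }
  }
  spacer <- function(prev_motif = NULL, next_motif = NULL) {
    add(.clean_dna(spec$spacer_length, spec$spacer_gc, cfg,
                   forbid_first = if (!is.null(prev_motif))
                     .forbid_first_of(prev_motif),
                   forbid_last = if (!is.null(next_motif))
                     .forbid_last_of(next_motif)))
  }

  # intergenic plant groups, in declaration order
  inter <- plants[plants$region == "intergenic", , drop = FALSE]
  genic <- plants[plants$region != "intergenic", , drop = FALSE]
  inter_groups <- if (nrow(inter) > 0)
    split(inter, ifelse(is.na(inter$group),
                        paste0("solo", seq_len(nrow(inter))),
                        paste0("g", inter$group)))
  else list()
  # preserve declaration order of groups
  if (length(inter_groups) > 1) {
    first_idx <- vapply(inter_groups, function(d)
      min(match(rownames(d), rownames(inter))), numeric(1))
    inter_groups <- inter_groups[order(first_idx)]
  }

  prev_motif <- NULL
  for (gi in seq_along(inter_groups)) {
    gr <- inter_groups[[gi]]
    spacer(prev_motif, next_motif = gr$motif[1])
    plant_group(gr, "intergenic")
    prev_motif <- gr$motif[nrow(gr)]
  }
  spacer(prev_motif)

  gene_part_name <- c(utr5 = "five_prime_UTR", exon = "exon",
                      intron = "intron", utr3 = "three_prime_UTR")
  for (gi in seq_along(spec$genes)) {
    gm <- spec$genes[[gi]]
    exl <- gm$exons
    inl <- if (is.null(gm$introns)) integer(0) else gm$introns
    if (length(inl) != max(0L, length(exl) - 1L))
      stop("gene ", gi, ": need one intron length per internal junction")
    parts <- list(list(kind = "utr5", len = gm$utr5 %||% 0L))
    for (k in seq_along(exl)) {
      parts[[length(parts) + 1L]] <- list(kind = "exon", len = exl[k])
      if (k <= length(inl))
        parts[[length(parts) + 1L]] <- list(kind = "intron", len = inl[k])
    }
    parts[[length(parts) + 1L]] <- list(kind = "utr3", len = gm$utr3 %||% 0L)

    mine_plants <- genic[genic$gene == gi, , drop = FALSE]
    used <- rep(FALSE, nrow(mine_plants))
    gene_start <- pos + 1L
    part_coords <- list()
    for (p in parts) {
      if (p$len == 0L) next
      part_start <- pos + 1L
      want <- which(!used & mine_plants$region == gene_part_name[p$kind])
      if (length(want) > 0) {
        half <- p$len %/% 2L
        add(.clean_dna(half, spec$spacer_gc, cfg,
                       forbid_last = .forbid_last_of(
                         mine_plants$motif[want[1]])))
        for (wi in seq_along(want)) {
          w <- want[wi]
          if (wi > 1L)
            add(.clean_dna(10L, spec$spacer_gc, cfg,
                           forbid_first = .forbid_first_of(
                             mine_plants$motif[want[wi - 1L]]),
                           forbid_last = .forbid_last_of(
                             mine_plants$motif[w])))
          plant_one(mine_plants[w, ], gene_part_name[p$kind])
          used[w] <- TRUE
        }
        add(.clean_dna(p$len - half, spec$spacer_gc, cfg,
                       forbid_first = .forbid_first_of(
                         mine_plants$motif[want[length(want)]])))
      } else add(.clean_dna(p$len, spec$spacer_gc, cfg))
      part_coords[[length(part_coords) + 1L]] <-
        data.frame(kind = p$kind, start = part_start, end = pos,
                   stringsAsFactors = FALSE)
    }
    if (any(!used)) stop("gene ", gi, ": plant targets a region the gene ",
                         "model does not contain")
    gene_end <- pos
    gene_rows[[gi]] <- list(id = sprintf("gene%d", gi), start = gene_start,
                            end = gene_end,
                            parts = do.call(rbind, part_coords))
    spacer()
  }

  genome <- stats::setNames(paste(pieces, collapse = ""), seq_id)
  truth <- if (length(truth) > 0) do.call(rbind, truth)
    else data.frame(seq_id = character(), start = integer(),
                    end = integer(), motif = character(),
                    motif_length = integer(), repeats = integer(),
                    length = integer(), group = integer(),
                    region = character(), stringsAsFactors = FALSE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL

  if (length(gene_rows) > 0)
    gff <- .gff_lines(gene_rows, seq_id, nchar(genome[[1]]))
  list(genome = genome, truth = truth, gff = gff, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# GFF3 text for the generated gene models; UTRs are parts of terminal exons
.gff_lines <- function(gene_rows, seq_id, seq_len) {
  out <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", seq_id, seq_len))
  feat <- function(type, s, e, id, parent = NULL) {
    attrs <- sprintf("ID=%s", id)
    if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t+\t.\t%s",
            seq_id, "ssrkit", type, s, e, attrs)
  }
  for (g in gene_rows) {
    out <- c(out, feat("gene", g$start, g$end, g$id),
             feat("mRNA", g$start, g$end, paste0(g$id, ".t1"), g$id))
    p <- g$parts
    tx <- paste0(g$id, ".t1")
    # exon features: merge each UTR with its neighbouring coding part
    kinds <- p$kind
    exon_no <- 0L
    i <- 1L
    while (i <= nrow(p)) {
      if (kinds[i] == "intron") { i <- i + 1L; next }
      s <- p$start[i]; e <- p$end[i]
      while (i + 1L <= nrow(p) && kinds[i + 1L] != "intron") {
        i <- i + 1L; e <- p$end[i]
      }
      exon_no <- exon_no + 1L
      out <- c(out, feat("exon", s, e,
                         sprintf("%s.exon%d", tx, exon_no), tx))
      i <- i + 1L
    }
    for (k in which(kinds == "utr5"))
      out <- c(out, feat("five_prime_UTR", p$start[k], p$end[k],
                         paste0(tx, ".utr5"), tx))
    for (k in which(kinds == "utr3"))
      out <- c(out, feat("three_prime_UTR", p$start[k], p$end[k],
                         paste0(tx, ".utr3"), tx))
  }
  out
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d bp, %d planted SSR(s), %s gene model(s)\n",
              nchar(x$genome[[1]]), nrow(x$truth),
              if (is.null(x$spec$genes)) 0 else length(x$spec$genes)))
  invisible(x)
}

#' Specification of a synthetic genotype panel
#'
#' @param loci List of locus definitions, each a list with `name`,
#'   `motif_length`, `ref_size` (fragment size of the first allele, bp) and
#'   either `freqs` (allele frequency vector, or a named list of vectors per
#'   population) for Hardy-Weinberg sampling, or `counts` (exact allele
#'   counts over all `2N` gene copies) for deterministic count placement.
#' @param populations Named integer vector of population sizes.
#' @param missing_rate Probability that a call is set missing (sampled
#'   modes only).
#' @param mode `"hw"` draws each individual's two alleles independently
#'   from its population's frequency vector; `"counts"` places exact allele
#'   counts deterministically (no sampling), pairing gene copies
#'   round-robin across alleles.
#' @param seed Random seed.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(loci, populations = c(pop1 = 12L),
                       missing_rate = 0, mode = c("hw", "counts"),
                       seed = 1L) {
  mode <- match.arg(mode)
  for (l in loci) {
    stopifnot(!is.null(l$name), !is.null(l$motif_length),
              !is.null(l$ref_size))
    if (mode == "hw") {
      fr <- l$freqs
      if (is.null(fr)) stop("locus ", l$name, ": 'freqs' required in hw mode")
      frs <- if (is.list(fr)) fr else list(fr)
      for (f in frs)
        if (abs(sum(f) - 1) > 1e-8)
          stop("locus ", l$name, ": frequencies must sum to 1")
    } else if (is.null(l$counts))
      stop("locus ", l$name, ": 'counts' required in counts mode")
  }
  if (any(populations < 1L)) stop("population sizes must be >= 1")
  structure(list(loci = loci, populations = populations,
                 missing_rate = missing_rate, mode = mode,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a co-dominant genotype panel
#'
#' In Hardy-Weinberg mode each diploid genotype is drawn allele-by-allele
#' from the locus frequency vector of the individual's population; in
#' counts mode the exact allele counts are placed deterministically (used
#' when per-locus statistics must reproduce a known allele-count vector
#' exactly). Fragment sizes are `ref_size + (allele_index - 1) *
#' motif_length`.
#'
#' @param spec A [panel_spec()].
#' @return A [genotype_matrix()].
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  .with_seed(spec$seed, {
    pops <- rep(names(spec$populations), spec$populations)
    n <- length(pops)
    samples <- sprintf("%s_%02d", pops, unlist(lapply(spec$populations,
                                                      seq_len)))
    a1 <- a2 <- matrix(NA_real_, n, length(spec$loci),
                       dimnames = list(samples,
                         vapply(spec$loci, `[[`, character(1), "name")))
    for (j in seq_along(spec$loci)) {
      l <- spec$loci[[j]]
      sizes <- function(idx) l$ref_size + (idx - 1) * l$motif_length
      if (spec$mode == "hw") {
        for (pp in names(spec$populations)) {
          rows <- which(pops == pp)
          f <- if (is.list(l$freqs)) l$freqs[[pp]] else l$freqs
          draws <- sample.int(length(f), 2L * length(rows), replace = TRUE,
                              prob = f)
          g1 <- sizes(draws[seq_along(rows)])
          g2 <- sizes(draws[length(rows) + seq_along(rows)])
          a1[rows, j] <- pmin(g1, g2); a2[rows, j] <- pmax(g1, g2)
        }
        if (spec$missing_rate > 0) {
          miss <- stats::runif(n) < spec$missing_rate
          a1[miss, j] <- NA_real_; a2[miss, j] <- NA_real_
        }
      } else {
        counts <- as.integer(l$counts)
        if (sum(counts) != 2L * n)
          stop("locus ", l$name, ": counts must sum to 2N = ", 2L * n)
        # round-robin across alleles (descending count), then pair
        ord <- order(-counts)
        remaining <- counts[ord]
        copies <- integer(0)
        while (any(remaining > 0L)) {
          take <- which(remaining > 0L)
          copies <- c(copies, ord[take])
          remaining[take] <- remaining[take] - 1L
        }
        g1 <- sizes(copies[seq(1L, 2L * n, by = 2L)])
        g2 <- sizes(copies[seq(2L, 2L * n, by = 2L)])
        a1[, j] <- pmin(g1, g2); a2[, j] <- pmax(g1, g2)
      }
    }
    g <- genotype_matrix(a1, a2,
      motif_length = stats::setNames(
        vapply(spec$loci, `[[`, numeric(1), "motif_length"),
        vapply(spec$loci, `[[`, character(1), "name")))
    attr(g, "populations") <- stats::setNames(pops, samples)
    g
  })
}
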
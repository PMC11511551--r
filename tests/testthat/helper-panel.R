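# Reference diversity panel: 28 co-dominant SSR markers scored on 12
# diploid samples (24 gene copies per locus). The integer allele-count
# vectors were back-derived so that the four frequency statistics
# (Ne, I, He, PIC) jointly reproduce the published reference values to
# four decimals; the suite asserts that joint consistency.
reference_panel <- function() {
  rows <- list(
    list("SSR2",   c(16, 4, 4),          2.0000, 0.8676, 0.5217, 0.4491),
    list("SSR84",  c(10, 6, 4, 4),       3.4286, 1.3086, 0.7391, 0.6589),
    list("SSR52",  c(14, 10),            1.9459, 0.6792, 0.5072, 0.3680),
    list("SSR522", c(8, 6, 6, 2, 2),     4.0000, 1.4735, 0.7826, 0.7078),
    list("SSR18",  c(20, 4),             1.3846, 0.4506, 0.2899, 0.2392),
    list("SSR394", c(15, 3, 3, 1, 1, 1), 2.3415, 1.2109, 0.5978, 0.5436),
    list("SSR751", c(13, 11),            1.9862, 0.6897, 0.5181, 0.3733),
    list("SSR243", c(11, 11, 2),         2.3415, 0.9222, 0.5978, 0.4788),
    list("SSR571", c(11, 10, 2, 1),      2.5487, 1.0618, 0.6341, 0.5280),
    list("SSR122", c(20, 4),             1.3846, 0.4506, 0.2899, 0.2392),
    list("SSR599", c(10, 10, 3, 1),      2.7429, 1.1219, 0.6630, 0.5630),
    list("SSR41",  c(22, 2),             1.1803, 0.2868, 0.1594, 0.1411),
    list("SSR554", c(14, 8, 2),          2.1818, 0.8877, 0.5652, 0.4598),
    list("SSR49",  c(22, 2),             1.1803, 0.2868, 0.1594, 0.1411),
    list("SSR711", c(22, 2),             1.1803, 0.2868, 0.1594, 0.1411),
    list("SSR100", c(20, 2, 2),          1.4118, 0.5661, 0.3043, 0.2723),
    list("SSR237", c(13, 11),            1.9862, 0.6897, 0.5181, 0.3733),
    list("SSR417", c(22, 2),             1.1803, 0.2868, 0.1594, 0.1411),
    list("SSR236", c(10, 10, 2, 1, 1),   2.7961, 1.2015, 0.6703, 0.5748),
    list("SSR527", c(12, 10, 1, 1),      2.3415, 0.9762, 0.5978, 0.4832),
    list("SSR39",  c(12, 10, 2),         2.3226, 0.9184, 0.5942, 0.4768),
    list("SSR497", c(14, 10),            1.9459, 0.6792, 0.5072, 0.3680),
    list("SSR624", c(14, 10),            1.9459, 0.6792, 0.5072, 0.3680),
    list("SSR102", c(20, 4),             1.3846, 0.4506, 0.2899, 0.2392),
    list("SSR205", c(14, 10),            1.9459, 0.6792, 0.5072, 0.3680),
    list("SSR602", c(11, 11, 2),         2.3415, 0.9222, 0.5978, 0.4788),
    list("SSR171", c(14, 10),            1.9459, 0.6792, 0.5072, 0.3680),
    list("SSR570", c(20, 2, 2),          1.4118, 0.5661, 0.3043, 0.2723))
  list(
    counts = setNames(lapply(rows, `[[`, 2),
                      vapply(rows, `[[`, character(1), 1)),
    expected = data.frame(
      locus = vapply(rows, `[[`, character(1), 1),
      Na = vapply(rows, function(r) length(r[[2]]), numeric(1)),
      Ne = vapply(rows, `[[`, numeric(1), 3),
      I = vapply(rows, `[[`, numeric(1), 4),
      He = vapply(rows, `[[`, numeric(1), 5),
      PIC = vapply(rows, `[[`, numeric(1), 6),
      stringsAsFactors = FALSE))
}

# deterministic 12-sample genotype panel realizing the reference counts
reference_panel_genotypes <- function() {
  rp <- reference_panel()
  loci <- lapply(names(rp$counts), function(nm)
    list(name = nm, motif_length = 2, ref_size = 200,
         counts = rp$counts[[nm]]))
  generate_panel(panel_spec(loci = loci, populations = c(panel = 12L),
                            mode = "counts", seed = 1L))
}
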
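#' Synthetic reconstruction of a muroid mitochondrial gene map
#'
#' A full-size (16,353 bp) gene plan laid out in the standard muroid
#' mitochondrial gene order, with every intergenic spacer and gene
#' boundary consistent with the published bank vole coordinate table:
#' twelve 1-5 bp non-coding spacers totalling 26 bp, the 946-bp
#' control region between trnP and trnF, the 31-bp light-strand
#' replication-origin spacer between trnN and trnC, tail-to-head ORF
#' overlaps of 43 bp (atp8/atp6) and 7 bp (nad4l/nad4), a 4-bp
#' tail-to-tail overlap (nad5/nad6), a 69-bp cox1 3' UTR budget
#' (antisense trnS2 plus 3 bp of spacer) and a 595-bp nad5 3' UTR
#' budget, and 13 protein-coding genes totalling 11,390 bp. The
#' sequence itself is synthetic (seeded), since only the coordinates
#' are published; gene boundaries not pinned by a printed spacer are
#' filled with realistic gene lengths.
#'
#' @return Layout tibble in the format of [default_layout()].
#' @export
vole_like_layout <- function() {
  tibble::tribble(
    ~name, ~ftype, ~strand, ~length, ~stop_mode, ~gap_after, ~gap_kind, ~overlap_next,
    "trnF", "tRNA", "H", 66L, NA, 2L, "random", 0L,
    "rrnS", "rRNA", "H", 950L, NA, 0L, "random", 0L,
    "trnV", "tRNA", "H", 68L, NA, 0L, "random", 0L,
    "rrnL", "rRNA", "H", 1580L, NA, 0L, "random", 0L,
    "trnL1", "tRNA", "H", 74L, NA, 0L, "random", 0L,
    "nad1", "PCG", "H", 955L, "incomplete_T", 0L, "random", 0L,
    "trnI", "tRNA", "H", 66L, NA, 0L, "random", 0L,
    "trnQ", "tRNA", "L", 67L, NA, 0L, "random", 0L,
    "trnM", "tRNA", "H", 67L, NA, 0L, "random", 0L,
    "nad2", "PCG", "H", 1035L, "full_TAA", 2L, "random", 0L,
    "trnW", "tRNA", "H", 67L, NA, 1L, "random", 0L,
    "trnA", "tRNA", "L", 69L, NA, 2L, "random", 0L,
    "trnN", "tRNA", "L", 70L, NA, 31L, "stemloop", 0L,
    "trnC", "tRNA", "L", 67L, NA, 0L, "random", 0L,
    "trnY", "tRNA", "L", 68L, NA, 1L, "random", 0L,
    "cox1", "PCG", "H", 1545L, "full_TAA", 0L, "random", 0L,
    "trnS2", "tRNA", "L", 66L, NA, 3L, "random", 0L,
    "trnD", "tRNA", "H", 68L, NA, 1L, "random", 0L,
    "cox2", "PCG", "H", 684L, "full_TAA", 3L, "random", 0L,
    "trnK", "tRNA", "H", 68L, NA, 0L, "random", 0L,
    "atp8", "PCG", "H", 204L, "bicistronic_upstream", 0L, "random", 43L,
    "atp6", "PCG", "H", 680L, "incomplete_TA", 0L, "random", 0L,
    "cox3", "PCG", "H", 784L, "incomplete_T", 0L, "random", 0L,
    "trnG", "tRNA", "H", 68L, NA, 0L, "random", 0L,
    "nad3", "PCG", "H", 345L, "full_TAA", 1L, "random", 0L,
    "trnR", "tRNA", "H", 68L, NA, 3L, "random", 0L,
    "nad4l", "PCG", "H", 297L, "bicistronic_upstream", 0L, "random", 7L,
    "nad4", "PCG", "H", 1378L, "incomplete_T", 0L, "random", 0L,
    "trnH", "tRNA", "H", 68L, NA, 0L, "random", 0L,
    "trnS1", "tRNA", "H", 58L, NA, 0L, "random", 0L,
    "trnL2", "tRNA", "H", 70L, NA, 0L, "random", 0L,
    "nad5", "PCG", "H", 1812L, "full_TAA", 0L, "random", 4L,
    "nad6", "PCG", "L", 528L, "full_TAA", 0L, "random", 0L,
    "trnE", "tRNA", "L", 66L, NA, 5L, "random", 0L,
    "cob", "PCG", "H", 1143L, "full_TAA", 2L, "random", 0L,
    "trnT", "tRNA", "H", 68L, NA, 0L, "random", 0L,
    "trnP", "tRNA", "L", 67L, NA, 946L, "control", 0L
  )
}

#' Synthetic full-size mitogenome fixture
#'
#' Builds the [vole_like_layout()] into a seeded synthetic genome and
#' annotation via the same constrained sequence generator as
#' [build_toy_genome()]. The coordinates are deterministic (they do
#' not depend on the seed); the sequence is synthetic.
#'
#' @param seed Seed for the synthetic sequence.
#' @return List with `genome` and `annotation`.
#' @export
vole_like_fixture <- function(seed = 101L) {
  cfg <- sim_config(seed = seed, layout = vole_like_layout())
  build_toy_genome(cfg, genome_id = "synthetic_vole_like")
}
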
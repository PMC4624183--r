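# Shared fixtures, built once per test run. Everything is generated in
# code; nothing binary is stored.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_fixture <- function(seed = 7L) {
  cached(paste0("toy_", seed), build_toy_genome(sim_config(seed = seed)))
}

vole_fixture <- function() cached("vole", vole_like_fixture())

# A complete noiseless simulate -> map -> call run at the study depth.
toy_run <- function(seed = 7L, error_rate = 0, depth = 200) {
  key <- paste("run", seed, error_rate, depth, sep = "_")
  cached(key, {
    cfg <- sim_config(seed = seed, error_rate = error_rate, depth = depth)
    toy <- build_toy_genome(cfg)
    transcripts <- transcribe_and_process(toy$genome, toy$annotation, cfg)
    sim <- simulate_reads(transcripts, toy$genome, cfg)
    reads <- dplyr::bind_rows(
      tibble::tibble(read_id = sim$reads$read_id, seq = sim$reads$seq1, mate = 1L),
      tibble::tibble(read_id = sim$reads$read_id, seq = sim$reads$seq2, mate = 2L)
    )
    mapped <- map_reads(reads, toy$genome)
    evidence <- detect_tails(mapped, toy$genome$length)
    sites <- aggregate_sites(evidence)
    list(
      config = cfg, genome = toy$genome, annotation = toy$annotation,
      transcripts = transcripts, sim = sim, reads = reads,
      mapped = mapped, evidence = evidence, sites = sites,
      truth = truth_polya_sites(toy$annotation)
    )
  })
}

random_genome <- function(len, seed = NULL) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  circular_genome("rand", s, "circular")
}

# a small non-overlapping random annotation for property tests
random_annotation <- function(len, n_features, seed) {
  withr::with_seed(seed, {
    cuts <- sort(sample(seq_len(len - 1L), 2L * n_features))
    starts <- cuts[seq(1L, length(cuts), by = 2L)]
    ends <- cuts[seq(2L, length(cuts), by = 2L)]
    annotation(
      tibble::tibble(
        name = paste0("g", seq_along(starts)),
        ftype = sample(c("PCG", "tRNA", "rRNA"), length(starts), TRUE),
        strand = sample(c("H", "L"), length(starts), TRUE),
        start = starts, end = ends
      ),
      genome_id = "rand", genome_length = len
    )
  })
}

write_mini_genbank <- function(path) {
  writeLines(c(
    "LOCUS       TESTMT                 16353 bp    DNA     circular ROD 01-JAN-2015",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..16353",
    "     CDS             100..1099",
    "                     /gene=\"ND1\"",
    "     tRNA            complement(1100..1165)",
    "                     /product=\"tRNA-Gln\"",
    "     tRNA            1166..1231",
    "                     /product=\"tRNA-Ser\"",
    "     tRNA            1300..1365",
    "                     /product=\"tRNA-Ser\"",
    "     rRNA            1400..2399",
    "                     /product=\"12S ribosomal RNA\"",
    "     D-loop          14400..15346",
    "     CDS             join(15408..16353,1..66)",
    "                     /gene=\"CYTB\"",
    "ORIGIN",
    "//"
  ), path)
  path
}

write_mini_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chrM 1 2000",
    "chrM\ttest\tCDS\t100\t1099\t.\t+\t0\tID=cds1;Name=ND2",
    "chrM\ttest\ttRNA\t1100\t1165\t.\t-\t.\tID=t1;Name=tRNA-Gln",
    "chrM\ttest\trRNA\t1200\t1900\t.\t+\t.\tID=r1;Name=12S"
  ), path)
  path
}
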
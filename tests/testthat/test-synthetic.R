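test_that("the generator is deterministic for a fixed seed", {
  cfg <- sim_config(seed = 13)
  a <- build_toy_genome(cfg)
  b <- build_toy_genome(cfg)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
  tr_a <- transcribe_and_process(a$genome, a$annotation, cfg)
  tr_b <- transcribe_and_process(b$genome, b$annotation, cfg)
  expect_identical(tr_a, tr_b)
  sim_a <- simulate_reads(tr_a, a$genome, cfg)
  sim_b <- simulate_reads(tr_b, b$genome, cfg)
  expect_identical(sim_a$reads, sim_b$reads)
  expect_identical(sim_a$truth, sim_b$truth)
  # a different seed changes the sequence
  c <- build_toy_genome(sim_config(seed = 14))
  expect_false(identical(a$genome$seq, c$genome$seq))
})

test_that("the default layout plants every archetype", {
  toy <- toy_fixture()
  ov <- find_overlaps(toy$annotation)
  th <- ov[ov$geometry == "tail_to_head", ]
  expect_setequal(th$overlap_bp, c(43L, 7L))
  tt <- ov[ov$geometry == "tail_to_tail", ]
  expect_equal(tt$overlap_bp, 4L)
  expect_setequal(tt[, c("gene_a", "gene_b")] |> unlist() |> unname(),
    c("nad5", "nad6"))
  # incomplete stops are physically present at the gene ends
  g <- toy$genome
  ann <- toy$annotation
  end_of <- function(n) ann$end[ann$name == n]
  expect_equal(seq_slice1(g, end_of("nad1"), end_of("nad1")), "T")
  expect_equal(seq_slice1(g, end_of("atp6") - 1L, end_of("atp6")), "TA")
  expect_equal(seq_slice1(g, end_of("cox3"), end_of("cox3")), "T")
  # abutting pair without intervening tRNA
  expect_equal(ann$start[ann$name == "cox3"], end_of("atp6") + 1L)
})

test_that("ORFs are stop-free in frame, including shifted overlap frames", {
  toy <- toy_fixture()
  ann <- toy$annotation
  for (g in ann$name[ann$ftype == "PCG"]) {
    row <- as.list(ann[ann$name == g, ])
    cds <- mitotail:::cds_sequence(row, toy$genome)
    n_full <- nchar(cds) %/% 3L
    codons <- substring(cds, 3L * (seq_len(n_full) - 1L) + 1L, 3L * seq_len(n_full))
    internal <- codons[seq_len(n_full - 1L)]
    expect_false(any(internal %in% mitotail:::mt_stop_codons), info = g)
  }
})

test_that("removing the overlap removes the tail-to-head record", {
  layout <- default_layout()
  layout$overlap_next[layout$name == "atp8"] <- 0L
  toy <- build_toy_genome(sim_config(seed = 3, layout = layout))
  ov <- find_overlaps(toy$annotation)
  expect_false(any(
    ov$geometry == "tail_to_head" & ov$gene_a == "atp8"
  ))
})

test_that("processing honours tRNA punctuation with archetype exceptions", {
  toy <- toy_fixture()
  tr <- transcribe_and_process(toy$genome, toy$annotation, sim_config(seed = 7))
  # bicistronic pairs come out as single transcripts
  expect_true("atp8,atp6" %in% tr$gene_names)
  expect_true("nad4l,nad4" %in% tr$gene_names)
  # the L-strand mRNA is emitted untailed
  nad6 <- tr[tr$gene_names == "nad6", ]
  expect_equal(nad6$tail_length, 0L)
  # every tailed transcript ends in exactly tail_length A's beyond a
  # body that equals the strand-oriented genomic slice
  len <- toy$genome$length
  for (i in which(tr$tail_length > 0L)) {
    body_len <- nchar(tr$sequence[i]) - tr$tail_length[i]
    body <- substr(tr$sequence[i], 1L, body_len)
    expect_equal(
      body, seq_slice1(toy$genome, tr$genome_start[i], tr$genome_end[i]),
      info = tr$name[i]
    )
    tail <- substr(tr$sequence[i], body_len + 1L, nchar(tr$sequence[i]))
    expect_equal(tail, strrep("A", tr$tail_length[i]))
    expect_gte(tr$tail_length[i], 3L)
  }
  # the nad5-archetype transcript ends at the IGS/gene boundary and its
  # span carries the antisense L-strand gene and tRNA
  nad5 <- tr[tr$gene_names == "nad5", ]
  cob_start <- toy$annotation$start[toy$annotation$name == "cob"]
  expect_equal(nad5$genome_end, cob_start - 1L)
})

test_that("an annotation without tRNAs yields one full-precursor transcript", {
  toy <- toy_fixture()
  ann_no_trna <- annotation(
    as.data.frame(toy$annotation)[
      toy$annotation$ftype != "tRNA",
      c("name", "ftype", "strand", "start", "end")
    ],
    genome_id = "x", genome_length = genome_length(toy$annotation)
  )
  pieces <- mitotail:::processing_pieces(ann_no_trna)
  h <- pieces[pieces$strand == "H", ]
  # punctuation-free precursor: one uncut H transcript carrying every
  # H-strand PCG (the archetype extra cuts need an upstream tRNA-free
  # PCG pair, which still applies, so allow the archetype splits)
  expect_true(any(grepl("nad1", h$gene_names)))
  all_genes <- unlist(strsplit(h$gene_names, ","))
  expect_setequal(
    all_genes,
    toy$annotation$name[toy$annotation$ftype == "PCG" &
      toy$annotation$strand == "H"]
  )
})

test_that("true sites are immediately 3' of each tailed transcript", {
  toy <- toy_fixture()
  truth <- truth_polya_sites(toy$annotation)
  tr <- transcribe_and_process(toy$genome, toy$annotation, sim_config(seed = 7))
  len <- toy$genome$length
  tailed <- tr[tr$tail_length > 0L, ]
  expect_equal(nrow(truth), nrow(tailed))
  m <- match(truth$transcript, tailed$name)
  expect_equal(
    truth$site_position,
    mitotail:::wrap1(tailed$genome_end[m] + 1L, len)
  )
})

test_that("read simulation respects enrichment, leak-through and tails", {
  toy <- toy_fixture()
  cfg0 <- sim_config(seed = 5, error_rate = 0, leak_fraction = 0)
  tr <- transcribe_and_process(toy$genome, toy$annotation, cfg0)
  sim <- simulate_reads(tr, toy$genome, cfg0)
  # leak-through 0: no fragments from untailed transcripts
  expect_false(any(grepl("nad6", sim$truth$source)))
  # tail bases in reads are exclusively A on the transcript strand
  tailed <- sim$truth[sim$truth$tail_bases > 0L, ]
  frag_tails <- substr(
    tailed$frag, nchar(tailed$frag) - tailed$tail_bases + 1L,
    nchar(tailed$frag)
  )
  expect_true(all(grepl("^A*$", frag_tails)))
  # every simulated read pair appears exactly once in the truth table
  expect_equal(anyDuplicated(sim$truth$read_id), 0L)
  expect_setequal(sim$reads$read_id, sim$truth$read_id)
})

test_that("constant tails and zero error give exact terminal A runs", {
  toy <- toy_fixture()
  cfg <- sim_config(seed = 9, error_rate = 0)
  tr <- transcribe_and_process(toy$genome, toy$annotation, cfg)
  tr$tail_length <- ifelse(tr$tail_length > 0L, 10L, 0L)
  # rebuild sequences with the constant tail
  bodies <- purrr::pmap_chr(
    tr[, c("genome_start", "genome_end", "strand")],
    function(genome_start, genome_end, strand) {
      s <- seq_slice1(toy$genome, genome_start, genome_end)
      if (strand == "L") mitotail:::revcomp(s) else s
    }
  )
  tr$sequence <- paste0(bodies, strrep("A", tr$tail_length))
  sim <- simulate_reads(tr, toy$genome, cfg)
  ends <- sim$truth[sim$truth$tail_bases > 0L, ]
  expect_true(all(ends$tail_bases <= 10L))
  full_tail <- ends[ends$tail_bases == 10L, ]
  expect_gt(nrow(full_tail), 0L)
  # reads spanning a transcript end carry exactly 10 terminal A's
  r2 <- sim$reads$seq2[match(full_tail$read_id, sim$reads$read_id)]
  expect_true(all(startsWith(r2, strrep("T", 10L))))
})

test_that("simulated depth matches the target within sampling error", {
  run <- toy_run()
  prof <- coverage_profile(run$mapped, ann = run$annotation)
  pcg <- prof$features[prof$features$ftype == "PCG" &
    prof$features$strand == "H", ]
  # mapped coverage loses the tail-heavy boundary reads, so allow the
  # stated +/-20% band around the configured depth
  expect_gt(mean(pcg$mean_depth), 0.8 * run$config$depth * 0.8)
  expect_lt(mean(pcg$mean_depth), 1.2 * run$config$depth * 1.2)
})
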
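# A minimal one-gene genome whose CDS tail and downstream context are
# fully controlled.
mini_gene <- function(cds, downstream = "CGCGCG") {
  seqs <- paste0("GGTACC", cds, downstream)
  genome <- circular_genome("mini", seqs, "circular")
  ann <- annotation(
    tibble::tibble(
      name = "g1", ftype = "PCG", strand = "H",
      start = 7L, end = 6L + nchar(cds)
    ),
    genome_id = "mini", genome_length = genome$length
  )
  list(genome = genome, ann = ann, cds_end = 6L + nchar(cds))
}

test_that("stop-codon classification follows the completion logic", {
  # solitary T, site immediately after: polyadenylation-completed TAA
  x <- mini_gene(paste0("ATG", "GCA", "CTT", "T"))
  call <- classify_stop("g1", x$ann, x$genome, site_position = x$cds_end + 1L)
  expect_equal(call$genomic_suffix, "T")
  expect_equal(call$mechanism, "polyadenylation")
  expect_equal(call$completed_codon, "TAA")
  expect_equal(call$polyA_distance, 0L)

  # TA suffix, site at distance 0
  x <- mini_gene(paste0("ATG", "GCA", "CTT", "TA"))
  call <- classify_stop("g1", x$ann, x$genome, site_position = x$cds_end + 1L)
  expect_equal(call$genomic_suffix, "TA")
  expect_equal(call$mechanism, "polyadenylation")
  expect_equal(call$completed_codon, "TAA")

  # full genomic TAG with a distant site: encoded, polyadenylation not
  # needed
  x <- mini_gene(paste0("ATG", "GCA", "CTT", "TAG"))
  call <- classify_stop("g1", x$ann, x$genome, site_position = x$cds_end + 3L)
  expect_equal(call$mechanism, "encoded")
  expect_equal(call$completed_codon, "TAG")
  expect_equal(call$polyA_distance, 2L)

  # AGA/AGG count as stops under the vertebrate mitochondrial code
  x <- mini_gene(paste0("ATG", "GCA", "CTT", "AGA"))
  expect_equal(classify_stop("g1", x$ann, x$genome)$mechanism, "encoded")

  # T suffix with no site stays unresolved
  x <- mini_gene(paste0("ATG", "GCA", "CTT", "T"))
  call <- classify_stop("g1", x$ann, x$genome)
  expect_equal(call$mechanism, "unresolved")
  expect_true(is.na(call$completed_codon))

  # frame-inconsistent annotations are an error
  x <- mini_gene(paste0("ATG", "GCA", "CTT", "G"))
  expect_error(classify_stop("g1", x$ann, x$genome), "frame-inconsistent")
})

test_that("polyadenylation completion always yields TAA over all suffixes", {
  # enumerate all 1- and 2-base suffixes times site distance 0/1
  bases <- c("A", "C", "G", "T")
  completions <- character()
  for (suffix in c(bases, as.vector(outer(bases, bases, paste0)))) {
    for (dist in 0:1) {
      x <- mini_gene(paste0("ATG", "GCA", "CTT", suffix))
      call <- tryCatch(
        classify_stop("g1", x$ann, x$genome,
          site_position = x$cds_end + 1L + dist
        ),
        error = function(e) NULL
      )
      if (is.null(call)) next # frame-inconsistent suffix, correctly rejected
      if (call$mechanism == "polyadenylation") {
        completions <- c(completions, call$completed_codon)
        expect_true(suffix %in% c("T", "TA"))
        expect_equal(dist, 0L)
      }
    }
  }
  expect_gt(length(completions), 0L)
  expect_true(all(completions == "TAA"))
})

test_that("3' UTRs are measured between stop codon and site", {
  toy <- toy_fixture()
  ann <- toy$annotation
  truth <- truth_polya_sites(ann)
  # nad2 archetype: full stop, 2 bp UTR
  s <- truth$site_position[truth$transcript == "nad2"]
  u <- call_utr("nad2", s, ann, toy$genome)
  expect_equal(u$utr_length, 2L)
  expect_equal(nchar(u$utr_sequence), 2L)
  # distance 0: empty UTR
  s1 <- truth$site_position[truth$transcript == "nad1"]
  u1 <- call_utr("nad1", s1, ann, toy$genome)
  expect_equal(u1$utr_length, 0L)
  expect_equal(u1$utr_sequence, "")
  # nad5 archetype: long UTR carrying the antisense L gene and tRNA
  s5 <- truth$site_position[truth$transcript == "nad5"]
  u5 <- call_utr("nad5", s5, ann, toy$genome)
  expect_equal(u5$utr_length, truth$utr_length[truth$transcript == "nad5"])
  got <- strsplit(u5$contained_antisense_features, ",")[[1]]
  expect_setequal(got, c("nad6", "trnE"))
  # a site upstream of the stop is a mis-assignment error
  expect_error(call_utr("nad5", ann$start[ann$name == "nad5"] - 200L,
    ann, toy$genome), "upstream")
})

test_that("punctuation predictions skip antisense features and flag bicistronic genes", {
  toy <- toy_fixture()
  ann <- toy$annotation
  pred <- predict_punctuation_ends(ann)
  expect_equal(nrow(pred), sum(ann$ftype == "PCG"))
  # PCG followed directly by a sense tRNA: UTR 0
  expect_equal(pred$predicted_utr[pred$gene == "nad1"], 0L)
  # cox1 archetype: antisense tRNA cluster is transparent, long UTR to
  # the next sense tRNA
  expect_equal(
    pred$predicted_end[pred$gene == "cox1"],
    ann$start[ann$name == "trnD"] - 1L
  )
  expect_equal(pred$predicted_utr[pred$gene == "cox1"], 69L)
  # bicistronic-upstream genes have no 3' end of their own
  expect_equal(pred$bicistronic_with[pred$gene == "atp8"], "atp6")
  expect_true(is.na(pred$predicted_end[pred$gene == "atp8"]))
  # abutting genes without a tRNA share the downstream prediction
  expect_equal(
    pred$predicted_end[pred$gene == "atp6"],
    pred$predicted_end[pred$gene == "cox3"]
  )

  # inserting an L-strand feature between a gene and its punctuating
  # tRNA changes only the UTR length, not the predicted end
  feats <- as.data.frame(ann)[, c("name", "ftype", "strand", "start", "end")]
  gap_start <- ann$end[ann$name == "nad2"] + 1L
  feats <- rbind(feats, data.frame(
    name = "trnX", ftype = "tRNA", strand = "L",
    start = gap_start, end = gap_start + 1L
  ))
  ann2 <- annotation(feats, "toy2", genome_length(ann))
  pred2 <- predict_punctuation_ends(ann2)
  expect_equal(
    pred2$predicted_end[pred2$gene == "nad2"],
    pred$predicted_end[pred$gene == "nad2"]
  )
})

test_that("bicistronic calls require overlap plus upstream silence", {
  toy <- toy_fixture()
  run <- toy_run()
  calls <- detect_bicistronic(toy$annotation, run$sites)
  called <- calls[calls$called, ]
  expect_equal(nrow(called), 2L)
  expect_setequal(called$upstream_gene, c("atp8", "nad4l"))
  expect_setequal(called$overlap_bp, c(43L, 7L))
  expect_true(all(called$evidence == "both"))

  # planting a supported site right after the upstream ORF vetoes the call
  atp8_end <- toy$annotation$end[toy$annotation$name == "atp8"]
  planted <- dplyr::bind_rows(
    run$sites,
    tibble::tibble(
      site_id = "H_planted", position = atp8_end + 1L, strand = "H",
      support = 50L, tail_length_mean = 8, pass = TRUE
    )
  )
  calls2 <- detect_bicistronic(toy$annotation, planted)
  atp8_row <- calls2[calls2$upstream_gene == "atp8", ]
  expect_false(atp8_row$called)
  expect_equal(atp8_row$evidence, "orf_overlap")
})

test_that("conformance auditing matches the archetype expectations", {
  run <- toy_run()
  toy <- toy_fixture()
  assigned <- assign_sites_to_genes(run$sites, toy$annotation)
  pred <- predict_punctuation_ends(toy$annotation)
  report <- check_punctuation_conformance(assigned, pred, toy$annotation)
  expect_equal(nrow(report), sum(toy$annotation$ftype == "PCG"))
  verdict <- function(g) report$conformance[report$gene == g]
  note <- function(g) report$note[report$gene == g]
  expect_equal(verdict("nad1"), "conforms")
  expect_equal(verdict("cox3"), "conforms")
  expect_equal(verdict("nad2"), "conforms_with_UTR")
  expect_equal(verdict("cox1"), "conforms_with_UTR")
  # the abutting pair's upstream member deviates (no tRNA junction)
  expect_equal(verdict("atp6"), "deviation")
  expect_match(note("atp6"), "without tRNA")
  # the long-UTR gene ends at an IGS/gene boundary
  expect_equal(verdict("nad5"), "deviation")
  expect_match(note("nad5"), "IGS/gene boundary")
  # the L-strand gene has no site and stays unresolved
  expect_equal(verdict("nad6"), "unresolved")
  # bicistronic-upstream genes conform silently
  expect_equal(verdict("atp8"), "conforms")
  expect_match(note("atp8"), "bicistronic")
})

test_that("stem-loop scanning finds planted hairpins and rejects homopolymers", {
  # perfect 10-bp inverted repeat around a 4-nt loop
  stem <- "GCATCGGATC"
  hp <- paste0(stem, "TTTT", mitotail:::revcomp(stem))
  res <- stemloop_scan(hp)
  expect_equal(res$stem_pairs, 10L)
  expect_equal(res$loop_length, 4L)
  expect_true(res$candidate)
  expect_equal(res$stem_start, 1L)
  expect_equal(res$stem_end, nchar(hp))

  # homopolymer folds nothing
  res_a <- stemloop_scan(strrep("A", 31L))
  expect_equal(res_a$stem_pairs, 0L)
  expect_false(res_a$candidate)

  # the planted spacer in the toy genome is detected through the IGS
  # classifier (31 bp with a 12-pair stem)
  toy <- toy_fixture()
  igs <- derive_igs(toy$annotation, toy$genome)
  ol <- igs[igs$igs_class == "OL_candidate", ]
  res_ol <- stemloop_scan(seq_slice1(toy$genome, ol$start, ol$end))
  expect_gte(res_ol$stem_pairs, 12L)
})

test_that("stem-loop scan equals brute-force enumeration on short sequences", {
  # independent enumeration over every (innermost pair, stem length)
  brute_force <- function(s, min_loop = 3L) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    w <- function(a, b) {
      key <- paste0(a, b)
      if (key %in% c("GC", "CG")) {
        3L
      } else if (key %in% c("AT", "TA")) {
        2L
      } else if (key %in% c("GT", "TG")) {
        1L
      } else {
        0L
      }
    }
    best <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j - i - 1L < min_loop) next # loop between i and j
        sc <- 0L
        for (d in 0:(n - 1L)) { # contiguous stem outward from (i, j)
          if (i - d < 1L || j + d > n) break
          ww <- w(ch[i - d], ch[j + d])
          if (ww == 0L) break
          sc <- sc + ww
          if (sc > best) best <- sc
        }
      }
    }
    best
  }
  withr::with_seed(77, {
    for (rep in 1:12) {
      n <- sample(13:30, 1L)
      s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      expect_equal(
        stemloop_scan(s)$score, brute_force(s),
        info = paste("rep", rep, s)
      )
    }
  })
})
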
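test_that("a perfect genomic read maps full-length without clips", {
  toy <- toy_fixture()
  r <- seq_slice1(toy$genome, 1001L, 1100L)
  m <- map_read(r, toy$genome)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos, 1001L)
  expect_equal(m$strand, "+")
  expect_equal(m$aligned_fraction, 1.0)
  expect_equal(m$identity, 1.0)
  expect_equal(m$cigar, "100M")
  expect_equal(m$clip_left, "")
  expect_equal(m$clip_right, "")
})

test_that("a tailed read passes exactly at the 90% length-fraction boundary", {
  toy <- toy_fixture()
  truth <- truth_polya_sites(toy$annotation)
  site <- truth$site_position[truth$transcript == "nad1"]
  # 90 template bases ending at the transcript end + 10 non-template A's
  r <- paste0(
    seq_slice1(toy$genome, site - 90L, site - 1L), strrep("A", 10L)
  )
  m <- map_read(r, toy$genome)
  expect_equal(nrow(m), 1L)
  expect_equal(m$aligned_fraction, 0.9)
  expect_equal(m$clip_right, strrep("A", 10L))
  expect_match(m$cigar, "^90M10S$")
  # one base fewer aligned fails the inclusive threshold
  r11 <- paste0(
    seq_slice1(toy$genome, site - 89L, site - 1L), strrep("A", 11L)
  )
  expect_equal(nrow(map_read(r11, toy$genome)), 0L)
})

test_that("reads breaching the 95% identity threshold are unmapped", {
  withr::with_seed(11, {
    gen <- random_genome(1500L)
    r <- strsplit(seq_slice1(gen, 301L, 400L), "")[[1]]
    # 6 substitutions in 100 aligned columns: identity 0.94 at the
    # original placement; mutated bases are interior so clipping them
    # costs length fraction instead
    for (k in c(20L, 30L, 45L, 60L, 75L, 90L)) {
      r[k] <- setdiff(c("A", "C", "G", "T"), r[k])[1]
    }
    m <- map_reads(
      tibble::tibble(read_id = "r", seq = paste(r, collapse = "")),
      gen,
      keep_unmapped = TRUE, full_scan = TRUE
    )
    expect_true(is.na(m$pos[1]))
    # 4 substitutions pass (identity 0.96)
    r2 <- strsplit(seq_slice1(gen, 301L, 400L), "")[[1]]
    for (k in c(20L, 30L, 45L, 60L)) {
      r2[k] <- setdiff(c("A", "C", "G", "T"), r2[k])[1]
    }
    m2 <- map_read(paste(r2, collapse = ""), gen, full_scan = TRUE)
    expect_equal(nrow(m2), 1L)
    expect_gte(m2$identity, 0.95)
  })
})

test_that("soft clips plus aligned core reconstruct the read exactly", {
  run <- toy_run()
  m <- withr::with_seed(5, run$mapped[sample.int(nrow(run$mapped), 200L), ])
  # seq_fwd is the oriented full read; verify clip lengths match CIGAR
  left_s <- as.integer(stringr::str_match(m$cigar, "^([0-9]+)S")[, 2])
  right_s <- as.integer(stringr::str_match(m$cigar, "([0-9]+)S$")[, 2])
  left_s[is.na(left_s)] <- 0L
  right_s[is.na(right_s)] <- 0L
  expect_equal(nchar(m$clip_left), left_s)
  expect_equal(nchar(m$clip_right), right_s)
  expect_equal(
    substr(m$seq_fwd, 1L, left_s), m$clip_left
  )
  expect_equal(
    substr(m$seq_fwd, nchar(m$seq_fwd) - right_s + 1L, nchar(m$seq_fwd)),
    m$clip_right
  )
})

test_that("reads spanning the circular origin map with the modulo convention", {
  toy <- toy_fixture()
  len <- toy$genome$length
  r <- seq_slice1(toy$genome, len - 49L, 50L) # 100 bp across the origin
  m <- map_read(r, toy$genome)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos, len - 49L)
  expect_equal(m$cigar, "100M")
  expect_equal(m$end_pos, len + 50L) # consumes past the origin
  # brute-force check against the rotated genome
  k <- 1000L
  m_rot <- map_read(r, rotate_genome(toy$genome, k))
  expect_equal(m_rot$pos, mitotail:::wrap1(m$pos - k, len))
})

test_that("mapping is rotation invariant", {
  run <- toy_run()
  toy <- toy_fixture()
  len <- toy$genome$length
  k <- 777L
  idx <- withr::with_seed(6, sample.int(nrow(run$reads), 150L))
  orig <- map_reads(run$reads[idx, ], toy$genome)
  rot <- map_reads(run$reads[idx, ], rotate_genome(toy$genome, k))
  expect_equal(nrow(orig), nrow(rot))
  both <- dplyr::inner_join(
    orig, rot,
    by = c("read_id", "mate"), suffix = c("", "_rot")
  )
  expect_equal(
    mitotail:::wrap1(both$pos_rot + k, len), mitotail:::wrap1(both$pos, len)
  )
  expect_equal(both$cigar_rot, both$cigar)
  expect_equal(both$score_rot, both$score)
})

test_that("alignment scores equal the Biostrings local-alignment oracle", {
  # dual-route check on small random cases; the acceptance suite runs
  # the large-scale version
  bases <- c("A", "C", "G", "T")
  mat <- matrix(-2L, 4L, 4L, dimnames = list(bases, bases))
  diag(mat) <- 1L
  withr::with_seed(31, {
    for (i in 1:25) {
      len <- sample(200:1200, 1L)
      gen <- random_genome(len)
      rl <- sample(25:60, 1L)
      st <- sample(seq_len(len), 1L)
      r <- strsplit(
        seq_slice1(gen, st, mitotail:::wrap1(st + rl - 1L, len)), ""
      )[[1]]
      nmut <- sample(0:4, 1L)
      for (k in sample(rl, nmut)) r[k] <- sample(setdiff(bases, r[k]), 1L)
      if (stats::runif(1) < 0.5) {
        r <- rev(strsplit(chartr("ACGT", "TGCA", paste(r, collapse = "")), "")[[1]])
      }
      r <- paste(r, collapse = "")
      mine <- map_reads(
        tibble::tibble(read_id = "r", seq = r), gen,
        keep_unmapped = TRUE, full_scan = TRUE
      )$score
      g2 <- Biostrings::DNAString(paste0(gen$seq, gen$seq))
      o1 <- Biostrings::score(Biostrings::pairwiseAlignment(
        Biostrings::DNAString(r), g2,
        type = "local", substitutionMatrix = mat,
        gapOpening = 3, gapExtension = 1
      ))
      o2 <- Biostrings::score(Biostrings::pairwiseAlignment(
        Biostrings::reverseComplement(Biostrings::DNAString(r)), g2,
        type = "local", substitutionMatrix = mat,
        gapOpening = 3, gapExtension = 1
      ))
      expect_equal(mine, max(o1, o2), info = paste("case", i))
    }
  })
})

test_that("the seeded path agrees with exhaustive scanning", {
  run <- toy_run()
  idx <- withr::with_seed(8, sample.int(nrow(run$reads), 60L))
  seeded <- map_reads(run$reads[idx, ], run$genome, keep_unmapped = TRUE)
  full <- map_reads(run$reads[idx, ], run$genome,
    keep_unmapped = TRUE, full_scan = TRUE
  )
  expect_equal(seeded$score, full$score)
  expect_equal(seeded$pos, full$pos)
  expect_equal(seeded$cigar, full$cigar)
})

test_that("map_pairs writes valid SAM and an empty FASTQ gives header only", {
  run <- toy_run()
  toy <- toy_fixture()
  dir <- withr::local_tempdir()
  r1 <- file.path(dir, "r1.fastq")
  r2 <- file.path(dir, "r2.fastq")
  write_fastq_pair(run$sim$reads[1:50, ], r1, r2)
  sam <- file.path(dir, "aln.sam")
  mapped <- map_pairs(r1, r2, toy$genome, sam_out = sam)
  expect_true(file.exists(sam))
  lines <- readLines(sam)
  expect_true(any(grepl(
    sprintf("^@SQ\tSN:%s\tLN:%d", toy$genome$id, toy$genome$length), lines
  )))
  back <- read_sam(sam)
  expect_equal(nrow(back), nrow(mapped))
  expect_setequal(back$cigar, mapped$cigar)

  # noiseless reads map at identity 1.0
  expect_true(all(mapped$identity == 1))

  empty <- file.path(dir, "empty.fastq")
  writeLines(character(), empty)
  sam0 <- file.path(dir, "empty.sam")
  m0 <- map_pairs(empty, NULL, toy$genome, sam_out = sam0)
  expect_equal(nrow(m0), 0L)
  expect_true(all(startsWith(readLines(sam0), "@")))

  # mismatched pair lengths are a validation error
  expect_error(map_pairs(r1, empty, toy$genome), "mismatched")
})

test_that("coverage profile summarises depth per window and feature", {
  toy <- toy_fixture()
  one <- map_read(seq_slice1(toy$genome, 1L, 100L), toy$genome)
  prof <- coverage_profile(one, genome_length = toy$genome$length)
  expect_equal(prof$windows$mean[1], 1.0)
  expect_equal(prof$windows$max[1], 1L)
  expect_true(all(prof$windows$mean[-1] == 0))

  run <- toy_run()
  prof2 <- coverage_profile(run$mapped, ann = run$annotation)
  pcg <- prof2$features[prof2$features$ftype == "PCG" &
    prof2$features$strand == "H", ]
  # poly(A) enrichment: excised sense tRNAs lose coverage relative to
  # mRNA (antisense tRNAs retained inside long UTRs keep theirs)
  trna <- prof2$features[prof2$features$ftype == "tRNA" &
    prof2$features$strand == "H", ]
  expect_lt(max(trna$mean_depth), min(pcg$mean_depth))
  # bicistronic members show no coverage drop
  atp8 <- prof2$features$mean_depth[prof2$features$name == "atp8"]
  expect_gt(atp8, 0.5 * prof2$features$mean_depth[
    prof2$features$name == "atp6"
  ])
})
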
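#' Mapper acceptance parameters
#'
#' The acceptance contract for a mapped read: at least
#' `min_length_fraction` of the read aligned, at `min_similarity_fraction`
#' identity (both inclusive). Scoring is match/mismatch with affine
#' gaps (a gap of length L costs `gap_open + L * gap_extend`).
#'
#' @param min_length_fraction Minimum aligned-read-bases / read-length.
#' @param min_similarity_fraction Minimum matches / alignment columns.
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @return A list of class `mapper_params`.
#' @export
mapper_params <- function(min_length_fraction = 0.9,
                          min_similarity_fraction = 0.95,
                          match = 1L, mismatch = -2L,
                          gap_open = 3L, gap_extend = 1L) {
  stopifnot(
    min_length_fraction >= 0, min_length_fraction <= 1,
    min_similarity_fraction >= 0, min_similarity_fraction <= 1,
    gap_open >= 0, gap_extend >= 0
  )
  structure(
    list(
      min_length_fraction = min_length_fraction,
      min_similarity_fraction = min_similarity_fraction,
      match = as.integer(match), mismatch = as.integer(mismatch),
      gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend)
    ),
    class = "mapper_params"
  )
}

empty_mapped <- function() {
  tibble::tibble(
    read_id = character(), mate = integer(), strand = character(),
    pos = integer(), end_pos = integer(), cigar = character(),
    seq_fwd = character(), clip_left = character(), clip_right = character(),
    aligned_fraction = double(), identity = double(), score = integer()
  )
}

#' Map reads to a circular genome
#'
#' Aligns each read (and its reverse complement) against the genome,
#' extended across the origin by sequence doubling for circular
#' genomes; positions are reported modulo the genome length. Read
#' bases outside the aligned core become soft clips; records failing
#' either acceptance fraction are dropped. Ties are broken towards the
#' smallest genome start, then the forward strand.
#'
#' All sequences and clips in the result are reported in
#' genome-forward orientation (reverse-strand alignments store the
#' reverse complement of the read, as in SAM), so the genomic
#' left/right clip of a record is always `clip_left`/`clip_right`.
#'
#' @param reads A data frame with columns `read_id`, `seq` and
#'   optionally `mate` (1 or 2), or a character vector of sequences.
#' @param genome A [circular_genome()].
#' @param params A [mapper_params()].
#' @param keep_unmapped Keep threshold-failing reads (with `pos = NA`)?
#' @param full_scan Force exhaustive dynamic programming over the whole
#'   (doubled) genome instead of seeded windows.
#'
#' @return A tibble with one row per mapped read: `read_id`, `mate`,
#'   `strand` (`"+"`/`"-"`), `pos` (1-based first aligned base, wrapped),
#'   `end_pos` (may exceed the genome length for origin-spanning
#'   alignments; interpret modulo length), `cigar` (with soft clips),
#'   `seq_fwd`, `clip_left`, `clip_right`, `aligned_fraction`,
#'   `identity`, `score`.
#' @export
map_reads <- function(reads, genome, params = mapper_params(),
                      keep_unmapped = FALSE, full_scan = FALSE) {
  if (is.character(reads)) {
    reads <- tibble::tibble(
      read_id = paste0("read", seq_along(reads)), seq = reads
    )
  }
  reads <- tibble::as_tibble(reads)
  if (!"mate" %in% names(reads)) reads$mate <- 1L
  if (nrow(reads) == 0L) {
    return(empty_mapped())
  }
  seqs <- toupper(reads$seq)
  if (any(nchar(seqs) < 20L)) {
    stop("reads shorter than 20 bp are not mappable here", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("read sequences contain characters outside {A,C,G,T,N}",
      call. = FALSE
    )
  }
  res <- map_reads_cpp(
    seqs, genome$seq, genome$length,
    genome$topology == "circular",
    params$match, params$mismatch, params$gap_open, params$gap_extend,
    force_full_scan = full_scan
  )
  m <- nchar(seqs)
  aligned_bases <- res$qend - res$qstart + 1L
  oriented <- ifelse(res$strand == "-", revcomp(seqs), seqs)
  out <- tibble::tibble(
    read_id = reads$read_id,
    mate = as.integer(reads$mate),
    strand = res$strand,
    pos = res$gstart,
    end_pos = res$gend,
    cigar = res$cigar,
    seq_fwd = oriented,
    clip_left = substr(oriented, 1L, pmax(res$qstart - 1L, 0L)),
    clip_right = substr(oriented, pmax(res$qend, 0L) + 1L, m),
    aligned_fraction = aligned_bases / m,
    identity = ifelse(res$cols > 0L, res$matches / res$cols, 0),
    score = res$score
  ) |>
    dplyr::mutate(
      cigar = paste0(
        ifelse(nchar(.data$clip_left) > 0L,
          paste0(nchar(.data$clip_left), "S"), ""
        ),
        .data$cigar,
        ifelse(nchar(.data$clip_right) > 0L,
          paste0(nchar(.data$clip_right), "S"), ""
        )
      ),
      mapped = .data$score > 0L &
        .data$aligned_fraction + 1e-9 >= params$min_length_fraction &
        .data$identity + 1e-9 >= params$min_similarity_fraction
    )
  if (!keep_unmapped) {
    out <- out |> dplyr::filter(.data$mapped)
  } else {
    out <- out |>
      dplyr::mutate(pos = ifelse(.data$mapped, .data$pos, NA_integer_))
  }
  dplyr::select(out, -"mapped")
}

#' Map a single read
#'
#' Convenience wrapper over [map_reads()] for one sequence.
#'
#' @param read DNA string (length >= 20).
#' @param genome A [circular_genome()].
#' @inheritParams map_reads
#' @return One-row mapped tibble, or a zero-row tibble if the read
#'   fails the acceptance thresholds.
#' @export
map_read <- function(read, genome, params = mapper_params(),
                     full_scan = FALSE) {
  map_reads(
    tibble::tibble(read_id = "read1", seq = read),
    genome, params,
    full_scan = full_scan
  )
}

#' Map a FASTQ read pair to the genome and emit SAM
#'
#' Mates are mapped independently (the acceptance contract is
#' per-read; there is no pair rescue or insert-size filter).
#'
#' @param fastq_r1,fastq_r2 FASTQ paths (R2 optional, `NULL` for
#'   single-end).
#' @param genome A [circular_genome()].
#' @param params A [mapper_params()].
#' @param sam_out Optional path; when given, a SAM file with an `@SQ`
#'   header and soft-clipped records is written.
#' @return The mapped tibble (see [map_reads()]), invisibly carrying
#'   the SAM path in attribute `"sam"` when written.
#' @export
map_pairs <- function(fastq_r1, fastq_r2 = NULL, genome,
                      params = mapper_params(), sam_out = NULL) {
  r1 <- read_fastq(fastq_r1)
  r1$mate <- 1L
  reads <- r1
  if (!is.null(fastq_r2)) {
    r2 <- read_fastq(fastq_r2)
    r2$mate <- 2L
    if (nrow(r1) != nrow(r2)) {
      stop("mismatched FASTQ pair: ", nrow(r1), " vs ", nrow(r2), " reads",
        call. = FALSE
      )
    }
    reads <- dplyr::bind_rows(r1, r2)
  }
  mapped <- map_reads(reads, genome, params)
  if (!is.null(sam_out)) {
    write_sam(mapped, genome, sam_out)
    attr(mapped, "sam") <- sam_out
  }
  mapped
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Tibble with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(
    read_id = sub("\\s.*$", "", sub("/[12]$", "", names(x))),
    seq = as.character(x)
  )
}

# --- SAM ---------------------------------------------------------------

#' Write mapped reads as SAM
#'
#' Emits a spec-conformant SAM file with soft clips. Alignments that
#' extend across the circular origin keep POS near the genome end and
#' let the CIGAR consume past it; this modulo convention is stated in
#' an `@CO` header line.
#'
#' @param mapped Mapped tibble from [map_reads()].
#' @param genome The [circular_genome()] mapped against.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(mapped, genome, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$id, genome$length),
    "@PG\tID:mitotail\tPN:mitotail",
    paste0(
      "@CO\tcircular genome: alignments may consume past the reference ",
      "end; positions are interpreted modulo LN"
    )
  )
  if (nrow(mapped) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  pair_info <- mapped |>
    dplyr::group_by(.data$read_id) |>
    dplyr::mutate(n_mates = dplyr::n()) |>
    dplyr::ungroup()
  flags <- purrr::pmap_int(
    list(pair_info$mate, pair_info$strand, pair_info$n_mates),
    function(mate, strand, n_mates) {
      f <- 1L # paired
      if (strand == "-") f <- f + 16L
      f <- f + (if (mate == 1L) 64L else 128L)
      if (n_mates < 2L) f <- f + 8L # mate unmapped/absent
      f
    }
  )
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
    pair_info$read_id, flags, genome$id, pair_info$pos,
    pair_info$cigar, pair_info$seq_fwd
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

cigar_ops <- function(cigar) {
  m <- stringr::str_match_all(cigar, "([0-9]+)([MIDNSHP=X])")[[1]]
  tibble::tibble(len = as.integer(m[, 2]), op = m[, 3])
}

# genome positions consumed (M/D/N ops) by a CIGAR starting at pos
cigar_ref_span <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

#' Read a SAM file produced by [write_sam()]
#'
#' Reconstructs the mapped tibble (clips and end positions are derived
#' from CIGAR and SEQ). Only primary mapped records are returned.
#'
#' @param path SAM path.
#' @return Mapped tibble (without scores/fractions, which SAM does not
#'   carry).
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(empty_mapped()[, c(
      "read_id", "mate", "strand", "pos", "end_pos",
      "cigar", "seq_fwd", "clip_left", "clip_right"
    )])
  }
  fields <- stringr::str_split_fixed(lines, "\t", 12L)
  flag <- as.integer(fields[, 2])
  cigar <- fields[, 6]
  seqs <- fields[, 10]
  left_s <- as.integer(stringr::str_match(cigar, "^([0-9]+)S")[, 2])
  right_s <- as.integer(stringr::str_match(cigar, "([0-9]+)S$")[, 2])
  left_s[is.na(left_s)] <- 0L
  right_s[is.na(right_s)] <- 0L
  ref_span <- vapply(cigar, cigar_ref_span, integer(1), USE.NAMES = FALSE)
  pos <- as.integer(fields[, 4])
  tibble::tibble(
    read_id = fields[, 1],
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    pos = pos,
    end_pos = pos + ref_span - 1L,
    cigar = cigar,
    seq_fwd = seqs,
    clip_left = substr(seqs, 1L, left_s),
    clip_right = substr(seqs, nchar(seqs) - right_s + 1L, nchar(seqs))
  ) |>
    dplyr::filter(bitwAnd(flag, 4L) == 0L)
}

#' Coverage profile of mapped reads
#'
#' Per-position depth is computed from aligned (non-clipped) read
#' bases, wrapped around the circular origin, then summarised in
#' fixed-width windows (min/mean/max) and per annotated feature (mean
#' depth and the fraction of feature positions at or above
#' `threshold`).
#'
#' @param x Mapped tibble from [map_reads()] or a SAM path.
#' @param genome_length Genome length in bp (taken from `ann` if
#'   supplied).
#' @param ann Optional [annotation()] for per-feature summaries.
#' @param window Window size in bp (default 100).
#' @param threshold Depth threshold for the per-feature covered
#'   fraction (default 100).
#' @return An object of class `coverage_profile`: list with `depth`
#'   (integer vector), `windows` and `features` tibbles.
#' @export
coverage_profile <- function(x, genome_length = NULL, ann = NULL,
                             window = 100L, threshold = 100L) {
  if (is.character(x)) x <- read_sam(x)
  if (is.null(genome_length)) {
    if (is.null(ann)) {
      stop("supply genome_length or an annotation", call. = FALSE)
    }
    genome_length <- genome_length(ann)
  }
  len <- as.integer(genome_length)
  depth <- integer(len)
  for (i in seq_len(nrow(x))) {
    ops <- cigar_ops(x$cigar[i])
    gpos <- x$pos[i]
    for (k in seq_len(nrow(ops))) {
      if (ops$op[k] %in% c("M", "=", "X")) {
        span <- wrap1(seq.int(gpos, gpos + ops$len[k] - 1L), len)
        depth[span] <- depth[span] + 1L
        gpos <- gpos + ops$len[k]
      } else if (ops$op[k] %in% c("D", "N")) {
        gpos <- gpos + ops$len[k]
      }
    }
  }
  win_id <- ((seq_len(len) - 1L) %/% window) + 1L
  windows <- tibble::tibble(window = win_id, depth = depth) |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(
      start = (.data$window[1] - 1L) * !!window + 1L,
      end = min(.data$window[1] * !!window, len),
      min = min(.data$depth), mean = mean(.data$depth),
      max = max(.data$depth),
      .groups = "drop"
    )
  features <- NULL
  if (!is.null(ann)) {
    features <- ann |>
      dplyr::mutate(
        mean_depth = purrr::map2_dbl(
          .data$start, .data$end,
          ~ mean(depth[interval_positions(.x, .y, len)])
        ),
        frac_ge_threshold = purrr::map2_dbl(
          .data$start, .data$end,
          ~ mean(depth[interval_positions(.x, .y, len)] >= threshold)
        )
      ) |>
      dplyr::select(
        "name", "ftype", "strand", "start", "end",
        "mean_depth", "frac_ge_threshold"
      ) |>
      tibble::as_tibble()
  }
  structure(
    list(
      depth = depth, windows = windows, features = features,
      genome_length = len, window = as.integer(window),
      threshold = threshold
    ),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf(
    "<coverage_profile> %d bp, window %d bp, mean depth %.1f\n",
    x$genome_length, x$window, mean(x$depth)
  ))
  invisible(x)
}
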
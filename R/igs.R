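#' Derive intergenic sequences (IGS) from an annotation
#'
#' Returns every maximal run of genomic positions covered by no
#' annotated feature, wrap-aware, with the names of the flanking genes.
#' Each IGS is classified: runs at least `min_control_length` bp long
#' (or abutting an annotated control-region feature) are called
#' `control_region`; shorter runs whose sequence folds into a hairpin
#' with at least `min_stem` contiguous stem pairs (see
#' [stemloop_scan()]) are `OL_candidate`; the rest are
#' `short_noncoding`. Sequence-based classification needs `genome`;
#' without it every non-control run is `short_noncoding`.
#'
#' @param ann An [annotation()].
#' @param genome Optional [circular_genome()] matching the annotation.
#' @param ol_scan Scan candidate spacers for stem-loop capacity.
#' @param min_control_length Minimum length for the control-region call.
#' @param min_stem,min_loop Hairpin candidacy parameters passed to
#'   [stemloop_scan()].
#'
#' @return A tibble with columns `upstream_gene`, `downstream_gene`,
#'   `start`, `end` (1-based inclusive, wrap-aware), `length`,
#'   `igs_class`.
#' @export
derive_igs <- function(ann, genome = NULL, ol_scan = TRUE,
                       min_control_length = 100L,
                       min_stem = 5L, min_loop = 3L) {
  if (nrow(ann) == 0L) {
    stop("annotation is empty", call. = FALSE)
  }
  len <- genome_length(ann)
  covered <- logical(len)
  for (i in seq_len(nrow(ann))) {
    covered[interval_positions(ann$start[i], ann$end[i], len)] <- TRUE
  }
  if (all(covered)) {
    return(tibble::tibble(
      upstream_gene = character(), downstream_gene = character(),
      start = integer(), end = integer(), length = integer(),
      igs_class = character()
    ))
  }
  if (all(!covered)) {
    stop("annotation covers no genomic position", call. = FALSE)
  }
  # Maximal uncovered runs on the circle: find run starts (uncovered
  # position whose predecessor is covered), then extend.
  pred_covered <- covered[wrap1(seq_len(len) - 1L, len)]
  run_starts <- which(!covered & pred_covered)
  runs <- purrr::map(run_starts, function(s) {
    e <- s
    while (!covered[wrap1(e + 1L, len)]) e <- wrap1(e + 1L, len)
    c(start = s, end = e)
  })
  ends_at <- integer(len) # feature index by end position (last wins)
  starts_at <- integer(len)
  for (i in seq_len(nrow(ann))) {
    ends_at[ann$end[i]] <- i
    starts_at[ann$start[i]] <- i
  }
  out <- purrr::map_dfr(runs, function(r) {
    s <- r[["start"]]
    e <- r[["end"]]
    up_i <- ends_at[wrap1(s - 1L, len)]
    dn_i <- starts_at[wrap1(e + 1L, len)]
    tibble::tibble(
      upstream_gene = if (up_i > 0L) ann$name[up_i] else NA_character_,
      downstream_gene = if (dn_i > 0L) ann$name[dn_i] else NA_character_,
      start = s, end = e,
      length = interval_length(s, e, len)
    )
  })
  # Classification
  cr_features <- ann |> dplyr::filter(.data$ftype == "control_region")
  out$igs_class <- purrr::pmap_chr(
    out[, c("start", "end", "length")],
    function(start, end, length) {
      if (length >= min_control_length) {
        return("control_region")
      }
      abuts_cr <- nrow(cr_features) > 0L &&
        any(
          wrap1(cr_features$end + 1L, len) == start |
            wrap1(cr_features$start - 1L, len) == end
        )
      if (abuts_cr) {
        return("control_region")
      }
      if (ol_scan && !is.null(genome) && length >= 2L * min_stem + min_loop) {
        sl <- stemloop_scan(
          seq_slice1(genome, start, end),
          min_stem = min_stem, min_loop = min_loop
        )
        if (sl$candidate) {
          return("OL_candidate")
        }
      }
      "short_noncoding"
    }
  )
  dplyr::arrange(out, .data$start)
}

#' Find pairwise feature overlaps
#'
#' Every pair of annotated features sharing at least one genomic
#' position is reported with the overlap width and a geometry call:
#' same-strand overlaps where the upstream gene's 3' end reaches into
#' the downstream gene are `tail_to_head`; opposite-strand overlaps
#' with both 3' ends (or both 5' ends) inside the shared region are
#' `tail_to_tail` (`head_to_head`).
#'
#' @param ann An [annotation()].
#' @return A tibble with columns `gene_a`, `gene_b`, `overlap_bp`,
#'   `geometry`.
#' @export
find_overlaps <- function(ann) {
  len <- genome_length(ann)
  n <- nrow(ann)
  empty <- tibble::tibble(
    gene_a = character(), gene_b = character(),
    overlap_bp = integer(), geometry = character()
  )
  if (n < 2L) {
    return(empty)
  }
  pos_sets <- purrr::map(
    seq_len(n),
    ~ interval_positions(ann$start[.x], ann$end[.x], len)
  )
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- intersect(pos_sets[[i]], pos_sets[[j]])
      ov <- length(shared)
      if (ov == 0L) next
      a3 <- feature_3p(ann$strand[i], ann$start[i], ann$end[i])
      b3 <- feature_3p(ann$strand[j], ann$start[j], ann$end[j])
      a5 <- feature_5p(ann$strand[i], ann$start[i], ann$end[i])
      b5 <- feature_5p(ann$strand[j], ann$start[j], ann$end[j])
      if (ann$strand[i] == ann$strand[j]) {
        geometry <- "tail_to_head"
        # upstream gene first: its 3' end lies inside the partner
        a_upstream <- a3 %in% shared
        first <- if (a_upstream) i else j
        second <- if (a_upstream) j else i
      } else {
        geometry <- if (a3 %in% shared && b3 %in% shared) {
          "tail_to_tail"
        } else if (a5 %in% shared && b5 %in% shared) {
          "head_to_head"
        } else {
          "tail_to_head"
        }
        first <- i
        second <- j
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_a = ann$name[first], gene_b = ann$name[second],
        overlap_bp = ov, geometry = geometry
      )
    }
  }
  if (length(rows) == 0L) {
    return(empty)
  }
  dplyr::bind_rows(rows)
}

#' Write / read an IGS table as TSV
#'
#' Serialises the shape of the intergenic-sequence report: flanking
#' genes, 1-based position, length and class. Round-trips losslessly.
#'
#' @param records Tibble from [derive_igs()].
#' @param path Output path.
#' @return `path` invisibly; for the reader, the records tibble.
#' @export
write_igs_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_igs_table
#' @export
read_igs_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      upstream_gene = readr::col_character(),
      downstream_gene = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      length = readr::col_integer(),
      igs_class = readr::col_character()
    )
  )
}
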
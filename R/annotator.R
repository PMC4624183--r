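# Vertebrate mitochondrial translation: stop codons include the
# standard ochre/amber plus the AGR codons.
mt_stop_codons <- c("TAA", "TAG", "AGA", "AGG")

# Strand-oriented CDS sequence of a feature (coding strand, 5'->3').
cds_sequence <- function(gene_row, genome) {
  s <- seq_slice1(genome, gene_row$start, gene_row$end)
  if (gene_row$strand == "L") revcomp(s) else s
}

# Distance (bp, transcript orientation) from a gene's last genomic base
# to a site coordinate; 0 = site immediately follows the gene.
site_distance <- function(gene_row, site_position, len) {
  if (is.na(site_position)) {
    return(NA_integer_)
  }
  if (gene_row$strand == "H") {
    as.integer(circ_dist_fwd(gene_row$end + 1L, site_position, len))
  } else {
    as.integer(circ_dist_fwd(site_position, gene_row$start - 1L, len))
  }
}

#' Classify the stop codon of a protein-coding gene
#'
#' Reads the in-frame tail of the CDS under the vertebrate
#' mitochondrial code. A full terminal TAA/TAG/AGA/AGG is an encoded
#' stop. A CDS whose length leaves one (T) or two (TA) bases beyond
#' the last full codon is an incomplete stop: with a polyadenylation
#' site immediately following (distance 0) it is completed to TAA by
#' polyadenylation; without one it is unresolved.
#'
#' @param gene Gene name (must be a PCG in `ann`).
#' @param ann An [annotation()].
#' @param genome A [circular_genome()].
#' @param site_position Genomic coordinate of the assigned poly(A)
#'   site (first non-template base), or `NA`.
#' @return One-row tibble: `gene`, `genomic_suffix` (TAA/TAG/AGA/AGG/
#'   TA/T/other), `completed_codon`, `mechanism` (encoded/
#'   polyadenylation/unresolved), `polyA_distance`.
#' @export
classify_stop <- function(gene, ann, genome, site_position = NA) {
  len <- genome_length(ann)
  row <- ann[ann$name == gene & ann$ftype == "PCG", ]
  if (nrow(row) != 1L) {
    stop("'", gene, "' is not a unique PCG in the annotation", call. = FALSE)
  }
  row <- as.list(row[1, ])
  cds <- cds_sequence(row, genome)
  n <- nchar(cds)
  rem <- n %% 3L
  dist <- site_distance(row, site_position, len)
  if (rem == 0L) {
    last3 <- substr(cds, n - 2L, n)
    if (last3 %in% mt_stop_codons) {
      suffix <- last3
      completed <- last3
      mechanism <- "encoded"
    } else {
      suffix <- "other"
      completed <- NA_character_
      mechanism <- "unresolved"
    }
  } else if (rem == 1L) {
    if (substr(cds, n, n) != "T") {
      stop(
        "CDS of '", gene, "' has one base beyond the last full codon ",
        "but it is not T: frame-inconsistent annotation",
        call. = FALSE
      )
    }
    suffix <- "T"
    if (!is.na(dist) && dist == 0L) {
      completed <- "TAA"
      mechanism <- "polyadenylation"
    } else {
      completed <- NA_character_
      mechanism <- "unresolved"
    }
  } else {
    if (substr(cds, n - 1L, n) != "TA") {
      stop(
        "CDS of '", gene, "' has two bases beyond the last full codon ",
        "but they are not TA: frame-inconsistent annotation",
        call. = FALSE
      )
    }
    suffix <- "TA"
    if (!is.na(dist) && dist == 0L) {
      completed <- "TAA"
      mechanism <- "polyadenylation"
    } else {
      completed <- NA_character_
      mechanism <- "unresolved"
    }
  }
  tibble::tibble(
    gene = gene, genomic_suffix = suffix, completed_codon = completed,
    mechanism = mechanism, polyA_distance = dist
  )
}

#' Classify stop codons for all protein-coding genes
#'
#' @param assigned_sites Output of [assign_sites_to_genes()]; only
#'   passing sites are used, the strongest per gene.
#' @inheritParams classify_stop
#' @return Tibble with one row per PCG (see [classify_stop()]).
#' @export
classify_stops <- function(ann, genome, assigned_sites = NULL) {
  pcg <- ann |> dplyr::filter(.data$ftype == "PCG")
  best <- gene_best_sites(assigned_sites)
  purrr::map_dfr(pcg$name, function(g) {
    site <- best$position[match(g, best$gene)]
    classify_stop(g, ann, genome, site_position = site)
  })
}

# strongest passing site per gene
gene_best_sites <- function(assigned_sites) {
  if (is.null(assigned_sites) || nrow(assigned_sites) == 0L) {
    return(tibble::tibble(gene = character(), position = integer()))
  }
  assigned_sites |>
    dplyr::filter(.data$pass, !is.na(.data$gene)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$support, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "position")
}

#' Compute the 3' untranslated region of a gene
#'
#' The 3' UTR is the region between the last template-encoded stop
#' base and the poly(A) site, strand-aware; a site at distance 0 gives
#' an empty UTR. Opposite-strand features fully contained in the UTR
#' interval are listed (the source of long UTRs carrying antisense
#' genes).
#'
#' @param gene Gene name (a PCG).
#' @param site_position Genomic coordinate of the gene's poly(A) site.
#' @param ann An [annotation()].
#' @param genome A [circular_genome()].
#' @return One-row tibble: `gene`, `utr_length`, `utr_sequence`
#'   (transcript orientation), `contained_antisense_features`
#'   (comma-separated).
#' @export
call_utr <- function(gene, site_position, ann, genome) {
  len <- genome_length(ann)
  row <- ann[ann$name == gene & ann$ftype == "PCG", ]
  if (nrow(row) != 1L) {
    stop("'", gene, "' is not a unique PCG in the annotation", call. = FALSE)
  }
  row <- as.list(row[1, ])
  dist <- site_distance(row, site_position, len)
  if (is.na(dist)) {
    stop("no site supplied for '", gene, "'", call. = FALSE)
  }
  if (dist > len / 2) {
    stop(
      "site at ", site_position, " lies upstream of the stop codon of '",
      gene, "' (mis-assignment?)",
      call. = FALSE
    )
  }
  if (dist == 0L) {
    utr_seq <- ""
    utr_start <- NA_integer_
    utr_end <- NA_integer_
  } else if (row$strand == "H") {
    utr_start <- wrap1(row$end + 1L, len)
    utr_end <- wrap1(site_position - 1L, len)
    utr_seq <- seq_slice1(genome, utr_start, utr_end)
  } else {
    utr_start <- wrap1(site_position + 1L, len)
    utr_end <- wrap1(row$start - 1L, len)
    utr_seq <- revcomp(seq_slice1(genome, utr_start, utr_end))
  }
  contained <- character()
  if (dist > 0L) {
    utr_pos <- interval_positions(utr_start, utr_end, len)
    # the transcript's span: a tail-to-tail antisense gene may poke a
    # few bases into the host CDS and still be fully carried by the UTR
    span_pos <- c(interval_positions(row$start, row$end, len), utr_pos)
    anti <- ann |> dplyr::filter(.data$strand != row$strand)
    contained <- anti$name[purrr::map2_lgl(
      anti$start, anti$end,
      function(s, e) {
        p <- interval_positions(s, e, len)
        all(p %in% span_pos) && any(p %in% utr_pos)
      }
    )]
  }
  tibble::tibble(
    gene = gene,
    utr_length = dist,
    utr_sequence = utr_seq,
    contained_antisense_features = paste(contained, collapse = ",")
  )
}

#' Predict mature 3' ends from the tRNA punctuation model
#'
#' Under the punctuation model, mRNA ends are defined by excision of
#' the tRNAs from the polycistronic precursor: an H-strand gene's
#' mature 3' end is the base before the next H-strand (sense) tRNA
#' downstream; L-strand (antisense) features are transparent and end
#' up inside UTRs. The symmetric rule applies to the L-strand
#' precursor. A gene overlapping the next same-strand PCG tail-to-head
#' is predicted bicistronic and has no 3' end of its own.
#'
#' @param ann An [annotation()].
#' @return Tibble: `gene`, `strand`, `bicistronic_with` (downstream
#'   partner or `NA`), `predicted_end` (genomic coordinate of the
#'   predicted last template base; `NA` for bicistronic-upstream genes
#'   or when the strand has no sense tRNA), `predicted_utr` (bp from
#'   the gene's own last base to the predicted end).
#' @export
predict_punctuation_ends <- function(ann) {
  len <- genome_length(ann)
  pcg <- ann |> dplyr::filter(.data$ftype == "PCG")
  trna <- ann |> dplyr::filter(.data$ftype == "tRNA")
  ov <- find_overlaps(ann)
  purrr::map_dfr(seq_len(nrow(pcg)), function(i) {
    g <- as.list(pcg[i, ])
    partner <- ov |>
      dplyr::filter(
        .data$geometry == "tail_to_head",
        .data$gene_a == g$name,
        .data$gene_b %in% pcg$name
      )
    if (nrow(partner) > 0L) {
      return(tibble::tibble(
        gene = g$name, strand = g$strand,
        bicistronic_with = partner$gene_b[1],
        predicted_end = NA_integer_, predicted_utr = NA_integer_
      ))
    }
    sense_trna <- trna |> dplyr::filter(.data$strand == g$strand)
    if (nrow(sense_trna) == 0L) {
      return(tibble::tibble(
        gene = g$name, strand = g$strand, bicistronic_with = NA_character_,
        predicted_end = NA_integer_, predicted_utr = NA_integer_
      ))
    }
    if (g$strand == "H") {
      d <- circ_dist_fwd(g$end, wrap1(sense_trna$start - 1L, len), len)
      j <- which.min(d)
      pred <- wrap1(sense_trna$start[j] - 1L, len)
    } else {
      d <- circ_dist_fwd(wrap1(sense_trna$end + 1L, len), g$start, len)
      j <- which.min(d)
      pred <- wrap1(sense_trna$end[j] + 1L, len)
    }
    tibble::tibble(
      gene = g$name, strand = g$strand, bicistronic_with = NA_character_,
      predicted_end = pred, predicted_utr = as.integer(d[j])
    )
  })
}

#' Detect bicistronic transcripts
#'
#' Same-strand tail-to-head ORF-overlapping gene pairs where the
#' upstream ORF has no supported polyadenylation site between its end
#' and the downstream ORF's end are called bicistronic (evidence
#' `"both"`); pairs with a site in that window are reported but not
#' called (evidence `"orf_overlap"`).
#'
#' @param ann An [annotation()].
#' @param sites Site tibble from [aggregate_sites()].
#' @param min_support Minimum site support to count against a call.
#' @return Tibble: `upstream_gene`, `downstream_gene`, `overlap_bp`,
#'   `evidence`, `called`.
#' @export
detect_bicistronic <- function(ann, sites, min_support = 3L) {
  len <- genome_length(ann)
  pcg_names <- ann$name[ann$ftype == "PCG"]
  pairs <- find_overlaps(ann) |>
    dplyr::filter(
      .data$geometry == "tail_to_head",
      .data$gene_a %in% pcg_names,
      .data$gene_b %in% pcg_names
    )
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(
      upstream_gene = character(), downstream_gene = character(),
      overlap_bp = integer(), evidence = character(), called = logical()
    ))
  }
  strong <- sites |> dplyr::filter(.data$support >= min_support)
  purrr::pmap_dfr(pairs, function(gene_a, gene_b, overlap_bp, geometry) {
    up <- as.list(ann[ann$name == gene_a, ][1, ])
    dn <- as.list(ann[ann$name == gene_b, ][1, ])
    same <- strong |> dplyr::filter(.data$strand == up$strand)
    blocked <- FALSE
    if (nrow(same) > 0L) {
      if (up$strand == "H") {
        window_len <- circ_dist_fwd(up$end + 1L, dn$end, len)
        d <- circ_dist_fwd(up$end + 1L, same$position, len)
      } else {
        window_len <- circ_dist_fwd(dn$start, up$start - 1L, len)
        d <- circ_dist_fwd(same$position, up$start - 1L, len)
      }
      blocked <- any(d < window_len) # site strictly before downstream end
    }
    tibble::tibble(
      upstream_gene = gene_a, downstream_gene = gene_b,
      overlap_bp = overlap_bp,
      evidence = if (blocked) "orf_overlap" else "both",
      called = !blocked
    )
  })
}

#' Audit observed sites against the tRNA punctuation model
#'
#' Compares each protein-coding gene's observed polyadenylation site
#' with the punctuation-model prediction. A site whose transcript end
#' equals the predicted end conforms (with a UTR when the stop lies
#' upstream of the processing boundary); anything else is a deviation,
#' classified as a no-tRNA gene/gene junction, an IGS/gene boundary,
#' or other. Genes without a supported site are unresolved;
#' bicistronic-upstream genes conform when silent.
#'
#' @param assigned_sites Output of [assign_sites_to_genes()].
#' @param predictions Output of [predict_punctuation_ends()].
#' @param ann An [annotation()].
#' @return Tibble: `gene`, `strand`, `predicted_end`, `observed_site`,
#'   `observed_end`, `conformance`, `note`.
#' @export
check_punctuation_conformance <- function(assigned_sites, predictions, ann) {
  len <- genome_length(ann)
  best <- gene_best_sites(assigned_sites)
  covered <- logical(len)
  for (i in seq_len(nrow(ann))) {
    covered[interval_positions(ann$start[i], ann$end[i], len)] <- TRUE
  }
  purrr::pmap_dfr(predictions, function(gene, strand, bicistronic_with,
                                        predicted_end, predicted_utr) {
    site <- best$position[match(gene, best$gene)]
    observed_end <- if (is.na(site)) {
      NA_integer_
    } else if (strand == "H") {
      wrap1(site - 1L, len)
    } else {
      wrap1(site + 1L, len)
    }
    if (!is.na(bicistronic_with)) {
      conf <- if (is.na(site)) "conforms" else "deviation"
      note <- if (is.na(site)) {
        paste0("bicistronic with ", bicistronic_with)
      } else {
        "unexpected site on bicistronic-upstream gene"
      }
    } else if (is.na(site)) {
      conf <- "unresolved"
      note <- "no supported polyadenylation site"
    } else if (!is.na(predicted_end) && observed_end == predicted_end) {
      g <- as.list(ann[ann$name == gene, ][1, ])
      own_end <- feature_3p(g$strand, g$start, g$end)
      conf <- if (observed_end == own_end) "conforms" else "conforms_with_UTR"
      note <- ""
    } else {
      conf <- "deviation"
      # classify the junction at the observed transcript end
      nxt <- if (strand == "H") wrap1(site, len) else wrap1(site, len)
      at_feature_start <- any(
        ann$start == nxt & ann$strand == "H" |
          ann$end == nxt & ann$strand == "L"
      )
      end_in_igs <- !covered[observed_end]
      note <- if (at_feature_start && end_in_igs) {
        "IGS/gene boundary"
      } else if (at_feature_start) {
        "gene/gene junction without tRNA"
      } else {
        "other"
      }
    }
    tibble::tibble(
      gene = gene, strand = strand,
      predicted_end = predicted_end, observed_site = site,
      observed_end = observed_end, conformance = conf, note = note
    )
  })
}

# --- stem-loop scan ----------------------------------------------------

sl_pair_score <- function(a, b) {
  key <- paste0(a, b)
  switch(key,
    "GC" = 3L, "CG" = 3L,
    "AT" = 2L, "TA" = 2L,
    "GT" = 1L, "TG" = 1L,
    0L
  )
}

#' Scan a sequence for its best hairpin (stem-loop)
#'
#' Exhaustively evaluates all contiguous-stem hairpins with loop
#' length at least `min_loop`, scoring stems by a weighted pair count
#' (GC = 3, AT = 2, GU = 1; DNA alphabet, so GU appears as GT). The
#' maximum-score hairpin is returned; candidacy requires at least
#' `min_stem` stem pairs. This is a structural capacity screen, not a
#' thermodynamic folding model.
#'
#' @param sequence DNA string (the spacer to scan).
#' @param min_stem Minimum stem pairs for candidacy (default 5).
#' @param min_loop Minimum loop length in nt (default 3).
#' @return Object of class `stemloop_result`: list with `sequence`,
#'   `stem_pairs`, `loop_length`, `score`, `stem_start`, `stem_end`
#'   (outermost paired positions, 1-based), `candidate`, `dotbracket`.
#' @export
stemloop_scan <- function(sequence, min_stem = 5L, min_loop = 3L) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  best <- list(
    sequence = sequence, stem_pairs = 0L, loop_length = NA_integer_,
    score = 0L, stem_start = NA_integer_, stem_end = NA_integer_,
    candidate = FALSE, dotbracket = strrep(".", n)
  )
  if (n >= min_loop + 2L) {
    for (a in 2:(n - min_loop)) { # innermost pair: (a-1, b+1), loop a..b
      for (b in (a + min_loop - 1L):(n - 1L)) {
        i <- a - 1L
        j <- b + 1L
        pairs <- 0L
        score <- 0L
        while (i >= 1L && j <= n) {
          w <- sl_pair_score(s[i], s[j])
          if (w == 0L) break
          pairs <- pairs + 1L
          score <- score + w
          i <- i - 1L
          j <- j + 1L
        }
        if (pairs > 0L && score > best$score) {
          best$stem_pairs <- pairs
          best$score <- score
          best$loop_length <- b - a + 1L
          best$stem_start <- i + 1L
          best$stem_end <- j - 1L
        }
      }
    }
  }
  if (best$stem_pairs > 0L) {
    db <- rep(".", n)
    k <- best$stem_pairs
    db[best$stem_start:(best$stem_start + k - 1L)] <- "("
    db[(best$stem_end - k + 1L):best$stem_end] <- ")"
    best$dotbracket <- paste(db, collapse = "")
    best$candidate <- best$stem_pairs >= min_stem
  }
  structure(best, class = "stemloop_result")
}

#' @export
print.stemloop_result <- function(x, ...) {
  cat(sprintf(
    "<stemloop_result> %d nt: %d stem pairs, loop %s nt, score %d%s\n",
    nchar(x$sequence), x$stem_pairs,
    ifelse(is.na(x$loop_length), "-", x$loop_length), x$score,
    if (x$candidate) " (candidate)" else ""
  ))
  cat(x$sequence, "\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}
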
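#' Simulation configuration
#'
#' Parameters of the synthetic mitochondrial transcriptome generator.
#' The default layout (see [default_layout()]) packs the archetypes of
#' a mammalian mitogenome into a few kilobases: genes with incomplete
#' (T / TA) stops punctuated by sense tRNAs, two bicistronic pairs
#' with 43- and 7-bp tail-to-head ORF overlaps, an abutting gene pair
#' with no intervening tRNA, a light-strand gene overlapping
#' tail-to-tail by 4 bp whose antisense sits in a long 3' UTR, a
#' 31-bp palindromic spacer inside a light-strand tRNA cluster, and a
#' long control-region-like block.
#'
#' @param seed Integer seed; every random choice in the generator is
#'   derived from it.
#' @param layout Gene plan tibble (see [default_layout()]).
#' @param tail_mean,tail_min Poly(A) tail length model: truncated
#'   geometric with this mean and minimum.
#' @param read_length Read length in bp.
#' @param insert_range Fragment size range in bp (size selection).
#' @param error_rate Per-base substitution error rate.
#' @param depth Mean coverage of polyadenylated transcripts.
#' @param leak_fraction Fraction of nominal depth at which
#'   non-polyadenylated transcripts leak through poly(A) enrichment.
#' @param precursor_fraction Fraction of fragments drawn from the
#'   unprocessed polycistronic precursor.
#' @param deplete_A_after_sites Make the 3 genomic bases immediately
#'   downstream of each true poly(A) site non-A (the default), so that
#'   called site coordinates are unambiguous; set to `FALSE` to force
#'   genomic A runs there and exercise the aligner's template-maximal
#'   tie-break.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       layout = default_layout(),
                       tail_mean = 30, tail_min = 3L,
                       read_length = 100L,
                       insert_range = c(250L, 400L),
                       error_rate = 0.002,
                       depth = 200,
                       leak_fraction = 0.05,
                       precursor_fraction = 0.10,
                       deplete_A_after_sites = TRUE) {
  stopifnot(
    tail_min >= 1, tail_mean > tail_min,
    length(insert_range) == 2L, insert_range[1] <= insert_range[2],
    error_rate >= 0, error_rate < 1, depth > 0,
    leak_fraction >= 0, leak_fraction <= 1,
    precursor_fraction >= 0, precursor_fraction < 1
  )
  structure(
    list(
      seed = as.integer(seed), layout = layout,
      tail_mean = tail_mean, tail_min = as.integer(tail_min),
      read_length = as.integer(read_length),
      insert_range = as.integer(insert_range),
      error_rate = error_rate, depth = depth,
      leak_fraction = leak_fraction,
      precursor_fraction = precursor_fraction,
      deplete_A_after_sites = deplete_A_after_sites
    ),
    class = "sim_config"
  )
}

#' Default synthetic gene plan
#'
#' Ordered gene plan of the toy mitogenome. `gap_after` is the
#' intergenic spacer after the feature (`gap_kind` selects random
#' sequence, the palindromic stem-loop insert, or the control-region
#' block); `overlap_next` shifts the next feature back to create a
#' tail-to-head (or, for the light-strand gene, tail-to-tail) overlap.
#'
#' @return Layout tibble.
#' @export
default_layout <- function() {
  tibble::tribble(
    ~name, ~ftype, ~strand, ~length, ~stop_mode, ~gap_after, ~gap_kind, ~overlap_next,
    "trnF", "tRNA", "H", 60L, NA, 0L, "random", 0L,
    "rrnS", "rRNA", "H", 150L, NA, 0L, "random", 0L,
    "trnV", "tRNA", "H", 60L, NA, 0L, "random", 0L,
    "nad1", "PCG", "H", 301L, "incomplete_T", 0L, "random", 0L,
    "trnI", "tRNA", "H", 60L, NA, 0L, "random", 0L,
    "trnQ", "tRNA", "L", 60L, NA, 0L, "random", 0L,
    "trnM", "tRNA", "H", 60L, NA, 0L, "random", 0L,
    "nad2", "PCG", "H", 300L, "full_TAA", 2L, "random", 0L,
    "trnW", "tRNA", "H", 60L, NA, 1L, "random", 0L,
    "trnA", "tRNA", "L", 60L, NA, 2L, "random", 0L,
    "trnN", "tRNA", "L", 60L, NA, 31L, "stemloop", 0L,
    "trnC", "tRNA", "L", 60L, NA, 0L, "random", 0L,
    "trnY", "tRNA", "L", 60L, NA, 1L, "random", 0L,
    "cox1", "PCG", "H", 300L, "full_TAA", 0L, "random", 0L,
    "trnS2", "tRNA", "L", 66L, NA, 3L, "random", 0L,
    "trnD", "tRNA", "H", 60L, NA, 1L, "random", 0L,
    "cox2", "PCG", "H", 300L, "full_TAA", 3L, "random", 0L,
    "trnK", "tRNA", "H", 60L, NA, 0L, "random", 0L,
    "atp8", "PCG", "H", 150L, "bicistronic_upstream", 0L, "random", 43L,
    "atp6", "PCG", "H", 302L, "incomplete_TA", 0L, "random", 0L,
    "cox3", "PCG", "H", 301L, "incomplete_T", 0L, "random", 0L,
    "trnG", "tRNA", "H", 60L, NA, 0L, "random", 0L,
    "nad3", "PCG", "H", 300L, "full_TAA", 1L, "random", 0L,
    "trnR", "tRNA", "H", 60L, NA, 3L, "random", 0L,
    "nad4l", "PCG", "H", 150L, "bicistronic_upstream", 0L, "random", 7L,
    "nad4", "PCG", "H", 301L, "incomplete_T", 0L, "random", 0L,
    "trnH", "tRNA", "H", 60L, NA, 0L, "random", 0L,
    "nad5", "PCG", "H", 300L, "full_TAA", 0L, "random", 4L,
    "nad6", "PCG", "L", 150L, "full_TAA", 0L, "random", 0L,
    "trnE", "tRNA", "L", 60L, NA, 5L, "random", 0L,
    "cob", "PCG", "H", 300L, "full_TAA", 2L, "random", 0L,
    "trnT", "tRNA", "H", 60L, NA, 0L, "random", 0L,
    "trnP", "tRNA", "L", 60L, NA, 500L, "control", 0L
  )
}

layout_coordinates <- function(layout) {
  n <- nrow(layout)
  start <- integer(n)
  end <- integer(n)
  cursor <- 1L
  for (i in seq_len(n)) {
    start[i] <- cursor
    end[i] <- cursor + layout$length[i] - 1L
    cursor <- end[i] + 1L + layout$gap_after[i] - layout$overlap_next[i]
  }
  list(start = start, end = end, genome_length = cursor - 1L)
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random codons avoiding vertebrate-mito stop codons, as one string
random_codons <- function(n_codons) {
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- random_bases(3L)
      if (!cod %in% mt_stop_codons) break
    }
    out[i] <- cod
  }
  paste(out, collapse = "")
}

codons_of <- function(s, frame_offset = 0L) {
  s <- substr(s, frame_offset + 1L, nchar(s))
  n <- nchar(s) %/% 3L
  if (n == 0L) {
    return(character())
  }
  substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

# Coding-strand CDS for a gene given its stop mode. Lengths must
# satisfy length %% 3 == 0 (full stops), 1 (T) or 2 (TA).
build_cds <- function(length, stop_mode) {
  body_start <- "ATG"
  suffix <- switch(stop_mode,
    full_TAA = "TAA", full_TAG = "TAG",
    bicistronic_upstream = "TAA",
    incomplete_T = "T", incomplete_TA = "TA"
  )
  n_body <- (length - nchar(body_start) - nchar(suffix)) / 3L
  if (n_body != floor(n_body) || n_body < 1) {
    stop(
      "CDS length ", length, " incompatible with stop mode ", stop_mode,
      call. = FALSE
    )
  }
  paste0(body_start, random_codons(n_body), suffix)
}

# Force the last four coding bases to "TTAA" (stop TAA preceded by a
# codon ending in T); safe because no vertebrate-mito stop ends in T.
force_last4_ttaa <- function(cds) {
  n <- nchar(cds)
  paste0(substr(cds, 1L, n - 4L), "TTAA")
}

#' Build the toy circular genome and its annotation
#'
#' Deterministic for a given config seed. The genome sequence honours
#' every layout constraint: in-frame stop-free ORFs (vertebrate
#' mitochondrial code), pinned stop codons of bicistronic-upstream
#' genes inside the downstream ORF's sequence, the 4-bp tail-to-tail
#' palindromic junction of the heavy/light gene pair, the palindromic
#' stem-loop spacer, and (by default) A-depletion of the 3 bases
#' immediately downstream of every true polyadenylation site.
#'
#' @param config A [sim_config()].
#' @param genome_id Identifier for the generated genome.
#' @return List with elements `genome` (a [circular_genome()]) and
#'   `annotation` (an [annotation()]).
#' @export
build_toy_genome <- function(config = sim_config(), genome_id = "toy_mtDNA") {
  layout <- config$layout
  coords <- layout_coordinates(layout)
  L <- coords$genome_length
  layout$start <- coords$start
  layout$end <- coords$end
  if (any(layout$end > L) || any(layout$start < 1L)) {
    stop("layout cannot be packed into the genome", call. = FALSE)
  }
  ann <- annotation(
    layout[, c("name", "ftype", "strand", "start", "end")],
    genome_id = genome_id, genome_length = L
  )

  withr::with_seed(config$seed, {
    seq_chars <- rep(NA_character_, L)
    put <- function(start, end, s, strand = "H") {
      if (strand == "L") s <- revcomp(s)
      stopifnot(nchar(s) == end - start + 1L)
      seq_chars[start:end] <<- strsplit(s, "")[[1]]
    }
    get_region <- function(start, end) {
      paste(seq_chars[start:end], collapse = "")
    }
    row_of <- function(name) as.list(layout[layout$name == name, ][1, ])

    # 1. tRNA and rRNA features
    for (i in which(layout$ftype %in% c("tRNA", "rRNA"))) {
      put(
        layout$start[i], layout$end[i],
        random_bases(layout$length[i]), layout$strand[i]
      )
    }
    # 2. plain PCGs (no overlap constraints)
    overlap_upstream <- layout$name[layout$overlap_next > 0L]
    overlap_downstream <- layout$name[
      c(FALSE, utils::head(layout$overlap_next, -1) > 0L)
    ]
    plain <- layout$ftype == "PCG" &
      !layout$name %in% c(overlap_upstream, overlap_downstream)
    for (i in which(plain)) {
      put(
        layout$start[i], layout$end[i],
        build_cds(layout$length[i], layout$stop_mode[i]),
        layout$strand[i]
      )
    }
    # 3. bicistronic pairs: downstream gene first with pinned codons
    # placing the upstream gene's TAA in the shifted frame, then the
    # upstream body; resample until the shifted frame is stop-free.
    build_bicistronic_pair <- function(up_name, dn_name, ov) {
      up <- row_of(up_name)
      dn <- row_of(dn_name)
      stopifnot(ov %% 3L == 1L) # layout uses 43 and 7
      repeat {
        dn_seq <- build_cds(dn$length, dn$stop_mode)
        # pin bases (ov-2)..ov to TAA (the upstream ORF's stop in its
        # shifted frame) and the two following bases to CT so the host
        # frame stays stop-free around the pin
        pre <- substr(dn_seq, 1L, ov - 3L)
        post <- substr(dn_seq, ov + 3L, dn$length)
        cand <- paste0(pre, "TAACT", post)
        cand <- substr(cand, 1L, dn$length)
        # ensure host frame still stop-free and ends correctly
        host_ok <- !any(codons_of(substr(
          cand, 4L, dn$length - nchar_suffix(dn$stop_mode)
        )) %in% mt_stop_codons)
        shifted <- codons_of(substr(cand, 2L, ov))
        up_ok <- !any(utils::head(shifted, -1) %in% mt_stop_codons) &&
          shifted[length(shifted)] == "TAA"
        if (host_ok && up_ok) {
          put(dn$start, dn$end, cand, dn$strand)
          break
        }
      }
      # upstream body: random codons ending with "CC" filler so the
      # codon spanning into the overlap cannot form a stop
      body_len <- up$length - ov
      stopifnot(body_len %% 3L == 2L)
      body <- paste0("ATG", random_codons((body_len - 5L) / 3L), "CC")
      put(up$start, up$start + body_len - 1L, body, up$strand)
      # consistency: upstream shifted frame across the junction
      junction <- paste0(
        substr(body, body_len - 1L, body_len),
        substr(get_region(dn$start, dn$start), 1L, 1L)
      )
      stopifnot(!junction %in% mt_stop_codons)
    }
    build_bicistronic_pair("atp8", "atp6", 43L)
    build_bicistronic_pair("nad4l", "nad4", 7L)

    # 4. tail-to-tail heavy/light pair: shared 4-bp junction "TTAA"
    nad5 <- row_of("nad5")
    nad6 <- row_of("nad6")
    put(
      nad5$start, nad5$end,
      force_last4_ttaa(build_cds(nad5$length, nad5$stop_mode)), "H"
    )
    nad6_seq <- force_last4_ttaa(build_cds(nad6$length, nad6$stop_mode))
    # nad6 is L-strand: its genomic image starts with revcomp("TTAA")
    # == "TTAA", which is exactly what nad5 wrote at the shared bases.
    put(nad6$start + 4L, nad6$end, substr(nad6_seq, 1L, nad6$length - 4L), "L")
    stopifnot(get_region(nad6$start, nad6$start + 3L) == "TTAA")

    # 5. spacers
    for (i in seq_len(nrow(layout))) {
      gap <- layout$gap_after[i] - 0L
      if (gap <= 0L) next
      gs <- layout$end[i] + 1L
      ge <- gs + gap - 1L
      gseq <- if (layout$gap_kind[i] == "stemloop") {
        stem <- random_bases(12L)
        paste0(stem, random_bases(gap - 24L), revcomp(stem))
      } else {
        random_bases(gap)
      }
      # spacers may be partially covered by a shifted next feature on
      # overlap rows; only fill still-empty positions
      fill <- gs:ge
      fill <- fill[fill <= L & is.na(seq_chars[fill])]
      if (length(fill) > 0L) {
        seq_chars[fill] <- strsplit(gseq, "")[[1]][seq_along(fill)]
      }
    }
    if (anyNA(seq_chars)) {
      seq_chars[is.na(seq_chars)] <- sample(
        c("A", "C", "G", "T"), sum(is.na(seq_chars)),
        replace = TRUE
      )
    }

    # 6. A-depletion (or A-forcing) just downstream of true sites
    truth <- truth_polya_sites(ann)
    for (s in truth$site_position[truth$strand == "H"]) {
      span <- wrap1(s + 0:2, L)
      if (config$deplete_A_after_sites) {
        is_a <- seq_chars[span] == "A"
        seq_chars[span[is_a]] <- sample(
          c("C", "G", "T"), sum(is_a),
          replace = TRUE
        )
        # a rewritten PCG start codon becomes GTG
        hit <- which(layout$ftype == "PCG" & layout$start %in% span)
        for (h in hit) {
          if (layout$strand[h] == "H") {
            seq_chars[layout$start[h] + 0:2] <- c("G", "T", "G")
          }
        }
      } else {
        seq_chars[span] <- "A"
      }
    }

    genome <- circular_genome(
      genome_id, paste(seq_chars, collapse = ""), "circular"
    )
    list(genome = genome, annotation = ann)
  })
}

nchar_suffix <- function(stop_mode) {
  switch(stop_mode,
    incomplete_T = 1L, incomplete_TA = 2L, 3L
  )
}

# --- processing: tRNA punctuation with archetype exceptions ------------

# Cut positions (starts of downstream pieces) inside inter-tRNA
# fragments: a heavy-strand PCG preceded in its fragment by another
# heavy-strand PCG that does NOT overlap it gets its own cleavage site
# at its start (the atp6/cox3-type junction and the IGS/gene-boundary
# junction archetypes).
extra_cut_starts <- function(ann) {
  len <- genome_length(ann)
  pcg <- ann |> dplyr::filter(.data$ftype == "PCG", .data$strand == "H")
  trna <- ann |> dplyr::filter(.data$ftype == "tRNA", .data$strand == "H")
  if (nrow(pcg) < 2L) {
    return(integer())
  }
  cuts <- integer()
  for (i in seq_len(nrow(pcg))) {
    g <- as.list(pcg[i, ])
    others <- pcg[pcg$name != g$name, ]
    d_up <- circ_dist_fwd(others$end, g$start - 1L, len)
    t_up <- if (nrow(trna) > 0L) {
      min(circ_dist_fwd(trna$end, g$start - 1L, len))
    } else {
      len
    }
    # an upstream, non-overlapping H PCG closer than the nearest
    # upstream H tRNA?
    ov_with_g <- purrr::map_lgl(seq_len(nrow(others)), function(k) {
      length(intersect(
        interval_positions(others$start[k], others$end[k], len),
        interval_positions(g$start, g$end, len)
      )) > 0L
    })
    if (any(d_up < t_up & !ov_with_g)) {
      cuts <- c(cuts, g$start)
    }
  }
  sort(unique(cuts))
}

#' Process the synthetic precursor into mature transcripts
#'
#' Applies the tRNA punctuation model to the heavy-strand precursor:
#' cleavage at every heavy-strand (sense) tRNA boundary — light-strand
#' tRNAs are transparent and stay inside mRNAs as antisense sequence —
#' plus the archetype exceptions (a cleavage site at the start of a
#' heavy-strand gene directly preceded by another heavy-strand gene
#' without an intervening tRNA and without ORF overlap). Pieces
#' containing at least one protein-coding gene become mRNAs;
#' overlapping pairs come out as a single bicistronic transcript.
#' Every heavy-strand mRNA receives a poly(A) tail drawn from the
#' truncated-geometric tail model; light-strand mRNAs are emitted
#' untailed (no stable poly(A) site).
#'
#' @param genome A [circular_genome()] from [build_toy_genome()].
#' @param ann The matching [annotation()].
#' @param config A [sim_config()].
#' @return Tibble of mature transcripts: `name`, `gene_names`
#'   (comma-separated), `genome_start`, `genome_end` (1-based template
#'   interval, wrap-aware), `strand`, `tail_length`, `sequence`
#'   (transcript orientation, tail included).
#' @export
transcribe_and_process <- function(genome, ann, config = sim_config()) {
  len <- genome_length(ann)
  pieces <- processing_pieces(ann)
  withr::with_seed(config$seed + 1L, {
    purrr::pmap_dfr(pieces, function(start, end, strand, gene_names, tailed) {
      tail_length <- if (tailed) {
        rtrunc_geom(1L, config$tail_mean, config$tail_min)
      } else {
        0L
      }
      body <- seq_slice1(genome, start, end)
      if (strand == "L") body <- revcomp(body)
      tibble::tibble(
        name = gsub(",", "_", gene_names),
        gene_names = gene_names,
        genome_start = start, genome_end = end, strand = strand,
        tail_length = tail_length,
        sequence = paste0(body, strrep("A", tail_length))
      )
    })
  })
}

# mature-transcript template intervals implied by the annotation alone
processing_pieces <- function(ann) {
  len <- genome_length(ann)
  h_trna <- ann |>
    dplyr::filter(.data$ftype == "tRNA", .data$strand == "H") |>
    dplyr::arrange(.data$start)
  pcg <- ann |> dplyr::filter(.data$ftype == "PCG")
  h_pcg <- pcg |> dplyr::filter(.data$strand == "H")
  cuts <- extra_cut_starts(ann)

  frags <- if (nrow(h_trna) == 0L) {
    tibble::tibble(start = 1L, span = len)
  } else {
    n <- nrow(h_trna)
    purrr::map_dfr(seq_len(n), function(i) {
      nxt <- if (i == n) 1L else i + 1L
      span <- circ_dist_fwd(h_trna$end[i], h_trna$start[nxt], len) - 1L
      tibble::tibble(start = wrap1(h_trna$end[i] + 1L, len), span = span)
    }) |>
      dplyr::filter(.data$span > 0L)
  }

  out <- list()
  for (i in seq_len(nrow(frags))) {
    fs <- frags$start[i]
    span <- frags$span[i]
    offs <- circ_dist_fwd(fs, cuts, len)
    offs <- sort(offs[offs > 0L & offs < span])
    bounds <- c(0L, offs, span)
    for (b in seq_len(length(bounds) - 1L)) {
      ps <- wrap1(fs + bounds[b], len)
      pe <- wrap1(fs + bounds[b + 1L] - 1L, len)
      plen <- bounds[b + 1L] - bounds[b]
      in_piece <- circ_dist_fwd(ps, h_pcg$end, len) < plen
      if (!any(in_piece)) next
      genes <- h_pcg$name[in_piece]
      # order genes along the piece
      genes <- genes[order(circ_dist_fwd(ps, h_pcg$end[in_piece], len))]
      out[[length(out) + 1L]] <- tibble::tibble(
        start = ps, end = pe, strand = "H",
        gene_names = paste(genes, collapse = ","), tailed = TRUE
      )
    }
  }
  # light-strand mRNAs: ORF span only, no stable poly(A) site
  l_pcg <- pcg |> dplyr::filter(.data$strand == "L")
  for (i in seq_len(nrow(l_pcg))) {
    out[[length(out) + 1L]] <- tibble::tibble(
      start = l_pcg$start[i], end = l_pcg$end[i], strand = "L",
      gene_names = l_pcg$name[i], tailed = FALSE
    )
  }
  dplyr::bind_rows(out)
}

#' True polyadenylation sites implied by an annotation
#'
#' The processing model (see [transcribe_and_process()]) determines
#' each tailed transcript's last template base; the true site is the
#' position immediately 3' of it.
#'
#' @param ann An [annotation()].
#' @return Tibble: `transcript`, `gene_names`, `strand`,
#'   `site_position`, `utr_length` (distance from the 3'-most gene's
#'   last base), `bicistronic`.
#' @export
truth_polya_sites <- function(ann) {
  len <- genome_length(ann)
  pieces <- processing_pieces(ann) |> dplyr::filter(.data$tailed)
  purrr::pmap_dfr(pieces, function(start, end, strand, gene_names, tailed) {
    genes <- strsplit(gene_names, ",")[[1]]
    last_gene <- genes[length(genes)]
    g <- as.list(ann[ann$name == last_gene, ][1, ])
    site <- wrap1(end + 1L, len)
    tibble::tibble(
      transcript = gsub(",", "_", gene_names),
      gene_names = gene_names, strand = strand,
      site_position = site,
      utr_length = as.integer(circ_dist_fwd(g$end + 1L, site, len)),
      bicistronic = length(genes) > 1L
    )
  })
}

# truncated geometric tail lengths: min + geometric with mean - min
rtrunc_geom <- function(n, mean, min) {
  p <- 1 / (mean - min + 1)
  as.integer(min + stats::rgeom(n, p))
}

#' Simulate poly(A)-enriched paired-end reads
#'
#' Fragments are drawn from mature transcripts (tails included) with
#' insert sizes from the configured range; only polyadenylated
#' transcripts are sampled at full depth, untailed ones at the
#' leak-through fraction, and a configurable fraction of fragments
#' comes from the unprocessed heavy-strand precursor (the whole
#' circle). Substitution errors are applied at the configured rate;
#' mate orientation is FR.
#'
#' @param transcripts Tibble from [transcribe_and_process()].
#' @param genome The [circular_genome()] (precursor source).
#' @param config A [sim_config()].
#' @return List with `reads` (tibble: `read_id`, `seq1`, `seq2`) and
#'   `truth` (per-read tibble: source transcript, template interval in
#'   transcript coordinates, tail bases contained in the fragment).
#' @export
simulate_reads <- function(transcripts, genome, config = sim_config()) {
  stopifnot(nrow(transcripts) > 0L)
  rl <- config$read_length
  withr::with_seed(config$seed + 2L, {
    frag_rows <- list()
    for (i in seq_len(nrow(transcripts))) {
      t <- as.list(transcripts[i, ])
      mol_len <- nchar(t$sequence)
      scale <- if (t$tail_length > 0L) 1 else config$leak_fraction
      n_pairs <- round(
        config$depth * scale * (mol_len - t$tail_length) / (2 * rl)
      )
      if (n_pairs < 1L) next
      inserts <- pmin(
        sample(config$insert_range[1]:config$insert_range[2], n_pairs,
          replace = TRUE
        ),
        mol_len
      )
      starts <- purrr::map_int(
        inserts, ~ sample.int(mol_len - .x + 1L, 1L)
      )
      ends <- starts + inserts - 1L
      frag_rows[[length(frag_rows) + 1L]] <- tibble::tibble(
        source = t$name,
        frag = substring(t$sequence, starts, ends),
        template_start = starts,
        template_end = pmin(ends, mol_len - t$tail_length),
        tail_bases = pmax(0L, ends - (mol_len - t$tail_length))
      )
    }
    frags <- dplyr::bind_rows(frag_rows)
    # precursor background from the unprocessed heavy-strand circle
    n_prec <- round(
      config$precursor_fraction * nrow(frags) / (1 - config$precursor_fraction)
    )
    if (n_prec > 0L) {
      inserts <- sample(config$insert_range[1]:config$insert_range[2],
        n_prec,
        replace = TRUE
      )
      starts <- sample.int(genome$length, n_prec, replace = TRUE)
      frag <- purrr::map2_chr(
        starts, inserts,
        ~ seq_slice(genome, .x - 1L, wrap1(.x + .y - 1L, genome$length))
      )
      frags <- dplyr::bind_rows(frags, tibble::tibble(
        source = "precursor", frag = frag,
        template_start = starts, template_end = starts + inserts - 1L,
        tail_bases = 0L
      ))
    }
    r1 <- substr(frags$frag, 1L, rl)
    r2 <- revcomp(substr(frags$frag, nchar(frags$frag) - rl + 1L,
      nchar(frags$frag)
    ))
    if (config$error_rate > 0) {
      r1 <- apply_substitutions(r1, config$error_rate)
      r2 <- apply_substitutions(r2, config$error_rate)
    }
    read_id <- sprintf("sim_%06d_%s", seq_len(nrow(frags)), frags$source)
    list(
      reads = tibble::tibble(read_id = read_id, seq1 = r1, seq2 = r2),
      truth = dplyr::bind_cols(tibble::tibble(read_id = read_id), frags)
    )
  })
}

apply_substitutions <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hits <- which(stats::runif(n) < rate)
    if (length(hits) == 0L) {
      return(s)
    }
    ch <- strsplit(s, "")[[1]]
    for (h in hits) {
      ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write simulated reads as a FASTQ pair
#'
#' Constant quality symbols (Q30) are written; no stage of the
#' pipeline uses base qualities.
#'
#' @param reads Tibble from [simulate_reads()]`$reads`.
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  fq <- function(ids, seqs, path, mate) {
    qual <- strrep("?", nchar(seqs))
    writeLines(
      as.vector(rbind(paste0("@", ids, "/", mate), seqs, "+", qual)),
      path
    )
  }
  fq(reads$read_id, reads$seq1, r1_path, 1L)
  fq(reads$read_id, reads$seq2, r2_path, 2L)
  invisible(c(r1_path, r2_path))
}
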
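#' Poly(A) caller parameters
#'
#' @param min_tail Minimum number of terminal non-template adenines
#'   (transcript strand) required for evidence; the first `min_tail`
#'   clipped bases must all be A.
#' @param min_purity Minimum fraction of A over the whole clipped
#'   segment (transcript orientation).
#' @param min_support Minimum number of distinct evidence reads for a
#'   primary site; sites below it are kept as low-confidence.
#' @param merge_window Sites within this many bp are merged to the
#'   position with maximal support (0 = exact-position aggregation).
#' @return List of class `polya_params`.
#' @export
polya_params <- function(min_tail = 3L, min_purity = 0.8,
                         min_support = 3L, merge_window = 0L) {
  structure(
    list(
      min_tail = as.integer(min_tail), min_purity = min_purity,
      min_support = as.integer(min_support),
      merge_window = as.integer(merge_window)
    ),
    class = "polya_params"
  )
}

leading_run <- function(x, ch) {
  n <- nchar(x)
  i <- 0L
  while (i < n && substr(x, i + 1L, i + 1L) == ch) i <- i + 1L
  i
}

trailing_run <- function(x, ch) {
  n <- nchar(x)
  i <- 0L
  while (i < n && substr(x, n - i, n - i) == ch) i <- i + 1L
  i
}

char_fraction <- function(x, ch) {
  n <- nchar(x)
  if (n == 0L) {
    return(0)
  }
  stringr::str_count(x, stringr::fixed(ch)) / n
}

#' Detect non-template poly(A) tail evidence on mapped reads
#'
#' Examines the soft clip on the transcript-3' side of each alignment.
#' In genome-forward terms a heavy-strand (H) tail appears as a run of
#' A at the start of the right-hand clip (site = position after the
#' last aligned base) and a light-strand (L) tail as a run of T at the
#' end of the left-hand clip (site = position before the first aligned
#' base). Evidence requires at least `min_tail` leading tail bases and
#' clip purity of at least `min_purity` in transcript orientation.
#' Fully aligned reads yield no evidence (they are read-throughs of
#' unprocessed precursor or internal fragments).
#'
#' @param mapped Mapped tibble from [map_reads()] or a SAM path.
#' @param genome_length Genome length for coordinate wrapping.
#' @param params A [polya_params()].
#' @return Evidence tibble: `read_id`, `site_position` (1-based genomic
#'   coordinate of the first non-template base), `strand` (`"H"`/`"L"`),
#'   `tail_length_observed`, `tail_purity`.
#' @export
detect_tails <- function(mapped, genome_length, params = polya_params()) {
  if (is.character(mapped)) mapped <- read_sam(mapped)
  len <- as.integer(genome_length)
  empty <- tibble::tibble(
    read_id = character(), site_position = integer(), strand = character(),
    tail_length_observed = integer(), tail_purity = double()
  )
  if (nrow(mapped) == 0L) {
    return(empty)
  }
  rows <- purrr::pmap(
    mapped[, c("read_id", "pos", "end_pos", "clip_left", "clip_right")],
    function(read_id, pos, end_pos, clip_left, clip_right) {
      h <- NULL
      l <- NULL
      # H-strand: genomic-right clip starts with A's
      tail_h <- leading_run(clip_right, "A")
      if (tail_h >= params$min_tail) {
        pur <- char_fraction(clip_right, "A")
        if (pur >= params$min_purity) {
          h <- tibble::tibble(
            read_id = read_id,
            site_position = wrap1(end_pos + 1L, len),
            strand = "H",
            tail_length_observed = tail_h,
            tail_purity = pur
          )
        }
      }
      # L-strand: genomic-left clip ends with T's (A's in transcript
      # orientation)
      tail_l <- trailing_run(clip_left, "T")
      if (tail_l >= params$min_tail) {
        pur <- char_fraction(clip_left, "T")
        if (pur >= params$min_purity) {
          l <- tibble::tibble(
            read_id = read_id,
            site_position = wrap1(pos - 1L, len),
            strand = "L",
            tail_length_observed = tail_l,
            tail_purity = pur
          )
        }
      }
      if (!is.null(h) && !is.null(l)) {
        # chimera-like double evidence: keep the longer tail, H on ties
        if (l$tail_length_observed > h$tail_length_observed) l else h
      } else if (!is.null(h)) {
        h
      } else if (!is.null(l)) {
        l
      } else {
        NULL
      }
    }
  )
  rows <- purrr::compact(rows)
  if (length(rows) == 0L) {
    return(empty)
  }
  dplyr::bind_rows(rows)
}

#' Aggregate tail evidence into polyadenylation sites
#'
#' Evidence is grouped by strand and exact genomic position; with a
#' positive `merge_window`, nearby positions are absorbed into the
#' position with maximal support (ties go to the most 5' position in
#' transcript orientation). Duplicate reads are counted individually.
#' Sites below `min_support` are retained with `pass = FALSE` as the
#' low-confidence sidecar.
#'
#' @param evidence Tibble from [detect_tails()].
#' @param params A [polya_params()].
#' @return Site tibble: `site_id`, `position`, `strand`, `support`,
#'   `tail_length_mean`, `pass`.
#' @export
aggregate_sites <- function(evidence, params = polya_params()) {
  empty <- tibble::tibble(
    site_id = character(), position = integer(), strand = character(),
    support = integer(), tail_length_mean = double(), pass = logical()
  )
  if (nrow(evidence) == 0L) {
    return(empty)
  }
  sites <- evidence |>
    dplyr::group_by(.data$strand, .data$site_position) |>
    dplyr::summarise(
      support = dplyr::n(),
      tail_length_mean = mean(.data$tail_length_observed),
      .groups = "drop"
    ) |>
    dplyr::rename(position = "site_position")
  if (params$merge_window > 0L) {
    sites <- sites |>
      dplyr::group_split(.data$strand) |>
      purrr::map_dfr(merge_nearby_sites, window = params$merge_window)
  }
  sites |>
    dplyr::mutate(
      pass = .data$support >= params$min_support,
      site_id = paste0(.data$strand, "_", .data$position)
    ) |>
    dplyr::arrange(.data$position) |>
    dplyr::select(
      "site_id", "position", "strand", "support", "tail_length_mean", "pass"
    )
}

# Greedy absorption: strongest site absorbs neighbours within window;
# ties prefer the most 5' position in transcript orientation (smaller
# genomic coordinate on H, larger on L).
merge_nearby_sites <- function(sites, window) {
  if (nrow(sites) <= 1L) {
    return(sites)
  }
  five_prime_first <- if (sites$strand[1] == "H") {
    order(-sites$support, sites$position)
  } else {
    order(-sites$support, -sites$position)
  }
  sites <- sites[five_prime_first, ]
  taken <- rep(FALSE, nrow(sites))
  out <- list()
  for (i in seq_len(nrow(sites))) {
    if (taken[i]) next
    near <- !taken & abs(sites$position - sites$position[i]) <= window
    grp <- sites[near, ]
    taken[near] <- TRUE
    out[[length(out) + 1L]] <- tibble::tibble(
      strand = sites$strand[i],
      position = sites$position[i],
      support = sum(grp$support),
      tail_length_mean = stats::weighted.mean(
        grp$tail_length_mean, grp$support
      )
    )
  }
  dplyr::bind_rows(out)
}

#' Assign polyadenylation sites to upstream protein-coding genes
#'
#' Each site is assigned to the closest same-strand protein-coding
#' gene whose 3' end lies at or upstream of the site (transcript
#' orientation), within `max_downstream` bp. Distance 0 means the site
#' immediately follows the gene's last genomic base.
#'
#' @param sites Site tibble from [aggregate_sites()].
#' @param ann An [annotation()].
#' @param max_downstream Maximum distance in bp (default unlimited,
#'   which on a circular genome means up to the next same-strand gene).
#' @return `sites` with added `gene` and `distance` columns
#'   (`NA` when unassignable).
#' @export
assign_sites_to_genes <- function(sites, ann, max_downstream = Inf) {
  len <- genome_length(ann)
  pcg <- ann |> dplyr::filter(.data$ftype == "PCG")
  assign_one <- function(position, strand) {
    cand <- pcg |> dplyr::filter(.data$strand == !!strand)
    if (nrow(cand) == 0L) {
      return(tibble::tibble(gene = NA_character_, distance = NA_integer_))
    }
    dist <- if (strand == "H") {
      circ_dist_fwd(cand$end + 1L, position, len)
    } else {
      circ_dist_fwd(position, cand$start - 1L, len)
    }
    i <- which.min(dist)
    if (dist[i] > max_downstream) {
      return(tibble::tibble(gene = NA_character_, distance = NA_integer_))
    }
    tibble::tibble(gene = cand$name[i], distance = as.integer(dist[i]))
  }
  dplyr::bind_cols(
    sites,
    purrr::map2_dfr(sites$position, sites$strand, assign_one)
  )
}

#' Write / read polyadenylation sites as BED6
#'
#' BED is 0-based half-open; the single-base interval covers the first
#' non-template position. `name` holds the site id and `score` the read
#' support; strand is `+` for H, `-` for L. Only passing sites are
#' written unless `all = TRUE`.
#'
#' @param sites Site tibble from [aggregate_sites()].
#' @param path Output path.
#' @param all Also write low-confidence sites?
#' @return `path` invisibly; the reader returns a site tibble.
#' @export
write_sites_bed <- function(sites, path, all = FALSE) {
  x <- if (all) sites else dplyr::filter(sites, .data$pass)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s",
    "genome", x$position - 1L, x$position, x$site_id, x$support,
    ifelse(x$strand == "H", "+", "-")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sites_bed
#' @export
read_sites_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(tibble::tibble(
      site_id = character(), position = integer(), strand = character(),
      support = integer(), pass = logical()
    ))
  }
  f <- stringr::str_split_fixed(lines, "\t", 6L)
  tibble::tibble(
    site_id = f[, 4],
    position = as.integer(f[, 3]),
    strand = ifelse(f[, 6] == "-", "L", "H"),
    support = as.integer(f[, 5]),
    pass = TRUE
  )
}
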
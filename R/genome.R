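#' Circular genome container
#'
#' A minimal container for a (usually circular) mitochondrial genome
#' sequence. External coordinates throughout the package are 1-based
#' inclusive, matching GenBank and GFF3; the only places 0-based
#' half-open coordinates appear are the internal slicing helpers and
#' BED output, and each conversion is done exactly once.
#'
#' @param id Sequence identifier.
#' @param sequence DNA string over A, C, G, T, N (case-insensitive).
#' @param topology `"circular"` or `"linear"`.
#'
#' @return An object of class `circular_genome`: a list with elements
#'   `id`, `seq` (uppercase character scalar), `length` and `topology`.
#' @export
circular_genome <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("empty genome sequence", call. = FALSE)
  }
  bad <- stringr::str_remove_all(sequence, "[ACGTN]")
  if (nchar(bad) > 0L) {
    stop(
      "genome sequence contains characters outside {A,C,G,T,N}: ",
      paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      id = as.character(id),
      seq = sequence,
      length = nchar(sequence),
      topology = topology
    ),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf(
    "<circular_genome> %s: %d bp (%s)\n", x$id, x$length, x$topology
  ))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' A mitogenome FASTA is expected to hold a single record; multi-record
#' files raise an error unless `id` selects one of the records.
#'
#' @param path Path to a FASTA file.
#' @param topology Genome topology, `"circular"` (default) or `"linear"`.
#' @param id Optional record id to select from a multi-record file.
#'
#' @return A [circular_genome()].
#' @export
read_genome <- function(path, topology = c("circular", "linear"), id = NULL) {
  topology <- match.arg(topology)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records in ", path, call. = FALSE)
  }
  if (!is.null(id)) {
    hit <- which(sub("\\s.*$", "", names(set)) == id)
    if (length(hit) != 1L) {
      stop("record id '", id, "' not found (or ambiguous) in ", path,
        call. = FALSE
      )
    }
    set <- set[hit]
  } else if (length(set) > 1L) {
    stop(
      "FASTA file has ", length(set),
      " records; pass `id` to select one", call. = FALSE
    )
  }
  circular_genome(
    id = sub("\\s.*$", "", names(set)[1]),
    sequence = as.character(set[[1]]),
    topology = topology
  )
}

#' Write a genome to FASTA
#'
#' @param genome A [circular_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Wrap a 1-based position onto 1..L.
wrap1 <- function(pos, len) ((pos - 1L) %% len) + 1L

#' Slice a genome with 0-based half-open, wrap-aware coordinates
#'
#' On a circular genome, `end <= start` wraps through the origin and
#' returns exactly `length - start + end` bases. On a linear genome
#' wrapping is an error.
#'
#' @param genome A [circular_genome()].
#' @param start,end 0-based half-open interval.
#' @return Character scalar.
#' @export
seq_slice <- function(genome, start, end) {
  len <- genome$length
  stopifnot(start >= 0, start <= len, end >= 0, end <= len)
  if (end > start) {
    return(substr(genome$seq, start + 1L, end))
  }
  if (genome$topology != "circular") {
    stop("wrap-around slice on a linear genome", call. = FALSE)
  }
  paste0(
    substr(genome$seq, start + 1L, len),
    substr(genome$seq, 1L, end)
  )
}

#' Slice a genome with 1-based inclusive, wrap-aware coordinates
#'
#' `start > end` wraps through the origin on a circular genome,
#' matching GenBank `join(start..L,1..end)` semantics.
#'
#' @inheritParams seq_slice
#' @return Character scalar.
#' @export
seq_slice1 <- function(genome, start, end) {
  len <- genome$length
  stopifnot(start >= 1, start <= len, end >= 1, end <= len)
  if (start <= end) {
    substr(genome$seq, start, end)
  } else {
    seq_slice(genome, start - 1L, end)
  }
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(
    strsplit(out, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

#' Rotate a circular genome
#'
#' Moves the origin so that old position `k + 1` becomes position 1.
#' Used mainly to assert rotation invariance of downstream results.
#'
#' @param genome A circular [circular_genome()].
#' @param k Number of positions to rotate by (0 ≤ k < length).
#' @return A rotated [circular_genome()].
#' @export
rotate_genome <- function(genome, k) {
  stopifnot(genome$topology == "circular")
  k <- as.integer(k %% genome$length)
  if (k == 0L) {
    return(genome)
  }
  circular_genome(
    id = genome$id,
    sequence = seq_slice(genome, k, k),
    topology = "circular"
  )
}

# Distance from a to b walking forward (increasing coordinates) on the
# circle, in steps; 0 when a == b.
circ_dist_fwd <- function(a, b, len) (b - a) %% len

# All genomic positions of a (possibly wrapping) 1-based inclusive
# feature interval, in 5'->3' genomic-forward order.
interval_positions <- function(start, end, len) {
  if (start <= end) {
    seq.int(start, end)
  } else {
    c(seq.int(start, len), seq.int(1L, end))
  }
}

# Length of a 1-based inclusive interval, wrap-aware.
interval_length <- function(start, end, len) {
  if (start <= end) end - start + 1L else len - start + 1L + end
}
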
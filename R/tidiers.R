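#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline run into its site table
#'
#' @param x A `mitotail_run`.
#' @param ... Unused.
#' @return The gene-assigned polyadenylation site tibble.
#' @export
tidy.mitotail_run <- function(x, ...) {
  tibble::as_tibble(x$assigned)
}

#' One-row summary of a pipeline run
#'
#' @param x A `mitotail_run`.
#' @param ... Unused.
#' @return One-row tibble with headline counts.
#' @export
glance.mitotail_run <- function(x, ...) {
  tibble::tibble(
    genome_length = x$genome$length,
    n_reads_mapped = nrow(x$mapped),
    n_sites = sum(x$sites$pass),
    n_stops_polyadenylation = sum(x$stops$mechanism == "polyadenylation"),
    n_stops_encoded = sum(x$stops$mechanism == "encoded"),
    n_bicistronic = sum(x$bicistronic$called),
    n_punctuation_deviations = sum(x$punctuation$conformance == "deviation"),
    n_igs = nrow(x$igs)
  )
}

#' Tidy a stem-loop scan result
#'
#' @param x A `stemloop_result`.
#' @param ... Unused.
#' @return One-row tibble of the best hairpin's statistics.
#' @export
tidy.stemloop_result <- function(x, ...) {
  tibble::tibble(
    length = nchar(x$sequence),
    stem_pairs = x$stem_pairs,
    loop_length = x$loop_length,
    score = x$score,
    stem_start = x$stem_start,
    stem_end = x$stem_end,
    candidate = x$candidate
  )
}
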
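#' Run the full 3'-end mapping pipeline
#'
#' Orchestrates simulate (or load) -> map -> call poly(A) sites ->
#' annotate, writing every intermediate as a plain-text file
#' (FASTQ/SAM/BED/TSV) plus a YAML run manifest, so each stage is
#' independently inspectable and a rerun with the same configuration
#' reproduces byte-identical outputs.
#'
#' Inputs are either a simulation configuration (the default) or a
#' genome FASTA + annotation + FASTQ pair.
#'
#' @param outdir Output directory (created if needed).
#' @param sim A [sim_config()] used when no external reads are given.
#' @param genome_path,annotation_path,reads_r1,reads_r2 Optional
#'   external inputs; all four must be supplied together.
#' @param mapper A [mapper_params()].
#' @param caller A [polya_params()].
#' @param min_stem,min_loop Stem-loop candidacy parameters for the IGS
#'   classifier.
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `mitotail_run` (list of all stage
#'   results and file paths), invisibly.
#' @export
run_pipeline <- function(outdir,
                         sim = sim_config(),
                         genome_path = NULL, annotation_path = NULL,
                         reads_r1 = NULL, reads_r2 = NULL,
                         mapper = mapper_params(),
                         caller = polya_params(),
                         min_stem = 5L, min_loop = 3L,
                         quiet = FALSE) {
  external <- !is.null(genome_path)
  if (external) {
    missing_in <- c(
      genome = genome_path, annotation = annotation_path,
      r1 = reads_r1, r2 = reads_r2
    )
    bad <- !file.exists(missing_in)
    if (any(bad)) {
      stop(
        "validation failed, missing input file(s): ",
        paste(names(missing_in)[bad], collapse = ", "),
        call. = FALSE
      )
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[mitotail] ", sprintf(...))

  truth_sites <- NULL
  if (external) {
    say("loading genome and annotation")
    genome <- read_genome(genome_path)
    ann <- read_annotation(annotation_path, genome_length = genome$length)
    r1 <- reads_r1
    r2 <- reads_r2
  } else {
    say("simulating synthetic transcriptome (seed %d)", sim$seed)
    toy <- build_toy_genome(sim)
    genome <- toy$genome
    ann <- toy$annotation
    transcripts <- transcribe_and_process(genome, ann, sim)
    simulated <- simulate_reads(transcripts, genome, sim)
    truth_sites <- truth_polya_sites(ann)
    r1 <- file.path(outdir, "reads_R1.fastq")
    r2 <- file.path(outdir, "reads_R2.fastq")
    write_fastq_pair(simulated$reads, r1, r2)
    readr::write_tsv(truth_sites, file.path(outdir, "truth_sites.tsv"))
    write_genome(genome, file.path(outdir, "genome.fasta"))
    say(
      "%d transcripts, %d read pairs",
      nrow(transcripts), nrow(simulated$reads)
    )
  }

  say("mapping reads")
  sam_path <- file.path(outdir, "aln.sam")
  mapped <- map_pairs(r1, r2, genome, mapper, sam_out = sam_path)
  say("%d reads mapped", nrow(mapped))

  say("calling polyadenylation sites")
  evidence <- detect_tails(mapped, genome$length, caller)
  sites <- aggregate_sites(evidence, caller)
  assigned <- assign_sites_to_genes(sites, ann)
  write_sites_bed(sites, file.path(outdir, "sites.bed"))
  write_sites_bed(sites, file.path(outdir, "sites_low_confidence.bed"),
    all = TRUE
  )
  readr::write_tsv(assigned, file.path(outdir, "sites.tsv"))
  say(
    "%d sites (%d passing support >= %d)",
    nrow(sites), sum(sites$pass), caller$min_support
  )

  say("annotating transcripts")
  stops <- classify_stops(ann, genome, assigned)
  n_unresolved <- sum(stops$mechanism == "unresolved")
  if (n_unresolved > 0L) {
    say("warning: %d gene(s) with unresolved stop codons", n_unresolved)
  }
  utrs <- assigned |>
    dplyr::filter(.data$pass, !is.na(.data$gene)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$support, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  utrs <- purrr::map2_dfr(
    utrs$gene, utrs$position,
    ~ call_utr(.x, .y, ann, genome)
  )
  bicistronic <- detect_bicistronic(ann, sites, caller$min_support)
  predictions <- predict_punctuation_ends(ann)
  punctuation <- check_punctuation_conformance(assigned, predictions, ann)
  igs <- derive_igs(ann, genome,
    ol_scan = TRUE,
    min_stem = min_stem, min_loop = min_loop
  )
  coverage <- coverage_profile(mapped, ann = ann)

  readr::write_tsv(stops, file.path(outdir, "stops.tsv"))
  readr::write_tsv(utrs, file.path(outdir, "utrs.tsv"))
  readr::write_tsv(bicistronic, file.path(outdir, "bicistronic.tsv"))
  readr::write_tsv(punctuation, file.path(outdir, "punctuation.tsv"))
  write_igs_table(igs, file.path(outdir, "igs.tsv"))

  manifest <- list(
    package = "mitotail",
    version = as.character(utils::packageVersion("mitotail")),
    mode = if (external) "external" else "simulation",
    seed = if (external) NA else sim$seed,
    genome_id = genome$id,
    genome_length = genome$length,
    mapper = unclass(mapper),
    caller = unclass(caller),
    n_reads_mapped = nrow(mapped),
    n_sites = nrow(sites),
    input_checksums = as.list(tools::md5sum(c(r1, r2)))
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  res <- structure(
    list(
      outdir = outdir, genome = genome, annotation = ann,
      mapped = mapped, evidence = evidence, sites = sites,
      assigned = assigned, stops = stops, utrs = utrs,
      bicistronic = bicistronic, punctuation = punctuation,
      igs = igs, coverage = coverage, truth_sites = truth_sites,
      manifest = manifest
    ),
    class = "mitotail_run"
  )
  say("done: %s", outdir)
  invisible(res)
}

#' @export
print.mitotail_run <- function(x, ...) {
  cat(summarize_run(x), sep = "\n")
  invisible(x)
}

#' Summarise a pipeline run
#'
#' One-page markdown summary of a completed run: mapped reads, site
#' counts, polyadenylation-completed stop codons, UTRs, bicistronic
#' pairs and punctuation-model deviations.
#'
#' @param run A `mitotail_run` object or a run directory path.
#' @return Character vector of markdown lines.
#' @export
summarize_run <- function(run) {
  if (is.character(run)) {
    need <- file.path(run, c(
      "sites.tsv", "stops.tsv", "bicistronic.tsv",
      "punctuation.tsv", "igs.tsv"
    ))
    if (!all(file.exists(need))) {
      stop("incomplete run directory: ", run, call. = FALSE)
    }
    run <- list(
      sites = readr::read_tsv(need[1], show_col_types = FALSE),
      stops = readr::read_tsv(need[2], show_col_types = FALSE),
      bicistronic = readr::read_tsv(need[3], show_col_types = FALSE),
      punctuation = readr::read_tsv(need[4], show_col_types = FALSE),
      igs = read_igs_table(need[5]),
      mapped = NULL
    )
  }
  sites_pass <- dplyr::filter(run$sites, .data$pass)
  lines <- c(
    "# mitotail run summary",
    "",
    sprintf(
      "- mapped reads: %s",
      if (is.null(run$mapped)) "(not retained)" else nrow(run$mapped)
    ),
    sprintf(
      "- polyadenylation sites: %d passing (%d total)",
      nrow(sites_pass), nrow(run$sites)
    ),
    sprintf(
      "- stop codons completed by polyadenylation: %d; encoded: %d; unresolved: %d",
      sum(run$stops$mechanism == "polyadenylation"),
      sum(run$stops$mechanism == "encoded"),
      sum(run$stops$mechanism == "unresolved")
    ),
    sprintf(
      "- bicistronic transcripts called: %d",
      sum(run$bicistronic$called)
    ),
    sprintf(
      "- punctuation model: %d conform, %d with UTR, %d deviations, %d unresolved",
      sum(run$punctuation$conformance == "conforms"),
      sum(run$punctuation$conformance == "conforms_with_UTR"),
      sum(run$punctuation$conformance == "deviation"),
      sum(run$punctuation$conformance == "unresolved")
    ),
    sprintf(
      "- intergenic sequences: %d (%d short non-coding, %d bp total short)",
      nrow(run$igs),
      sum(run$igs$igs_class == "short_noncoding"),
      sum(run$igs$length[run$igs$igs_class == "short_noncoding"])
    )
  )
  if (nrow(sites_pass) == 0L) {
    lines <- c(lines, "", "No transcript 3' ends were resolved.")
  }
  lines
}
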
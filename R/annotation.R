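#' Build an annotation table
#'
#' An annotation is a tibble of strand-aware gene features with 1-based
#' inclusive genomic coordinates, sorted by start, carrying the genome
#' id and length as attributes. A feature spanning the origin of a
#' circular genome is written with `start > end` and gets
#' `wraps_origin = TRUE`.
#'
#' @param features A data frame with columns `name`, `ftype` (one of
#'   `"PCG"`, `"tRNA"`, `"rRNA"`, `"control_region"`, `"other"`),
#'   `strand` (`"H"` or `"L"`), `start`, `end` (1-based inclusive).
#' @param genome_id Identifier of the genome the coordinates refer to.
#' @param genome_length Genome length in bp.
#'
#' @return A tibble of class `mt_annotation` with an added
#'   `wraps_origin` column, sorted by `start`.
#' @export
annotation <- function(features, genome_id, genome_length) {
  features <- tibble::as_tibble(features)
  req <- c("name", "ftype", "strand", "start", "end")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols) > 0) {
    stop(
      "annotation is missing columns: ",
      paste(missing_cols, collapse = ", "), call. = FALSE
    )
  }
  genome_length <- as.integer(genome_length)
  features <- features |>
    dplyr::mutate(
      name = as.character(.data$name),
      ftype = as.character(.data$ftype),
      strand = as.character(.data$strand),
      start = as.integer(.data$start),
      end = as.integer(.data$end)
    )
  bad_type <- setdiff(
    unique(features$ftype),
    c("PCG", "tRNA", "rRNA", "control_region", "other")
  )
  if (length(bad_type) > 0) {
    stop("unknown feature type(s): ", paste(bad_type, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(features$strand %in% c("H", "L"))) {
    stop("strand must be 'H' or 'L'", call. = FALSE)
  }
  if (any(features$start < 1L | features$start > genome_length) ||
    any(features$end < 1L | features$end > genome_length)) {
    stop("feature coordinates outside 1..", genome_length, call. = FALSE)
  }
  if (anyDuplicated(features$name)) {
    dup <- unique(features$name[duplicated(features$name)])
    warning(
      "duplicate feature names auto-suffixed: ",
      paste(dup, collapse = ", "),
      call. = FALSE
    )
    for (d in dup) {
      idx <- which(features$name == d)
      features$name[idx] <- paste0(d, seq_along(idx))
    }
  }
  features <- features |>
    dplyr::mutate(wraps_origin = .data$start > .data$end) |>
    dplyr::arrange(.data$start)
  structure(
    features,
    genome_id = as.character(genome_id),
    genome_length = genome_length,
    class = c("mt_annotation", class(tibble::tibble()))
  )
}

#' @export
#' @rdname annotation
#' @param ann An annotation.
genome_length <- function(ann) {
  len <- attr(ann, "genome_length", exact = TRUE)
  if (is.null(len)) {
    stop("annotation lacks a genome_length attribute", call. = FALSE)
  }
  len
}

#' Feature lengths of an annotation, wrap-aware
#'
#' @param ann An [annotation()].
#' @return Integer vector of feature lengths in bp.
#' @export
feature_lengths <- function(ann) {
  len <- genome_length(ann)
  purrr::map2_int(
    ann$start, ann$end,
    ~ interval_length(.x, .y, len)
  )
}

# 3' and 5' genomic coordinates of a feature given its strand.
feature_3p <- function(strand, start, end) ifelse(strand == "H", end, start)
feature_5p <- function(strand, start, end) ifelse(strand == "H", start, end)

#' Read an annotation from a GenBank flat file or GFF3
#'
#' GenBank `complement(...)` locations and GFF3 `-` strand both map to
#' the light (L) strand; `join(a..b, c..d)` across the origin yields a
#' single wrapping feature. Feature keys are mapped to the internal
#' types: CDS to PCG, tRNA, rRNA, D-loop to control_region, anything
#' else to other. Gene names are normalised to lowercase symbols with
#' tRNAs as `trnX` (one-letter amino-acid code; duplicates are
#' number-suffixed in file order, e.g. trnS1/trnS2).
#'
#' @param path Path to a `.gb`/`.gbk` GenBank flat file or a
#'   `.gff`/`.gff3` file.
#' @param genome_length Genome length; required for GFF3, read from the
#'   LOCUS line for GenBank if omitted.
#' @param format `"auto"` (by extension), `"genbank"` or `"gff3"`.
#'
#' @return An [annotation()].
#' @export
read_annotation <- function(path, genome_length = NULL,
                            format = c("auto", "genbank", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
      "gff3"
    } else {
      "genbank"
    }
  }
  if (format == "genbank") {
    read_annotation_genbank(path, genome_length)
  } else {
    read_annotation_gff3(path, genome_length)
  }
}

# --- GenBank flat file -------------------------------------------------

gb_ftype_map <- c(
  CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
  "D-loop" = "control_region"
)

aa3to1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

symbol_map <- c(
  nd1 = "nad1", nd2 = "nad2", nd3 = "nad3", nd4 = "nad4",
  nd4l = "nad4l", nd5 = "nad5", nd6 = "nad6",
  coi = "cox1", coii = "cox2", coiii = "cox3",
  co1 = "cox1", co2 = "cox2", co3 = "cox3",
  cox1 = "cox1", cox2 = "cox2", cox3 = "cox3",
  atp6 = "atp6", atp8 = "atp8", atpase6 = "atp6", atpase8 = "atp8",
  cytb = "cob", cob = "cob",
  "12s" = "rrnS", "16s" = "rrnL", rrns = "rrnS", rrnl = "rrnL",
  "s-rrna" = "rrnS", "l-rrna" = "rrnL"
)

#' Normalise a gene name to the field's convention
#'
#' Protein-coding and rRNA symbols are lowercased and mapped to the
#' nad/cox/atp/cob/rrn nomenclature; tRNA products such as "tRNA-Ser"
#' become `trnS`. Duplicate-name disambiguation happens at annotation
#' construction time.
#'
#' @param name Raw gene or product string.
#' @param ftype Feature type string.
#' @return Normalised name.
#' @export
normalize_gene_name <- function(name, ftype = "other") {
  name <- trimws(name)
  if (ftype == "tRNA" || grepl("^tRNA", name, ignore.case = TRUE)) {
    m <- stringr::str_match(name, stringr::regex("tRNA[-_ ]?([A-Za-z]{3})",
      ignore_case = TRUE
    ))[, 2]
    if (!is.na(m)) {
      aa <- aa3to1[stringr::str_to_title(m)]
      if (!is.na(aa)) {
        return(paste0("trn", aa))
      }
    }
    m2 <- stringr::str_match(name, "^trn([A-Za-z])([0-9]?)$")
    if (!is.na(m2[1, 1])) {
      return(paste0("trn", toupper(m2[1, 2]), m2[1, 3]))
    }
    return(name)
  }
  if (ftype == "rRNA" || grepl("ribosomal|rRNA", name, ignore.case = TRUE)) {
    if (grepl("12S|small|rrnS", name, ignore.case = FALSE)) {
      return("rrnS")
    }
    if (grepl("16S|large|rrnL", name, ignore.case = FALSE)) {
      return("rrnL")
    }
  }
  key <- tolower(gsub("[^A-Za-z0-9]", "", name))
  if (key %in% names(symbol_map)) {
    return(unname(symbol_map[key]))
  }
  tolower(name)
}

parse_gb_location <- function(loc) {
  complemented <- grepl("complement", loc, fixed = TRUE)
  inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  inner <- gsub("[<>]", "", inner)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  rng <- stringr::str_match(parts, "^([0-9]+)\\.\\.([0-9]+)$")
  single <- stringr::str_match(parts, "^([0-9]+)$")
  starts <- ifelse(is.na(rng[, 2]), single[, 2], rng[, 2])
  ends <- ifelse(is.na(rng[, 3]), single[, 2], rng[, 3])
  if (anyNA(starts) || anyNA(ends)) {
    stop("cannot parse GenBank location: ", loc, call. = FALSE)
  }
  list(
    start = as.integer(starts[1]),
    end = as.integer(ends[length(ends)]),
    strand = if (complemented) "L" else "H",
    joined = length(parts) > 1L
  )
}

read_annotation_genbank <- function(path, genome_length = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (is.null(genome_length)) {
    m <- stringr::str_match(locus[1], "([0-9]+)\\s+bp")[, 2]
    if (is.na(m)) {
      stop("cannot determine genome length from LOCUS line; pass genome_length",
        call. = FALSE
      )
    }
    genome_length <- as.integer(m)
  }
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0L) {
    stop("no FEATURES table in ", path, call. = FALSE)
  }
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (any(fend > fstart[1])) min(fend[fend > fstart[1]]) else length(lines) + 1L
  body <- lines[(fstart[1] + 1L):(fend - 1L)]

  # A feature header line has its key in columns 6-20; qualifier and
  # continuation lines are indented to column 22.
  is_header <- grepl("^ {5}\\S", body)
  idx <- cumsum(is_header)
  feats <- list()
  for (i in seq_len(max(idx, 0))) {
    block <- body[idx == i]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    if (!key %in% names(gb_ftype_map) && key != "misc_feature") next
    loc_lines <- c(sub("^ {5}\\S+\\s*", "", block[1]))
    j <- 2L
    while (j <= length(block) && !grepl("^\\s+/", block[j])) {
      loc_lines <- c(loc_lines, trimws(block[j]))
      j <- j + 1L
    }
    loc <- parse_gb_location(paste(loc_lines, collapse = ""))
    quals <- block[grepl("^\\s+/", block)]
    get_qual <- function(q) {
      hit <- grep(paste0("^\\s+/", q, "="), quals, value = TRUE)
      if (length(hit) == 0L) {
        return(NA_character_)
      }
      gsub("\"", "", sub(paste0("^\\s+/", q, "="), "", hit[1]))
    }
    ftype <- if (key %in% names(gb_ftype_map)) gb_ftype_map[[key]] else "other"
    raw_name <- get_qual("gene")
    if (is.na(raw_name)) raw_name <- get_qual("product")
    if (is.na(raw_name)) raw_name <- paste0(key, "_", i)
    feats[[length(feats) + 1L]] <- tibble::tibble(
      name = normalize_gene_name(raw_name, ftype),
      ftype = ftype,
      strand = loc$strand,
      start = loc$start,
      end = loc$end
    )
  }
  if (length(feats) == 0L) {
    stop("no usable features in ", path, call. = FALSE)
  }
  features <- dplyr::bind_rows(feats)
  # gene + CDS pairs for the same locus: keep the typed record
  features <- features |>
    dplyr::distinct(.data$name, .data$start, .data$end, .data$strand,
      .keep_all = TRUE
    )
  features <- disambiguate_trna(features)
  acc <- stringr::str_match(locus[1], "^LOCUS\\s+(\\S+)")[, 2]
  annotation(features,
    genome_id = ifelse(is.na(acc), basename(path), acc),
    genome_length = genome_length
  )
}

# Number-suffix duplicated tRNA isoacceptors (trnS -> trnS1, trnS2) and
# any other duplicated names, in file order.
disambiguate_trna <- function(features) {
  dup <- unique(features$name[duplicated(features$name)])
  for (d in dup) {
    idx <- which(features$name == d)
    features$name[idx] <- paste0(d, seq_along(idx))
  }
  features
}

# --- GFF3 --------------------------------------------------------------

gff_type_map <- c(
  CDS = "PCG", gene = "other", tRNA = "tRNA", rRNA = "rRNA",
  D_loop = "control_region", region = "other"
)

read_annotation_gff3 <- function(path, genome_length = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  keep <- as.character(gr$type) %in% c("CDS", "tRNA", "rRNA", "D_loop")
  gr <- gr[keep]
  if (length(gr) == 0L) {
    stop("no CDS/tRNA/rRNA/D_loop features in ", path, call. = FALSE)
  }
  meta <- as.data.frame(gr)
  raw_name <- meta$Name
  if (is.null(raw_name)) raw_name <- meta$ID
  if (is.null(raw_name)) raw_name <- paste0("feature_", seq_len(nrow(meta)))
  ftype <- unname(gff_type_map[as.character(meta$type)])
  features <- tibble::tibble(
    name = purrr::map2_chr(as.character(raw_name), ftype, normalize_gene_name),
    ftype = ftype,
    strand = ifelse(as.character(meta$strand) == "-", "L", "H"),
    start = meta$start,
    end = meta$end
  )
  features <- disambiguate_trna(features)
  if (is.null(genome_length)) {
    genome_length <- max(features$end)
    warning("genome_length not given; using max feature end (",
      genome_length, ")",
      call. = FALSE
    )
  }
  annotation(features,
    genome_id = as.character(meta$seqnames[1]),
    genome_length = genome_length
  )
}

#' Rotate an annotation to match a rotated genome
#'
#' @param ann An [annotation()].
#' @param k Rotation applied to the genome (old position k+1 becomes 1).
#' @return Rotated annotation.
#' @export
rotate_annotation <- function(ann, k) {
  len <- genome_length(ann)
  k <- as.integer(k %% len)
  rot <- function(p) wrap1(p - k, len)
  feats <- ann |>
    dplyr::mutate(start = rot(.data$start), end = rot(.data$end))
  annotation(feats[, c("name", "ftype", "strand", "start", "end")],
    genome_id = attr(ann, "genome_id"),
    genome_length = len
  )
}
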
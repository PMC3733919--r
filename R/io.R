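PEAK_LEVELS <- c("I", "II", "III", "IV")
SAMPLE_KINDS <- c("wheat_parent", "aegilops_parent", "introgression_line",
                  "peak_fraction", "genomic_control")

#' Default analysis thresholds
#'
#' The BLAST-hit significance cut-offs (E-value < 2.8e-08, identity > 58.44%,
#' alignment length > 100 bp, all strict) and the minimum amplicon size
#' difference (2 bp) regarded as a significant length polymorphism between
#' wheat and Aegilops alleles.
#'
#' @param e_max Maximum (exclusive) E-value for a significant hit.
#' @param identity_min Minimum (exclusive) percent identity.
#' @param length_min Minimum (exclusive) alignment length in bp.
#' @param polymorphism_min_bp Minimum size difference (bp) counting as a
#'   length polymorphism.
#' @return A named list of thresholds.
#' @export
default_thresholds <- function(e_max = 2.8e-08, identity_min = 58.44,
                               length_min = 100, polymorphism_min_bp = 2L) {
  stopifnot(e_max > 0, identity_min > 0, length_min > 0,
            polymorphism_min_bp >= 1)
  list(e_max = e_max, identity_min = identity_min, length_min = length_min,
       polymorphism_min_bp = as.integer(polymorphism_min_bp))
}

#' Read a fragment-analysis table
#'
#' One row per PCR product observed in one DNA sample: template sample, its
#' kind (parental wheat/Aegilops genotype, introgression line, flow-sorted
#' peak fraction, or unsorted genomic control), amplicon size in bp and
#' relative fluorescence yield.
#'
#' @param path Path to a TSV with header columns `marker`, `sample`, `kind`,
#'   `species`, `peak`, `size_bp`, `yield`.  Unknown columns are ignored;
#'   `peak` must be filled (I-IV) exactly for `peak_fraction` rows.
#' @return A tibble of validated observations in file order.
#' @export
read_fragment_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  required <- c("marker", "sample", "kind", "species", "peak", "size_bp", "yield")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("fragment table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  obs <- tibble::tibble(
    marker  = raw$marker,
    sample  = raw$sample,
    kind    = raw$kind,
    species = raw$species,
    peak    = ifelse(raw$peak %in% c("", "NA"), NA_character_, raw$peak),
    size_bp = suppressWarnings(as.integer(raw$size_bp)),
    yield   = suppressWarnings(as.numeric(raw$yield))
  )
  validate_observations(obs)
}

validate_observations <- function(obs) {
  row_fail <- function(ok, what) {
    if (!all(ok)) {
      stop("fragment table row ", which(!ok)[1L], ": ", what, call. = FALSE)
    }
  }
  row_fail(obs$kind %in% SAMPLE_KINDS,
           paste0("unknown sample kind (expected one of ",
                  paste(SAMPLE_KINDS, collapse = ", "), ")"))
  row_fail(!is.na(obs$size_bp) & obs$size_bp >= 50, "malformed size_bp (must be an integer >= 50)")
  row_fail(!is.na(obs$yield) & obs$yield >= 0, "malformed yield (must be a number >= 0)")
  is_frac <- obs$kind == "peak_fraction"
  row_fail(!is_frac | obs$peak %in% PEAK_LEVELS,
           "peak (I-IV) is required for peak_fraction samples")
  row_fail(is_frac | obs$peak %in% c("", NA),
           "peak must be empty for non-fraction samples")
  obs$peak[!is_frac] <- NA_character_
  obs
}

#' Read a flow-karyotype peak composition table
#'
#' Describes the chromosome content of the subgenomic DNA sample sorted from
#' each flow-karyotype peak.  The `percent` column is optional: when absent
#' (membership-only input, as in published peak-content tables) each listed
#' chromosome receives a nominal 100/n percent, where n is the number of
#' chromosomes listed in that peak, and unlisted chromosomes are 0.
#'
#' @param path TSV with columns `species`, `peak`, `chromosome` and optionally
#'   `percent` (blank cells allowed; values must lie in \[0, 100\]).
#' @return A tibble (`species`, `peak`, `chromosome`, `percent`).
#' @export
read_peak_composition <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"))
  required <- c("species", "peak", "chromosome")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("peak composition table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(raw$peak %in% PEAK_LEVELS)) {
    stop("peak identifiers must be one of ", paste(PEAK_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  chrom_parse(raw$chromosome)  # validates labels
  pct <- if ("percent" %in% names(raw)) suppressWarnings(as.numeric(raw$percent)) else rep(NA_real_, nrow(raw))
  if (any(!is.na(pct) & (pct < 0 | pct > 100))) {
    stop("percent values must lie in [0, 100]", call. = FALSE)
  }
  comp <- tibble::tibble(species = raw$species, peak = raw$peak,
                         chromosome = raw$chromosome, percent = pct)
  comp |>
    dplyr::group_by(.data$species, .data$peak) |>
    dplyr::mutate(percent = ifelse(is.na(.data$percent),
                                   100 / dplyr::n(), .data$percent)) |>
    dplyr::ungroup()
}

#' Major-location peak of each chromosome
#'
#' Each chromosome of a species is taken to have its major location in the
#' peak where its content percentage is highest; ties (a chromosome listed
#' with equal content in two peaks) go deterministically to the lower-numbered
#' peak, and all tying peaks are retained as carrier peaks.
#'
#' @param comp Composition tibble from [read_peak_composition()].
#' @return A tibble (`species`, `chromosome`, `major_peak`, `carrier_peaks`),
#'   `carrier_peaks` a slash-joined list of peaks achieving the maximum.
#' @export
major_locations <- function(comp) {
  comp |>
    dplyr::filter(.data$percent > 0) |>
    dplyr::mutate(.peak_rank = match(.data$peak, PEAK_LEVELS)) |>
    dplyr::group_by(.data$species, .data$chromosome) |>
    dplyr::summarise(
      major_peak = .data$peak[.data$.peak_rank == min(.data$.peak_rank[.data$percent == max(.data$percent)])][1L],
      carrier_peaks = paste(.data$peak[.data$percent == max(.data$percent)][
        order(.data$.peak_rank[.data$percent == max(.data$percent)])], collapse = "/"),
      .groups = "drop"
    )
}

# full content matrix for one species: chromosomes x peaks, zero-filled
content_matrix <- function(comp, species) {
  cs <- comp[comp$species == species, , drop = FALSE]
  if (nrow(cs) == 0) {
    stop("no peak composition recorded for species ", species, call. = FALSE)
  }
  peaks <- PEAK_LEVELS[PEAK_LEVELS %in% unique(cs$peak)]
  chroms <- sort(unique(cs$chromosome))
  m <- matrix(0, nrow = length(chroms), ncol = length(peaks),
              dimnames = list(chroms, peaks))
  m[cbind(match(cs$chromosome, chroms), match(cs$peak, peaks))] <- cs$percent
  m
}

#' Read a tabular sequence-hit file
#'
#' Consumes the standard 12-column tab-separated alignment format (query,
#' subject, identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore; no header).  Reverse-oriented hits
#' (sstart > send) are normalised so `start <= end` with the orientation
#' recorded; normalisation is idempotent.
#'
#' @param path Path to the hit file.
#' @param subject_parser Function mapping the subject-id column to a
#'   two-column data frame (`model_genome`, `chromosome`).  The default
#'   understands `Br`/`Bd` prefixes as Brachypodium and `R`/`Os`/`Chr`
#'   prefixes as rice, e.g. `"Br3"`, `"R10"`.
#' @return A tibble of hits (`query_id`, `model_genome`, `chromosome`,
#'   `start`, `end`, `orientation`, `score`, `e_value`, `identity_pct`,
#'   `aln_length`), in file order.
#' @export
read_hit_table <- function(path, subject_parser = default_subject_parser) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(query_id = character(), model_genome = character(),
                          chromosome = character(), start = integer(),
                          end = integer(), orientation = character(),
                          score = numeric(), e_value = numeric(),
                          identity_pct = numeric(), aln_length = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf != 12L)) {
    stop("hit table line ", which(nf != 12L)[1L],
         ": expected 12 tab-separated columns, found ", nf[nf != 12L][1L],
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  subj <- subject_parser(m[, 2L])
  sstart <- as.integer(m[, 9L])
  send <- as.integer(m[, 10L])
  hits <- tibble::tibble(
    query_id = m[, 1L],
    model_genome = subj$model_genome,
    chromosome = subj$chromosome,
    start = pmin(sstart, send),
    end = pmax(sstart, send),
    orientation = ifelse(sstart <= send, "plus", "minus"),
    score = as.numeric(m[, 12L]),
    e_value = as.numeric(m[, 11L]),
    identity_pct = as.numeric(m[, 3L]),
    aln_length = as.integer(m[, 4L])
  )
  if (any(is.na(hits$start)) || any(hits$start < 1) || any(hits$aln_length < 1) ||
      any(is.na(hits$e_value)) || any(hits$e_value < 0)) {
    stop("hit table contains malformed coordinate, length or E-value fields",
         call. = FALSE)
  }
  hits
}

#' @rdname read_hit_table
#' @param subject_id Character vector of subject sequence identifiers.
#' @export
default_subject_parser <- function(subject_id) {
  genome <- dplyr::case_when(
    grepl("^(Br|Bd)[0-9]+$", subject_id) ~ "brachypodium",
    grepl("^(R|Os|Chr)[0-9]+$", subject_id) ~ "rice",
    TRUE ~ NA_character_
  )
  if (any(is.na(genome))) {
    stop("cannot parse model genome from subject id(s): ",
         paste(unique(subject_id[is.na(genome)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(model_genome = genome, chromosome = subject_id,
             stringsAsFactors = FALSE)
}

#' Write a 12-column tabular hit file
#'
#' Inverse of [read_hit_table()] for hits produced by the simulator; minus
#' orientation is rendered as `sstart > send`.
#'
#' @param hits Hit tibble (see [read_hit_table()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  sstart <- ifelse(hits$orientation == "minus", hits$end, hits$start)
  send <- ifelse(hits$orientation == "minus", hits$start, hits$end)
  out <- data.frame(
    q = hits$query_id, s = hits$chromosome,
    id = format(hits$identity_pct, trim = TRUE),
    len = hits$aln_length, mm = 0L, go = 0L,
    qs = 1L, qe = hits$aln_length, ss = sstart, se = send,
    ev = format(hits$e_value, trim = TRUE, scientific = TRUE),
    bs = format(hits$score, trim = TRUE)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read introgression-line karyotypes
#'
#' Describes the wheat-Aegilops genetic stocks: disomic additions (added
#' chromosome or chromosomes), substitutions (added alien chromosome paired
#' with a removed wheat chromosome, e.g. 6M(6A)) and centric fusions
#' (represented as two arm-level added entries, e.g. 3MbL + 4BS).
#'
#' @param path TSV with columns `line_id`, `species`, `background`, `added`,
#'   `removed`; `added`/`removed` are comma-separated chromosome labels
#'   (`removed` may be blank).
#' @return A tibble with list-columns `added` and `removed`.
#' @export
read_line_karyotypes <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  required <- c("line_id", "species", "background", "added", "removed")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("karyotype table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  split_labels <- function(x) {
    lapply(strsplit(x, ",", fixed = TRUE), function(v) {
      v <- trimws(v[nzchar(trimws(v))])
      if (length(v) > 0) chrom_parse(v)  # validate
      v
    })
  }
  panel <- tibble::tibble(
    line_id = raw$line_id, species = raw$species, background = raw$background,
    added = split_labels(raw$added), removed = split_labels(raw$removed)
  )
  n_added <- vapply(panel$added, length, integer(1))
  n_removed <- vapply(panel$removed, length, integer(1))
  if (any(n_added == 0)) {
    stop("karyotype line ", panel$line_id[n_added == 0][1L],
         " has an empty added set", call. = FALSE)
  }
  if (any(n_removed > n_added)) {
    stop("substitution lines must pair removed with added chromosomes",
         call. = FALSE)
  }
  panel
}

#' Read model-chromosome lengths
#'
#' @param path TSV with columns `model_genome`, `chromosome`, `length_bp`.
#' @return A tibble of chromosome lengths.
#' @export
read_chrom_lengths <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    model_genome = "c", chromosome = "c", length_bp = "d"))
  if (any(out$length_bp <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  out
}

#' Write pipeline result tables
#'
#' Plain TSV writers for the assignment, duplication-event and map-placement
#' tables; each file round-trips through `readr::read_tsv()` unchanged.
#'
#' @param records A result tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_assignments <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_assignments
#' @export
write_duplications <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_assignments
#' @export
write_map <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' Export marker placements as BED
#'
#' Hit-table coordinates are 1-based inclusive; BED is 0-based half-open, so a
#' placement starting at base 1 with alignment length 200 becomes
#' `chromStart 0, chromEnd 200`.  The name field carries
#' `marker|track:groups`.
#'
#' @param placements Placement tibble from [make_placements()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_map_bed <- function(placements, path) {
  bed <- data.frame(
    chrom = placements$chromosome,
    chromStart = placements$start_bp - 1L,
    chromEnd = placements$start_bp - 1L + placements$aln_length,
    name = paste0(placements$marker, "|", placements$track, ":", placements$group)
  )
  utils::write.table(bed[order(bed$chrom, bed$chromStart, bed$name), ],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
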
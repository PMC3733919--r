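#' Read a locus catalogue (assignment-shaped TSV)
#'
#' Loads a table of chromosome-assigned, wheat-polymorphic loci -- one row per
#' (chromosome, species, marker, size) -- such as the transcription of a
#' published suitability table, and returns it in the assignment shape
#' accepted by [select_suitable_markers()] and [detect_marker_duplications()].
#'
#' @param path TSV with columns `chromosome`, `species`, `marker`, `size_bp`
#'   and optionally `predicted` (0/1: chromosomal location predicted by the
#'   cross-species transfer rule rather than observed directly).
#' @return An assignment tibble (`marker`, `size_bp`, `species`,
#'   `chromosomes`, `evidence`, `polymorphic`, `ambiguous`).
#' @export
read_locus_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  required <- c("chromosome", "species", "marker", "size_bp")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("locus table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  chrom_parse(raw$chromosome)
  predicted <- if ("predicted" %in% names(raw)) raw$predicted %in% c("1", "TRUE", "true") else FALSE
  tibble::tibble(
    marker = raw$marker,
    size_bp = as.integer(raw$size_bp),
    species = raw$species,
    chromosomes = raw$chromosome,
    evidence = ifelse(predicted, "transferred", "line"),
    polymorphic = TRUE,
    ambiguous = FALSE
  )
}

#' Read a duplication catalogue
#'
#' Loads duplication records -- one row per (marker, species) multi-locus
#' observation, chromosomes slash-joined -- such as the transcription of a
#' published duplication table, ready for [group_duplication_events()].
#'
#' @param path TSV with columns `genome`, `marker`, `species`, `chromosomes`.
#' @return A duplication-record tibble (`marker`, `species`, `genome`,
#'   `chromosomes`, `pattern`, `n_loci`).
#' @export
read_duplication_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  required <- c("genome", "marker", "species", "chromosomes")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("duplication table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    chroms <- strsplit(raw$chromosomes[i], "/", fixed = TRUE)[[1L]]
    p <- chrom_parse(chroms)
    if (!all(p$genome == raw$genome[i])) {
      stop("duplication table row ", i, ": chromosomes do not match genome ",
           raw$genome[i], call. = FALSE)
    }
    tibble::tibble(
      marker = raw$marker[i], species = raw$species[i], genome = raw$genome[i],
      chromosomes = paste(sort(chroms), collapse = "/"),
      pattern = paste(sort(p$group), collapse = "/"),
      n_loci = length(chroms)
    )
  })
  dplyr::bind_rows(rows)
}
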
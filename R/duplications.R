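#' Detect intragenomic duplications per marker
#'
#' A marker shows a duplication within one genome of one species when it has
#' at least two assigned loci there: distinct size bins on different
#' chromosomes, one size bin confidently placed on two or more chromosomes,
#' or two or more size bins on one chromosome (a same-chromosome duplicate
#' such as two loci both on 7M).  Assignments flagged ambiguous
#' (indistinguishable co-sorted chromosomes) are not counted as multi-locus
#' evidence.
#'
#' @param assignments Assignment tibble (see [assign_loci()]); transferred
#'   (predicted) assignments participate.
#' @return A tibble with one row per (marker, species, genome) duplication:
#'   `chromosomes` (slash-joined multiset, tags kept), `pattern` (slash-joined
#'   multiset of homoeologous groups, tags stripped), `n_loci`.
#' @export
detect_marker_duplications <- function(assignments) {
  a <- assignments[!is.na(assignments$chromosomes) &
                     nzchar(assignments$chromosomes) &
                     !(assignments$ambiguous %||% FALSE), , drop = FALSE]
  empty <- tibble::tibble(marker = character(), species = character(),
                          genome = character(), chromosomes = character(),
                          pattern = character(), n_loci = integer())
  if (nrow(a) == 0) return(empty)
  loci <- a |>
    tidyr::separate_rows("chromosomes", sep = "/") |>
    dplyr::rename(chromosome = "chromosomes")
  p <- chrom_parse(loci$chromosome)
  loci$genome <- p$genome
  loci$group <- p$group
  loci |>
    dplyr::distinct(.data$marker, .data$species, .data$genome,
                    .data$size_bp, .data$chromosome, .data$group) |>
    dplyr::group_by(.data$marker, .data$species, .data$genome) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      chromosomes = paste(sort(chrom_strip_arm(.data$chromosome)), collapse = "/"),
      pattern = paste(sort(.data$group), collapse = "/"),
      n_loci = dplyr::n(),
      .groups = "drop"
    )
}

#' Group duplication records into duplication events
#'
#' Records are merged into one event when they share the genome and the same
#' multiset of homoeologous groups after stripping subgenome tags, so a
#' duplication found in the diploid progenitor and again (tagged) in a
#' tetraploid counts once, as does the same pattern found by different
#' markers; a repeated group (e.g. 7/7) is distinct from the single locus.
#'
#' @param records Tibble from [detect_marker_duplications()] (columns
#'   `marker`, `species`, `genome`, `chromosomes`, `pattern`).
#' @return A tibble with one row per event: `genome`, `pattern`, `n_markers`,
#'   `markers` (slash-joined), `species_presence` (species=chromosomes,
#'   comma-joined).
#' @export
group_duplication_events <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(genome = character(), pattern = character(),
                          n_markers = integer(), markers = character(),
                          species_presence = character()))
  }
  records |>
    dplyr::group_by(.data$genome, .data$pattern) |>
    dplyr::summarise(
      n_markers = dplyr::n_distinct(.data$marker),
      markers = paste(sort(unique(.data$marker)), collapse = "/"),
      species_presence = paste(
        sort(unique(paste0(.data$species, "=", .data$chromosomes))),
        collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$genome, .data$pattern)
}
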
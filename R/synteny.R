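#' Filter sequence hits on significance thresholds
#'
#' A hit is significant when its E-value is smaller than `e_max`, its percent
#' identity greater than `identity_min` and its alignment length greater than
#' `length_min` -- all three strict inequalities, so hits sitting exactly on a
#' threshold are discarded.  Tightening any threshold never adds hits.
#'
#' @param hits Hit tibble from [read_hit_table()].
#' @param thresholds Threshold list from [default_thresholds()].
#' @return The significant hits, order preserved.
#' @export
filter_hits <- function(hits, thresholds = default_thresholds()) {
  hits[hits$e_value < thresholds$e_max &
         hits$identity_pct > thresholds$identity_min &
         hits$aln_length > thresholds$length_min, , drop = FALSE]
}

#' Select the best hit per query and model genome
#'
#' The best hit is the one with the highest score; ties break by lower
#' E-value, then smaller start, then lexicographic chromosome, so selection
#' is fully deterministic.
#'
#' @param hits Filtered hit tibble.
#' @return One row per (query_id, model_genome); queries with no surviving
#'   hits are absent.
#' @export
select_best_hit <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::group_by(.data$query_id, .data$model_genome) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$e_value, .data$start,
                   .data$chromosome, .by_group = TRUE) |>
    dplyr::slice_head(n = 1L) |>
    dplyr::ungroup()
}

#' Convert a genomic start position to a canvas pixel
#'
#' `pixel = floor((start_bp - 1) / chrom_length_bp * canvas_width_px)`:
#' position 1 maps to pixel 0, the last base maps to the last pixel, and the
#' mapping is monotone non-decreasing and bounded by the canvas.
#'
#' @param start_bp 1-based start position(s).
#' @param chrom_length_bp Chromosome length in bp.
#' @param canvas_width_px Canvas width in pixels (>= 1).
#' @return Integer pixel coordinate(s) in `[0, canvas_width_px - 1]`.
#' @export
scale_to_canvas <- function(start_bp, chrom_length_bp, canvas_width_px) {
  stopifnot(canvas_width_px >= 1, chrom_length_bp >= 1)
  if (any(start_bp < 1 | start_bp > chrom_length_bp)) {
    stop("start position outside the chromosome (1..", chrom_length_bp, ")",
         call. = FALSE)
  }
  as.integer(floor((start_bp - 1) / chrom_length_bp * canvas_width_px))
}

#' Place markers on the model genomes
#'
#' Combines best hits with the Triticeae-side labels: the D track carries the
#' wheat homoeologous-group annotation of each marker (wheat positions are
#' curated knowledge, not BLAST-derived), and the U/M tracks (tagged per
#' tetraploid) carry the homoeologous groups of the marker's assigned
#' Aegilops chromosomes.  One output row per (marker, model genome, track,
#' group).
#'
#' @param best_hits Best-hit tibble from [select_best_hit()].
#' @param assignments Assignment tibble ([assign_loci()] shape).
#' @param wheat_annotation Tibble (`marker`, `wheat_group` integer 1-7).
#' @param chrom_lengths Tibble from [read_chrom_lengths()].
#' @param canvas_width_px Canvas width for the pixel coordinate.
#' @return Placement tibble (`marker`, `model_genome`, `chromosome`,
#'   `start_bp`, `aln_length`, `pixel`, `track`, `group`), ordered by
#'   chromosome, start and marker.
#' @export
make_placements <- function(best_hits, assignments, wheat_annotation,
                            chrom_lengths, canvas_width_px = 1000L) {
  labels <- list()
  if (!is.null(wheat_annotation) && nrow(wheat_annotation) > 0) {
    labels$d <- tibble::tibble(marker = wheat_annotation$marker,
                               track = "D",
                               group = as.integer(wheat_annotation$wheat_group))
  }
  assigned <- assignments[!is.na(assignments$chromosomes) &
                            nzchar(assignments$chromosomes) &
                            !(assignments$ambiguous %||% FALSE), , drop = FALSE]
  if (nrow(assigned) > 0) {
    aeg <- assigned |>
      tidyr::separate_rows("chromosomes", sep = "/") |>
      dplyr::rename(chromosome = "chromosomes")
    p <- chrom_parse(aeg$chromosome)
    labels$aeg <- tibble::tibble(marker = aeg$marker,
                                 track = paste0(p$genome, p$tag),
                                 group = p$group)
  }
  lab <- dplyr::distinct(dplyr::bind_rows(labels))
  placed <- dplyr::inner_join(best_hits, lab, by = c(query_id = "marker"),
                              relationship = "many-to-many")
  placed <- dplyr::inner_join(placed, chrom_lengths,
                              by = c("model_genome", "chromosome"))
  placed$pixel <- scale_to_canvas(placed$start, placed$length_bp, canvas_width_px)
  placed |>
    dplyr::transmute(marker = .data$query_id, model_genome = .data$model_genome,
                     chromosome = .data$chromosome, start_bp = .data$start,
                     aln_length = .data$aln_length, pixel = .data$pixel,
                     track = .data$track, group = .data$group) |>
    dplyr::arrange(.data$model_genome, .data$chromosome, .data$start_bp,
                   .data$marker, .data$track, .data$group)
}

#' Build synteny blocks along one model chromosome
#'
#' Markers are ordered by start position (ties by name); maximal runs of
#' consecutive markers carrying the same homoeologous-group label on the
#' requested track merge into one block spanning the first to the last
#' placement, the "gap filling" that renders a syntenic interval.  A marker
#' carrying two labels (a duplicated locus) belongs to blocks of both labels;
#' blocks of a single label never overlap.
#'
#' @param placements Placement tibble restricted to one model chromosome.
#' @param track Track id (`"D"`, `"U"`, `"M"`, `"Ub"`, `"Mb"`, `"Ug"`,
#'   `"Mg"`).
#' @return Block tibble (`model_genome`, `chromosome`, `track`, `group`,
#'   `start_bp`, `end_bp`, `start_pixel`, `end_pixel`, `first_marker`,
#'   `last_marker`, `support`).
#' @export
build_blocks <- function(placements, track) {
  pl <- placements[placements$track == track, , drop = FALSE]
  empty <- tibble::tibble(model_genome = character(), chromosome = character(),
                          track = character(), group = integer(),
                          start_bp = integer(), end_bp = integer(),
                          start_pixel = integer(), end_pixel = integer(),
                          first_marker = character(), last_marker = character(),
                          support = integer())
  if (nrow(pl) == 0) return(empty)
  if (dplyr::n_distinct(pl$chromosome) > 1L) {
    stop("build_blocks expects placements of a single model chromosome",
         call. = FALSE)
  }
  markers <- pl |>
    dplyr::distinct(.data$marker, .data$start_bp) |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(start_bp = min(.data$start_bp), .groups = "drop") |>
    dplyr::arrange(.data$start_bp, .data$marker)
  label_sets <- lapply(markers$marker, function(m) unique(pl$group[pl$marker == m]))
  blocks <- list()
  for (g in sort(unique(pl$group))) {
    carries <- vapply(label_sets, function(s) g %in% s, logical(1))
    r <- rle(carries)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      first <- markers$marker[idx[1L]]
      last <- markers$marker[idx[length(idx)]]
      sub <- pl[pl$marker %in% markers$marker[idx] & pl$group == g, ]
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        model_genome = pl$model_genome[1L], chromosome = pl$chromosome[1L],
        track = track, group = g,
        start_bp = min(sub$start_bp), end_bp = max(sub$start_bp),
        start_pixel = min(sub$pixel), end_pixel = max(sub$pixel),
        first_marker = first, last_marker = last,
        support = length(idx))
    }
  }
  dplyr::arrange(dplyr::bind_rows(blocks), .data$start_bp, .data$group)
}

#' Build blocks for every model chromosome and track
#'
#' @param placements Full placement tibble.
#' @return Combined block tibble (see [build_blocks()]).
#' @export
build_all_blocks <- function(placements) {
  keys <- dplyr::distinct(placements, .data$model_genome, .data$chromosome,
                          .data$track)
  dplyr::bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    sub <- placements[placements$model_genome == keys$model_genome[i] &
                        placements$chromosome == keys$chromosome[i], ]
    build_blocks(sub, keys$track[i])
  }))
}

#' Call rearrangement regions between two tracks
#'
#' Scans the markers shared by two tracks along each model chromosome, in
#' start order, for maximal runs where the group labels of the two tracks
#' disagree on every marker (label sets disjoint) -- the signature of a
#' translocation or other structural rearrangement between the two genomes.
#' Runs supported by at least `min_support` markers are classed
#' `multi_marker` (the large-scale calls); the rest are `single_marker`.
#'
#' @param placements Full placement tibble.
#' @param track_a,track_b The two tracks to compare (e.g. `"U"` vs `"D"`).
#' @param min_support Minimum markers for a multi-marker call (default 2).
#' @return Call tibble (`model_genome`, `chromosome`, `track_a`, `track_b`,
#'   `first_marker`, `last_marker`, `start_bp`, `end_bp`, `groups_a`,
#'   `groups_b`, `support`, `class`).
#' @export
call_rearrangements <- function(placements, track_a, track_b,
                                min_support = 2L) {
  empty <- tibble::tibble(model_genome = character(), chromosome = character(),
                          track_a = character(), track_b = character(),
                          first_marker = character(), last_marker = character(),
                          start_bp = integer(), end_bp = integer(),
                          groups_a = character(), groups_b = character(),
                          support = integer(), class = character())
  keys <- dplyr::distinct(placements, .data$model_genome, .data$chromosome)
  calls <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- placements[placements$model_genome == keys$model_genome[i] &
                        placements$chromosome == keys$chromosome[i], ]
    a <- sub[sub$track == track_a, ]
    b <- sub[sub$track == track_b, ]
    shared <- intersect(a$marker, b$marker)
    if (length(shared) == 0) next
    ord <- sub |>
      dplyr::filter(.data$marker %in% shared) |>
      dplyr::distinct(.data$marker, .data$start_bp) |>
      dplyr::group_by(.data$marker) |>
      dplyr::summarise(start_bp = min(.data$start_bp), .groups = "drop") |>
      dplyr::arrange(.data$start_bp, .data$marker)
    discord <- vapply(ord$marker, function(m) {
      ga <- a$group[a$marker == m]
      gb <- b$group[b$marker == m]
      length(intersect(ga, gb)) == 0
    }, logical(1))
    r <- rle(discord)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      mk <- ord$marker[idx]
      calls[[length(calls) + 1L]] <- tibble::tibble(
        model_genome = keys$model_genome[i], chromosome = keys$chromosome[i],
        track_a = track_a, track_b = track_b,
        first_marker = mk[1L], last_marker = mk[length(mk)],
        start_bp = min(ord$start_bp[idx]), end_bp = max(ord$start_bp[idx]),
        groups_a = paste(sort(unique(a$group[a$marker %in% mk])), collapse = "/"),
        groups_b = paste(sort(unique(b$group[b$marker %in% mk])), collapse = "/"),
        support = length(mk),
        class = if (length(mk) >= min_support) "multi_marker" else "single_marker")
    }
  }
  if (length(calls) == 0) return(empty)
  dplyr::bind_rows(calls)
}

#' Summarise wheat-Aegilops homology
#'
#' Counts, per homoeologous group of the Aegilops chromosomes and per species
#' x genome, the markers supporting each wheat-D group -- the conserved-region
#' summary.  Markers without a wheat annotation are excluded from the counts
#' and reported in a remainder row (`wheat_group = NA`).
#'
#' @param assignments Assignment tibble.
#' @param wheat_annotation Tibble (`marker`, `wheat_group`).
#' @return Tibble (`genome`, `aegilops_group`, `species`, `wheat_group`,
#'   `n_markers`).
#' @export
homology_summary <- function(assignments, wheat_annotation) {
  assigned <- assignments[!is.na(assignments$chromosomes) &
                            nzchar(assignments$chromosomes) &
                            !(assignments$ambiguous %||% FALSE), , drop = FALSE]
  if (nrow(assigned) == 0) {
    return(tibble::tibble(genome = character(), aegilops_group = integer(),
                          species = character(), wheat_group = integer(),
                          n_markers = integer()))
  }
  loci <- assigned |>
    tidyr::separate_rows("chromosomes", sep = "/") |>
    dplyr::rename(chromosome = "chromosomes")
  p <- chrom_parse(loci$chromosome)
  loci$genome <- p$genome
  loci$aegilops_group <- p$group
  loci <- dplyr::left_join(loci,
                           dplyr::distinct(wheat_annotation[, c("marker", "wheat_group")]),
                           by = "marker")
  loci |>
    dplyr::distinct(.data$genome, .data$aegilops_group, .data$species,
                    .data$wheat_group, .data$marker) |>
    dplyr::count(.data$genome, .data$aegilops_group, .data$species,
                 .data$wheat_group, name = "n_markers") |>
    dplyr::arrange(.data$genome, .data$aegilops_group, .data$species,
                   .data$wheat_group)
}

#' Model-genome relationship table
#'
#' For each Aegilops chromosome (per track) lists the model-genome
#' chromosomes its markers hit, with per-chromosome marker counts; regions
#' represented by at least three markers are flagged `major`, single-marker
#' regions `single`.
#'
#' @param placements Placement tibble.
#' @param major_min Marker count for a major region (default 3).
#' @return Tibble (`track`, `group`, `model_genome`, `chromosome`,
#'   `n_markers`, `flag`).
#' @export
model_genome_relationship_table <- function(placements, major_min = 3L) {
  placements |>
    dplyr::filter(.data$track != "D") |>
    dplyr::distinct(.data$track, .data$group, .data$model_genome,
                    .data$chromosome, .data$marker) |>
    dplyr::count(.data$track, .data$group, .data$model_genome,
                 .data$chromosome, name = "n_markers") |>
    dplyr::mutate(flag = dplyr::case_when(
      .data$n_markers >= major_min ~ "major",
      .data$n_markers == 1L ~ "single",
      TRUE ~ "")) |>
    dplyr::arrange(.data$track, .data$group, .data$model_genome,
                   .data$chromosome)
}
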
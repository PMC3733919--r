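# Greedy 1 bp binning of amplicon sizes: two products of one marker are the
# same locus across samples when their sizes differ by at most `tol` bp
# (fragment-analyser sizing jitter).  The bin representative is the smallest
# member, so binning is deterministic.
bin_representative <- function(sizes, tol = 1L) {
  u <- sort(unique(sizes))
  rep_of <- integer(0)
  cur <- NA_integer_
  for (s in u) {
    if (is.na(cur) || s - cur > tol) cur <- s
    rep_of[as.character(s)] <- cur
  }
  unname(rep_of[as.character(sizes)])
}

# size-bin column per marker (and optionally species) for an observation table
add_size_bin <- function(tbl, tol = 1L, by_species = FALSE) {
  keys <- if (by_species) c("marker", "species") else "marker"
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(size_bin = bin_representative(.data$size_bp, tol)) |>
    dplyr::ungroup()
}

#' Classify Aegilops amplicons as polymorphic or non-polymorphic
#'
#' An Aegilops PCR product shows a significant length polymorphism relative to
#' wheat when no product of the same marker in any parental wheat genotype
#' lies within `polymorphism_min_bp - 1` bp of it (default: differences of
#' >= 2 bp count).  A product with no wheat amplicon at all for its marker is
#' a presence/absence polymorphism and is classified polymorphic.
#' Classification operates per (marker, species, size) after 1 bp binning.
#'
#' @param obs Observation tibble from [read_fragment_table()].
#' @param wheat_parent_ids Sample ids of the parental wheat genotypes used as
#'   the reference set (e.g. Chinese Spring, Mv9kr1, Mv25).
#' @param thresholds Threshold list from [default_thresholds()].
#' @return A tibble with one row per distinct Aegilops product
#'   (`marker`, `species`, `size_bp`, `polymorphic`, `nearest_wheat_size`,
#'   `delta_bp`).
#' @export
classify_polymorphism <- function(obs, wheat_parent_ids,
                                  thresholds = default_thresholds()) {
  wheat <- obs[obs$sample %in% wheat_parent_ids & obs$kind == "wheat_parent", ]
  if (nrow(wheat) == 0) {
    stop("no wheat-parent observations found for the supplied sample ids",
         call. = FALSE)
  }
  aeg <- obs[obs$kind == "aegilops_parent", ]
  if (nrow(aeg) == 0) {
    return(tibble::tibble(marker = character(), species = character(),
                          size_bp = integer(), polymorphic = logical(),
                          nearest_wheat_size = integer(), delta_bp = integer()))
  }
  min_bp <- thresholds$polymorphism_min_bp
  aeg <- add_size_bin(aeg)
  wheat_sizes <- split(wheat$size_bp, wheat$marker)
  aeg |>
    dplyr::group_by(.data$marker, .data$species, .data$size_bin) |>
    dplyr::summarise(sizes = list(unique(.data$size_bp)), .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      nearest_wheat_size = {
        ws <- wheat_sizes[[.data$marker]]
        if (is.null(ws)) NA_integer_ else {
          d <- abs(outer(unlist(.data$sizes), ws, "-"))
          ws[which(d == min(d), arr.ind = TRUE)[1L, 2L]]
        }
      },
      delta_bp = if (is.na(.data$nearest_wheat_size)) NA_integer_ else
        min(abs(unlist(.data$sizes) - .data$nearest_wheat_size))
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      size_bp = .data$size_bin,
      polymorphic = is.na(.data$delta_bp) | .data$delta_bp >= min_bp
    ) |>
    dplyr::select("marker", "species", "size_bp", "polymorphic",
                  "nearest_wheat_size", "delta_bp")
}

#' Summarise PCR products per marker and genotype
#'
#' Counts distinct products (after 1 bp binning) per marker x Aegilops
#' genotype pair with at least one product; the grand mean is total products
#' divided by the number of such pairs.
#'
#' @param obs Observation tibble.
#' @return A list with `per_pair` (marker, sample, n_products),
#'   `n_pairs`, `total_products`, `mean_products` and `product_range`.
#' @export
summarize_products <- function(obs) {
  gt <- obs[obs$kind == "aegilops_parent", ]
  if (nrow(gt) == 0) {
    return(list(per_pair = tibble::tibble(marker = character(),
                                          sample = character(),
                                          n_products = integer()),
                n_pairs = 0L, total_products = 0L,
                mean_products = NA_real_, product_range = c(NA_integer_, NA_integer_)))
  }
  per_pair <- gt |>
    add_size_bin() |>
    dplyr::distinct(.data$marker, .data$sample, .data$size_bin) |>
    dplyr::count(.data$marker, .data$sample, name = "n_products")
  list(
    per_pair = per_pair,
    n_pairs = nrow(per_pair),
    total_products = sum(per_pair$n_products),
    mean_products = sum(per_pair$n_products) / nrow(per_pair),
    product_range = range(per_pair$n_products)
  )
}

#' Select markers suitable for marker-assisted selection
#'
#' A locus is suitable for tracking Aegilops chromatin in a wheat background
#' when it is length-polymorphic relative to the parental wheat genotypes
#' (>= 2 bp) and has been assigned -- directly or by the cross-species
#' transfer rule -- to an Aegilops chromosome.
#'
#' @param assignments Assignment tibble (see [assign_loci()]) or any tibble
#'   with columns `marker`, `species`, `size_bp`, `chromosomes` (slash-joined
#'   labels) and optionally `polymorphic` and `evidence`.
#' @param product_classes Optional classification tibble from
#'   [classify_polymorphism()]; when supplied, polymorphism is looked up there
#'   instead of from an `assignments$polymorphic` column.
#' @return A list with `loci` (one row per suitable locus placement:
#'   `group`, `genome`, `chromosome`, `species`, `marker`, `size_bp`,
#'   `predicted`), `by_group` (locus counts per homoeologous group x genome x
#'   species), `n_markers` (distinct suitable markers) and `n_loci`.
#' @export
select_suitable_markers <- function(assignments, product_classes = NULL) {
  a <- assignments
  if (!is.null(product_classes)) {
    a <- dplyr::left_join(
      dplyr::select(a, -dplyr::any_of("polymorphic")),
      dplyr::select(product_classes, "marker", "species", "size_bp", "polymorphic"),
      by = c("marker", "species", "size_bp"))
  }
  if (!"polymorphic" %in% names(a)) {
    stop("polymorphism status unavailable: supply product_classes or a polymorphic column",
         call. = FALSE)
  }
  if (!"evidence" %in% names(a)) a$evidence <- "line"
  suitable <- a |>
    dplyr::filter(!is.na(.data$polymorphic), .data$polymorphic,
                  !is.na(.data$chromosomes), nzchar(.data$chromosomes))
  loci <- suitable |>
    tidyr::separate_rows("chromosomes", sep = "/") |>
    dplyr::rename(chromosome = "chromosomes")
  p <- chrom_parse(loci$chromosome)
  loci$group <- p$group
  loci$genome <- p$genome
  loci <- loci |>
    dplyr::mutate(predicted = .data$evidence == "transferred") |>
    dplyr::select("group", "genome", "chromosome", "species", "marker",
                  "size_bp", "predicted") |>
    dplyr::arrange(.data$genome, .data$group, .data$species, .data$marker,
                   .data$size_bp)
  by_group <- loci |>
    dplyr::count(.data$genome, .data$group, .data$species, name = "n_loci")
  list(loci = loci, by_group = by_group,
       n_markers = dplyr::n_distinct(loci$marker), n_loci = nrow(loci))
}
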
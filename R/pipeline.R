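#' Run the full analysis pipeline
#'
#' Chains every stage: polymorphism classification, chromosome assignment
#' (introgression lines, peak yields, cross-species transfer), suitability
#' summary, duplication detection and grouping, hit filtering and best-hit
#' placement, synteny blocks, rearrangement calls, and the homology and
#' model-genome relationship summaries.  All results are returned in memory;
#' when `out_dir` is given each table is also written as TSV with a header
#' comment recording the package version, seed and thresholds, so re-running
#' a stage on identical inputs yields byte-identical files.
#'
#' @param obs Observation tibble ([read_fragment_table()] shape).
#' @param panel Karyotype tibble ([read_line_karyotypes()] shape).
#' @param comp Peak-composition tibble.
#' @param wheat_parent_ids Parental wheat sample ids.
#' @param hits Hit tibble ([read_hit_table()] shape), or `NULL` to skip the
#'   synteny stage.
#' @param wheat_annotation Tibble (`marker`, `wheat_group`), or `NULL`.
#' @param chrom_lengths Model-chromosome length tibble (required with
#'   `hits`).
#' @param thresholds Threshold list from [default_thresholds()].
#' @param tau_min,presence_fraction,tol Assignment parameters (see
#'   [assign_loci()]).
#' @param min_support Minimum markers for a multi-marker rearrangement call.
#' @param canvas_width_px Physical-map canvas width.
#' @param track_pairs List of track pairs to scan for rearrangements.
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in output headers (the pipeline itself is
#'   deterministic).
#' @return A named list of stage results.
#' @export
run_pipeline <- function(obs, panel, comp, wheat_parent_ids,
                         hits = NULL, wheat_annotation = NULL,
                         chrom_lengths = NULL,
                         thresholds = default_thresholds(), tau_min = 0.8,
                         presence_fraction = 0.05, tol = 1L,
                         min_support = 2L, canvas_width_px = 1000L,
                         track_pairs = list(c("U", "D"), c("M", "D"),
                                            c("U", "M")),
                         out_dir = NULL, seed = NA_integer_) {
  classes <- classify_polymorphism(obs, wheat_parent_ids, thresholds)
  assignments <- assign_loci(obs, panel, comp, wheat_parent_ids, thresholds,
                             tau_min, presence_fraction, tol)
  suitability <- select_suitable_markers(assignments)
  dup_records <- detect_marker_duplications(assignments)
  dup_events <- group_duplication_events(dup_records)

  res <- list(classes = classes, assignments = assignments,
              suitability = suitability, dup_records = dup_records,
              dup_events = dup_events)

  if (!is.null(hits)) {
    if (is.null(chrom_lengths)) {
      stop("chrom_lengths is required when hits are supplied", call. = FALSE)
    }
    significant <- filter_hits(hits, thresholds)
    best <- select_best_hit(significant)
    placements <- make_placements(best, assignments, wheat_annotation,
                                  chrom_lengths, canvas_width_px)
    blocks <- build_all_blocks(placements)
    rearr <- dplyr::bind_rows(lapply(track_pairs, function(p)
      call_rearrangements(placements, p[1], p[2], min_support)))
    res$best_hits <- best
    res$placements <- placements
    res$blocks <- blocks
    res$rearrangements <- rearr
    if (!is.null(wheat_annotation)) {
      res$homology <- homology_summary(assignments, wheat_annotation)
    }
    res$relationships <- model_genome_relationship_table(placements)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- sprintf(
      "# cosmap %s | seed=%s | e_max=%g identity_min=%g length_min=%g poly_min_bp=%d tau_min=%g presence_fraction=%g min_support=%d",
      as.character(utils::packageVersion("cosmap")), seed,
      thresholds$e_max, thresholds$identity_min, thresholds$length_min,
      thresholds$polymorphism_min_bp, tau_min, presence_fraction, min_support)
    emit <- function(tbl, name) {
      if (is.null(tbl)) return(invisible(NULL))
      path <- file.path(out_dir, paste0(name, ".tsv"))
      writeLines(hdr, path)
      suppressWarnings(readr::write_tsv(tbl, path, append = TRUE,
                                        col_names = TRUE))
    }
    emit(res$classes, "product_classes")
    emit(res$assignments, "assignments")
    emit(res$suitability$loci, "suitable_loci")
    emit(res$dup_records, "duplication_records")
    emit(res$dup_events, "duplication_events")
    emit(res$best_hits, "best_hits")
    emit(res$placements, "placements")
    emit(res$blocks, "synteny_blocks")
    emit(res$rearrangements, "rearrangements")
    emit(res$homology, "homology_summary")
    emit(res$relationships, "model_relationships")
    if (!is.null(res$placements)) {
      write_map_bed(res$placements, file.path(out_dir, "placements.bed"))
    }
  }
  res
}

#' Run the pipeline end-to-end on simulated data
#'
#' Convenience wrapper: generates a synthetic study, emits its fragment and
#' hit tables, runs [run_pipeline()] and scores recovery against the planted
#' truth.
#'
#' @param config Configuration from [sim_config()].
#' @param seed Integer seed for the whole run.
#' @param noise Noise list from [sim_noise()].
#' @param ... Passed on to [run_pipeline()].
#' @return A list: `truth`, pipeline results (see [run_pipeline()]) and
#'   `metrics` from [score_recovery()].
#' @export
run_simulated_pipeline <- function(config = sim_config(), seed = 1L,
                                   noise = sim_noise(), ...) {
  truth <- generate_truth(config, seed)
  obs <- emit_fragment_table(truth, noise)
  hits <- emit_hit_table(truth)
  res <- run_pipeline(obs, truth$panel, truth$composition,
                      wheat_parent_ids = "wheat_CS", hits = hits,
                      wheat_annotation = truth$wheat_annotation,
                      chrom_lengths = truth$chrom_lengths,
                      canvas_width_px = truth$config$canvas_width_px,
                      seed = seed, ...)
  u_vs_d <- res$rearrangements[res$rearrangements$track_a == "U" &
                                 res$rearrangements$track_b == "D", ]
  res$truth <- truth
  res$metrics <- score_recovery(res$assignments, res$dup_records, u_vs_d,
                                truth)
  res
}
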
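mk_hit <- function(query, chrom = "Br1", start = 1000L, score = 200,
                   e_value = 1e-20, identity = 85, len = 240L,
                   genome = "brachypodium") {
  tibble::tibble(query_id = query, model_genome = genome, chromosome = chrom,
                 start = as.integer(start), end = as.integer(start + len - 1L),
                 orientation = "plus", score = score, e_value = e_value,
                 identity_pct = identity, aln_length = as.integer(len))
}

test_that("hit filtering is strict on all three thresholds and antitone", {
  base <- mk_hit("q")
  expect_equal(nrow(filter_hits(base)), 1L)
  expect_equal(nrow(filter_hits(mk_hit("q", e_value = 2.8e-08))), 0L)
  expect_equal(nrow(filter_hits(mk_hit("q", identity = 58.44))), 0L)
  expect_equal(nrow(filter_hits(mk_hit("q", len = 100L))), 0L)
  # antitonicity: tightening any threshold never adds hits
  set.seed(5)
  pool <- dplyr::bind_rows(lapply(1:120, function(i)
    mk_hit(paste0("q", i), e_value = 10^-stats::runif(1, 2, 30),
           identity = stats::runif(1, 40, 100),
           len = sample(50:400, 1))))
  loose <- default_thresholds()
  for (tight in list(default_thresholds(e_max = 1e-12),
                     default_thresholds(identity_min = 80),
                     default_thresholds(length_min = 200))) {
    expect_true(all(filter_hits(pool, tight)$query_id %in%
                      filter_hits(pool, loose)$query_id))
  }
})

test_that("best-hit selection maximises score with deterministic tie-breaks", {
  three <- dplyr::bind_rows(mk_hit("q", score = 100), mk_hit("q", score = 250),
                            mk_hit("q", score = 90))
  expect_equal(select_best_hit(three)$score, 250)
  tie <- dplyr::bind_rows(mk_hit("q", score = 250, e_value = 1e-10),
                          mk_hit("q", score = 250, e_value = 1e-30))
  expect_equal(select_best_hit(tie)$e_value, 1e-30)
  pos_tie <- dplyr::bind_rows(mk_hit("q", start = 900L),
                              mk_hit("q", start = 200L))
  expect_equal(select_best_hit(pos_tie)$start, 200L)
  chrom_tie <- dplyr::bind_rows(mk_hit("q", chrom = "Br3"),
                                mk_hit("q", chrom = "Br1"))
  expect_equal(select_best_hit(chrom_tie)$chromosome, "Br1")
  expect_equal(nrow(select_best_hit(three[0, ])), 0L)
})

test_that("canvas scaling is exact at the edges, monotone and bounded", {
  expect_equal(scale_to_canvas(1, 1e6, 1000), 0L)
  expect_equal(scale_to_canvas(1e6, 1e6, 1000), 999L)
  expect_equal(scale_to_canvas(50000001, 100000000, 1000), 500L)
  xs <- sort(sample.int(1e6, 200))
  px <- scale_to_canvas(xs, 1e6, 777)
  expect_true(all(diff(px) >= 0))
  expect_true(all(px >= 0 & px < 777))
  expect_error(scale_to_canvas(1e6 + 1, 1e6, 1000), "outside")
})

mk_placements <- function(labels_per_marker, track = "U") {
  rows <- list()
  for (i in seq_along(labels_per_marker)) {
    for (g in labels_per_marker[[i]]) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        marker = sprintf("m%02d", i), model_genome = "brachypodium",
        chromosome = "Br1", start_bp = i * 1000L, aln_length = 240L,
        pixel = i * 10L, track = track, group = g)
    }
  }
  dplyr::bind_rows(rows)
}

test_that("blocks are maximal runs matching the run-length oracle", {
  for (labels in list(c(3, 3, 3, 7, 7), c(3, 7, 3), c(5))) {
    pl <- mk_placements(as.list(labels))
    blocks <- build_blocks(pl, "U")
    oracle <- run_length_oracle(labels)
    expect_equal(nrow(blocks), length(oracle))
    ord <- order(blocks$start_bp)
    for (k in seq_along(oracle)) {
      expect_equal(blocks$group[ord][k], oracle[[k]]$label)
      expect_equal(blocks$support[ord][k], oracle[[k]]$len)
    }
    # partition: total support equals the number of (marker, label) pairs
    expect_equal(sum(blocks$support), nrow(pl))
  }
})

test_that("a marker with two labels joins blocks of both labels", {
  pl <- mk_placements(list(3, c(3, 7), 7))
  blocks <- build_blocks(pl, "U")
  expect_equal(nrow(blocks), 2L)
  b3 <- blocks[blocks$group == 3, ]
  b7 <- blocks[blocks$group == 7, ]
  expect_equal(b3$support, 2L)
  expect_equal(b7$support, 2L)
  expect_equal(b3$last_marker, "m02")
  expect_equal(b7$first_marker, "m02")
})

test_that("rearrangement calls find maximal discordant runs with support classes", {
  two_tracks <- function(u_labels, d_labels) {
    dplyr::bind_rows(mk_placements(as.list(u_labels), "U"),
                     mk_placements(as.list(d_labels), "D"))
  }
  # a three-marker discordant interior run (labels 6 vs 4)
  pl <- two_tracks(c(6, 4, 4, 4, 6), c(6, 6, 6, 6, 6))
  calls <- call_rearrangements(pl, "U", "D")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$first_marker, "m02")
  expect_equal(calls$last_marker, "m04")
  expect_equal(calls$support, 3L)
  expect_equal(calls$class, "multi_marker")
  expect_equal(calls$groups_a, "4")
  expect_equal(calls$groups_b, "6")
  # concordant everywhere: no calls
  expect_equal(nrow(call_rearrangements(two_tracks(c(3, 3), c(3, 3)), "U", "D")),
               0L)
  # one discordant marker flanked by concordant ones: single_marker class
  single <- call_rearrangements(two_tracks(c(3, 5, 3), c(3, 3, 3)), "U", "D")
  expect_equal(single$class, "single_marker")
  expect_equal(single$support, 1L)
  # a marker sharing one label with the other track is concordant
  dual <- dplyr::bind_rows(mk_placements(list(c(4, 6)), "U"),
                           mk_placements(list(6), "D"))
  expect_equal(nrow(call_rearrangements(dual, "U", "D")), 0L)
})

test_that("homology summary counts markers per wheat group with a remainder row", {
  a <- tibble::tibble(marker = c("Xa", "Xb"), size_bp = c(200L, 300L),
                      species = "umbellulata", chromosomes = c("3U", "3U"),
                      evidence = "line", polymorphic = TRUE, ambiguous = FALSE)
  annot <- tibble::tibble(marker = "Xa", wheat_group = 3L)
  hs <- homology_summary(a, annot)
  expect_equal(hs$n_markers[hs$wheat_group == 3 & !is.na(hs$wheat_group)], 1L)
  expect_equal(hs$n_markers[is.na(hs$wheat_group)], 1L)  # Xb unannotated
  expect_equal(nrow(homology_summary(a[0, ], annot)), 0L)
})

test_that("model-genome relationships flag major and single-marker regions", {
  pl <- dplyr::bind_rows(
    mk_placements(list(4, 4, 4), "U"),       # three group-4 markers on Br1
    mk_placements(list(2), "Ub"))            # one marker on the Ub track
  rel <- model_genome_relationship_table(pl)
  major <- rel[rel$track == "U", ]
  expect_equal(major$n_markers, 3L)
  expect_equal(major$flag, "major")
  single <- rel[rel$track == "Ub", ]
  expect_equal(single$flag, "single")
  # the D track is annotation, not a hit-derived relationship
  expect_false("D" %in% model_genome_relationship_table(
    mk_placements(list(1), "D"))$track)
})
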
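small_cfg <- function(...) {
  args <- list(...)
  if (is.null(args$n_rearrangements)) args$n_rearrangements <- 2L
  do.call(sim_config, c(list(n_markers = 30L), args))
}

test_that("truth and emitted tables are reproducible from (config, seed)", {
  t1 <- generate_truth(small_cfg(), seed = 5)
  t2 <- generate_truth(small_cfg(), seed = 5)
  expect_identical(t1$loci, t2$loci)
  expect_identical(t1$rearrangements, t2$rearrangements)
  expect_identical(t1$composition, t2$composition)
  # the full emitted files are byte-identical across runs
  emit_once <- function() {
    truth <- generate_truth(small_cfg(), seed = 5)
    obs <- emit_fragment_table(truth, sim_noise(0.3, 0.05, 1L))
    hits <- emit_hit_table(truth, jitter = 10)
    f1 <- tempfile(); f2 <- tempfile()
    readr::write_tsv(obs, f1)
    write_hit_table(hits, f2)
    c(tools::md5sum(f1), tools::md5sum(f2))
  }
  expect_identical(unname(emit_once()), unname(emit_once()))
  # a different seed changes the data
  t3 <- generate_truth(small_cfg(), seed = 6)
  expect_false(identical(t1$loci, t3$loci))
})

test_that("planted features follow the configuration", {
  none <- generate_truth(small_cfg(duplication_rate = 0), seed = 2)
  expect_equal(nrow(none$duplications), 0L)
  per_genome <- dplyr::count(none$loci, .data$marker, .data$species,
                             .data$genome)
  expect_true(all(per_genome$n == 1L))

  two <- generate_truth(small_cfg(n_rearrangements = 2), seed = 2)
  expect_equal(nrow(two$rearrangements), 2L)
  # rearranged markers really carry a shifted U group
  for (i in 1:2) {
    mk <- two$rearrangements$first_marker[i]
    expect_equal(two$markers$u_group[two$markers$marker == mk],
                 two$rearrangements$rearranged_group[i])
  }
  expect_error(generate_truth(sim_config(n_markers = 8, n_rearrangements = 8)),
               "infeasible")
})

test_that("zero-noise yields equal content fractions and jitter is bounded", {
  truth <- generate_truth(small_cfg(duplication_rate = 0), seed = 3)
  obs <- emit_fragment_table(truth, sim_noise(0, 0, 0))
  frac <- obs[obs$kind == "peak_fraction" & obs$species == "umbellulata", ]
  m <- cosmap:::content_matrix(truth$composition, "umbellulata")
  locus <- truth$loci[truth$loci$species == "umbellulata", ][1, ]
  y <- frac[frac$marker == locus$marker, ]
  expect_equal(y$yield[match(c("I", "II", "III", "IV"), y$peak)],
               unname(m[locus$chromosome, ]) / 100)

  jit <- emit_fragment_table(truth, sim_noise(0, 0, 1L))
  joined <- dplyr::inner_join(
    jit[jit$kind == "aegilops_parent", c("marker", "species", "size_bp")],
    truth$loci, by = c("marker", "species"), relationship = "many-to-many")
  expect_true(min(abs(joined$size_bp.x - joined$size_bp.y)) <= 1L)
  # every observed size is within 1 bp of some true locus size of its marker
  dev <- dplyr::group_by(joined, .data$marker, .data$species, .data$size_bp.x) |>
    dplyr::summarise(d = min(abs(.data$size_bp.x - .data$size_bp.y)),
                     .groups = "drop")
  expect_true(all(dev$d <= 1L))
})

test_that("decoy hits fall to the filter and best hits recover the truth", {
  truth <- generate_truth(small_cfg(), seed = 4)
  hits <- emit_hit_table(truth, jitter = 0)
  kept <- filter_hits(hits)
  # the three threshold-violating decoys per marker are gone
  expect_equal(nrow(kept), 2L * truth$config$n_markers)
  best <- select_best_hit(kept)
  expect_equal(nrow(best), truth$config$n_markers)
  mp <- truth$model_positions[match(best$query_id, truth$model_positions$marker), ]
  expect_equal(best$chromosome, mp$chromosome)
  expect_equal(best$start, mp$start_bp)
  # order along each model chromosome equals the true order
  for (ch in unique(mp$chromosome)) {
    got <- best$query_id[best$chromosome == ch][order(best$start[best$chromosome == ch])]
    want <- mp$marker[mp$chromosome == ch][order(mp$start_bp[mp$chromosome == ch])]
    expect_equal(got, want)
  }
})

test_that("recovery scoring detects label shuffles and dropout degradation", {
  cfg <- small_cfg(duplication_rate = 0, n_rearrangements = 0,
                   peak_structure = "distinct")
  truth <- generate_truth(cfg, seed = 9)
  obs <- emit_fragment_table(truth, sim_noise(0, 0, 0))
  a <- assign_loci(obs, truth$panel, truth$composition, "wheat_CS")
  no_calls <- tibble::tibble(chromosome = character(),
                             first_marker = character(),
                             last_marker = character())
  clean <- score_recovery(a, detect_marker_duplications(a), no_calls, truth)
  expect_equal(clean$assignment_accuracy, 1)

  # shuffling the truth labels sends accuracy towards chance
  shuffled <- truth
  set.seed(1)
  shuffled$loci$chromosome <- ave(
    shuffled$loci$chromosome,
    paste(shuffled$loci$species, shuffled$loci$genome),
    FUN = function(x) sample(x))
  mixed <- score_recovery(a, detect_marker_duplications(a), no_calls, shuffled)
  expect_lt(mixed$assignment_accuracy, 0.5)

  # dropout loses loci (recall) without inventing duplications (precision)
  truth_d <- generate_truth(small_cfg(duplication_rate = 0.3), seed = 9)
  obs_d <- emit_fragment_table(truth_d, sim_noise(0, 0.5, 0))
  a_d <- assign_loci(obs_d, truth_d$panel, truth_d$composition, "wheat_CS")
  dropped <- score_recovery(a_d, detect_marker_duplications(a_d), no_calls,
                            truth_d)
  expect_lt(dropped$assignment_accuracy, 1)
  expect_equal(dropped$duplication_precision, 1)
})
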
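test_that("introgression assignment matches the brute-force consistency oracle", {
  panel <- biuncialis_mini_panel()
  # every presence pattern over the three lines, against the oracle that
  # enumerates single chromosomes consistent with the pattern
  for (code in 0:7) {
    present <- as.logical(bitwAnd(code, c(4L, 2L, 1L)) > 0)
    obs <- pattern_obs(present)
    got <- assign_by_introgression("Xq", 400L, "biuncialis", panel, obs,
                                   "wheat_CS")
    want <- introgression_oracle(panel$added, present)
    expect_equal(sort(as.character(got)), want,
                 info = paste("pattern", paste(as.integer(present), collapse = "")))
  }
  # the double addition minus the single addition isolates 6Ub
  got <- assign_by_introgression("Xq", 400L, "biuncialis", panel,
                                 pattern_obs(c(FALSE, TRUE, FALSE)), "wheat_CS")
  expect_equal(as.character(got), "6Ub")
})

test_that("a multi-chromosome line without a disambiguating single line yields its full set", {
  panel <- biuncialis_mini_panel()[2:3, ]  # only 1Ub6Ub and 3Ub
  obs <- pattern_obs(c(FALSE, TRUE, FALSE))
  obs <- obs[obs$sample != "L_1Ub", ]
  got <- assign_by_introgression("Xq", 400L, "biuncialis", panel, obs,
                                 "wheat_CS")
  expect_equal(sort(as.character(got)), c("1Ub", "6Ub"))
})

test_that("wheat-shared products are non-diagnostic and parents are required", {
  panel <- biuncialis_mini_panel()
  obs <- pattern_obs(c(FALSE, TRUE, FALSE))
  obs$size_bp[obs$sample == "wheat_CS"] <- 400L  # same size in wheat
  got <- assign_by_introgression("Xq", 400L, "biuncialis", panel, obs,
                                 "wheat_CS")
  expect_length(got, 0L)
  expect_equal(attr(got, "reason"), "non-diagnostic")

  no_parent <- pattern_obs(c(FALSE, TRUE, FALSE))
  no_parent <- no_parent[no_parent$kind != "aegilops_parent", ]
  got2 <- assign_by_introgression("Xq", 400L, "biuncialis", panel, no_parent,
                                  "wheat_CS")
  expect_equal(attr(got2, "reason"), "absent_in_parent")
})

test_that("arm-level stocks restrict whole-chromosome calls to one arm", {
  panel <- tibble::tibble(
    line_id = c("L_3Mb", "L_fusion"),
    species = "biuncialis", background = "Mv9kr1",
    added = list("3Mb", c("3MbL", "4BS")),
    removed = list(character(0), character(0)))
  base <- function(fusion_present) {
    rows <- list(
      list("Xq", "aeg_biuncialis", "aegilops_parent", "biuncialis", "", "400", "1"),
      list("Xq", "L_3Mb", "introgression_line", "biuncialis", "", "400", "1"),
      list("Xq", "wheat_CS", "wheat_parent", "wheat", "", "450", "1"))
    if (fusion_present) {
      rows <- c(rows, list(list("Xq", "L_fusion", "introgression_line",
                                "biuncialis", "", "400", "1")))
    }
    do.call(obs_tbl, rows)
  }
  on_arm <- assign_by_introgression("Xq", 400L, "biuncialis", panel,
                                    base(TRUE), "wheat_CS")
  expect_equal(as.character(on_arm), "3MbL")
  off_arm <- assign_by_introgression("Xq", 400L, "biuncialis", panel,
                                     base(FALSE), "wheat_CS")
  expect_equal(as.character(off_arm), "3MbS")
})

test_that("the Kendall statistic agrees with a brute-force pair-counting oracle", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- sample(0:5, n, replace = TRUE)
    expected <- kendall_oracle(x, y)
    got <- suppressWarnings(stats::cor(x, y, method = "kendall"))
    if (is.na(expected)) expect_true(is.na(got)) else
      expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("a monotone yield profile scores its carrier chromosome at tau 1", {
  scores <- score_peak_concordance(fig1_profile(), table1_comp(), "umbellulata",
                                   control_yield = 12)
  top <- scores[1, ]
  expect_equal(top$chromosome, "1U")
  expect_equal(top$tau, 1)
  expect_true(top$presence_consistent)
  # no other chromosome is presence-consistent with tau above threshold
  rest <- scores[-1, ]
  expect_true(all(!rest$presence_consistent | rest$tau < 0.8))
})

test_that("degenerate yield profiles resolve as specified", {
  comp <- table1_comp()
  # uniform yields: nothing qualifies
  uniform <- score_peak_concordance(c(I = 1, II = 1, III = 1, IV = 1), comp,
                                    "umbellulata", control_yield = 1)
  expect_length(assign_by_peak_yield(uniform), 0L)
  # all-zero yields: empty score set with a reason
  dead <- score_peak_concordance(c(I = 0, II = 0, III = 0, IV = 0), comp,
                                 "umbellulata")
  expect_equal(attr(dead, "reason"), "no amplification")
  expect_length(assign_by_peak_yield(dead), 0L)
  # two peaks, one chromosome each, yields (1, 0): only A survives
  two <- tibble::tibble(species = "sp",
                        peak = c("I", "II"),
                        chromosome = c("1U", "2U"), percent = c(100, 100))
  sc <- score_peak_concordance(c(I = 1, II = 0), two, "sp", control_yield = 1)
  expect_equal(assign_by_peak_yield(sc), "1U")
})

test_that("peak-yield assignment is monotone in tau_min and flags co-sorted sets", {
  scores <- score_peak_concordance(c(I = 0, II = 0, III = 0, IV = 5),
                                   table1_comp(), "umbellulata",
                                   control_yield = 5)
  res <- assign_by_peak_yield(scores, tau_min = 0.8)
  expect_setequal(res, c("2U", "4U", "5U", "7U"))  # identical content vectors
  expect_true(attr(res, "ambiguous"))
  expect_length(assign_by_peak_yield(scores, tau_min = 1.01), 0L)
  # raising tau_min never adds assignments
  fig <- score_peak_concordance(fig1_profile(), table1_comp(), "umbellulata",
                                control_yield = 12)
  sets <- lapply(c(0.2, 0.5, 0.8, 0.95), function(tm)
    as.character(assign_by_peak_yield(fig, tm)))
  for (k in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[k + 1]] %in% sets[[k]]))
  }
})

test_that("cross-species transfer follows the anchored homoeologue", {
  sc <- x2n_scenario()
  final <- assign_loci(sc$obs, sc$panel, sc$comp, "wheat_CS")
  transferred <- final[final$evidence == "transferred", ]
  expect_setequal(transferred$chromosomes, c("2U", "2Ub"))
  expect_equal(unique(transferred$anchor_chromosome), "2Ug")
  # transfer preserves genome and homoeologous group
  p <- chrom_parse(transferred$chromosomes)
  expect_true(all(p$genome == "U" & p$group == 2))
  # the anchor itself stays a line assignment
  anchor <- final[final$species == "geniculata", ]
  expect_equal(anchor$chromosomes, "2Ug")
  expect_equal(anchor$evidence, "line")
})

test_that("transfer declines without a same-sized product or carrier peak and on conflicts", {
  comp <- table1_comp()
  profiles <- tibble::tibble(
    marker = "Xq", species = "umbellulata", size_bp = 300L,
    yields = list(c(I = 9, II = 0, III = 0, IV = 0)),  # argmax peak I
    control_yield = 9)
  anchor <- tibble::tibble(marker = "Xq", size_bp = 300L,
                           species = "geniculata", chromosomes = "4Ug",
                           ambiguous = FALSE)
  # peak I of umbellulata does not carry 4U: no transfer
  expect_equal(nrow(transfer_across_species(anchor, profiles, comp)), 0L)
  # no same-sized product in the other species: no transfer
  far <- dplyr::mutate(profiles, size_bp = 500L)
  expect_equal(nrow(transfer_across_species(anchor, far, comp)), 0L)
  # conflicting anchors in two species suppress the transfer and log it
  conflict <- dplyr::bind_rows(
    anchor,
    tibble::tibble(marker = "Xq", size_bp = 300L, species = "comosa",
                   chromosomes = "2M", ambiguous = FALSE))
  res <- transfer_across_species(conflict, profiles, comp)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "conflicts"), "Xq:300")
})

test_that("evidence reconciliation follows the precedence table", {
  key <- tibble::tibble(marker = "X", size_bp = 100L, species = "umbellulata")
  line <- function(ch) dplyr::mutate(key, chromosomes = ch, reason = NA_character_)
  peak <- function(ch, amb = FALSE) dplyr::mutate(key, chromosomes = ch,
                                                  ambiguous = amb,
                                                  reason = NA_character_)
  both <- reconcile_evidence(line("1U"), peak("1U"))
  expect_equal(both$evidence, "both")
  expect_equal(both$chromosomes, "1U")

  line_only <- reconcile_evidence(line("1U"), peak(""))
  expect_equal(line_only$evidence, "line")

  clash <- reconcile_evidence(line("1U"), peak("3U"))
  expect_equal(clash$chromosomes, "1U")   # line evidence wins
  expect_true(clash$conflict)
  expect_match(clash$reason, "3U")

  peak_only <- reconcile_evidence(line(""), peak("3U"))
  expect_equal(peak_only$evidence, "peak_yield")

  neither <- reconcile_evidence(
    dplyr::mutate(key, chromosomes = "", reason = "no_panel_lines"),
    dplyr::mutate(key, chromosomes = "", ambiguous = FALSE,
                  reason = "no_peak_profile"))
  expect_equal(neither$evidence, "unassigned")
  expect_match(neither$reason, "no_panel_lines; no_peak_profile")
})
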
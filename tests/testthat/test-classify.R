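test_that("polymorphism classification enumerates the size-difference boundary", {
  # wheat allele at 300 bp; Aegilops products at deltas 0..3
  for (delta in 0:3) {
    obs <- obs_tbl(
      list("Xa", "wheat_CS", "wheat_parent", "wheat", "", "300", "1"),
      list("Xa", "aeg_comosa", "aegilops_parent", "comosa", "",
           as.character(300 + delta), "1"))
    cls <- classify_polymorphism(obs, "wheat_CS")
    expect_equal(cls$polymorphic, delta >= 2,
                 info = paste("delta =", delta))
    expect_equal(cls$delta_bp, delta)
    expect_equal(cls$nearest_wheat_size, 300L)
  }
})

test_that("a null wheat allele counts as polymorphism and no wheat samples error", {
  obs <- obs_tbl(
    list("Xa", "wheat_CS", "wheat_parent", "wheat", "", "300", "1"),
    list("Xb", "aeg_comosa", "aegilops_parent", "comosa", "", "410", "1"))
  cls <- classify_polymorphism(obs, "wheat_CS")
  expect_true(cls$polymorphic)
  expect_true(is.na(cls$delta_bp))
  expect_error(classify_polymorphism(obs, "nonexistent_sample"), "wheat-parent")
})

test_that("classification partitions products and is monotone in the threshold", {
  set.seed(42)
  rows <- lapply(seq_len(60), function(i) {
    list(paste0("X", sample(8, 1)), "aeg_umb", "aegilops_parent",
         "umbellulata", "", as.character(sample(100:140, 1)), "1")
  })
  wheat <- lapply(1:8, function(i) {
    list(paste0("X", i), "wheat_CS", "wheat_parent", "wheat", "",
         as.character(sample(100:140, 1)), "1")
  })
  obs <- do.call(obs_tbl, c(rows, wheat))
  counts <- vapply(1:6, function(mb) {
    cls <- classify_polymorphism(obs, "wheat_CS",
                                 default_thresholds(polymorphism_min_bp = mb))
    expect_equal(sum(cls$polymorphic) + sum(!cls$polymorphic), nrow(cls))
    sum(cls$polymorphic)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("product summaries count per marker-genotype pair", {
  one <- obs_tbl(
    list("Xa", "g1", "aegilops_parent", "comosa", "", "100", "1"),
    list("Xa", "g1", "aegilops_parent", "comosa", "", "120", "1"),
    list("Xa", "g1", "aegilops_parent", "comosa", "", "140", "1"))
  s1 <- summarize_products(one)
  expect_equal(s1$mean_products, 3)
  expect_equal(s1$n_pairs, 1L)

  two <- obs_tbl(
    list("Xa", "g1", "aegilops_parent", "comosa", "", "100", "1"),
    list("Xb", "g1", "aegilops_parent", "comosa", "", "100", "1"),
    list("Xb", "g1", "aegilops_parent", "comosa", "", "120", "1"),
    list("Xb", "g1", "aegilops_parent", "comosa", "", "140", "1"),
    list("Xb", "g1", "aegilops_parent", "comosa", "", "160", "1"),
    list("Xb", "g1", "aegilops_parent", "comosa", "", "180", "1"))
  s2 <- summarize_products(two)
  expect_equal(s2$product_range, c(1L, 5L))
  expect_equal(s2$mean_products, 3)

  s0 <- summarize_products(one[0, ])
  expect_equal(s0$n_pairs, 0L)
})

test_that("1 bp sizing jitter collapses into one product bin", {
  obs <- obs_tbl(
    list("Xa", "g1", "aegilops_parent", "comosa", "", "200", "1"),
    list("Xa", "g2", "aegilops_parent", "comosa", "", "201", "1"))
  s <- summarize_products(obs)
  expect_equal(sort(s$per_pair$n_products), c(1L, 1L))
  cls <- classify_polymorphism(
    dplyr::bind_rows(obs, obs_tbl(
      list("Xa", "wheat_CS", "wheat_parent", "wheat", "", "250", "1"))),
    "wheat_CS")
  expect_equal(nrow(cls), 1L)  # one locus, not two
})

test_that("suitability de-duplicates markers but counts loci per species", {
  assignments <- tibble::tibble(
    marker = c("Xa", "Xa", "Xb"),
    size_bp = c(200L, 200L, 300L),
    species = c("umbellulata", "biuncialis", "comosa"),
    chromosomes = c("3U", "3Ub", ""),
    evidence = c("line", "transferred", "unassigned"),
    polymorphic = c(TRUE, TRUE, TRUE),
    ambiguous = FALSE)
  s <- select_suitable_markers(assignments)
  expect_equal(s$n_markers, 1L)
  expect_equal(s$n_loci, 2L)
  expect_false(s$loci$predicted[s$loci$species == "umbellulata"])
  expect_true(s$loci$predicted[s$loci$species == "biuncialis"])
  # no polymorphic loci -> empty table
  none <- dplyr::mutate(assignments, polymorphic = FALSE)
  expect_equal(select_suitable_markers(none)$n_loci, 0L)
})
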
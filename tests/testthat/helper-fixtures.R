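# shared fixture builders and independent oracles

ext_file <- function(name) {
  path <- system.file("extdata", name, package = "cosmap")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata", name)
  path
}

table1_comp <- function() read_peak_composition(ext_file("table1_peak_composition.tsv"))

# observation-table constructor: rows as c(marker, sample, kind, species,
# peak, size, yield)
obs_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    marker = vapply(rows, `[[`, character(1), 1L),
    sample = vapply(rows, `[[`, character(1), 2L),
    kind = vapply(rows, `[[`, character(1), 3L),
    species = vapply(rows, `[[`, character(1), 4L),
    peak = {
      p <- vapply(rows, `[[`, character(1), 5L)
      ifelse(nzchar(p), p, NA_character_)
    },
    size_bp = as.integer(vapply(rows, `[[`, character(1), 6L)),
    yield = as.numeric(vapply(rows, `[[`, character(1), 7L))
  )
}

# the Fig-1-style monotone yield profile: X1N amplicon over umbellulata peaks
fig1_profile <- function() c(I = 12, II = 5, III = 2, IV = 0)

# brute-force Kendall tau-b oracle: explicit pair counting with tie
# correction, independent of stats::cor
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  denom <- sqrt((conc + disc + tx) * (conc + disc + ty))
  if (denom == 0) return(NA_real_)
  (conc - disc) / denom
}

# run-length oracle for synteny blocks: maximal runs of a label along an
# ordered label sequence, returned as (label, start index, length)
run_length_oracle <- function(labels) {
  out <- list()
  i <- 1L
  while (i <= length(labels)) {
    j <- i
    while (j < length(labels) && labels[j + 1L] == labels[i]) j <- j + 1L
    out[[length(out) + 1L]] <- list(label = labels[i], start = i,
                                    len = j - i + 1L)
    i <- j + 1L
  }
  out
}

# brute-force single-chromosome consistency oracle for introgression panels:
# chromosomes whose carrier-line indicator equals the observed presence
# pattern exactly
introgression_oracle <- function(added_sets, present) {
  cands <- unique(unlist(added_sets))
  keep <- vapply(cands, function(ch) {
    expected <- vapply(added_sets, function(a) ch %in% a, logical(1))
    identical(unname(expected), unname(present))
  }, logical(1))
  sort(cands[keep])
}

# minimal biuncialis panel used by several assignment tests
biuncialis_mini_panel <- function() {
  tibble::tibble(
    line_id = c("L_1Ub", "L_1Ub6Ub", "L_3Ub"),
    species = "biuncialis", background = "Mv9kr1",
    added = list("1Ub", c("1Ub", "6Ub"), "3Ub"),
    removed = list(character(0), character(0), character(0))
  )
}

# observations realising a presence pattern over the mini panel
pattern_obs <- function(present, marker = "Xq", size = 400L) {
  lines <- c("L_1Ub", "L_1Ub6Ub", "L_3Ub")
  rows <- list(
    list(marker, "aeg_biuncialis", "aegilops_parent", "biuncialis", "",
         as.character(size), "1"))
  for (i in seq_along(lines)) {
    if (present[i]) {
      rows[[length(rows) + 1L]] <- list(marker, lines[i], "introgression_line",
                                        "biuncialis", "", as.character(size), "1")
    }
  }
  # an unrelated wheat-parent product keeps the classifier satisfied
  rows[[length(rows) + 1L]] <- list(marker, "wheat_CS", "wheat_parent", "wheat",
                                    "", as.character(size + 50L), "1")
  do.call(obs_tbl, rows)
}

# the cross-species transfer scenario: a 558 bp product anchored on 2Ug by a
# geniculata addition line, with peak profiles peaking on IV (umbellulata)
# and III (biuncialis)
x2n_scenario <- function() {
  panel <- tibble::tibble(
    line_id = paste0("CS_", c("1Ug", "2Ug", "3Ug")),
    species = "geniculata", background = "CS",
    added = list("1Ug", "2Ug", "3Ug"),
    removed = rep(list(character(0)), 3))
  obs <- obs_tbl(
    list("X2N", "wheat_CS", "wheat_parent", "wheat", "", "550", "1"),
    list("X2N", "aeg_geniculata", "aegilops_parent", "geniculata", "", "558", "1"),
    list("X2N", "CS_2Ug", "introgression_line", "geniculata", "", "558", "1"),
    list("X2N", "aeg_umbellulata", "aegilops_parent", "umbellulata", "", "558", "1"),
    list("X2N", "umb_peakI", "peak_fraction", "umbellulata", "I", "558", "0"),
    list("X2N", "umb_peakII", "peak_fraction", "umbellulata", "II", "558", "0"),
    list("X2N", "umb_peakIII", "peak_fraction", "umbellulata", "III", "558", "0"),
    list("X2N", "umb_peakIV", "peak_fraction", "umbellulata", "IV", "558", "9"),
    list("X2N", "aeg_biuncialis", "aegilops_parent", "biuncialis", "", "558", "1"),
    list("X2N", "biu_peakI", "peak_fraction", "biuncialis", "I", "558", "0"),
    list("X2N", "biu_peakII", "peak_fraction", "biuncialis", "II", "558", "0"),
    list("X2N", "biu_peakIII", "peak_fraction", "biuncialis", "III", "558", "8"),
    list("X2N", "biu_peakIV", "peak_fraction", "biuncialis", "IV", "558", "0"))
  list(panel = panel, obs = obs, comp = table1_comp())
}
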
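#' Flow-karyotype peak membership of the study design
#'
#' The chromosome-to-peak layout of the four Aegilops flow karyotypes that
#' the simulator emulates: which chromosomes sort into which of the four
#' peaks in each species (some chromosomes occur in two peaks; some peaks
#' carry up to seven chromosomes).
#'
#' @return A tibble (`species`, `peak`, `chromosome`).
#' @export
study_peak_membership <- function() {
  spec <- list(
    umbellulata = list(I = "1U", II = "6U", III = "3U",
                       IV = c("2U", "4U", "5U", "7U")),
    comosa = list(I = c("1M", "4M"), II = c("2M", "6M"), III = c("2M", "5M"),
                  IV = c("3M", "7M")),
    biuncialis = list(I = "1Ub",
                      II = c("3Ub", "6Ub", "2Mb", "3Mb", "4Mb", "6Mb"),
                      III = c("2Ub", "5Ub", "4Ub", "7Ub", "1Mb", "3Mb", "5Mb"),
                      IV = "7Mb"),
    geniculata = list(I = c("1Ug", "6Mg"), II = c("3Ug", "4Ug", "6Ug"),
                      III = c("2Ug", "5Ug", "7Ug", "2Mg", "4Mg", "5Mg"),
                      IV = c("1Mg", "3Mg", "7Mg"))
  )
  dplyr::bind_rows(lapply(names(spec), function(sp) {
    dplyr::bind_rows(lapply(names(spec[[sp]]), function(pk) {
      tibble::tibble(species = sp, peak = pk, chromosome = spec[[sp]][[pk]])
    }))
  }))
}

#' Introgression-line panel of the study design
#'
#' The wheat-Aegilops genetic stocks available in the study: partial
#' addition-line sets for *Ae. umbellulata*, *Ae. comosa* and
#' *Ae. biuncialis*, a near-complete set for *Ae. geniculata*, the
#' substitutions 6M(6A) and 3Mb(4B), and the centric fusion 3Mb.4BS
#' (arm-level entries).
#'
#' @return A karyotype tibble in the [read_line_karyotypes()] shape.
#' @export
study_panel <- function() {
  mk <- function(line_id, species, background, added, removed = character(0)) {
    tibble::tibble(line_id = line_id, species = species,
                   background = background, added = list(added),
                   removed = list(removed))
  }
  dplyr::bind_rows(c(
    lapply(c("1U", "2U", "4U", "5U", "6U", "7U"), function(ch)
      mk(paste0("CS_", ch), "umbellulata", "CS", ch)),
    lapply(c("2M", "3M", "4M", "5M", "6M", "7M"), function(ch)
      mk(paste0("CS_", ch), "comosa", "CS", ch)),
    list(mk("CS_6M(6A)", "comosa", "CS", "6M", "6A")),
    lapply(c("1Ub", "3Ub", "2Mb", "3Mb", "7Mb"), function(ch)
      mk(paste0("Mv9kr1_", ch), "biuncialis", "Mv9kr1", ch)),
    list(mk("Mv9kr1_1Ub6Ub", "biuncialis", "Mv9kr1", c("1Ub", "6Ub")),
         mk("Mv9kr1_3Mb(4B)", "biuncialis", "Mv9kr1", "3Mb", "4B"),
         mk("Mv9kr1_3Mb.4BS", "biuncialis", "Mv9kr1", c("3MbL", "4BS"))),
    lapply(paste0(1:7, "Ug"), function(ch)
      mk(paste0("CS_", ch), "geniculata", "CS", ch)),
    lapply(paste0(c(1, 2, 3, 5, 6, 7), "Mg"), function(ch)
      mk(paste0("CS_", ch), "geniculata", "CS", ch))
  ))
}

#' Simulation configuration
#'
#' Describes the study design the simulator emulates: four Aegilops species
#' (two diploids carrying the U and M genomes, two allotetraploids carrying
#' tagged copies of both), seven homoeologous groups, four flow-karyotype
#' peaks per species, and a model genome on which markers have physical
#' positions.
#'
#' @param n_markers Number of COS markers.
#' @param duplication_rate Probability that a marker carries a second,
#'   duplicated locus.
#' @param n_rearrangements Number of planted translocated segments (contiguous
#'   marker runs whose U-genome group differs from the wheat-D and M groups).
#' @param peak_structure `"study"` reproduces the study's peak membership with
#'   deterministic minor cross-contamination; `"distinct"` gives every
#'   chromosome its own rank-distinct content profile (every locus resolvable
#'   from peak yields alone).
#' @param panel `"complete"` (an addition line per chromosome per species),
#'   `"study"` (the study's partial stock list) or `"none"` (peak-only
#'   assignment).
#' @param wheat_delta_range Range (bp) of the wheat allele size offset; the
#'   lower bound defaults to the 2 bp polymorphism threshold so simulated
#'   wheat alleles are diagnostic.
#' @param wheat_null_rate Probability that wheat shows no amplicon for a
#'   marker (presence/absence polymorphism).
#' @param n_model_chromosomes,model_chrom_length_bp Model-genome geometry.
#' @param canvas_width_px Canvas width for physical-map pixels.
#' @return A config list.
#' @export
sim_config <- function(n_markers = 140L, duplication_rate = 0.1,
                       n_rearrangements = 5L,
                       peak_structure = c("study", "distinct"),
                       panel = c("complete", "study", "none"),
                       wheat_delta_range = c(2L, 10L), wheat_null_rate = 0.1,
                       n_model_chromosomes = 5L,
                       model_chrom_length_bp = 5e7,
                       canvas_width_px = 1000L) {
  stopifnot(n_markers >= 1, duplication_rate >= 0, duplication_rate < 1,
            n_rearrangements >= 0, wheat_delta_range[1] >= 1,
            canvas_width_px >= 1)
  list(n_markers = as.integer(n_markers),
       duplication_rate = duplication_rate,
       n_rearrangements = as.integer(n_rearrangements),
       peak_structure = match.arg(peak_structure),
       panel = match.arg(panel),
       wheat_delta_range = as.integer(wheat_delta_range),
       wheat_null_rate = wheat_null_rate,
       n_model_chromosomes = as.integer(n_model_chromosomes),
       model_chrom_length_bp = model_chrom_length_bp,
       canvas_width_px = as.integer(canvas_width_px))
}

#' Noise model for the fragment-analysis emitter
#'
#' Yield noise is multiplicative lognormal with unit mean (coefficient of
#' variation `yield_cv`), applied to peak-fraction yields; dropout is
#' Bernoulli per observation on introgression-line rows (PCR allele dropout
#' of a presence call); sizing jitter perturbs observed amplicon sizes by at
#' most `size_jitter` bp (0 or 1, the fragment-analyser resolution bin).
#'
#' @param yield_cv Coefficient of variation of the yield noise (default 0.2,
#'   a typical relative-fluorescence spread).
#' @param dropout_rate Per-observation dropout probability.
#' @param size_jitter Maximum absolute size error in bp (0 or 1).
#' @return A noise list.
#' @export
sim_noise <- function(yield_cv = 0.2, dropout_rate = 0.01, size_jitter = 0L) {
  stopifnot(yield_cv >= 0, dropout_rate >= 0, dropout_rate < 1,
            size_jitter %in% c(0L, 1L))
  list(yield_cv = yield_cv, dropout_rate = dropout_rate,
       size_jitter = as.integer(size_jitter))
}

AEG_SPECIES <- c("umbellulata", "comosa", "biuncialis", "geniculata")

# quantitative composition from a membership layout: listed peaks get major
# content (88%, then 30% for a second listed peak); unlisted peaks get small
# cross-contamination values whose per-chromosome ordering cycles through
# distinct permutations, so chromosomes sharing a peak differ in rank profile
# wherever the permutation space allows
quantify_membership <- function(membership) {
  minor_pool <- c(9, 4, 1.5, 0.5)
  out <- list()
  for (sp in unique(membership$species)) {
    ms <- membership[membership$species == sp, ]
    chroms <- sort(unique(ms$chromosome))
    perms <- perm_list(4L)
    for (i in seq_along(chroms)) {
      ch <- chroms[i]
      listed <- PEAK_LEVELS[PEAK_LEVELS %in% ms$peak[ms$chromosome == ch]]
      unlisted <- setdiff(PEAK_LEVELS, listed)
      major_vals <- c(88, 30)[seq_along(listed)]
      perm <- perms[[(i - 1L) %% length(perms) + 1L]][seq_along(unlisted)]
      minor_vals <- minor_pool[perm][seq_along(unlisted)]
      out[[length(out) + 1L]] <- tibble::tibble(
        species = sp, peak = c(listed, unlisted), chromosome = ch,
        percent = c(major_vals, minor_vals))
    }
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$species, .data$peak, .data$chromosome)
}

perm_list <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(perm_list(n - 1L), function(p) c(i, p + (p >= i)))
  }))
}

# rank-distinct composition: every chromosome of a species receives its own
# permutation of (60, 25, 10, 5) across the four peaks
distinct_composition <- function(chrom_by_species) {
  vals <- c(60, 25, 10, 5)
  out <- list()
  for (sp in names(chrom_by_species)) {
    chroms <- sort(chrom_by_species[[sp]])
    perms <- perm_list(4L)
    if (length(chroms) > length(perms)) {
      stop("too many chromosomes for rank-distinct composition", call. = FALSE)
    }
    for (i in seq_along(chroms)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        species = sp, peak = PEAK_LEVELS, chromosome = chroms[i],
        percent = vals[order(perms[[i]])])
    }
  }
  dplyr::bind_rows(out)
}

complete_panel <- function(chrom_by_species) {
  dplyr::bind_rows(lapply(names(chrom_by_species), function(sp) {
    tibble::tibble(line_id = paste0("add_", chrom_by_species[[sp]]),
                   species = sp, background = "CS",
                   added = as.list(chrom_by_species[[sp]]),
                   removed = rep(list(character(0)),
                                 length(chrom_by_species[[sp]])))
  }))
}

#' Generate a synthetic study with planted ground truth
#'
#' Produces every input the pipeline consumes -- marker loci with true
#' chromosomes and amplicon sizes, wheat alleles, peak-composition matrices,
#' an introgression-line panel, model-genome marker positions -- together
#' with a record of every planted feature (duplications, translocated
#' segments), reproducibly from `(config, seed)`.
#'
#' @param config Configuration from [sim_config()].
#' @param seed Integer seed; a single pseudo-random stream is seeded once and
#'   used for all draws (including the subsequent emitters, in call order).
#' @return A truth list: `config`, `seed`, `markers`, `loci`,
#'   `wheat_alleles`, `duplications`, `rearrangements`, `composition`,
#'   `panel`, `model_positions`, `chrom_lengths`, `wheat_annotation`.
#' @export
generate_truth <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_markers
  if (config$n_rearrangements * 2L > n) {
    stop("infeasible config: more rearranged segments than marker intervals",
         call. = FALSE)
  }
  marker_ids <- sprintf("Xs%03d", seq_len(n))
  wheat_group <- sample(1:7, n, replace = TRUE)

  # model-genome layout: each homoeologous group owns a segment of one model
  # chromosome; markers of a group are spread over its segment
  mc_of_group <- ((1:7 - 1L) %% config$n_model_chromosomes) + 1L
  model_chrom <- paste0("Br", mc_of_group[wheat_group])
  start_bp <- integer(n)
  for (g in 1:7) {
    idx <- which(wheat_group == g)
    if (length(idx) == 0) next
    groups_here <- which(mc_of_group == mc_of_group[g])
    seg_w <- config$model_chrom_length_bp / length(groups_here)
    seg_start <- (match(g, groups_here) - 1L) * seg_w
    offs <- sort(sample.int(floor(seg_w) - 2L, length(idx)))
    start_bp[idx] <- as.integer(seg_start + offs + 1L)
  }
  markers <- tibble::tibble(marker = marker_ids, wheat_group = wheat_group,
                            u_group = wheat_group, m_group = wheat_group)

  # planted rearrangements: contiguous positional runs within one group's
  # segment get a shifted U-genome group (discordant with both D and M)
  rearr <- list()
  used <- logical(n)
  ord <- order(model_chrom, start_bp)
  if (config$n_rearrangements > 0) {
    seg_runs <- split(ord, paste0(model_chrom[ord], ":", wheat_group[ord]))
    # keep planted runs interior to their segment (a concordant marker on
    # each side) so two planted intervals can never merge into one call
    seg_runs <- seg_runs[vapply(seg_runs, length, integer(1)) >= 4L]
    if (length(seg_runs) < config$n_rearrangements) {
      stop("infeasible config: not enough multi-marker segments to rearrange",
           call. = FALSE)
    }
    chosen <- sample(names(seg_runs), config$n_rearrangements)
    for (key in chosen) {
      run <- seg_runs[[key]]
      len <- min(length(run) - 2L, sample(2:3, 1L))
      at <- sample(2:(length(run) - len), 1L)
      idx <- run[at:(at + len - 1L)]
      g <- wheat_group[idx[1L]]
      new_g <- (g %% 7L) + 1L
      markers$u_group[idx] <- new_g
      used[idx] <- TRUE
      pos <- start_bp[idx]
      rearr[[length(rearr) + 1L]] <- tibble::tibble(
        model_genome = "brachypodium", chromosome = model_chrom[idx[1L]],
        first_marker = marker_ids[idx[order(pos)][1L]],
        last_marker = marker_ids[idx[order(pos)][len]],
        original_group = g, rearranged_group = new_g, n_markers = len)
    }
  }
  rearrangements <- if (length(rearr) > 0) dplyr::bind_rows(rearr) else
    tibble::tibble(model_genome = character(), chromosome = character(),
                   first_marker = character(), last_marker = character(),
                   original_group = integer(), rearranged_group = integer(),
                   n_markers = integer())

  # base loci: one U-genome and one M-genome locus per marker, distinct sizes
  draw_sizes <- function(k, existing = integer(0)) {
    out <- integer(0)
    while (length(out) < k) {
      s <- sample(120:600, 1L)
      if (all(abs(s - c(out, existing)) >= 4L)) out <- c(out, s)
    }
    out
  }
  loci_rows <- list()
  dup_rows <- list()
  for (i in seq_len(n)) {
    sizes <- draw_sizes(2L)
    base <- tibble::tibble(
      marker = marker_ids[i],
      genome = c("U", "M"),
      group = c(markers$u_group[i], markers$m_group[i]),
      size_bp = sizes)
    if (!used[i] && stats::runif(1) < config$duplication_rate) {
      dgenome <- sample(c("U", "M"), 1L)
      dgroup0 <- base$group[base$genome == dgenome]
      same_chrom <- stats::runif(1) < 0.25
      dgroup <- if (same_chrom) dgroup0 else
        sample(setdiff(1:7, dgroup0), 1L)
      dsize <- draw_sizes(1L, existing = sizes)
      base <- dplyr::bind_rows(base, tibble::tibble(
        marker = marker_ids[i], genome = dgenome, group = dgroup,
        size_bp = dsize))
      dup_rows[[length(dup_rows) + 1L]] <- tibble::tibble(
        marker = marker_ids[i], genome = dgenome,
        pattern = paste(sort(c(dgroup0, dgroup)), collapse = "/"))
    }
    loci_rows[[i]] <- base
  }
  base_loci <- dplyr::bind_rows(loci_rows)

  # species-level loci: diploids carry their own genome, tetraploids both
  sp_genomes <- list(umbellulata = "U", comosa = "M",
                     biuncialis = c("U", "M"), geniculata = c("U", "M"))
  loci <- dplyr::bind_rows(lapply(AEG_SPECIES, function(sp) {
    b <- base_loci[base_loci$genome %in% sp_genomes[[sp]], ]
    tibble::tibble(marker = b$marker, species = sp,
                   chromosome = chrom_format(b$group, b$genome, species_tag(sp)),
                   genome = b$genome, group = b$group, size_bp = b$size_bp)
  }))

  duplications <- if (length(dup_rows) > 0) {
    dr <- dplyr::bind_rows(dup_rows)
    dplyr::bind_rows(lapply(AEG_SPECIES, function(sp) {
      d <- dr[dr$genome %in% sp_genomes[[sp]], ]
      if (nrow(d) == 0) return(NULL)
      tibble::tibble(marker = d$marker, species = sp, genome = d$genome,
                     pattern = d$pattern)
    }))
  } else {
    tibble::tibble(marker = character(), species = character(),
                   genome = character(), pattern = character())
  }

  # wheat alleles: offset from the first Aegilops locus by at least the
  # polymorphism threshold, or a null allele
  wheat_alleles <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    if (stats::runif(1) < config$wheat_null_rate) return(NULL)
    sizes <- base_loci$size_bp[base_loci$marker == marker_ids[i]]
    delta <- sample(config$wheat_delta_range[1]:config$wheat_delta_range[2], 1L) *
      sample(c(-1L, 1L), 1L)
    ws <- max(sizes[1L] + delta, 60L)
    while (any(abs(ws - sizes) < 2L)) ws <- ws + 2L
    tibble::tibble(marker = marker_ids[i], size_bp = ws)
  }))

  chrom_by_species <- lapply(stats::setNames(AEG_SPECIES, AEG_SPECIES),
                             function(sp) {
    unlist(lapply(sp_genomes[[sp]], function(g)
      chrom_format(1:7, g, species_tag(sp))))
  })
  composition <- switch(config$peak_structure,
    study = quantify_membership(study_peak_membership()),
    distinct = distinct_composition(chrom_by_species))
  panel <- switch(config$panel,
    complete = complete_panel(chrom_by_species),
    study = study_panel(),
    none = tibble::tibble(line_id = character(), species = character(),
                          background = character(), added = list(),
                          removed = list()))

  list(config = config, seed = seed, markers = markers, loci = loci,
       wheat_alleles = wheat_alleles, duplications = duplications,
       rearrangements = rearrangements, composition = composition,
       panel = panel,
       model_positions = tibble::tibble(marker = marker_ids,
                                        model_genome = "brachypodium",
                                        chromosome = model_chrom,
                                        start_bp = start_bp),
       chrom_lengths = tibble::tibble(
         model_genome = "brachypodium",
         chromosome = paste0("Br", seq_len(config$n_model_chromosomes)),
         length_bp = config$model_chrom_length_bp),
       wheat_annotation = tibble::tibble(marker = marker_ids,
                                         wheat_group = wheat_group))
}

#' Emit a fragment-analysis table from a truth object
#'
#' Generates the observation table the genotyping readers consume: parental
#' wheat and Aegilops products, genomic controls, introgression-line products
#' (wheat background plus loci on added chromosomes), and peak-fraction
#' products whose yield is proportional to the carrier chromosome's content
#' in each peak, under the configured noise model.
#'
#' @param truth Truth list from [generate_truth()].
#' @param noise Noise list from [sim_noise()].
#' @return An observation tibble in the [read_fragment_table()] shape.
#' @export
emit_fragment_table <- function(truth, noise = sim_noise()) {
  jitter <- function(size) {
    if (noise$size_jitter == 0L) size else
      size + sample((-noise$size_jitter):noise$size_jitter, length(size),
                    replace = TRUE)
  }
  ynoise <- function(k) {
    if (noise$yield_cv == 0) rep(1, k) else {
      sdlog <- sqrt(log(1 + noise$yield_cv^2))
      stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
  }
  keep <- function(k) {
    if (noise$dropout_rate == 0) rep(TRUE, k) else
      stats::runif(k) >= noise$dropout_rate
  }
  rows <- list()
  add <- function(tbl) rows[[length(rows) + 1L]] <<- tbl

  wa <- truth$wheat_alleles
  if (nrow(wa) > 0) {
    add(tibble::tibble(marker = wa$marker, sample = "wheat_CS",
                       kind = "wheat_parent", species = "wheat",
                       peak = NA_character_, size_bp = jitter(wa$size_bp),
                       yield = 1))
  }
  cm_cache <- lapply(stats::setNames(AEG_SPECIES, AEG_SPECIES), function(sp)
    content_matrix(truth$composition, sp))
  for (sp in AEG_SPECIES) {
    l <- truth$loci[truth$loci$species == sp, ]
    add(tibble::tibble(marker = l$marker, sample = paste0("aeg_", sp),
                       kind = "aegilops_parent", species = sp,
                       peak = NA_character_, size_bp = jitter(l$size_bp),
                       yield = 1))
    add(tibble::tibble(marker = l$marker, sample = paste0("gdna_", sp),
                       kind = "genomic_control", species = sp,
                       peak = NA_character_, size_bp = jitter(l$size_bp),
                       yield = 1))
    m <- cm_cache[[sp]]
    for (pk in colnames(m)) {
      content <- unname(m[chrom_strip_arm(l$chromosome), pk])
      y <- content / 100 * ynoise(nrow(l))
      add(tibble::tibble(marker = l$marker,
                         sample = paste0(sp, "_peak", pk),
                         kind = "peak_fraction", species = sp, peak = pk,
                         size_bp = jitter(l$size_bp), yield = y))
    }
    panel_sp <- truth$panel[truth$panel$species == sp, ]
    for (j in seq_len(nrow(panel_sp))) {
      added <- chrom_strip_arm(panel_sp$added[[j]])
      carried <- l[chrom_strip_arm(l$chromosome) %in% added, ]
      line_rows <- dplyr::bind_rows(
        if (nrow(carried) > 0)
          tibble::tibble(marker = carried$marker, size_bp = carried$size_bp),
        if (nrow(wa) > 0) tibble::tibble(marker = wa$marker, size_bp = wa$size_bp))
      if (is.null(line_rows) || nrow(line_rows) == 0) next
      ok <- keep(nrow(line_rows))
      add(tibble::tibble(marker = line_rows$marker,
                         sample = panel_sp$line_id[j],
                         kind = "introgression_line", species = sp,
                         peak = NA_character_,
                         size_bp = jitter(line_rows$size_bp), yield = 1)[ok, ])
    }
  }
  validate_observations(dplyr::bind_rows(rows))
}

#' Emit a 12-column hit table from a truth object
#'
#' One strong best hit per marker at its true model-genome position, plus
#' optional decoy hits that sit on the wrong side of each significance
#' threshold (and one passing lower-score decoy on another chromosome) to
#' exercise the filtering and best-hit logic.  Every second hit is written in
#' reverse orientation.
#'
#' @param truth Truth list.
#' @param jitter Maximum absolute positional noise (bp) on the best hit.
#' @param decoys Emit decoy hits (default `TRUE`).
#' @return A hit tibble in the [read_hit_table()] shape.
#' @export
emit_hit_table <- function(truth, jitter = 0, decoys = TRUE) {
  mp <- truth$model_positions
  n <- nrow(mp)
  off <- if (jitter == 0) rep(0L, n) else
    sample((-jitter):jitter, n, replace = TRUE)
  len_bp <- truth$config$model_chrom_length_bp
  pos <- pmin(pmax(1L, mp$start_bp + off), as.integer(len_bp) - 240L)
  best <- tibble::tibble(
    query_id = mp$marker, model_genome = mp$model_genome,
    chromosome = mp$chromosome,
    start = pos,
    end = pos + 239L,
    orientation = rep(c("plus", "minus"), length.out = n),
    score = 250, e_value = 1e-40, identity_pct = 92.5, aln_length = 240L)
  if (!decoys) return(best)
  other_chrom <- paste0("Br", (as.integer(sub("Br", "", mp$chromosome)) %%
                                 truth$config$n_model_chromosomes) + 1L)
  decoy <- function(chrom, start, score, e_value, identity, len) {
    tibble::tibble(query_id = mp$marker, model_genome = "brachypodium",
                   chromosome = chrom, start = start, end = start + len - 1L,
                   orientation = "plus", score = score, e_value = e_value,
                   identity_pct = identity, aln_length = as.integer(len))
  }
  dplyr::bind_rows(
    best,
    decoy(other_chrom, 1000L, 180, 1e-03, 85, 240),   # fails E-value
    decoy(other_chrom, 2000L, 170, 1e-20, 50, 240),   # fails identity
    decoy(other_chrom, 3000L, 160, 1e-20, 85, 80),    # fails length
    decoy(other_chrom, 4000L, 120, 1e-25, 85, 240)    # passes, lower score
  ) |> dplyr::arrange(.data$query_id, dplyr::desc(.data$score))
}

#' Score pipeline outputs against planted truth
#'
#' Assignment accuracy is the fraction of true loci whose final assignment is
#' exactly the true chromosome set (per marker x species x size bin);
#' duplication precision/recall compare detected (marker, species, genome,
#' group-pattern) records with planted ones; rearrangement recall is the
#' fraction of planted translocated segments whose U-vs-D call reproduces the
#' segment's marker interval exactly.
#'
#' @param assignments Final assignment tibble from [assign_loci()].
#' @param dup_records Records from [detect_marker_duplications()].
#' @param rearrangement_calls Calls from [call_rearrangements()] for the
#'   relevant track pair.
#' @param truth Truth list.
#' @param tol Size-bin tolerance (bp) used when matching loci.
#' @return A named list of metrics in `[0, 1]`.
#' @export
score_recovery <- function(assignments, dup_records, rearrangement_calls,
                           truth, tol = 1L) {
  tl <- truth$loci
  correct <- vapply(seq_len(nrow(tl)), function(i) {
    hit <- assignments[assignments$marker == tl$marker[i] &
                         assignments$species == tl$species[i] &
                         abs(assignments$size_bp - tl$size_bp[i]) <= tol, ]
    truth_set <- unique(tl$chromosome[
      tl$marker == tl$marker[i] & tl$species == tl$species[i] &
        abs(tl$size_bp - tl$size_bp[i]) <= tol])
    if (nrow(hit) == 0) return(FALSE)
    pred <- unique(unlist(strsplit(hit$chromosomes[nzchar(hit$chromosomes)],
                                   "/", fixed = TRUE)))
    setequal(pred, truth_set)
  }, logical(1))
  assignment_accuracy <- mean(correct)

  truth_keys <- unique(paste(truth$duplications$marker,
                             truth$duplications$species,
                             truth$duplications$genome,
                             truth$duplications$pattern))
  found_keys <- unique(paste(dup_records$marker, dup_records$species,
                             dup_records$genome, dup_records$pattern))
  duplication_recall <- if (length(truth_keys) == 0) 1 else
    mean(truth_keys %in% found_keys)
  duplication_precision <- if (length(found_keys) == 0) 1 else
    mean(found_keys %in% truth_keys)

  tr <- truth$rearrangements
  rearrangement_recall <- if (nrow(tr) == 0) 1 else {
    mean(vapply(seq_len(nrow(tr)), function(i) {
      any(rearrangement_calls$chromosome == tr$chromosome[i] &
            rearrangement_calls$first_marker == tr$first_marker[i] &
            rearrangement_calls$last_marker == tr$last_marker[i])
    }, logical(1)))
  }
  list(assignment_accuracy = assignment_accuracy,
       duplication_precision = duplication_precision,
       duplication_recall = duplication_recall,
       rearrangement_recall = rearrangement_recall)
}
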
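# is a product of `marker` with size within `tol` bp of `size_bp` observed in
# sample `sample_id`?
present_in_sample <- function(obs, marker, sample_id, size_bp, tol = 1L) {
  any(obs$marker == marker & obs$sample == sample_id &
        abs(obs$size_bp - size_bp) <= tol & obs$yield > 0)
}

other_arm <- function(arm) c(S = "L", L = "S")[[arm]]

#' Assign a marker product using introgression lines
#'
#' A product is placed on every added Aegilops chromosome C such that it is
#' present in the Aegilops parent, present in every panel line carrying C,
#' absent from all lines not carrying C, and absent (or size-shifted by at
#' least the polymorphism threshold) in the wheat background parents.  A line
#' adding several chromosomes (e.g. a double disomic addition) supports its
#' whole added set unless a single-chromosome line disambiguates; arm-level
#' stocks (telosomes, centric fusions) restrict the call to one arm.
#'
#' @param marker,size_bp,species The product: marker id, amplicon size (bp)
#'   and Aegilops species.
#' @param panel Karyotype tibble from [read_line_karyotypes()].
#' @param obs Observation tibble; introgression-line samples must be keyed by
#'   `sample == line_id`.
#' @param wheat_parent_ids Parental wheat sample ids (the diagnosticity
#'   check).
#' @param thresholds Threshold list; `polymorphism_min_bp` governs how close a
#'   wheat allele may be before the product is non-diagnostic.
#' @param tol Size-bin tolerance in bp (fragment-analyser resolution).
#' @return Character vector of chromosome labels (possibly empty); when empty,
#'   attribute `"reason"` is one of `"non-diagnostic"`,
#'   `"absent_in_parent"`, `"no_panel_lines"` or `"no_consistent_chromosome"`.
#' @export
assign_by_introgression <- function(marker, size_bp, species, panel, obs,
                                    wheat_parent_ids,
                                    thresholds = default_thresholds(),
                                    tol = 1L) {
  fail <- function(reason) structure(character(0), reason = reason)

  wheat <- obs[obs$sample %in% wheat_parent_ids & obs$kind == "wheat_parent" &
                 obs$marker == marker, ]
  if (nrow(wheat) > 0 &&
      min(abs(wheat$size_bp - size_bp)) < thresholds$polymorphism_min_bp) {
    return(fail("non-diagnostic"))
  }
  parent_obs <- obs[obs$kind == "aegilops_parent" & obs$species == species, ]
  if (nrow(parent_obs) == 0 ||
      !any(parent_obs$marker == marker & abs(parent_obs$size_bp - size_bp) <= tol)) {
    return(fail("absent_in_parent"))
  }
  lines <- panel[panel$species == species, , drop = FALSE]
  if (nrow(lines) == 0) return(fail("no_panel_lines"))

  present <- vapply(lines$line_id, function(id)
    present_in_sample(obs, marker, id, size_bp, tol), logical(1))
  added <- lines$added
  aeg_genomes <- species_genomes(species)[[1L]]

  all_labels <- unique(unlist(added))
  info <- chrom_parse(all_labels)
  candidates <- all_labels[info$genome %in% aeg_genomes]
  cinfo <- info[info$genome %in% aeg_genomes, , drop = FALSE]

  carries_whole <- function(lab) vapply(added, function(a) lab %in% a, logical(1))
  carries_arm_of <- function(whole) vapply(added, function(a) {
    if (length(a) == 0) return(FALSE)
    pa <- chrom_parse(a)
    any(pa$arm != "" & chrom_format(pa$group, pa$genome, pa$tag, "") == whole)
  }, logical(1))

  qualifies <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    lab <- candidates[i]
    if (cinfo$arm[i] == "") {
      carrier <- carries_whole(lab)
      partial <- carries_arm_of(lab)
      noncarrier <- !carrier & !partial
    } else {
      whole <- chrom_format(cinfo$group[i], cinfo$genome[i], cinfo$tag[i], "")
      carrier <- carries_whole(lab) | carries_whole(whole)
      opp <- chrom_format(cinfo$group[i], cinfo$genome[i], cinfo$tag[i],
                          other_arm(cinfo$arm[i]))
      noncarrier <- !carrier  # includes opposite-arm stocks
      noncarrier[carries_whole(opp)] <- TRUE
    }
    qualifies[i] <- any(carrier) && all(present[carrier]) && all(!present[noncarrier])
  }
  hit <- candidates[qualifies]
  if (length(hit) == 0) return(fail("no_consistent_chromosome"))
  hinfo <- cinfo[qualifies, , drop = FALSE]

  # arm refinement: a whole-chromosome call is narrowed when an arm-level
  # stock of that chromosome pins the locus to one arm (presence -> that arm,
  # absence -> the other arm)
  refined <- character(0)
  for (i in seq_len(nrow(hinfo))) {
    lab <- hit[i]
    if (hinfo$arm[i] != "") { refined <- c(refined, lab); next }
    partial <- carries_arm_of(lab)
    if (!any(partial)) { refined <- c(refined, lab); next }
    arms <- character(0)
    for (j in which(partial)) {
      pa <- chrom_parse(added[[j]])
      pa <- pa[pa$arm != "" & chrom_format(pa$group, pa$genome, pa$tag, "") == lab, ]
      for (k in seq_len(nrow(pa))) {
        arms <- c(arms, if (present[j]) pa$arm[k] else other_arm(pa$arm[k]))
      }
    }
    arms <- unique(arms)
    refined <- c(refined,
                 if (length(arms) == 1L)
                   chrom_format(hinfo$group[i], hinfo$genome[i], hinfo$tag[i], arms)
                 else lab)  # conflicting arm evidence: keep whole chromosome
  }
  # an arm label supersedes its own whole-chromosome label
  parents <- chrom_strip_arm(refined)
  keep <- !(refined %in% parents[chrom_parse(refined)$arm != ""] &
              chrom_parse(refined)$arm == "")
  out <- sort(unique(refined[keep]))
  if (length(out) == 0) return(fail("no_consistent_chromosome"))
  out
}

#' Peak-yield profiles of marker products
#'
#' Collects, per (marker, species, size bin), the PCR yield observed on each
#' flow-karyotype peak fraction, together with the yield on the species'
#' unsorted genomic control when present.
#'
#' @param obs Observation tibble.
#' @param tol Size-bin tolerance in bp.
#' @return A tibble (`marker`, `species`, `size_bp`, `yields` list-column of
#'   named numeric vectors keyed by peak, `control_yield`).
#' @export
peak_yield_profiles <- function(obs, tol = 1L) {
  frac <- obs[obs$kind == "peak_fraction", ]
  if (nrow(frac) == 0) {
    return(tibble::tibble(marker = character(), species = character(),
                          size_bp = integer(), yields = list(),
                          control_yield = numeric()))
  }
  frac <- as.data.frame(add_size_bin(frac, tol))
  ctrl <- as.data.frame(obs[obs$kind == "genomic_control", ])
  ctrl_idx <- split(seq_len(nrow(ctrl)), paste(ctrl$marker, ctrl$species, sep = "\r"))
  groups <- split(seq_len(nrow(frac)),
                  paste(frac$marker, frac$species, frac$size_bin, sep = "\r"))
  first <- vapply(groups, `[[`, integer(1), 1L)
  out <- tibble::new_tibble(list(
    marker = frac$marker[first],
    species = frac$species[first],
    size_bp = frac$size_bin[first],
    yields = lapply(groups, function(i) {
      y <- tapply(frac$yield[i], frac$peak[i], max)
      stats::setNames(as.numeric(y), names(y))
    }),
    control_yield = vapply(seq_along(groups), function(k) {
      i1 <- first[k]
      ci <- ctrl_idx[[paste(frac$marker[i1], frac$species[i1], sep = "\r")]]
      ci <- ci[abs(ctrl$size_bp[ci] - frac$size_bin[i1]) <= tol]
      if (length(ci) == 0) NA_real_ else max(ctrl$yield[ci])
    }, numeric(1))
  ), nrow = length(groups))
  dplyr::arrange(out, .data$marker, .data$species, .data$size_bp)
}

#' Score yield/content concordance for every candidate chromosome
#'
#' The diagnostic signal of the flow-sorted fractions is that a locus's PCR
#' yield tracks the content of its carrier chromosome across peaks: the
#' highest yield falls in the peak where that chromosome has its major
#' location.  The concordance statistic is Kendall's tau-b between the yield
#' vector and each chromosome's content vector across peaks; in addition a
#' presence test requires the yield to stay at background in every peak with
#' zero recorded content and above detection in the major-location peak.
#'
#' @param yields Named numeric vector of yields keyed by peak (I-IV); peaks of
#'   the species missing from the vector count as zero yield.
#' @param comp Composition tibble from [read_peak_composition()], or a
#'   pre-built chromosome-by-peak content matrix.
#' @param species Species whose peaks/chromosomes are scored (ignored when
#'   `comp` is already a matrix).
#' @param control_yield Yield on the species' unsorted genomic DNA; when `NA`
#'   the maximum peak yield is used as the reference for the detection
#'   threshold.
#' @param presence_fraction Detection threshold as a fraction of the reference
#'   yield (MDA-amplified fractions show background amplification, so absence
#'   is "at most this fraction", not strictly zero).
#' @return A tibble (`chromosome`, `tau`, `presence_consistent`, `content`
#'   list-column), sorted by presence then tau (descending) then label; empty
#'   with attribute `reason = "no amplification"` when all yields are zero.
#' @export
score_peak_concordance <- function(yields, comp, species = NULL,
                                   control_yield = NA_real_,
                                   presence_fraction = 0.05) {
  m <- if (is.matrix(comp)) comp else content_matrix(comp, species)
  y <- stats::setNames(rep(0, ncol(m)), colnames(m))
  known <- intersect(names(yields), colnames(m))
  y[known] <- yields[known]
  if (all(y == 0)) {
    return(structure(
      tibble::tibble(chromosome = character(), tau = numeric(),
                     presence_consistent = logical(), content = list()),
      reason = "no amplification"))
  }
  ref <- if (is.na(control_yield)) max(y) else control_yield
  thr <- presence_fraction * ref
  chroms <- rownames(m)
  tau <- numeric(length(chroms))
  presence <- logical(length(chroms))
  for (i in seq_along(chroms)) {
    v <- m[i, ]
    tau[i] <- suppressWarnings(stats::cor(y, v, method = "kendall"))
    major <- which(v == max(v))[1L]  # columns are in peak order I..IV
    presence[i] <- all(y[v == 0] <= thr) && y[major] > thr
  }
  out <- tibble::new_tibble(
    list(chromosome = chroms, tau = tau, presence_consistent = presence,
         content = lapply(seq_along(chroms), function(i) m[i, ])),
    nrow = length(chroms))
  out[order(-out$presence_consistent, -ifelse(is.na(out$tau), -Inf, out$tau),
            out$chromosome), ]
}

#' Assign a product from its concordance scores
#'
#' Returns the unique chromosome that is presence-consistent with tau at or
#' above `tau_min`.  When several chromosomes qualify and their content
#' vectors are identical (chromosomes always co-sorted into the same peaks,
#' hence indistinguishable by this assay) the full set is returned flagged
#' ambiguous; qualifying chromosomes with distinct profiles mean the evidence
#' is contradictory and nothing is returned.
#'
#' @param scores Score tibble from [score_peak_concordance()].
#' @param tau_min Minimum Kendall tau-b (default 0.8).
#' @return Character vector of chromosome labels; attribute `"ambiguous"` is
#'   `TRUE` for an indistinguishable set; when empty, attribute `"reason"`
#'   explains why.
#' @export
assign_by_peak_yield <- function(scores, tau_min = 0.8) {
  if (nrow(scores) == 0) {
    return(structure(character(0),
                     reason = attr(scores, "reason") %||% "no_scores"))
  }
  qual <- scores[scores$presence_consistent & !is.na(scores$tau) &
                   scores$tau >= tau_min, ]
  if (nrow(qual) == 0) {
    return(structure(character(0), reason = "no_concordant_chromosome"))
  }
  if (nrow(qual) == 1L) return(qual$chromosome)
  first <- qual$content[[1L]]
  identical_profiles <- all(vapply(qual$content, function(v)
    isTRUE(all.equal(v, first)), logical(1)))
  if (identical_profiles) {
    return(structure(sort(qual$chromosome), ambiguous = TRUE))
  }
  structure(character(0), reason = "tie_between_distinct_profiles")
}

#' Transfer unambiguous assignments across species
#'
#' When a locus's chromosomal location is determined unambiguously in at
#' least one Aegilops species, and another species shows a same-sized product
#' whose highest yield falls on the subgenomic sample containing the
#' homoeologous chromosome (same genome and group, that species' subgenome
#' tag), the locus is concluded to sit on that chromosome in the other
#' species as well.  Transfers never change genome or homoeologous group.
#'
#' @param assignments Direct-assignment tibble with columns `marker`,
#'   `size_bp`, `species`, `chromosomes` (slash-joined), `ambiguous`.
#' @param profiles Profile tibble from [peak_yield_profiles()].
#' @param comp Composition tibble.
#' @param size_bin Size tolerance (bp) for "same-sized" across species.
#' @return A tibble of transferred assignments (`marker`, `size_bp`,
#'   `species`, `chromosomes`, `evidence = "transferred"`, `anchor_species`,
#'   `anchor_chromosome`); attribute `"conflicts"` lists (marker, size) keys
#'   whose anchors disagreed between species (no transfer emitted).
#' @export
transfer_across_species <- function(assignments, profiles, comp,
                                    size_bin = 1L) {
  empty <- tibble::tibble(marker = character(), size_bp = integer(),
                          species = character(), chromosomes = character(),
                          evidence = character(), anchor_species = character(),
                          anchor_chromosome = character())
  if (is.null(assignments$ambiguous)) assignments$ambiguous <- FALSE
  anchors <- assignments[!is.na(assignments$chromosomes) &
                           nzchar(assignments$chromosomes) &
                           !grepl("/", assignments$chromosomes, fixed = TRUE) &
                           !(assignments$ambiguous %||% FALSE), , drop = FALSE]
  if (nrow(anchors) == 0) return(structure(empty, conflicts = character(0)))

  out <- list()
  conflicts <- character(0)
  keys <- unique(anchors[, c("marker", "size_bp")])
  for (i in seq_len(nrow(keys))) {
    mk <- keys$marker[i]; sz <- keys$size_bp[i]
    a <- anchors[anchors$marker == mk & abs(anchors$size_bp - sz) <= size_bin, ]
    p <- chrom_parse(a$chromosomes)
    if (dplyr::n_distinct(paste(p$genome, p$group)) > 1L) {
      conflicts <- c(conflicts, paste0(mk, ":", sz))
      next
    }
    anchor_chrom <- a$chromosomes[1L]
    # species already carrying an unambiguous direct assignment need no
    # transfer; an ambiguous co-sorted set does not block one
    assigned_species <- assignments$species[
      assignments$marker == mk & abs(assignments$size_bp - sz) <= size_bin &
        nzchar(assignments$chromosomes) & !assignments$ambiguous]
    targets <- profiles[profiles$marker == mk &
                          abs(profiles$size_bp - sz) <= size_bin &
                          !profiles$species %in% c(a$species, assigned_species), ]
    for (j in seq_len(nrow(targets))) {
      sp <- targets$species[j]
      y <- targets$yields[[j]]
      if (length(y) == 0 || all(y == 0)) next
      # argmax-yield peak, ties to the lower-numbered peak
      ord <- order(-y[PEAK_LEVELS[PEAK_LEVELS %in% names(y)]])
      peak_star <- PEAK_LEVELS[PEAK_LEVELS %in% names(y)][ord[1L]]
      target_chrom <- homoeologous_label(anchor_chrom, sp)
      carried <- comp$percent[comp$species == sp & comp$peak == peak_star &
                                comp$chromosome == target_chrom]
      if (length(carried) > 0 && any(carried > 0)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          marker = mk, size_bp = targets$size_bp[j], species = sp,
          chromosomes = target_chrom, evidence = "transferred",
          anchor_species = a$species[1L], anchor_chromosome = anchor_chrom)
      }
    }
  }
  res <- if (length(out) > 0) dplyr::bind_rows(out) else empty
  structure(dplyr::distinct(res), conflicts = unique(conflicts))
}

#' Reconcile introgression-line and peak-yield evidence
#'
#' Products supported by both evidence streams take the intersection
#' (`evidence = "both"`); on disagreement the line evidence wins and the peak
#' result is kept as a logged conflict; products with neither stream land in
#' the unassigned pool with their reason codes.
#'
#' @param line_tbl Tibble (`marker`, `size_bp`, `species`, `chromosomes`
#'   slash-joined or `""`, `reason`).
#' @param peak_tbl Tibble (`marker`, `size_bp`, `species`, `chromosomes`,
#'   `ambiguous`, `reason`).
#' @return Assignment tibble (`marker`, `size_bp`, `species`, `chromosomes`,
#'   `evidence`, `ambiguous`, `conflict`, `reason`).
#' @export
reconcile_evidence <- function(line_tbl, peak_tbl) {
  keys <- c("marker", "size_bp", "species")
  merged <- dplyr::full_join(
    dplyr::rename(line_tbl, line_chroms = "chromosomes", line_reason = "reason"),
    dplyr::rename(peak_tbl, peak_chroms = "chromosomes", peak_reason = "reason"),
    by = keys)
  merged$line_chroms[is.na(merged$line_chroms)] <- ""
  merged$peak_chroms[is.na(merged$peak_chroms)] <- ""
  merged$ambiguous[is.na(merged$ambiguous)] <- FALSE
  split_set <- function(x) if (nzchar(x)) strsplit(x, "/", fixed = TRUE)[[1L]] else character(0)
  rows <- lapply(seq_len(nrow(merged)), function(i) {
    L <- split_set(merged$line_chroms[i])
    P <- split_set(merged$peak_chroms[i])
    if (length(L) > 0 && length(P) > 0) {
      I <- intersect(L, P)
      if (length(I) > 0) {
        list(chromosomes = paste(sort(I), collapse = "/"), evidence = "both",
             ambiguous = FALSE, conflict = FALSE, reason = NA_character_)
      } else {
        list(chromosomes = paste(sort(L), collapse = "/"), evidence = "line",
             ambiguous = FALSE, conflict = TRUE,
             reason = paste0("peak evidence disagreed: ", merged$peak_chroms[i]))
      }
    } else if (length(L) > 0) {
      list(chromosomes = paste(sort(L), collapse = "/"), evidence = "line",
           ambiguous = FALSE, conflict = FALSE, reason = NA_character_)
    } else if (length(P) > 0) {
      list(chromosomes = paste(sort(P), collapse = "/"), evidence = "peak_yield",
           ambiguous = isTRUE(merged$ambiguous[i]), conflict = FALSE,
           reason = NA_character_)
    } else {
      list(chromosomes = "", evidence = "unassigned", ambiguous = FALSE,
           conflict = FALSE,
           reason = paste(stats::na.omit(c(merged$line_reason[i],
                                           merged$peak_reason[i])),
                          collapse = "; "))
    }
  })
  dplyr::bind_cols(merged[, keys], dplyr::bind_rows(lapply(rows, tibble::as_tibble)))
}

#' Assign all marker products to chromosomes
#'
#' End-to-end assignment: classifies polymorphism, runs the introgression-line
#' and peak-yield evidence streams on every distinct Aegilops product,
#' reconciles them, and finally applies the cross-species transfer rule for
#' species left without a direct assignment.
#'
#' @param obs Observation tibble from [read_fragment_table()].
#' @param panel Karyotype tibble (may have zero rows to disable the line
#'   path).
#' @param comp Composition tibble.
#' @param wheat_parent_ids Parental wheat sample ids.
#' @param thresholds Threshold list.
#' @param tau_min Minimum Kendall tau-b for a peak-yield call.
#' @param presence_fraction Detection threshold fraction (see
#'   [score_peak_concordance()]).
#' @param tol Size-bin tolerance in bp.
#' @return Assignment tibble (`marker`, `size_bp`, `species`, `chromosomes`,
#'   `evidence`, `polymorphic`, `ambiguous`, `conflict`, `reason`,
#'   `anchor_species`, `anchor_chromosome`); attribute `"transfer_conflicts"`
#'   lists anchors that disagreed across species.
#' @export
assign_loci <- function(obs, panel, comp, wheat_parent_ids,
                        thresholds = default_thresholds(), tau_min = 0.8,
                        presence_fraction = 0.05, tol = 1L) {
  classes <- classify_polymorphism(obs, wheat_parent_ids, thresholds)
  profiles <- peak_yield_profiles(obs, tol)

  # the product universe: every distinct (marker, species, size bin) seen in
  # an Aegilops parent or a peak fraction
  products <- dplyr::bind_rows(
    dplyr::select(classes, "marker", "species", "size_bp"),
    dplyr::select(profiles, "marker", "species", "size_bp")
  ) |> dplyr::distinct()

  # pre-split observations by marker: every evidence check is marker-local
  obs_idx <- split(seq_len(nrow(obs)), obs$marker)
  cm_cache <- lapply(stats::setNames(nm = unique(products$species)),
                     function(sp) content_matrix(comp, sp))

  n_prod <- nrow(products)
  line_chroms <- line_reason <- character(n_prod)
  peak_chroms <- peak_reason <- character(n_prod)
  peak_ambiguous <- logical(n_prod)
  prof_key <- paste(profiles$marker, profiles$species, profiles$size_bp,
                    sep = "\r")
  for (i in seq_len(n_prod)) {
    obs_m <- obs[obs_idx[[products$marker[i]]], , drop = FALSE]
    res <- if (nrow(panel) > 0) {
      assign_by_introgression(products$marker[i], products$size_bp[i],
                              products$species[i], panel, obs_m,
                              wheat_parent_ids, thresholds, tol)
    } else structure(character(0), reason = "no_panel_lines")
    line_chroms[i] <- paste(res, collapse = "/")
    line_reason[i] <- attr(res, "reason") %||% NA_character_

    j <- match(paste(products$marker[i], products$species[i],
                     products$size_bp[i], sep = "\r"), prof_key)
    if (is.na(j)) {
      peak_reason[i] <- "no_peak_profile"
      next
    }
    scores <- score_peak_concordance(profiles$yields[[j]],
                                     cm_cache[[products$species[i]]],
                                     control_yield = profiles$control_yield[j],
                                     presence_fraction = presence_fraction)
    res <- assign_by_peak_yield(scores, tau_min)
    peak_chroms[i] <- paste(res, collapse = "/")
    peak_ambiguous[i] <- isTRUE(attr(res, "ambiguous"))
    peak_reason[i] <- attr(res, "reason") %||% NA_character_
  }
  line_tbl <- tibble::tibble(marker = products$marker,
                             size_bp = products$size_bp,
                             species = products$species,
                             chromosomes = line_chroms, reason = line_reason)
  peak_tbl <- tibble::tibble(marker = products$marker,
                             size_bp = products$size_bp,
                             species = products$species,
                             chromosomes = peak_chroms,
                             ambiguous = peak_ambiguous, reason = peak_reason)

  direct <- reconcile_evidence(line_tbl, peak_tbl)
  transfers <- transfer_across_species(direct, profiles, comp, size_bin = tol)

  final <- dplyr::bind_rows(
    dplyr::mutate(direct, anchor_species = NA_character_,
                  anchor_chromosome = NA_character_),
    dplyr::mutate(transfers, polymorphic = NA, ambiguous = FALSE,
                  conflict = FALSE, reason = NA_character_)
  )
  final <- dplyr::left_join(
    dplyr::select(final, -dplyr::any_of("polymorphic")),
    dplyr::select(classes, "marker", "species", "size_bp", "polymorphic"),
    by = c("marker", "size_bp", "species"))
  final <- final |>
    dplyr::arrange(.data$marker, .data$size_bp, .data$species) |>
    dplyr::select("marker", "size_bp", "species", "chromosomes", "evidence",
                  "polymorphic", "ambiguous", "conflict", "reason",
                  "anchor_species", "anchor_chromosome")
  structure(final, transfer_conflicts = attr(transfers, "conflicts"))
}
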
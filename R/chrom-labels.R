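#' Parse chromosome labels
#'
#' Triticeae/Aegilops chromosome nomenclature combines a homoeologous group
#' (1-7), a genome symbol (U, M, D, A, B), an optional subgenome tag for the
#' allotetraploid-derived versions of U and M (`b` for *Ae. biuncialis*, `g`
#' for *Ae. geniculata*) and an optional arm (`S`/`L`).  `"2Ug"` is the
#' *Ae. geniculata* group-2 U-genome chromosome; `"4BS"` is the short arm of
#' wheat chromosome 4B.
#'
#' @param x Character vector of labels such as `"3Mb"`, `"6U"`, `"4BS"`,
#'   `"3MbL"`.
#' @return A tibble with one row per label and columns `label` (canonical
#'   rendering), `group` (integer 1-7), `genome`, `tag` (`""` when none) and
#'   `arm` (`""` when whole-chromosome).
#' @examples
#' chrom_parse(c("3Mb", "6U", "4BS"))
#' @export
chrom_parse <- function(x) {
  x <- as.character(x)
  if (length(x) == 0) {
    return(tibble::new_tibble(list(label = character(), group = integer(),
                                   genome = character(), tag = character(),
                                   arm = character()), nrow = 0L))
  }
  ux <- unique(x)
  cached <- mget(ux, envir = .label_cache, ifnotfound = list(NULL))
  new <- ux[vapply(cached, is.null, logical(1))]
  if (length(new) > 0) {
    m <- regmatches(new, regexec("^([1-7])([UMDAB])([bg]?)([SL]?)$", new))
    bad <- vapply(m, length, integer(1)) == 0L
    if (any(bad)) {
      stop("invalid chromosome label(s): ", paste(new[bad], collapse = ", "),
           call. = FALSE)
    }
    for (i in seq_along(new)) {
      p <- m[[i]]
      if (p[3L] %in% c("D", "A", "B") && nzchar(p[4L])) {
        stop("subgenome tags are only valid for U and M genome chromosomes",
             call. = FALSE)
      }
      assign(new[i],
             list(group = as.integer(p[2L]), genome = p[3L], tag = p[4L],
                  arm = p[5L],
                  label = paste0(p[2L], p[3L], p[4L], p[5L])),
             envir = .label_cache)
    }
  }
  vals <- unname(mget(x, envir = .label_cache))
  tibble::new_tibble(list(
    label  = vapply(vals, `[[`, character(1), "label"),
    group  = vapply(vals, `[[`, integer(1), "group"),
    genome = vapply(vals, `[[`, character(1), "genome"),
    tag    = vapply(vals, `[[`, character(1), "tag"),
    arm    = vapply(vals, `[[`, character(1), "arm")
  ), nrow = length(x))
}

.label_cache <- new.env(parent = emptyenv())

#' Render a chromosome label
#'
#' Inverse of [chrom_parse()]: `chrom_format(3, "M", "b")` gives `"3Mb"`.
#'
#' @param group Integer 1-7.
#' @param genome Genome symbol (`U`, `M`, `D`, `A`, `B`).
#' @param tag Subgenome tag (`""`, `"b"` or `"g"`); only valid for U/M.
#' @param arm Arm (`""`, `"S"` or `"L"`).
#' @return Character vector of labels.
#' @export
chrom_format <- function(group, genome, tag = "", arm = "") {
  stopifnot(all(group %in% 1:7), all(genome %in% c("U", "M", "D", "A", "B")))
  tag <- ifelse(is.na(tag), "", tag)
  arm <- ifelse(is.na(arm), "", arm)
  if (any(tag != "" & !genome %in% c("U", "M"))) {
    stop("subgenome tags are only valid for U and M genome chromosomes",
         call. = FALSE)
  }
  paste0(group, genome, tag, arm)
}

#' Strip the subgenome tag from labels
#'
#' Collapses the tetraploid-specific versions onto the diploid nomenclature
#' (`"2Mb"` and `"2Mg"` both become `"2M"`), which is how duplication patterns
#' are compared across species.
#'
#' @param x Character vector of labels.
#' @return Character vector with tags removed (arms preserved).
#' @export
chrom_strip_tag <- function(x) {
  p <- chrom_parse(x)
  chrom_format(p$group, p$genome, "", p$arm)
}

#' Strip the arm from labels
#'
#' @param x Character vector of labels.
#' @return Whole-chromosome labels (tags preserved).
#' @export
chrom_strip_arm <- function(x) {
  p <- chrom_parse(x)
  chrom_format(p$group, p$genome, p$tag, "")
}

#' Subgenome tag used by a species
#'
#' The diploids carry untagged U/M chromosomes; *Ae. biuncialis* chromosomes
#' are tagged `b` and *Ae. geniculata* chromosomes `g`.
#'
#' @param species Character vector of species codes
#'   (`"umbellulata"`, `"comosa"`, `"biuncialis"`, `"geniculata"`).
#' @return Character vector of tags (`""`, `"b"` or `"g"`).
#' @export
species_tag <- function(species) {
  tags <- c(umbellulata = "", comosa = "", biuncialis = "b", geniculata = "g")
  unknown <- setdiff(unique(species), names(tags))
  if (length(unknown) > 0) {
    stop("unknown Aegilops species code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(tags[species])
}

#' Homoeologous chromosome label in another species
#'
#' Keeps genome and homoeologous group, swaps the subgenome tag for the target
#' species' tag and drops any arm.  Used by the cross-species transfer rule,
#' which by construction never changes genome or group.
#'
#' @param label Chromosome label(s) in the source species.
#' @param species Target species code(s).
#' @return Chromosome label(s) in the target species' nomenclature.
#' @export
homoeologous_label <- function(label, species) {
  p <- chrom_parse(label)
  chrom_format(p$group, p$genome, species_tag(species), "")
}

# genomes native to each Aegilops species (used when enumerating candidates)
species_genomes <- function(species) {
  g <- list(umbellulata = "U", comosa = "M",
            biuncialis = c("U", "M"), geniculata = c("U", "M"))
  unknown <- setdiff(unique(species), names(g))
  if (length(unknown) > 0) {
    stop("unknown Aegilops species code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  g[species]
}
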
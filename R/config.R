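#' Marker configuration
#'
#' A marker configuration declares how gene coordinates map onto alignment
#' columns and which sites are diagnostic for strain (and, for Tpi, subgroup)
#' classification. Diagnostic positions are 1-based and numbered from the
#' predicted translational start site of the gene; a per-marker signed
#' `offset` converts them to 1-based alignment columns
#' (`column = position + offset`). Tpi intron sites are numbered within the
#' fourth intron and converted with their own `intron_offset`.
#'
#' Two classifier types exist:
#' * `"vote"` — majority vote over a table of class-specific alleles
#'   (used for COI; see [call_coi()]),
#' * `"tpi"` — the bespoke exon/intron rule set of the Tpi marker
#'   (see [call_tpi()]).
#'
#' @param marker Marker label.
#' @param type `"vote"` or `"tpi"`.
#' @param amplicon_length Alignment length in columns.
#' @param offset Signed integer: gene position + offset = alignment column.
#' @param sites For `"vote"`: a data frame with a `position` column and one
#'   column of unambiguous expected alleles per class label.
#' @param threshold For `"vote"`: minimum match fraction to assign a class.
#' @param strain_site For `"tpi"`: list `(position, alleles)` where `alleles`
#'   maps strain label to base, e.g. `c(C = "C", R = "T")` at gTpi183.
#' @param subgroup_exon_sites For `"tpi"`: the two exon positions whose
#'   (C,C)/(T,T)/(Y,Y) genotypes separate Ca1 / Ca2 / Ca1-Ca2 heterozygote.
#' @param intron_offset For `"tpi"`: intron position + intron_offset = column.
#' @param intron_het_sites For `"tpi"`: intron positions expected to carry
#'   IUPAC ambiguity codes in a Ca1/Ca2 heterozygote.
#' @param subgroup_site For `"tpi"`: list `(position, alleles)` splitting Ca2
#'   into Ca2a/Ca2b at intron position 148.
#' @return A `marker_config` object.
#' @export
marker_config <- function(marker, type = c("vote", "tpi"), amplicon_length,
                          offset = 0L, sites = NULL, threshold = 0.8,
                          strain_site = NULL, subgroup_exon_sites = NULL,
                          intron_offset = 0L, intron_het_sites = integer(),
                          subgroup_site = NULL) {
  type <- match.arg(type)
  cfg <- structure(
    list(
      marker = marker, type = type,
      amplicon_length = as.integer(amplicon_length),
      offset = as.integer(offset), threshold = threshold,
      sites = if (!is.null(sites)) as_tibble(sites),
      strain_site = strain_site,
      subgroup_exon_sites = subgroup_exon_sites,
      intron_offset = as.integer(intron_offset),
      intron_het_sites = as.integer(intron_het_sites),
      subgroup_site = subgroup_site
    ),
    class = "marker_config"
  )
  validate_marker_config(cfg)
}

validate_marker_config <- function(cfg) {
  if (cfg$type == "vote") {
    if (is.null(cfg$sites) || !"position" %in% names(cfg$sites)) {
      abort("vote config requires a `sites` table with a `position` column")
    }
    alleles <- unlist(cfg$sites[setdiff(names(cfg$sites), "position")])
    if (!all(is_unambiguous(alleles))) {
      abort("class alleles must be unambiguous bases (A/C/G/T)")
    }
    resolve_column(cfg, cfg$sites$position)
  } else {
    if (is.null(cfg$strain_site)) abort("tpi config requires `strain_site`")
    resolve_column(cfg, c(
      cfg$strain_site$position, cfg$subgroup_exon_sites
    ))
    resolve_column(cfg, c(cfg$intron_het_sites, cfg$subgroup_site$position),
      intron = TRUE
    )
  }
  cfg
}

# Gene/intron position -> alignment column, with bounds checking.
resolve_column <- function(cfg, position, intron = FALSE) {
  off <- if (intron) cfg$intron_offset else cfg$offset
  col <- as.integer(position) + off
  bad <- col < 1L | col > cfg$amplicon_length
  if (any(bad)) {
    abort(paste0(
      "configuration error: position(s) ",
      paste(position[bad], collapse = ", "),
      " map outside the ", cfg$amplicon_length, "-column alignment of ",
      cfg$marker
    ))
  }
  col
}

#' @export
print.marker_config <- function(x, ...) {
  cat("<marker_config> ", x$marker, " (", x$type, "), ",
    x$amplicon_length, " bp, offset ", x$offset, "\n",
    sep = ""
  )
  if (x$type == "vote") {
    cat("  ", nrow(x$sites), " diagnostic sites, vote threshold ",
      x$threshold, "\n",
      sep = ""
    )
  } else {
    cat("  strain site ", x$strain_site$position,
      ", subgroup exon sites ",
      paste(x$subgroup_exon_sites, collapse = "/"),
      ", ", length(x$intron_het_sites), " intron sites\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Default COI marker configuration
#'
#' The 658 bp COI barcode amplicon spans gene positions 39-696 (offset -38).
#' Ten positions (mCOI72, 117, 171, 207, 258, 564, 570, 600, 634, 663,
#' numbered from the translational start) separate the corn (C) and rice (R)
#' mitochondrial lineages. The per-class alleles at those sites are not
#' published as machine-readable text, so the shipped values are the synthetic
#' convention used by [simulate_faw_survey()]; replace them with empirically
#' calibrated alleles (via [read_marker_config()]) when typing real data.
#'
#' @param threshold Minimum vote fraction for a strain call (default 0.8,
#'   tolerant of a few Ns across the ten sites).
#' @return A `marker_config`.
#' @export
coi_config <- function(threshold = 0.8) {
  marker_config(
    marker = "COI", type = "vote", amplicon_length = 658L, offset = -38L,
    threshold = threshold,
    sites = tibble(
      position = c(72L, 117L, 171L, 207L, 258L, 564L, 570L, 600L, 634L, 663L),
      R = c("A", "C", "A", "T", "C", "T", "A", "C", "A", "T"),
      C = c("G", "T", "G", "C", "T", "C", "G", "T", "G", "C")
    )
  )
}

#' Default Tpi marker configuration
#'
#' The 444 bp Tpi amplicon contains 166 bp of the fourth exon followed by
#' 278 bp of the fourth intron. Exon positions are numbered from the
#' translational start (offset -140: gTpi183 is column 43); intron positions
#' are numbered within the intron (offset +166). gTpi183 carries the
#' strain-diagnostic allele (C = corn strain, T = rice strain); gTpi192/198
#' separate the corn-strain subgroups Ca1 (C,C), Ca2 (T,T) and the Ca1/Ca2
#' heterozygote (Y,Y); intron position 148 splits Ca2 into Ca2a and Ca2b.
#' The ten intron positions listed are polymorphic between Ca1 and Ca2 and are
#' expected to show two-base IUPAC codes in a Ca1/Ca2 heterozygote.
#'
#' @return A `marker_config`.
#' @export
tpi_config <- function() {
  marker_config(
    marker = "Tpi", type = "tpi", amplicon_length = 444L, offset = -140L,
    strain_site = list(position = 183L, alleles = c(C = "C", R = "T")),
    subgroup_exon_sites = c(192L, 198L),
    intron_offset = 166L,
    intron_het_sites = c(31L, 38L, 53L, 55L, 58L, 70L, 77L, 87L, 96L, 148L),
    subgroup_site = list(position = 148L, alleles = c(Ca2a = "G", Ca2b = "T"))
  )
}

#' Read / write a marker configuration as YAML
#'
#' @param path Path to a YAML file.
#' @return `read_marker_config()` a `marker_config`;
#'   `write_marker_config()` `path`, invisibly.
#' @export
read_marker_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (identical(y$type, "vote")) {
    marker_config(
      marker = y$marker, type = "vote",
      amplicon_length = y$amplicon_length, offset = y$offset %||% 0L,
      threshold = y$threshold %||% 0.8,
      sites = bind_rows(lapply(y$sites, as_tibble))
    )
  } else {
    marker_config(
      marker = y$marker, type = "tpi",
      amplicon_length = y$amplicon_length, offset = y$offset %||% 0L,
      strain_site = list(
        position = y$strain_site$position,
        alleles = unlist(y$strain_site$alleles)
      ),
      subgroup_exon_sites = unlist(y$subgroup_exon_sites),
      intron_offset = y$intron_offset %||% 0L,
      intron_het_sites = unlist(y$intron_het_sites),
      subgroup_site = list(
        position = y$subgroup_site$position,
        alleles = unlist(y$subgroup_site$alleles)
      )
    )
  }
}

#' @rdname read_marker_config
#' @param cfg A `marker_config`.
#' @export
write_marker_config <- function(cfg, path) {
  y <- list(
    marker = cfg$marker, type = cfg$type,
    amplicon_length = cfg$amplicon_length, offset = cfg$offset
  )
  if (cfg$type == "vote") {
    y$threshold <- cfg$threshold
    y$sites <- purrr::pmap(cfg$sites, function(...) list(...))
  } else {
    y$strain_site <- list(
      position = cfg$strain_site$position,
      alleles = as.list(cfg$strain_site$alleles)
    )
    y$subgroup_exon_sites <- cfg$subgroup_exon_sites
    y$intron_offset <- cfg$intron_offset
    y$intron_het_sites <- cfg$intron_het_sites
    y$subgroup_site <- list(
      position = cfg$subgroup_site$position,
      alleles = as.list(cfg$subgroup_site$alleles)
    )
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
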
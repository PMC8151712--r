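base_at <- function(seq, col) substr(seq, col, col)

#' Call the Tpi strain from the gTpi183 diagnostic site
#'
#' C at gTpi183 is the corn strain, T the rice strain, Y (C/T) a corn/rice
#' heterozygote (the gene is Z-linked, so only males can be heterozygous);
#' any other base, ambiguity code or gap is undetermined.
#'
#' @param seq Character vector of aligned Tpi sequences.
#' @param cfg A Tpi `marker_config` (default [tpi_config()]).
#' @return Character vector over
#'   `{"C", "R", "C/R heterozygous", "undetermined"}`.
#' @export
call_tpi_strain <- function(seq, cfg = tpi_config()) {
  col <- resolve_column(cfg, cfg$strain_site$position)
  b <- base_at(seq, col)
  al <- cfg$strain_site$alleles
  het <- iupac_code(al[["C"]], al[["R"]])
  dplyr::case_when(
    b == al[["C"]] ~ "C",
    b == al[["R"]] ~ "R",
    b == het ~ "C/R heterozygous",
    TRUE ~ "undetermined"
  )
}

# Subgroup resolution for one specimen already called corn-strain (or C/R het).
tpi_subgroup_one <- function(seq, cfg) {
  ex <- resolve_column(cfg, cfg$subgroup_exon_sites)
  b192 <- base_at(seq, ex[1])
  b198 <- base_at(seq, ex[2])
  intron_cols <- resolve_column(cfg, cfg$intron_het_sites, intron = TRUE)
  intron <- setNames(
    vapply(intron_cols, function(cc) base_at(seq, cc), character(1)),
    cfg$intron_het_sites
  )
  note <- NA_character_
  if (b192 == "C" && b198 == "C") {
    # Ca1 family; within-subgroup intron variants do not split it further,
    # so the single observed Ca1 subtype label is reported.
    subgroup <- "Ca1a"
  } else if (b192 == "T" && b198 == "T") {
    s148 <- intron[[as.character(cfg$subgroup_site$position)]]
    al <- cfg$subgroup_site$alleles
    subgroup <- names(al)[match(s148, al)]
    if (is.na(subgroup)) {
      subgroup <- "Ca2"
      note <- paste0(
        "intron ", cfg$subgroup_site$position, " base '", s148,
        "' matches neither Ca2a nor Ca2b allele"
      )
    }
  } else if (b192 == "Y" && b198 == "Y") {
    subgroup <- "Ca1/Ca2"
    ok <- is_ambiguity(intron) & intron %in% c("S", "M", "W", "Y")
    if (!all(ok)) {
      note <- paste0(
        "heterozygote intron pattern inconsistent: expected two-base ",
        "ambiguity codes (S/M/W/Y) at intron sites ",
        paste(names(intron)[!ok], collapse = ", ")
      )
    }
  } else {
    subgroup <- "undetermined"
    note <- paste0(
      "inconsistent subgroup pair at gTpi",
      paste(cfg$subgroup_exon_sites, collapse = "/"),
      ": (", b192, ",", b198, ")"
    )
  }
  list(
    subgroup = subgroup, base192 = b192, base198 = b198,
    intron_bases = intron, note = note
  )
}

#' Classify Tpi sequences: strain, subgroup and heterozygosity
#'
#' Applies the diagnostic-SNP rules of the nuclear Tpi marker: gTpi183 for
#' the corn/rice strain call, gTpi192/gTpi198 for the corn-strain subgroup
#' family (Ca1, Ca2 or the Ca1/Ca2 heterozygote), and intron position 148 to
#' split Ca2 into Ca2a/Ca2b. A specimen is flagged heterozygous when any
#' diagnostic exon site carries an IUPAC ambiguity code. In a Ca1/Ca2
#' heterozygote every Ca1-vs-Ca2 intron site is expected to be a two-base
#' ambiguity code (S/M/W/Y); departures are reported in `note`, not used to
#' reassign the subgroup.
#'
#' @param aln A Tpi `marker_alignment`.
#' @param cfg A Tpi `marker_config`.
#' @return A tibble with one row per specimen: `specimen_id`, `marker`,
#'   `strain`, `subgroup`, `heterozygous`, `score` (NA for this marker),
#'   `base183`, `base192`, `base198`, `intron_bases` (list column of named
#'   bases at the Ca1/Ca2 intron sites), `note`.
#' @export
call_tpi <- function(aln, cfg = tpi_config()) {
  strain <- call_tpi_strain(aln$seq, cfg)
  ex <- resolve_column(cfg, c(cfg$strain_site$position, cfg$subgroup_exon_sites))
  het <- vapply(
    aln$seq,
    function(s) any(is_ambiguity(vapply(ex, function(cc) base_at(s, cc), character(1)))),
    logical(1), USE.NAMES = FALSE
  )
  details <- purrr::map2(aln$seq, strain, function(s, st) {
    if (st %in% c("C", "C/R heterozygous")) {
      tpi_subgroup_one(s, cfg)
    } else {
      list(
        subgroup = NA_character_,
        base192 = base_at(s, ex[2]), base198 = base_at(s, ex[3]),
        intron_bases = setNames(
          rep(NA_character_, length(cfg$intron_het_sites)),
          cfg$intron_het_sites
        ),
        note = NA_character_
      )
    }
  })
  tibble(
    specimen_id = aln$specimen_id,
    marker = cfg$marker,
    strain = strain,
    subgroup = purrr::map_chr(details, "subgroup"),
    heterozygous = het,
    score = NA_real_,
    base183 = base_at(aln$seq, ex[1]),
    base192 = purrr::map_chr(details, "base192"),
    base198 = purrr::map_chr(details, "base198"),
    intron_bases = purrr::map(details, "intron_bases"),
    note = purrr::map_chr(details, "note")
  )
}

#' Classify COI sequences by majority vote over diagnostic sites
#'
#' Each sequence is scored against every class's expected-allele vector at the
#' configured diagnostic positions. Sites where the observed base is not an
#' unambiguous nucleotide (gap, N or ambiguity code) are excluded from both
#' numerator and denominator. The class with the higher match fraction is
#' assigned if that fraction reaches the vote threshold; ties and sub-threshold
#' scores are `undetermined`. A sequence with no usable diagnostic site is
#' `undetermined` with a zero-coverage note.
#'
#' @param aln A COI `marker_alignment`.
#' @param cfg A vote-type `marker_config` (default [coi_config()]).
#' @return A tibble with one row per specimen: `specimen_id`, `marker`,
#'   `strain`, `subgroup` (NA), `heterozygous` (FALSE), `score` (match
#'   fraction of the winning class), `n_compared`, `site_bases` (list column),
#'   `note`.
#' @export
call_coi <- function(aln, cfg = coi_config()) {
  cols <- resolve_column(cfg, cfg$sites$position)
  classes <- setdiff(names(cfg$sites), "position")
  rows <- purrr::map(aln$seq, function(s) {
    obs <- vapply(cols, function(cc) base_at(s, cc), character(1))
    usable <- is_unambiguous(obs)
    n_cmp <- sum(usable)
    if (n_cmp == 0) {
      return(list(
        strain = "undetermined", score = NA_real_, n_compared = 0L,
        site_bases = setNames(obs, cfg$sites$position),
        note = "zero coverage at diagnostic sites"
      ))
    }
    frac <- vapply(
      classes,
      function(cl) sum(obs[usable] == cfg$sites[[cl]][usable]) / n_cmp,
      numeric(1)
    )
    best <- which(frac == max(frac))
    if (length(best) > 1 || frac[best] < cfg$threshold) {
      strain <- "undetermined"
      score <- max(frac)
    } else {
      strain <- classes[best]
      score <- frac[best]
    }
    list(
      strain = strain, score = unname(score), n_compared = n_cmp,
      site_bases = setNames(obs, cfg$sites$position), note = NA_character_
    )
  })
  tibble(
    specimen_id = aln$specimen_id,
    marker = cfg$marker,
    strain = purrr::map_chr(rows, "strain"),
    subgroup = NA_character_,
    heterozygous = FALSE,
    score = purrr::map_dbl(rows, "score"),
    n_compared = purrr::map_int(rows, "n_compared"),
    site_bases = purrr::map(rows, "site_bases"),
    note = purrr::map_chr(rows, "note")
  )
}

#' Classify a marker alignment with its configuration
#'
#' Dispatches to [call_tpi()] or [call_coi()] according to the configuration
#' type, so pipelines can treat markers uniformly.
#'
#' @param aln A `marker_alignment`.
#' @param cfg A `marker_config`.
#' @return A per-specimen classification tibble.
#' @export
classify_marker <- function(aln, cfg) {
  switch(cfg$type,
    tpi = call_tpi(aln, cfg),
    vote = call_coi(aln, cfg),
    abort(paste0("unknown config type: ", cfg$type))
  )
}

#' Combine per-marker calls into a two-marker genotype
#'
#' The combined label (e.g. `"Tpi-C/COI-R"`, the corn-male x rice-female
#' hybrid class) is derived deterministically from the two strain calls.
#' A specimen whose Tpi or COI call is undetermined (or a Tpi C/R
#' heterozygote) gets `complete = FALSE` and a `?` in the label.
#'
#' @param tpi_calls,coi_calls Classification tibbles from [call_tpi()] /
#'   [call_coi()].
#' @return A tibble: `specimen_id`, `tpi_strain`, `tpi_subgroup`,
#'   `coi_strain`, `label`, `complete`.
#' @export
combine_genotypes <- function(tpi_calls, coi_calls) {
  tpi <- select(tpi_calls, "specimen_id",
    tpi_strain = "strain", tpi_subgroup = "subgroup"
  )
  coi <- select(coi_calls, "specimen_id", coi_strain = "strain")
  out <- dplyr::full_join(tpi, coi, by = "specimen_id")
  lab <- function(x) ifelse(is.na(x) | !x %in% c("C", "R"), "?", x)
  mutate(out,
    label = paste0("Tpi-", lab(.data$tpi_strain), "/COI-", lab(.data$coi_strain)),
    complete = .data$tpi_strain %in% c("C", "R") & .data$coi_strain %in% c("C", "R")
  )
}

#' Genotype frequency summary
#'
#' @param genotypes Output of [combine_genotypes()].
#' @return A tibble of `label`, `n`, `pct` (percent of all specimens,
#'   1 decimal), sorted by decreasing count.
#' @export
genotype_frequencies <- function(genotypes) {
  genotypes |>
    count(.data$label, name = "n") |>
    mutate(pct = round(100 * .data$n / sum(.data$n), 1)) |>
    arrange(dplyr::desc(.data$n))
}

#' Percent identity between two aligned sequences
#'
#' Positions where either sequence has a gap (`-`) or missing base (`N`) are
#' excluded; remaining positions are compared literally. The result is
#' reported to two decimals, matching how marker similarities are usually
#' quoted (e.g. one mismatch over 658 bp is 99.85).
#'
#' @param a,b Aligned sequences of equal length.
#' @return Percent identity (numeric, 2 decimals); `NA` with a warning when no
#'   position is comparable.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("sequences must have equal aligned length")
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- !(x %in% c("-", "N")) & !(y %in% c("-", "N"))
  if (!any(ok)) {
    warn("no comparable positions; identity undefined")
    return(NA_real_)
  }
  round(100 * sum(x[ok] == y[ok]) / sum(ok), 2)
}
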
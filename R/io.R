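#' Country-to-continent lookup for the survey countries
#'
#' The survey covers eight countries, four African and four Asian. The lookup
#' is deliberately closed: an unknown country is an error rather than a guess,
#' so that regional subsets in the diversity analysis can never be silently
#' mis-assigned.
#'
#' @return A tibble with columns `country` and `region`.
#' @export
#' @examples
#' country_regions()
country_regions <- function() {
  tibble(
    country = c(
      "DR Congo", "Tanzania", "Uganda", "Zimbabwe",
      "Bangladesh", "Korea", "Nepal", "Vietnam"
    ),
    region = rep(c("Africa", "Asia"), each = 4L)
  )
}

#' Map a country to its survey region
#'
#' @param country Character vector of country names.
#' @return Character vector of regions (`"Africa"` or `"Asia"`).
#' @export
#' @examples
#' region_of(c("DR Congo", "Korea"))
region_of <- function(country) {
  lk <- country_regions()
  idx <- match(country, lk$country)
  if (anyNA(idx)) {
    abort(paste0(
      "unknown country (no region mapping): ",
      paste(unique(country[is.na(idx)]), collapse = ", ")
    ))
  }
  lk$region[idx]
}

new_marker_alignment <- function(tbl, marker_name, length) {
  structure(
    as_tibble(tbl),
    marker_name = marker_name,
    aln_length = as.integer(length),
    class = c("marker_alignment", class(as_tibble(tbl)))
  )
}

#' Alignment attribute accessors
#'
#' @param aln A `marker_alignment` tibble as returned by [read_marker_fasta()].
#' @return `marker_name()` the marker label; `alignment_length()` the number of
#'   columns shared by all sequences.
#' @export
marker_name <- function(aln) attr(aln, "marker_name")

#' @rdname marker_name
#' @export
alignment_length <- function(aln) attr(aln, "aln_length")

validate_alignment_tbl <- function(tbl, marker_name) {
  if (anyDuplicated(tbl$specimen_id)) {
    abort(paste0(
      "duplicate specimen ids in alignment: ",
      paste(unique(tbl$specimen_id[duplicated(tbl$specimen_id)]), collapse = ", ")
    ))
  }
  lens <- nchar(tbl$seq)
  if (nrow(tbl) > 0 && length(unique(lens)) > 1) {
    bad <- which(lens != lens[1])[1]
    abort(paste0(
      "ragged alignment: record '", tbl$specimen_id[bad], "' has length ",
      lens[bad], ", expected ", lens[1]
    ))
  }
  chars <- unique(unlist(strsplit(tbl$seq, "", fixed = TRUE)))
  bad <- setdiff(chars, .ALPHABET)
  if (length(bad) > 0) {
    abort(paste0(
      "alignment contains characters outside {ACGT, IUPAC, '-', 'N'}: ",
      paste(bad, collapse = " ")
    ))
  }
  new_marker_alignment(tbl, marker_name, if (nrow(tbl)) lens[1] else 0L)
}

#' Read an aligned marker FASTA file
#'
#' Record ids are taken from the header up to the first whitespace and bases
#' are upper-cased. All records must have identical length (these are
#' alignments, not raw reads); a ragged file is an error naming the offending
#' record. Characters outside the nucleotide alphabet (ACGT, IUPAC ambiguity
#' codes, `-`, `N`) are a hard error so that a corrupt file cannot produce
#' silent miscalls at diagnostic sites. Wrapped and unwrapped FASTA are both
#' accepted.
#'
#' @param path Path to a FASTA file.
#' @param marker Marker label to attach (e.g. `"Tpi"`); defaults to the file
#'   name without extension.
#' @return A `marker_alignment`: a tibble with columns `specimen_id` and `seq`,
#'   plus `marker_name` and `aln_length` attributes.
#' @export
read_marker_fasta <- function(path, marker = NULL) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  marker <- marker %||% sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  tbl <- tibble(specimen_id = ids, seq = unname(toupper(as.character(ss))))
  validate_alignment_tbl(tbl, marker)
}

#' Write a marker alignment as unwrapped FASTA
#'
#' @param aln A `marker_alignment` (or any tibble with `specimen_id`, `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(setNames(aln$seq, aln$specimen_id))
  Biostrings::writeXStringSet(ss, path, width = 200000L)
  invisible(path)
}

#' Build a marker alignment from in-memory sequences
#'
#' @param seqs Named character vector (names are specimen ids) or a tibble with
#'   `specimen_id` and `seq` columns.
#' @param marker Marker label.
#' @return A `marker_alignment`.
#' @export
marker_alignment <- function(seqs, marker = "marker") {
  tbl <- if (is.data.frame(seqs)) {
    as_tibble(seqs[c("specimen_id", "seq")])
  } else {
    tibble(specimen_id = names(seqs), seq = unname(seqs))
  }
  tbl$seq <- toupper(tbl$seq)
  validate_alignment_tbl(tbl, marker)
}

#' Read the specimen metadata table
#'
#' Expects delimited text (TSV or CSV, auto-detected) with a header row and at
#' least `specimen_id`, `country`, `collection_date` and `stage` columns.
#' `region` is inferred from the country through [region_of()] when absent;
#' a country outside the survey lookup with no explicit region is an error.
#' Dates are parsed month/day/year and stored as ISO `Date`s. Optional
#' `accession_tpi` / `accession_coi` columns are carried through.
#'
#' @param path Path to the table.
#' @return A tibble of specimen records, one row per specimen.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort(paste0("sample table not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tbl <- readr::read_delim(
    path,
    delim = delim, trim_ws = TRUE, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  names(tbl) <- tolower(names(tbl))
  required <- c("specimen_id", "country", "collection_date", "stage")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("sample table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tbl$specimen_id)) {
    abort(paste0(
      "duplicate specimen_id in sample table: ",
      paste(unique(tbl$specimen_id[duplicated(tbl$specimen_id)]), collapse = ", ")
    ))
  }
  if (nrow(tbl) == 0) {
    return(tibble(
      specimen_id = character(), country = character(), region = character(),
      collection_date = as.Date(character()), stage = character()
    ))
  }
  if (!"region" %in% names(tbl) || anyNA(tbl$region)) {
    inferred <- region_of(tbl$country)
    tbl$region <- if ("region" %in% names(tbl)) {
      dplyr::coalesce(tbl$region, inferred)
    } else {
      inferred
    }
  }
  bad_region <- setdiff(unique(tbl$region), c("Africa", "Asia"))
  if (length(bad_region) > 0) {
    abort(paste0("region must be Africa or Asia, got: ", paste(bad_region, collapse = ", ")))
  }
  tbl$collection_date <- as.Date(tbl$collection_date, format = "%m/%d/%Y")
  tbl$stage <- tolower(tbl$stage)
  dplyr::relocate(tbl, "specimen_id", "country", "region", "collection_date", "stage")
}

#' Cross-check specimens against marker alignments
#'
#' Lists specimens present in the metadata but absent from an alignment
#' (`missing_marker`, a warning: the pipeline proceeds with partial data) and
#' sequences whose id is absent from the metadata (`orphan_sequence`, an
#' error: downstream regional partitioning would be impossible).
#'
#' @param samples Specimen tibble from [read_sample_table()].
#' @param alignments Named list of `marker_alignment`s.
#' @return A `dataset_validation` tibble with columns `specimen_id`, `marker`,
#'   `issue`; zero rows means a fully consistent dataset. Use
#'   [dataset_ok()] to test whether the pipeline may proceed.
#' @export
validate_dataset <- function(samples, alignments) {
  stopifnot(is.list(alignments))
  report <- purrr::imap(alignments, function(aln, mk) {
    bind_rows(
      tibble(
        specimen_id = setdiff(samples$specimen_id, aln$specimen_id),
        marker = mk, issue = "missing_marker"
      ),
      tibble(
        specimen_id = setdiff(aln$specimen_id, samples$specimen_id),
        marker = mk, issue = "orphan_sequence"
      )
    )
  })
  out <- bind_rows(report)
  class(out) <- c("dataset_validation", class(out))
  out
}

#' @rdname validate_dataset
#' @param report A `dataset_validation` report.
#' @export
dataset_ok <- function(report) !any(report$issue == "orphan_sequence")
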
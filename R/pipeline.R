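fmt_num <- function(x, fmt) {
  ifelse(is.na(x), "NA", sprintf(fmt, x))
}

#' Format the diversity table for reporting
#'
#' Renders the marker x region diversity tibble with the report's mixed
#' precision: haplotype diversity to 3 decimals, nucleotide diversity to 5
#' significant figures, theta/site to 3 decimals, Tajima's D to 6 decimals
#' with significance stars (`*` p<0.05, `**` p<0.01) appended. Minus signs
#' are plain ASCII. Internal values stay full precision; this is a
#' presentation layer only.
#'
#' @param stats Tibble from [diversity_pipeline()].
#' @return A tibble of character columns, one row per marker x region, in the
#'   order given: `Gene, Region, n, S, h, Hd, pi, theta_site, TajimaD`.
#' @export
format_table2 <- function(stats) {
  stars <- dplyr::case_when(
    is.na(stats$significance) ~ "",
    stats$significance == "p<0.01" ~ " **",
    stats$significance == "p<0.05" ~ " *",
    TRUE ~ ""
  )
  tibble(
    Gene = stats$marker,
    Region = stats$region,
    n = as.character(stats$n),
    S = ifelse(is.na(stats$S), "NA", as.character(stats$S)),
    h = ifelse(is.na(stats$h), "NA", as.character(stats$h)),
    Hd = fmt_num(stats$Hd, "%.3f"),
    pi = ifelse(is.na(stats$pi), "NA", as.character(signif(stats$pi, 5))),
    theta_site = fmt_num(stats$theta_site, "%.3f"),
    TajimaD = paste0(fmt_num(stats$tajima_D, "%.6f"), stars)
  )
}

#' Run the full typing and diversity pipeline
#'
#' Orchestrates validation, per-marker classification, haplotype collapse,
#' regional diversity statistics and the minimum spanning networks, writing
#' all report tables to `out_dir`:
#' `classification.tsv` (per specimen and marker), `genotype_summary.tsv`
#' (two-marker genotype counts and percentages), `diversity.tsv` (formatted
#' marker x region statistics), `haplotypes_<marker>.tsv` (membership),
#' `network_<marker>_{edges,nodes}.tsv` and `network_<marker>.graphml`, and
#' `run_config.yaml` echoing the options used. Validation stops on orphan
#' sequences; specimens missing from one marker produce a warning and
#' partial outputs.
#'
#' @param samples Specimen metadata tibble (see [read_sample_table()]).
#' @param alignments Named list of `marker_alignment`s.
#' @param configs Named list of `marker_config`s (same names).
#' @param out_dir Output directory (created if needed).
#' @param policy Missing-data policy for the statistics.
#' @param exclude_heterozygotes Exclude exon-heterozygous specimens from
#'   Tpi-type statistics and haplotype tables.
#' @return Invisibly, a list with `calls`, `genotypes`, `frequencies`,
#'   `diversity`, `haplotypes`, `networks`, `validation`.
#' @export
run_pipeline <- function(samples, alignments, configs, out_dir,
                         policy = c("complete", "pairwise"),
                         exclude_heterozygotes = TRUE) {
  policy <- match.arg(policy)
  stopifnot(all(names(alignments) %in% names(configs)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  validation <- validate_dataset(samples, alignments)
  if (!dataset_ok(validation)) {
    readr::write_tsv(validation, file.path(out_dir, "validation.tsv"))
    abort(paste0(
      "orphan sequences (ids absent from metadata): ",
      paste(validation$specimen_id[validation$issue == "orphan_sequence"],
        collapse = ", "
      ),
      " -- see ", file.path(out_dir, "validation.tsv")
    ))
  }
  if (nrow(validation) > 0) {
    warn(paste0(
      nrow(validation), " specimen(s) missing from a marker alignment; ",
      "proceeding with partial data"
    ))
  }

  calls <- purrr::imap(alignments, function(aln, mk) {
    classify_marker(aln, configs[[mk]])
  })
  flat_calls <- bind_rows(purrr::map(
    calls,
    ~ select(
      .x, "specimen_id", "marker", "strain", "subgroup",
      "heterozygous", "score", "note"
    )
  ))
  readr::write_tsv(flat_calls, file.path(out_dir, "classification.tsv"))

  tpi_like <- names(configs)[purrr::map_chr(configs, "type") == "tpi"]
  vote_like <- names(configs)[purrr::map_chr(configs, "type") == "vote"]
  genotypes <- NULL
  frequencies <- NULL
  if (length(tpi_like) >= 1 && length(vote_like) >= 1) {
    genotypes <- combine_genotypes(calls[[tpi_like[1]]], calls[[vote_like[1]]])
    frequencies <- genotype_frequencies(genotypes)
    readr::write_tsv(genotypes[, c(
      "specimen_id", "tpi_strain", "tpi_subgroup",
      "coi_strain", "label", "complete"
    )], file.path(out_dir, "genotypes.tsv"))
    readr::write_tsv(frequencies, file.path(out_dir, "genotype_summary.tsv"))
  } else {
    warn("need one tpi-type and one vote-type marker for combined genotypes; skipping")
  }

  diversity <- diversity_pipeline(
    alignments, samples, configs,
    policy = policy, exclude_heterozygotes = exclude_heterozygotes
  )
  readr::write_tsv(format_table2(diversity), file.path(out_dir, "diversity.tsv"))

  haplotypes <- list()
  networks <- list()
  for (mk in names(alignments)) {
    aln <- alignments[[mk]]
    if (exclude_heterozygotes && configs[[mk]]$type == "tpi") {
      het <- calls[[mk]]$specimen_id[calls[[mk]]$heterozygous]
      aln <- new_marker_alignment(
        filter(aln, !.data$specimen_id %in% het),
        marker_name(aln), alignment_length(aln)
      )
    }
    ht <- collapse_haplotypes(aln, policy)
    haplotypes[[mk]] <- ht
    readr::write_tsv(
      haplotype_members(ht),
      file.path(out_dir, paste0("haplotypes_", mk, ".tsv"))
    )
    net <- build_msn(ht)
    net <- annotate_regions(net, ht, samples, calls = calls[[mk]])
    networks[[mk]] <- net
    write_msn_edges(net, file.path(out_dir, paste0("network_", mk, "_edges.tsv")))
    write_msn_nodes(net, file.path(out_dir, paste0("network_", mk, "_nodes.tsv")))
    write_msn_graphml(net, file.path(out_dir, paste0("network_", mk, ".graphml")))
  }

  yaml::write_yaml(
    list(
      markers = names(alignments), policy = policy,
      exclude_heterozygotes = exclude_heterozygotes,
      thresholds = purrr::map(configs, "threshold")
    ),
    file.path(out_dir, "run_config.yaml")
  )

  invisible(list(
    calls = calls, genotypes = genotypes, frequencies = frequencies,
    diversity = diversity, haplotypes = haplotypes, networks = networks,
    validation = validation
  ))
}
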
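#' Declare a haplotype structure for the synthetic generator
#'
#' A haplotype spec prescribes an alignment exactly: a random reference
#' sequence (seeded), a reference overlay pinning specific columns (e.g. the
#' diagnostic-class alleles of the base haplotype), and per-haplotype
#' mutation lists relative to that reference. Mutation bases may be `NA`,
#' meaning "any base different from the reference here" (resolved
#' deterministically as the next base in A<C<G<T cyclic order), or an IUPAC
#' ambiguity code to emulate an unphased heterozygote.
#'
#' @param marker Marker label.
#' @param length Alignment length (columns).
#' @param haplotypes Tibble with `hap_id` and `mutations` (list column of
#'   tibbles with `column`, `base`).
#' @param membership Tibble with `specimen_id`, `hap_id`; row order is the
#'   output sequence order (haplotype labels downstream follow first
#'   occurrence, so order encodes the labelling).
#' @param reference_overlay Optional tibble (`column`, `base`) applied to the
#'   reference before mutations.
#' @return A `haplotype_spec` object.
#' @export
haplotype_spec <- function(marker, length, haplotypes, membership,
                           reference_overlay = NULL) {
  haplotypes <- as_tibble(haplotypes)
  membership <- as_tibble(membership)
  stopifnot(
    all(c("hap_id", "mutations") %in% names(haplotypes)),
    all(c("specimen_id", "hap_id") %in% names(membership))
  )
  bad <- setdiff(membership$hap_id, haplotypes$hap_id)
  if (length(bad) > 0) {
    abort(paste0("membership references unknown haplotype(s): ", paste(bad, collapse = ", ")))
  }
  check_muts <- function(muts, label) {
    if (is.null(muts) || nrow(muts) == 0) {
      return(invisible())
    }
    if (any(muts$column < 1 | muts$column > length)) {
      abort(paste0(label, ": mutation column outside 1..", length))
    }
    dup <- muts |>
      group_by(.data$column) |>
      summarise(k = dplyr::n_distinct(.data$base)) |>
      filter(.data$k > 1)
    if (nrow(dup) > 0) {
      abort(paste0(
        label, ": conflicting assignments at column(s) ",
        paste(dup$column, collapse = ", ")
      ))
    }
  }
  purrr::walk2(haplotypes$mutations, haplotypes$hap_id, check_muts)
  if (!is.null(reference_overlay)) {
    check_muts(as_tibble(reference_overlay), "reference overlay")
  }
  structure(
    list(
      marker = marker, length = as.integer(length),
      haplotypes = haplotypes, membership = membership,
      reference_overlay = if (!is.null(reference_overlay)) as_tibble(reference_overlay)
    ),
    class = "haplotype_spec"
  )
}

apply_mutations <- function(chars, muts) {
  if (is.null(muts) || nrow(muts) == 0) {
    return(chars)
  }
  base <- muts$base
  auto <- is.na(base)
  if (any(auto)) {
    # deterministic alternative allele: next base in cyclic A<C<G<T order
    cur <- chars[muts$column[auto]]
    base[auto] <- .BASES[(match(cur, .BASES) %% 4) + 1]
  }
  chars[muts$column] <- base
  chars
}

#' Generate an alignment from a haplotype spec
#'
#' Deterministic for a fixed seed: the reference background is drawn
#' uniformly over A/C/G/T at unspecified columns, then the overlay and each
#' haplotype's mutations are applied exactly. After generation the realized
#' pairwise distances between haplotype sequences are checked against the
#' distances implied by the mutation lists; a mismatch is an error (it would
#' mean the spec silently assigned one column twice).
#'
#' @param spec A [haplotype_spec()].
#' @param seed Integer seed.
#' @return List with `alignment` (a `marker_alignment`, rows in membership
#'   order) and `truth` (the membership tibble).
#' @export
generate_alignment <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "haplotype_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ref <- sample(.BASES, spec$length, replace = TRUE)
  if (!is.null(spec$reference_overlay)) {
    ref <- apply_mutations(ref, spec$reference_overlay)
  }
  hap_chars <- setNames(
    purrr::map(spec$haplotypes$mutations, function(m) apply_mutations(ref, m)),
    spec$haplotypes$hap_id
  )
  # self-check: realized distances match the mutation lists
  ids <- spec$haplotypes$hap_id
  if (length(ids) >= 2) {
    eff <- purrr::map(spec$haplotypes$mutations, function(m) {
      if (is.null(m) || nrow(m) == 0) {
        integer()
      } else {
        m$column
      }
    })
    for (i in seq_along(ids)[-1]) {
      for (j in seq_len(i - 1)) {
        cols <- union(eff[[i]], eff[[j]])
        expected <- sum(hap_chars[[ids[i]]][cols] != hap_chars[[ids[j]]][cols])
        realized <- sum(hap_chars[[ids[i]]] != hap_chars[[ids[j]]])
        if (realized != expected) {
          abort(paste0(
            "spec self-check failed: realized distance ", ids[j], "-", ids[i],
            " (", realized, ") differs from mutation-implied (", expected, ")"
          ))
        }
      }
    }
  }
  seqs <- vapply(
    spec$membership$hap_id,
    function(h) paste(hap_chars[[h]], collapse = ""),
    character(1)
  )
  aln <- marker_alignment(
    tibble(specimen_id = spec$membership$specimen_id, seq = unname(seqs)),
    marker = spec$marker
  )
  list(alignment = aln, truth = spec$membership)
}

#' Generate a random dataset with known ground truth
#'
#' Draws `h` haplotypes over an alignment of `L` columns: haplotype 1 is the
#' reference; each further haplotype carries `steps` private substitutions in
#' its own block of columns, so all pairwise distances are sums of private
#' steps and every summary statistic has a closed form. Haplotype frequencies
#' are a random composition of `n` with all parts positive. The returned
#' `truth` holds the implied counts, S, mean pairwise differences, haplotype
#' diversity and per-site nucleotide diversity for parameter-recovery tests.
#'
#' @param n Number of sequences.
#' @param L Alignment length.
#' @param h Number of haplotypes (`h <= n`; `(h-1)*steps <= L`).
#' @param steps Private substitutions per non-reference haplotype.
#' @param seed Integer seed.
#' @return List with `alignment`, `membership`, and `truth` (list: `counts`,
#'   `S`, `k_bar`, `Hd`, `pi`).
#' @export
generate_random_dataset <- function(n, L, h, steps = 1L, seed = 1L) {
  if (h > n) abort("infeasible: more haplotypes than sequences (h > n)")
  if ((h - 1) * steps > L) {
    abort("infeasible: (h-1)*steps private columns exceed alignment length")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- if (h == 1) {
    n
  } else {
    cuts <- sort(sample(seq_len(n - 1), h - 1))
    diff(c(0, cuts, n))
  }
  muts <- purrr::map(seq_len(h), function(j) {
    if (j == 1) {
      tibble(column = integer(), base = character())
    } else {
      cols <- seq.int((j - 2) * steps + 1, (j - 1) * steps)
      tibble(column = cols, base = NA_character_)
    }
  })
  assign_order <- sample(rep(seq_len(h), counts))
  spec <- haplotype_spec(
    marker = "sim", length = L,
    haplotypes = tibble(hap_id = paste0("g", seq_len(h)), mutations = muts),
    membership = tibble(
      specimen_id = sprintf("s%02d", seq_len(n)),
      hap_id = paste0("g", assign_order)
    )
  )
  gen <- generate_alignment(spec, seed = seed + 1L)
  dmat <- outer(
    ifelse(seq_len(h) == 1, 0L, steps),
    ifelse(seq_len(h) == 1, 0L, steps),
    "+"
  )
  diag(dmat) <- 0L
  pairs_sum <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(h)) {
      if (i < j) pairs_sum <- pairs_sum + counts[i] * counts[j] * dmat[i, j]
    }
  }
  k_bar <- if (n >= 2) pairs_sum / choose(n, 2) else 0
  truth <- list(
    counts = as.integer(counts),
    S = if (h == 1) 0L else as.integer((h - 1) * steps),
    k_bar = k_bar,
    Hd = if (n >= 2) haplotype_diversity(counts) else NA_real_,
    pi = k_bar / L
  )
  list(alignment = gen$alignment, membership = gen$truth, truth = truth)
}

survey_tpi_spec <- function() {
  cfg <- tpi_config()
  ex <- resolve_column(cfg, c(183L, 192L, 198L)) # 43, 52, 58
  intron <- setNames(
    resolve_column(cfg, cfg$intron_het_sites, intron = TRUE),
    cfg$intron_het_sites
  )
  ica <- function(k) as.integer(k + cfg$intron_offset)
  # Ca1 canonical alleles form the reference; Ca2 differs at both subgroup
  # exon sites and all ten Ca1-vs-Ca2 intron sites.
  ca1_alleles <- c(
    `31` = "G", `38` = "A", `53` = "A", `55` = "C", `58` = "G",
    `70` = "T", `77` = "A", `87` = "A", `96` = "A", `148` = "C"
  )
  ca2_alleles <- c(
    `31` = "C", `38` = "C", `53` = "T", `55` = "T", `58` = "C",
    `70` = "C", `77` = "C", `87` = "T", `96` = "T", `148` = "T"
  ) # 148 allele: Ca2b (T); Ca2a overrides to G
  overlay <- bind_rows(
    tibble(column = ex, base = c("C", "C", "C")),
    tibble(
      column = unname(intron[names(ca1_alleles)]),
      base = unname(ca1_alleles)
    )
  )
  ca2_core <- bind_rows(
    tibble(column = ex[2:3], base = c("T", "T")),
    tibble(
      column = unname(intron[names(ca2_alleles)]),
      base = unname(ca2_alleles)
    )
  )
  with_extra <- function(core, column, base = NA_character_) {
    upd <- tibble(column = column, base = base)
    bind_rows(filter(core, !.data$column %in% upd$column), upd)
  }
  het_codes <- purrr::imap_chr(ca1_alleles, function(a, k) {
    b <- if (k == "148") cfg$subgroup_site$alleles[["Ca2a"]] else ca2_alleles[[k]]
    iupac_code(a, b)
  })
  haps <- tibble(
    hap_id = c(
      "h1", "h2", "h3", "h4", "h5", "h6",
      "h7", "h8", "h9", "h10", "h11", "h12", "het"
    ),
    mutations = list(
      ca2_core, # h1: Ca2b canonical (intron 87/96 = T,T)
      tibble(column = ica(96), base = "C"), # h2: Ca1 variant 96->C
      with_extra(ca2_core, ica(96), "C"), # h3: Ca2b, 87/96 = T,C
      with_extra(ca2_core, ica(148), "G"), # h4: Ca2a canonical
      tibble(column = integer(), base = character()), # h5: Ca1a canonical
      tibble(column = c(ica(70), ica(96)), base = c("C", "C")), # h6
      with_extra(
        with_extra(ca2_core, ica(148), "G"),
        ica(125) + 0L
      ), # h7: Ca2a + private intron variant
      with_extra(ca2_core, ica(87), "C"), # h8: Ca2b, 87/96 = C,T
      tibble(column = ica(110), base = NA_character_), # h9
      tibble(column = ica(115), base = NA_character_), # h10
      with_extra(ca2_core, ica(130)), # h11: Ca2b + private variant
      tibble(column = ica(120), base = NA_character_), # h12
      bind_rows( # Ca1/Ca2 heterozygote: Y at exon sites, S/M/W/Y introns
        tibble(column = ex[2:3], base = c("Y", "Y")),
        tibble(
          column = unname(intron[names(het_codes)]),
          base = unname(het_codes)
        )
      )
    )
  )
  membership <- tibble(
    specimen_id = c(
      "Ban-1", "Con-11", "Con-12", "Con-21", "Con-31", "Con-41", "Con-42",
      "Kor-1", "Kor-2", "Kor-3", "Kor-4", "Nep-1", "Nep-2", "Nep-3",
      "Tan-1", "Tan-2", "Tan-3", "Tan-4", "Uga-1", "Uga-2", "Uga-3",
      "Uga-4", "Vie-1", "Vie-2", "Vie-3", "Zim-1", "Zim-2"
    ),
    hap_id = c(
      "h1", "h2", "h3", "h4", "h4", "h3", "h5",
      "het", "h6", "h7", "h5", "h5", "h5", "h5",
      "h6", "h8", "h9", "h3", "h10", "h11", "h4",
      "h12", "h5", "h4", "h5", "h5", "h9"
    )
  )
  haplotype_spec(
    marker = "Tpi", length = cfg$amplicon_length,
    haplotypes = haps, membership = membership,
    reference_overlay = overlay
  )
}

survey_coi_spec <- function() {
  cfg <- coi_config()
  cols <- resolve_column(cfg, cfg$sites$position)
  overlay <- tibble(column = cols, base = cfg$sites$R)
  corn <- tibble(column = cols, base = cfg$sites$C)
  haps <- tibble(
    hap_id = c("h1", "h2", "h3"),
    mutations = list(
      tibble(column = integer(), base = character()), # h1: rice class
      bind_rows(corn, tibble(column = 300L, base = NA_character_)), # h2
      corn # h3: corn class, one step from h2
    )
  )
  h1_members <- c(
    "Ban-1", "Kor-1", "Kor-2", "Kor-3", "Kor-4", "Nep-1", "Nep-2", "Nep-3",
    "Vie-1", "Vie-2", "Con-11", "Con-12", "Con-21", "Con-31", "Con-41",
    "Con-42", "Tan-1", "Tan-2", "Tan-4", "Uga-1", "Uga-2", "Uga-3", "Uga-4",
    "Zim-1", "Zim-2"
  )
  membership <- tibble(
    specimen_id = c(h1_members, "Vie-3", "Tan-3"),
    hap_id = c(rep("h1", length(h1_members)), "h2", "h3")
  )
  haplotype_spec(
    marker = "COI", length = cfg$amplicon_length,
    haplotypes = haps, membership = membership,
    reference_overlay = overlay
  )
}

#' Synthetic two-marker invasion survey (27 specimens)
#'
#' Generates the package's reference dataset: 27 fall armyworm specimens from
#' four African and four Asian countries, typed at both markers, emulating
#' the published structure of the 2017-2020 African/Asian invasion survey.
#' The COI alignment carries three haplotypes (the rice-class haplotype with
#' 25 members; two corn-class haplotypes, one and eleven steps from it,
#' differing from the rice class exactly at the ten diagnostic positions).
#' The Tpi alignment carries twelve haplotypes across the Ca1a/Ca2a/Ca2b
#' subgroups plus one Ca1/Ca2 heterozygote (Kor-1, IUPAC codes at both
#' subgroup exon sites and all ten Ca1-vs-Ca2 intron sites). Sequence input
#' order is fixed so that haplotype labels assigned by first occurrence
#' reproduce the reference labelling (h1..h12 for Tpi, h1..h3 for COI).
#'
#' Background columns are random, so two different seeds give different
#' alignments with identical haplotype structure, classifications and
#' statistics; the same seed gives byte-identical output.
#'
#' @param seed Integer seed.
#' @return List with `samples` (metadata tibble), `alignments` (named list:
#'   `tpi`, `coi`), `configs` (named list of `marker_config`s), and `truth`
#'   (named list of membership tibbles).
#' @export
#' @examples
#' ds <- simulate_faw_survey(seed = 1)
#' genotype_frequencies(
#'   combine_genotypes(
#'     call_tpi(ds$alignments$tpi, ds$configs$tpi),
#'     call_coi(ds$alignments$coi, ds$configs$coi)
#'   )
#' )
simulate_faw_survey <- function(seed = 1L) {
  samples <- read_sample_table(
    system.file("extdata", "survey_samples.tsv",
      package = "spodotype", mustWork = TRUE
    )
  )
  tpi <- generate_alignment(survey_tpi_spec(), seed = seed)
  coi <- generate_alignment(survey_coi_spec(), seed = seed + 1L)
  list(
    samples = samples,
    alignments = list(tpi = tpi$alignment, coi = coi$alignment),
    configs = list(tpi = tpi_config(), coi = coi_config()),
    truth = list(tpi = tpi$truth, coi = coi$truth)
  )
}
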
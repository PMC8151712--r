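#' Column retention under a missing-data policy
#'
#' `"complete"` deletion (the DnaSP default) drops every alignment column in
#' which any included sequence carries a gap, an `N` or an IUPAC ambiguity
#' code; all statistics then run on the retained columns and the effective
#' length is their count. `"pairwise"` deletion keeps all columns and excludes
#' unusable positions pair by pair (effective length = mean comparable columns
#' per pair).
#'
#' @param m Character matrix (specimens x columns).
#' @return Logical vector marking retained columns.
#' @keywords internal
complete_columns <- function(m) {
  apply(m, 2, function(col) all(is_unambiguous(col)))
}

#' Number of segregating sites
#'
#' Counts alignment columns carrying two or more distinct unambiguous bases
#' among the included sequences. Under the default complete-deletion policy a
#' column containing any gap or ambiguity code in any included sequence is
#' excluded entirely before counting.
#'
#' @param aln A `marker_alignment` (or tibble with `specimen_id`, `seq`).
#' @param policy `"complete"` (default) or `"pairwise"`. Under `"pairwise"`
#'   a column segregates when its unambiguous bases (ignoring missing entries
#'   within the column) are not all equal.
#' @return Integer count of segregating sites.
#' @export
segregating_sites <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  if (nrow(aln) < 2) abort("segregating sites require at least 2 sequences")
  m <- seq_matrix(aln)
  if (policy == "complete") m <- m[, complete_columns(m), drop = FALSE]
  sum(apply(m, 2, function(col) {
    length(unique(col[is_unambiguous(col)])) >= 2
  }))
}

#' Haplotype (gene) diversity
#'
#' Nei's unbiased estimator `Hd = n/(n-1) * (1 - sum(p_i^2))`: the probability
#' that two sequences drawn without replacement carry different haplotypes.
#'
#' @param counts Positive integer vector of haplotype frequencies.
#' @return Hd in \[0, 1\]; 0 exactly when a single haplotype is present.
#' @export
#' @examples
#' haplotype_diversity(c(15, 1)) # 0.125
#' haplotype_diversity(c(6, 1, 1, 1, 1)) # 0.667 to 3 decimals
haplotype_diversity <- function(counts) {
  if (any(counts <= 0)) abort("haplotype counts must be positive")
  n <- sum(counts)
  if (n < 2) abort("haplotype diversity requires n >= 2")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Mean number of pairwise differences (k)
#'
#' Average over all unordered sequence pairs of the per-pair difference count.
#' Under complete deletion all pairs are compared on the same retained
#' columns; under pairwise deletion each pair is compared on its own
#' comparable columns.
#'
#' @inheritParams segregating_sites
#' @return Mean pairwise differences (absolute, not per site).
#' @export
mean_pairwise_differences <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  if (nrow(aln) < 2) abort("pairwise differences require at least 2 sequences")
  m <- seq_matrix(aln)
  if (policy == "complete") m <- m[, complete_columns(m), drop = FALSE]
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- is_unambiguous(m[i, ]) & is_unambiguous(m[j, ])
      tot <- tot + sum(m[i, ok] != m[j, ok])
    }
  }
  tot / choose(n, 2)
}

#' Nucleotide diversity per site
#'
#' @param k_bar Mean pairwise differences (absolute).
#' @param l_effective Number of analysed columns.
#' @return `k_bar / l_effective`.
#' @export
nucleotide_diversity <- function(k_bar, l_effective) {
  if (l_effective <= 0) abort("effective length must be positive")
  k_bar / l_effective
}

#' Watterson's theta per site
#'
#' `S / (a1 * L)` with `a1` the (n-1)-th harmonic number.
#'
#' @param S Segregating sites.
#' @param n Number of sequences.
#' @param l_effective Number of analysed columns.
#' @return Theta per site.
#' @export
watterson_theta <- function(S, n, l_effective) {
  if (n < 2) abort("Watterson's theta requires n >= 2")
  if (l_effective <= 0) abort("effective length must be positive")
  a1 <- sum(1 / seq_len(n - 1))
  S / (a1 * l_effective)
}

#' Tajima's constants a1..e2
#'
#' The full constant set of the neutrality test, recomputed from the sample
#' size alone and retained in results for audit.
#'
#' @param n Number of sequences (>= 2).
#' @return Named list `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 2) abort("Tajima constants require n >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(
    a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
    e1 = c1 / a1, e2 = c2 / (a1^2 + a2)
  )
}

#' Tajima's D neutrality statistic
#'
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))`: the normalised difference
#' between the pairwise-difference and segregating-sites estimates of the
#' population mutation parameter. Negative values indicate an excess of rare
#' variants, as after a recent population expansion. Significance is judged
#' against the beta-distribution approximation of the null (see
#' [tajima_significance()]), the same approximation DnaSP stars its output
#' with.
#'
#' @param n Number of sequences (>= 4 for the test to be meaningful).
#' @param S Segregating sites.
#' @param k_bar Mean pairwise differences (absolute).
#' @return A `tajima_d` object: `D`, two-tailed `p_value`, `band`
#'   (`"ns"`, `"p<0.05"`, `"p<0.01"`), inputs, and the constants
#'   `a1..e2`. `D` is `NA` when `S = 0` (statistic undefined).
#' @export
#' @examples
#' tajimas_d(n = 16, S = 10, k_bar = 1.25)
tajimas_d <- function(n, S, k_bar) {
  if (n < 2) abort("Tajima's D requires n >= 2")
  const <- tajima_constants(n)
  if (S == 0) {
    out <- list(
      D = NA_real_, p_value = NA_real_, band = NA_character_,
      n = n, S = S, k_bar = k_bar, constants = const
    )
    class(out) <- "tajima_d"
    return(out)
  }
  D <- (k_bar - S / const$a1) / sqrt(const$e1 * S + const$e2 * S * (S - 1))
  sig <- tajima_significance(D, n)
  out <- list(
    D = D, p_value = sig$p_value, band = sig$band,
    n = n, S = S, k_bar = k_bar, constants = const
  )
  class(out) <- "tajima_d"
  out
}

#' Significance band for Tajima's D
#'
#' Uses the beta-distribution approximation of the null distribution of D:
#' D is assumed beta-distributed on its attainable range
#' `[Dmin, Dmax] = [(2/n - 1/a1), ((n+1)/(2n) - 1/a1)] / sqrt(e2)` with mean 0
#' and variance 1, and a two-tailed p-value is read from that distribution.
#'
#' @param D Tajima's D value.
#' @param n Number of sequences used to compute it.
#' @return List with `p_value` (two-tailed) and `band` in
#'   `{"ns", "p<0.05", "p<0.01"}`.
#' @export
tajima_significance <- function(D, n) {
  if (is.na(D)) {
    return(list(p_value = NA_real_, band = NA_character_))
  }
  const <- tajima_constants(n)
  dmin <- (2 / n - 1 / const$a1) / sqrt(const$e2)
  dmax <- ((n + 1) / (2 * n) - 1 / const$a1) / sqrt(const$e2)
  alpha <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
  beta <- (1 + dmin * dmax) * dmin / (dmax - dmin)
  u <- (D - dmin) / (dmax - dmin)
  u <- min(max(u, 0), 1)
  p <- 2 * min(pbeta(u, beta, alpha), 1 - pbeta(u, beta, alpha))
  band <- if (p < 0.01) "p<0.01" else if (p < 0.05) "p<0.05" else "ns"
  list(p_value = p, band = band)
}

#' @export
print.tajima_d <- function(x, ...) {
  cat("Tajima's D: ",
    if (is.na(x$D)) "NA (S = 0)" else sprintf("%.6f", x$D),
    "  (n = ", x$n, ", S = ", x$S,
    ", k = ", format(x$k_bar), ")\n",
    sep = ""
  )
  if (!is.na(x$D)) {
    cat("two-tailed p (beta approximation): ", sprintf("%.4f", x$p_value),
      "  [", x$band, "]\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @method tidy tajima_d
#' @export
tidy.tajima_d <- function(x, ...) {
  tibble(
    n = x$n, S = x$S, k_bar = x$k_bar,
    D = x$D, p_value = x$p_value, band = x$band
  )
}

#' @method glance tajima_d
#' @export
glance.tajima_d <- function(x, ...) {
  as_tibble(x$constants)
}

#' Diversity statistics for one alignment subset
#'
#' Computes the full DnaSP-style summary for a set of aligned sequences:
#' sample size, segregating sites, haplotype count, haplotype diversity,
#' mean pairwise differences, nucleotide diversity per site, Watterson's
#' theta per site, and Tajima's D with its significance band. Under the
#' default complete-deletion policy the effective length is the number of
#' columns free of gaps and ambiguity codes across the subset.
#'
#' @inheritParams segregating_sites
#' @return A `diversity_stats` object; see [tidy.diversity_stats()] for the
#'   one-row tibble form.
#' @export
diversity_stats <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  if (nrow(aln) < 2) abort("diversity statistics require at least 2 sequences")
  m <- seq_matrix(aln)
  l_eff <- if (policy == "complete") {
    sum(complete_columns(m))
  } else {
    # mean comparable columns over pairs
    n <- nrow(m)
    tot <- 0
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        tot <- tot + sum(is_unambiguous(m[i, ]) & is_unambiguous(m[j, ]))
      }
    }
    tot / choose(n, 2)
  }
  if (l_eff == 0) abort("no analysable columns under the missing-data policy")
  n <- nrow(aln)
  S <- segregating_sites(aln, policy)
  haps <- collapse_haplotypes(aln, policy)
  k_bar <- mean_pairwise_differences(aln, policy)
  taj <- tajimas_d(n, S, k_bar)
  out <- list(
    n = n, S = S, h = nrow(haps),
    Hd = haplotype_diversity(haps$size),
    k_bar = k_bar,
    pi = nucleotide_diversity(k_bar, l_eff),
    theta_site = if (S == 0) 0 else watterson_theta(S, n, l_eff),
    tajima = taj,
    l_effective = l_eff, policy = policy,
    marker = marker_name(aln)
  )
  class(out) <- "diversity_stats"
  out
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("<diversity_stats>",
    if (!is.null(x$marker)) paste0(" ", x$marker), "\n",
    sep = ""
  )
  cat(
    " n =", x$n, " S =", x$S, " h =", x$h,
    " Hd =", sprintf("%.3f", x$Hd), "\n"
  )
  cat(
    " k =", format(x$k_bar), " pi =", signif(x$pi, 5),
    " theta/site =", signif(x$theta_site, 5), "\n"
  )
  cat(
    " Tajima's D =",
    if (is.na(x$tajima$D)) "NA" else sprintf("%.6f", x$tajima$D),
    if (!is.na(x$tajima$D)) paste0("[", x$tajima$band, "]"), "\n"
  )
  invisible(x)
}

#' Tidy a diversity_stats object
#'
#' @param x A `diversity_stats` object.
#' @param ... Unused.
#' @return One-row tibble with columns `n, S, h, Hd, k_bar, pi, theta_site,
#'   tajima_D, tajima_p, significance, l_effective`.
#' @method tidy diversity_stats
#' @export
tidy.diversity_stats <- function(x, ...) {
  tibble(
    n = x$n, S = x$S, h = x$h, Hd = x$Hd, k_bar = x$k_bar,
    pi = x$pi, theta_site = x$theta_site,
    tajima_D = x$tajima$D, tajima_p = x$tajima$p_value,
    significance = x$tajima$band, l_effective = x$l_effective
  )
}

#' @method glance diversity_stats
#' @export
glance.diversity_stats <- function(x, ...) {
  as_tibble(x$tajima$constants)
}

#' Region-partitioned diversity statistics for the survey markers
#'
#' Applies the exclusion rules, partitions each marker's alignment by
#' continental region, and computes [diversity_stats()] per marker x region.
#' For a Tpi-type marker every specimen whose call is heterozygous at a
#' diagnostic exon site is excluded from that marker's statistics (the
#' Z-linked marker cannot be phased from Sanger traces, and a Ca1/Ca2
#' heterozygote would double-count both subgroup alleles); exclusions are
#' logged in the `exclusions` attribute. Regions with fewer than two usable
#' sequences are reported as NA rows.
#'
#' @param alignments Named list of `marker_alignment`s.
#' @param samples Specimen metadata tibble (with `region`).
#' @param configs Named list of `marker_config`s matching `alignments`.
#' @param policy Missing-data policy, `"complete"` or `"pairwise"`.
#' @param exclude_heterozygotes Drop exon-heterozygous specimens from
#'   Tpi-type markers (default TRUE).
#' @return A tibble with one row per marker x region (`marker`, `region`,
#'   `n`, `S`, `h`, `Hd`, `k_bar`, `pi`, `theta_site`, `tajima_D`,
#'   `tajima_p`, `significance`, `l_effective`), with an `exclusions`
#'   attribute tibble (`specimen_id`, `marker`, `reason`).
#' @export
diversity_pipeline <- function(alignments, samples, configs,
                               policy = c("complete", "pairwise"),
                               exclude_heterozygotes = TRUE) {
  policy <- match.arg(policy)
  stopifnot(all(names(alignments) %in% names(configs)))
  exclusions <- tibble(
    specimen_id = character(), marker = character(), reason = character()
  )
  na_row <- function(marker, region, n) {
    tibble(
      marker = marker, region = region, n = n,
      S = NA_integer_, h = NA_integer_, Hd = NA_real_, k_bar = NA_real_,
      pi = NA_real_, theta_site = NA_real_, tajima_D = NA_real_,
      tajima_p = NA_real_, significance = NA_character_,
      l_effective = NA_real_
    )
  }
  rows <- purrr::imap(alignments, function(aln, mk) {
    cfg <- configs[[mk]]
    mk_label <- cfg$marker %||% mk
    keep <- aln
    if (exclude_heterozygotes && cfg$type == "tpi") {
      calls <- call_tpi(aln, cfg)
      het_ids <- calls$specimen_id[calls$heterozygous]
      if (length(het_ids) > 0) {
        exclusions <<- bind_rows(exclusions, tibble(
          specimen_id = het_ids, marker = mk_label,
          reason = "heterozygous at diagnostic exon site"
        ))
        keep <- filter(aln, !.data$specimen_id %in% het_ids)
        keep <- new_marker_alignment(keep, marker_name(aln), alignment_length(aln))
      }
    }
    region_of_id <- setNames(samples$region, samples$specimen_id)
    purrr::map(c("Africa", "Asia"), function(rg) {
      ids <- keep$specimen_id[region_of_id[keep$specimen_id] == rg]
      sub <- filter(keep, .data$specimen_id %in% ids)
      if (nrow(sub) < 2) {
        return(na_row(mk_label, rg, nrow(sub)))
      }
      sub <- new_marker_alignment(sub, marker_name(aln), alignment_length(aln))
      st <- tidy(diversity_stats(sub, policy))
      dplyr::bind_cols(tibble(marker = mk_label, region = rg), st)
    }) |> bind_rows()
  })
  out <- bind_rows(rows)
  attr(out, "exclusions") <- exclusions
  attr(out, "policy") <- policy
  out
}
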
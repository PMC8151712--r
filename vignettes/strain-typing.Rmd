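---
title: "Strain typing and population genetics of invasive fall armyworm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain typing and population genetics of invasive fall armyworm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spodotype)
```

## The problem

The fall armyworm (*Spodoptera frugiperda*) exists as two host-plant strains
— the corn strain (C) and the rice strain (R) — that are morphologically
indistinguishable and must be told apart molecularly. Since the species
invaded Africa (2016) and then Asia, surveillance programmes genotype field
specimens at two diagnostic markers:

* **COI** — the mitochondrial cytochrome oxidase subunit I barcode,
  maternally inherited, with ten nucleotide positions separating the corn
  and rice mitochondrial lineages;
* **Tpi** — the nuclear, Z-chromosome-linked triosephosphate isomerase gene.
  A single exon position (gTpi183: C in the corn strain, T in the rice
  strain) carries the strain diagnosis, and further exon and intron
  polymorphisms resolve corn-strain subgroups.

Because the two markers have different inheritance, their combination is
informative about hybrid ancestry: a specimen typing Tpi-C/COI-R descends
from a corn-strain male and a rice-strain female. Invasive African/Asian
populations are dominated by exactly this hybrid class, with a minority of
homogeneous Tpi-C/COI-C individuals — so the nuclear marker, not the
mitochondrial one, tracks the observed host preference (all specimens in
such surveys come from maize).

`spodotype` implements this analysis end to end: diagnostic-SNP
classification, haplotype collapse, regional diversity statistics, and a
minimum spanning haplotype network, together with a synthetic-data generator
that reproduces the structure of a published 27-specimen, eight-country
survey so that the full pipeline is testable without any sequence download.

## Diagnostic classification

### Coordinates

Diagnostic positions are quoted in the field as base numbers from the
predicted translational start site (gTpi183, mCOI72, ...), while alignments
store amplicon columns. Every `marker_config` therefore carries a signed
offset (`column = position + offset`). The shipped COI configuration uses
offset −38: the 658 bp barcode amplicon spans gene positions 39–696. For
Tpi, the 444 bp amplicon contains 166 bp of the fourth exon followed by
278 bp of the fourth intron; exon positions use offset −140 (placing
gTpi183 at column 43) and intron positions are numbered within the intron
(offset +166). The exon anchor is a packaging convention — the published
description fixes only the exon/intron split, not the amplicon's position
in the gene — and the offset mechanism absorbs any alternative numbering.

### Tpi rules

`call_tpi()` applies, per specimen:

1. **Strain** — gTpi183: C → corn strain, T → rice strain, Y → C/R
   heterozygote, anything else undetermined.
2. **Subgroup family** — (gTpi192, gTpi198): (C,C) → Ca1, (T,T) → Ca2,
   (Y,Y) → Ca1/Ca2 heterozygote. Inconsistent pairs such as (C,T) are
   reported undetermined with a diagnostic note rather than guessed.
3. **Within Ca2** — intron position 148 splits Ca2a from Ca2b. Ca1 is
   reported as Ca1a, the only Ca1 subtype observed in the invasive range;
   within-subgroup intron variants (positions 70, 87, 96) differentiate
   haplotypes but not subgroups.
4. **Heterozygosity** — the flag is set exactly when a diagnostic exon site
   carries an IUPAC ambiguity code. Because Tpi is Z-linked, only males can
   be heterozygous, and a Ca1/Ca2 male is expected to show two-base codes
   (S/M/W/Y) at all ten Ca1-vs-Ca2 intron sites; `call_tpi()` checks this
   expectation and reports departures as a consistency note, never as an
   assignment criterion.

### COI rule

The ten mitochondrial diagnostic positions are scored by majority vote
against each class's expected-allele vector; sites whose observed base is
not an unambiguous nucleotide are excluded from both numerator and
denominator. The winning class needs a match fraction of at least 0.8
(default), which tolerates a couple of sequencing Ns across ten sites while
still rejecting genuinely conflicted sequences; ties and sub-threshold
scores are undetermined. The published source for the per-class alleles is
a figure, not machine-readable text, so the shipped allele vectors are the
synthetic generator's convention and are documented as such — for real
data they should be replaced via `read_marker_config()` with empirically
calibrated values. The rule engine itself is indifferent to the choice.

## Diversity statistics

All statistics are computed from first principles on the analysed subset,
matching the conventions of the DnaSP summary that field studies report:

* **Segregating sites** `S`: columns with ≥ 2 distinct unambiguous bases.
* **Haplotype diversity** `Hd = n/(n−1) (1 − Σ p_i²)` (Nei's unbiased
  estimator).
* **Mean pairwise differences** `k`: brute-force average over all unordered
  pairs — at survey scale (tens of sequences, hundreds of columns) this is
  instantaneous and trivially auditable; the test suite checks it against
  an independent column-frequency formulation and against `ape`'s raw
  distance counts.
* **Nucleotide diversity** `π = k / L_eff` and **Watterson's theta**
  `θ_w = S / (a1 · L_eff)` per site.
* **Tajima's D** `D = (k − S/a1) / sqrt(e1·S + e2·S(S−1))` with the full
  constant set (a1, a2, b1, b2, c1, c2, e1, e2) recomputed from `n` and
  retained in the result for audit (`glance()` on a `tajima_d` object).
  `S = 0` leaves D undefined (reported NA). Significance uses the
  beta-distribution approximation of the null: D is taken to be
  beta-distributed on its attainable range
  `[Dmin, Dmax] = [(2/n − 1/a1), ((n+1)/(2n) − 1/a1)]/√e2` with mean 0 and
  variance 1, and a two-tailed p-value is banded as ns / p<0.05 / p<0.01 —
  the same approximation behind the stars in DnaSP output. A
  coalescent-simulation p-value is deliberately out of scope.

### Missing data

The default policy is **complete deletion**: any column containing a gap,
`N` or ambiguity code in any sequence of the analysed subset is dropped
entirely, and `L_eff` is the count of retained columns. This is what DnaSP
does by default and is the only policy under which "identical on retained
columns" is transitive, making haplotype collapse well defined. A
**pairwise deletion** alternative is provided for completeness (each pair
compared on its own usable columns, `L_eff` = mean comparable columns);
with it, haplotype collapse falls back to exact full-sequence matching.

### Exclusion rule

For Tpi-type markers, `diversity_pipeline()` excludes every specimen whose
call is heterozygous at a diagnostic exon site, and logs the exclusion.
An unphased Z-linked heterozygote superimposes two subgroup alleles in one
trace: keeping it would either wipe the diagnostic columns under complete
deletion or fabricate an artificial "haplotype" that exists in no
chromosome. In the reference survey this removes exactly one specimen
(the Ca1/Ca2 male from Jeju), giving Tpi subsets of 16 (Africa) and 10
(Asia) versus COI subsets of 16 and 11.

### A note on internal consistency

One published Tpi row (Asia: n = 10, S = 14, π = 0.011671, D = 1.11681) is
not internally consistent under the standard formulas: D recomputed from
those same summary inputs is ≈ 0.216. The likely cause is an undocumented
effective-length or site-filtering difference inside the original DnaSP
run. `spodotype` always reports the value implied by its own inputs and
makes every intermediate (k, S, L_eff, constants) available so such
discrepancies are visible rather than absorbed.

## Haplotype network

`collapse_haplotypes()` groups sequences identical on retained columns,
labelling haplotypes h1, h2, ... by first occurrence in the input (a fixed
input order therefore fixes the labels). `build_msn()` computes a minimum
spanning tree over the haplotype Hamming distances (Kruskal, deterministic
tie-break by haplotype order) and keeps every non-tree edge that could
replace a tree edge of equal weight as a flagged *alternative* edge, so
tied topologies are visible as a network rather than silently resolved.
This replaces the statistical-parsimony construction of TCS: at survey
scale (≤ 12 haplotypes, ≤ 11 steps between them, far below any plausible
parsimony connection limit) the two constructions give the same topology,
and the 95% connection-limit machinery is out of scope. The brute-force
spanning-tree enumeration in the test suite confirms minimality on small
instances, and `igraph`'s MST serves as an independent cross-check.

`annotate_regions()` adds per-node Africa/Asia membership counts and
(optionally) strain labels, and reports haplotypes shared between the two
continents — the survey's key qualitative observation, since shared
haplotypes across Africa and Asia indicate spread without significant
genetic change. `autoplot()` renders the network with node area
proportional to haplotype frequency.

## The synthetic survey

`simulate_faw_survey()` generates the package's reference dataset: 27
specimens from eight countries (metadata shipped as a plain-text table,
mirroring the published collection details), each with a 444 bp Tpi and a
658 bp COI sequence. The construction prescribes haplotypes exactly:

* **COI** — a rice-class base haplotype (25 specimens); a corn-class
  haplotype differing at exactly the ten diagnostic positions (one
  Tanzanian specimen, 10 steps); and a second corn-class haplotype one
  further non-diagnostic step away (one Vietnamese specimen, 11 steps from
  the rice haplotype). These distances are forced by the published percent
  identities (98.48%, 98.33%, 99.85% over 658 bp).
* **Tpi** — twelve haplotypes honouring the published membership table and
  subgroup structure: Ca1 and Ca2 differ at gTpi192/198 plus the ten intron
  sites; intron 148 splits Ca2a (two haplotypes) from Ca2b (four);
  within-subgroup variants sit at intron 70/96 (Ca1) and 87/96 (Ca2b,
  showing the three published combinations T/T, T/C, C/T); haplotypes not
  distinguished by any named site get a private variant at an unnamed
  intron column. One membership entry ("Con-14") does not exist in the
  collection table and is read as Con-41, the only specimen id consistent
  with both tables. The 27th specimen (Kor-1) is the Ca1/Ca2 heterozygote:
  Y/Y at the subgroup exon sites and the correct two-base IUPAC code at
  every Ca1-vs-Ca2 intron site (S, M, W and Y all occur).
* Background columns are drawn uniformly from A/C/G/T under the supplied
  seed; the same seed reproduces the FASTA byte for byte, and every seed
  satisfies the prescribed structure. After generation the realized
  haplotype distances are checked against the mutation lists (a violated
  check is an error, not a warning).
* Input order is fixed so that first-occurrence labelling reproduces the
  reference haplotype names (alphabetical specimen order does this for
  Tpi; for COI the two corn-strain specimens are placed last, Vietnamese
  before Tanzanian).

What the generator does **not** emulate: sequencing noise, indels, within-
haplotype polymorphism, transition/transversion bias, or a coalescent
genealogy — distances between haplotypes are exact sums of prescribed
steps. Tests passing on this fixture therefore demonstrate the correctness
of the classification rules, estimators and network construction on clean
alignments, not robustness to alignment error or base-calling noise. The
published Tpi segregating-site counts (18 Africa / 14 Asia) depend on the
full inter-haplotype distance matrix, which is published only as a figure;
the fixture realizes a consistent but not identical matrix (16 / 13), so
Tpi π, θ and D from raw fixture sequences are fixture properties, while
all COI statistics and all haplotype-count/membership quantities reproduce
the published values exactly.

`generate_random_dataset()` complements the fixed survey with randomized
instances (n, L, haplotype count, steps) whose Hd, k, S and π are known in
closed form by construction, which the test suite uses for exact
parameter-recovery checks.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_faw_survey(seed = 1)

# strain typing and the hybrid fraction
geno <- combine_genotypes(
  call_tpi(ds$alignments$tpi, ds$configs$tpi),
  call_coi(ds$alignments$coi, ds$configs$coi)
)
genotype_frequencies(geno)
#> Tpi-C/COI-R  25  92.6
#> Tpi-C/COI-C   2   7.4

# regional diversity, DnaSP-style
div <- diversity_pipeline(ds$alignments, ds$samples, ds$configs)
format_table2(div)

# COI haplotype network
ht <- collapse_haplotypes(ds$alignments$coi)
msn <- annotate_regions(build_msn(ht), ht, ds$samples)
autoplot(msn)
```

## Numerical and design choices

* Report formatting (`format_table2()`) mirrors the field's mixed
  precision — Hd to 3 decimals, θ/site to 3, D to 6 with significance
  stars, π to 5 significant figures — while every internal value stays
  full precision; ASCII minus throughout.
* Tie-breaks are deterministic everywhere: Kruskal edge order by (weight,
  haplotype order), haplotype labels by first occurrence, vote ties are
  undetermined rather than arbitrarily resolved.
* The vote threshold (0.8), the complete-deletion default and the
  heterozygote exclusion are all exposed as arguments so a user can study
  their effect; the defaults are the analysis actually performed.
* Degenerate inputs fail loudly: ragged alignments, alphabet violations,
  duplicate ids, unknown countries, conflicting generator specs and
  sub-2-sequence subsets all raise errors (or NA rows, for empty regions)
  rather than returning silently wrong numbers.
* Problem sizes in tests and checks are those of the survey itself
  (27 × 658 and 27 × 444 alignments, networks of ≤ 12 nodes) plus small
  randomized instances (n ≤ 20, L ≤ 100) for the property and oracle
  tests; everything runs in seconds.

## Limitations

* The package types specimens against configured diagnostic alleles; it
  does not discover new diagnostic sites, align sequences, or fetch
  accessions.
* The shipped COI allele vectors are a synthetic convention (see above),
  to be replaced for real-data use.
* No Tpi rice-strain subgroup taxonomy is implemented (none was observed
  in the invasive range the package models).
* The network is a minimum spanning network, not statistical parsimony or
  median-joining: no inferred intermediate haplotypes are added.
* Tajima significance bands come from the beta approximation, not
  coalescent simulation; treat p-values near the band edges accordingly.
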
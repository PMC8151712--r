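test_that("haplotype diversity matches closed forms and edge cases", {
  expect_equal(haplotype_diversity(c(15, 1)), 0.125)
  expect_equal(round(haplotype_diversity(c(6, 1, 1, 1, 1)), 3), 0.667)
  expect_equal(haplotype_diversity(c(10, 1)), 2 / 11)
  expect_equal(haplotype_diversity(20), 0)
  expect_error(haplotype_diversity(1), "n >= 2")
  expect_error(haplotype_diversity(c(3, 0)), "positive")
})

test_that("haplotype diversity is permutation-invariant and increases when a singleton splits off", {
  set.seed(7)
  for (rep in 1:20) {
    counts <- sample(1:8, sample(2:6, 1), replace = TRUE)
    expect_equal(
      haplotype_diversity(counts),
      haplotype_diversity(sample(counts))
    )
    big <- which(counts >= 2)[1]
    if (!is.na(big)) {
      split <- c(counts, 1)
      split[big] <- split[big] - 1
      expect_gt(haplotype_diversity(split), haplotype_diversity(counts))
    }
  }
})

test_that("mean pairwise differences match enumeration on prescribed mixtures", {
  base <- strrep("G", 658)
  # 15 copies + 1 copy at 10 differences: 15*10 / C(16,2) = 1.25
  seqs <- c(
    setNames(rep(base, 15), paste0("a", 1:15)),
    b = mutate_at(base, 1:10)
  )
  aln <- tiny_alignment(seqs)
  expect_equal(mean_pairwise_differences(aln), 1.25)
  expect_equal(mean_pairwise_differences(aln), oracle_kbar_colwise(aln))
  # 10 copies + 1 copy at 11 differences: 110 / C(11,2) = 2.0
  seqs2 <- c(
    setNames(rep(base, 10), paste0("a", 1:10)),
    b = mutate_at(base, 1:11)
  )
  aln2 <- tiny_alignment(seqs2)
  expect_equal(mean_pairwise_differences(aln2), 2.0)
  expect_equal(mean_pairwise_differences(aln2), oracle_kbar_colwise(aln2))
  expect_equal(mean_pairwise_differences(tiny_alignment(c(a = "ACGT", b = "ACGT"))), 0)
})

test_that("pair enumeration equals the column-frequency oracle on random alignments", {
  for (seed in 1:6) {
    aln <- random_alignment(n = sample(3:12, 1), L = sample(20:100, 1), seed = seed)
    expect_equal(mean_pairwise_differences(aln), oracle_kbar_colwise(aln))
  }
  # and with gap/ambiguity columns dropped by complete deletion
  aln <- random_alignment(8, 60, seed = 42)
  aln$seq[1] <- mutate_at(aln$seq[1], 5, "-")
  aln$seq[2] <- mutate_at(aln$seq[2], 12, "Y")
  expect_equal(mean_pairwise_differences(aln), oracle_kbar_colwise(aln))
})

test_that("pairwise differences agree with ape's raw distance counts", {
  skip_if_not_installed("ape")
  aln <- random_alignment(10, 80, seed = 11)
  mat <- do.call(rbind, strsplit(tolower(aln$seq), ""))
  rownames(mat) <- aln$specimen_id
  d <- ape::dist.dna(ape::as.DNAbin(mat), model = "N")
  expect_equal(mean_pairwise_differences(aln), mean(d))
})

test_that("segregating sites follow complete deletion", {
  aln <- tiny_alignment(c(a = "AAG-T", b = "AAGCT", c = "ACGCT"))
  # column 4 has a gap -> dropped; column 2 segregates
  expect_equal(segregating_sites(aln), 1L)
  expect_equal(segregating_sites(tiny_alignment(c(a = "ACGT", b = "ACGT"))), 0L)
  expect_error(segregating_sites(tiny_alignment(c(a = "ACGT"))), "at least 2")
})

test_that("for two sequences Watterson's theta equals pi", {
  for (seed in 1:5) {
    aln <- random_alignment(2, 50, seed = seed + 100)
    S <- segregating_sites(aln)
    k <- mean_pairwise_differences(aln)
    expect_equal(S, k) # a1 = 1 and every difference is one segregating site
    expect_equal(
      watterson_theta(S, 2, 50),
      nucleotide_diversity(k, 50)
    )
  }
})

test_that("Watterson's theta reproduces the survey report values", {
  expect_equal(round(watterson_theta(18, 16, 444), 3), 0.012)
  expect_equal(round(watterson_theta(14, 10, 444), 3), 0.011)
  expect_equal(watterson_theta(0, 10, 444), 0)
})

test_that("Tajima's D and constants match the published COI and Tpi values", {
  # constants rebuilt from n alone
  const <- tajima_constants(16)
  expect_equal(const$a1, sum(1 / 1:15))
  expect_equal(const$a2, sum(1 / (1:15)^2))

  d_af <- tajimas_d(n = 16, S = 10, k_bar = 1.25)
  expect_equal(d_af$D, -2.182611, tolerance = 5e-4)
  expect_equal(d_af$band, "p<0.01")

  d_as <- tajimas_d(n = 11, S = 11, k_bar = 2.0)
  expect_equal(d_as$D, -2.011459, tolerance = 5e-5)
  expect_equal(d_as$band, "p<0.05")

  d_tpi <- tajimas_d(n = 16, S = 18, k_bar = 0.016911 * 444)
  expect_equal(d_tpi$D, 1.531362, tolerance = 1e-3)
  expect_equal(d_tpi$band, "ns")

  # numerator vanishes when k equals S/a1
  expect_equal(tajimas_d(n = 8, S = 5, k_bar = 5 / sum(1 / 1:7))$D, 0)
  expect_equal(tajima_significance(0, 16)$band, "ns")
  # undefined without segregating sites
  expect_true(is.na(tajimas_d(n = 8, S = 0, k_bar = 0)$D))
})

test_that("tajima_d tidiers expose the estimate and audit constants", {
  fit <- tajimas_d(n = 16, S = 10, k_bar = 1.25)
  td <- tidy(fit)
  expect_equal(td$D, fit$D)
  expect_equal(td$band, "p<0.01")
  gl <- glance(fit)
  expect_named(gl, c("a1", "a2", "b1", "b2", "c1", "c2", "e1", "e2"))
  expect_equal(gl$e1, fit$constants$e1)
})

test_that("diversity_stats integrates the estimators coherently", {
  base <- strrep("T", 100)
  aln <- tiny_alignment(c(
    a1 = base, a2 = base, a3 = base,
    b1 = mutate_at(base, 1:2), c1 = mutate_at(base, 3)
  ))
  st <- diversity_stats(aln)
  expect_equal(st$n, 5L)
  expect_equal(st$h, 3L)
  expect_equal(st$S, 3L)
  expect_equal(st$Hd, haplotype_diversity(c(3, 1, 1)))
  expect_equal(st$pi, st$k_bar / 100)
  td <- tidy(st)
  expect_equal(td$tajima_D, st$tajima$D)
  expect_equal(td$l_effective, 100)
})

test_that("parameter recovery: pipeline statistics equal generator ground truth", {
  for (seed in c(7, 21)) {
    ds <- generate_random_dataset(n = 20, L = 100, h = 4, steps = 2, seed = seed)
    st <- diversity_stats(ds$alignment)
    expect_equal(st$h, 4L)
    expect_equal(sort(collapse_haplotypes(ds$alignment)$size), sort(ds$truth$counts))
    expect_equal(st$S, ds$truth$S)
    expect_equal(st$k_bar, ds$truth$k_bar)
    expect_equal(st$Hd, ds$truth$Hd)
    expect_equal(st$pi, ds$truth$pi)
  }
})

test_that("regional pipeline applies the heterozygote exclusion and partitions by continent", {
  ds <- survey()
  div <- diversity_pipeline(ds$alignments, ds$samples, ds$configs)
  expect_equal(div$marker, c("Tpi", "Tpi", "COI", "COI"))
  expect_equal(div$region, rep(c("Africa", "Asia"), 2))
  expect_equal(div$n, c(16L, 10L, 16L, 11L))
  excl <- attr(div, "exclusions")
  expect_equal(excl$specimen_id, "Kor-1")
  expect_equal(excl$marker, "Tpi")
  # the excluded heterozygote leaves no ambiguity: full amplicon analysed
  expect_equal(div$l_effective, c(444, 444, 658, 658))
})

test_that("regions with fewer than two sequences give NA rows", {
  ds <- survey()
  african <- ds$samples[ds$samples$region == "Africa" | ds$samples$specimen_id == "Ban-1", ]
  alns <- list(coi = ds$alignments$coi[
    ds$alignments$coi$specimen_id %in% african$specimen_id,
  ])
  alns$coi <- marker_alignment(alns$coi, "COI")
  div <- diversity_pipeline(alns, african, list(coi = ds$configs$coi))
  asia <- div[div$region == "Asia", ]
  expect_equal(asia$n, 1L)
  expect_true(is.na(asia$Hd))
  expect_true(is.na(asia$tajima_D))
})
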
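test_that("gTpi183 determines the Tpi strain call", {
  ds <- survey()
  cfg <- ds$configs$tpi
  base <- ds$alignments$tpi$seq[1]
  col183 <- 183 - 140 # offset maps gene position to alignment column
  seq_c <- mutate_at(base, col183, "C")
  seq_t <- mutate_at(base, col183, "T")
  seq_y <- mutate_at(base, col183, "Y")
  seq_n <- mutate_at(base, col183, "N")
  expect_equal(
    call_tpi_strain(c(seq_c, seq_t, seq_y, seq_n), cfg),
    c("C", "R", "C/R heterozygous", "undetermined")
  )
})

test_that("Tpi subgroups resolve from exon 192/198 and intron 148", {
  ds <- survey()
  calls <- call_tpi(ds$alignments$tpi, ds$configs$tpi)
  by_id <- setNames(calls$subgroup, calls$specimen_id)
  # Ca1a in both continents; Ca2a and Ca2b split by intron 148
  expect_equal(unname(by_id[c("Con-11", "Con-42", "Nep-1", "Kor-2")]), rep("Ca1a", 4))
  expect_equal(unname(by_id[c("Con-21", "Vie-2", "Kor-3")]), rep("Ca2a", 3))
  expect_equal(unname(by_id[c("Ban-1", "Con-12", "Tan-2", "Uga-2")]), rep("Ca2b", 4))
  expect_equal(unname(by_id[["Kor-1"]]), "Ca1/Ca2")
  expect_true(all(calls$strain == "C"))
  expect_equal(calls$specimen_id[calls$heterozygous], "Kor-1")
})

test_that("inconsistent or unresolvable subgroup genotypes are flagged", {
  ds <- survey()
  cfg <- ds$configs$tpi
  base <- ds$alignments$tpi$seq[ds$alignments$tpi$specimen_id == "Con-42"]
  # (C,T) at 192/198 matches no subgroup family
  odd <- tiny_alignment(c(x = mutate_at(base, 198 - 140, "T")), "Tpi")
  call <- call_tpi(odd, cfg)
  expect_equal(call$subgroup, "undetermined")
  expect_match(call$note, "inconsistent")
  # Ca2 family with an unrecognised base at intron 148
  ban <- ds$alignments$tpi$seq[ds$alignments$tpi$specimen_id == "Ban-1"]
  odd2 <- tiny_alignment(c(x = mutate_at(ban, 148 + 166, "A")), "Tpi")
  call2 <- call_tpi(odd2, cfg)
  expect_equal(call2$subgroup, "Ca2")
  expect_match(call2$note, "neither")
})

test_that("heterozygote intron pattern is checked but not used for assignment", {
  ds <- survey()
  cfg <- ds$configs$tpi
  kor1 <- ds$alignments$tpi$seq[ds$alignments$tpi$specimen_id == "Kor-1"]
  clean <- call_tpi(tiny_alignment(c(`Kor-1` = kor1), "Tpi"), cfg)
  expect_equal(clean$subgroup, "Ca1/Ca2")
  expect_true(is.na(clean$note))
  expect_equal(
    sort(unique(unlist(clean$intron_bases))),
    sort(unique(c("S", "M", "W", "Y")))
  )
  # un-ambiguous base at one intron site -> consistency warning, same subgroup
  broken <- mutate_at(kor1, 31 + 166, "A")
  call <- call_tpi(tiny_alignment(c(`Kor-1` = broken), "Tpi"), cfg)
  expect_equal(call$subgroup, "Ca1/Ca2")
  expect_match(call$note, "inconsistent")
})

test_that("heterozygous flag tracks ambiguity at diagnostic exon sites exactly", {
  ds <- survey()
  cfg <- ds$configs$tpi
  base <- ds$alignments$tpi$seq[1]
  exon_cols <- c(183, 192, 198) - 140
  for (cc in exon_cols) {
    het <- mutate_at(base, cc, "Y")
    expect_true(call_tpi(tiny_alignment(c(x = het), "Tpi"), cfg)$heterozygous)
  }
  # ambiguity elsewhere does not set the flag
  other <- mutate_at(base, 400, "Y")
  expect_false(call_tpi(tiny_alignment(c(x = other), "Tpi"), cfg)$heterozygous)
})

test_that("COI vote classifier scores classes and handles missing data", {
  ds <- survey()
  cfg <- ds$configs$coi
  calls <- call_coi(ds$alignments$coi, cfg)
  expect_equal(sum(calls$strain == "R"), 25L)
  expect_equal(sort(calls$specimen_id[calls$strain == "C"]), c("Tan-3", "Vie-3"))
  expect_true(all(calls$score == 1.0))

  cols <- cfg$sites$position - 38
  rice <- ds$alignments$coi$seq[1]
  # five sites from each class: symmetric conflict below threshold
  half <- mutate_at(rice, cols[1:5], NULL)
  for (k in 1:5) half <- mutate_at(half, cols[k], cfg$sites$C[k])
  conflicted <- call_coi(tiny_alignment(c(x = half), "COI"), cfg)
  expect_equal(conflicted$strain, "undetermined")

  # Ns are dropped from numerator and denominator
  holes <- rice
  for (k in 1:3) holes <- mutate_at(holes, cols[k], "N")
  partial <- call_coi(tiny_alignment(c(x = holes), "COI"), cfg)
  expect_equal(partial$strain, "R")
  expect_equal(partial$n_compared, 7L)
  expect_equal(partial$score, 1.0)

  # all ten sites missing
  blank <- rice
  for (k in 1:10) blank <- mutate_at(blank, cols[k], "N")
  zero <- call_coi(tiny_alignment(c(x = blank), "COI"), cfg)
  expect_equal(zero$strain, "undetermined")
  expect_equal(zero$n_compared, 0L)
  expect_match(zero$note, "zero coverage")
})

test_that("classification is invariant to bases at non-diagnostic positions", {
  ds <- survey()
  set.seed(99)
  coi_cols <- ds$configs$coi$sites$position - 38
  tpi_cols <- c(c(183, 192, 198) - 140, c(31, 38, 53, 55, 58, 70, 77, 87, 96, 148) + 166)
  for (rep in 1:5) {
    i <- sample(27, 1)
    coi_seq <- ds$alignments$coi$seq[i]
    free <- sample(setdiff(seq_len(658), coi_cols), 20)
    fuzzed <- mutate_at(coi_seq, free)
    expect_equal(
      call_coi(tiny_alignment(c(x = fuzzed), "COI"), ds$configs$coi)$strain,
      call_coi(tiny_alignment(c(x = coi_seq), "COI"), ds$configs$coi)$strain
    )
    tpi_seq <- ds$alignments$tpi$seq[i]
    free_t <- sample(setdiff(seq_len(444), tpi_cols), 20)
    fuzz_t <- mutate_at(tpi_seq, free_t)
    a <- call_tpi(tiny_alignment(c(x = fuzz_t), "Tpi"), ds$configs$tpi)
    b <- call_tpi(tiny_alignment(c(x = tpi_seq), "Tpi"), ds$configs$tpi)
    expect_equal(a$strain, b$strain)
    expect_equal(a$subgroup, b$subgroup)
  }
})

test_that("combined genotypes label hybrids and flag incomplete calls", {
  tpi <- tibble::tibble(
    specimen_id = c("a", "b", "c"), strain = c("C", "C", "undetermined"),
    subgroup = c("Ca1a", "Ca1a", NA)
  )
  coi <- tibble::tibble(
    specimen_id = c("a", "b", "c"), strain = c("R", "C", "R")
  )
  g <- combine_genotypes(tpi, coi)
  expect_equal(g$label, c("Tpi-C/COI-R", "Tpi-C/COI-C", "Tpi-?/COI-R"))
  expect_equal(g$complete, c(TRUE, TRUE, FALSE))
  freq <- genotype_frequencies(g)
  expect_equal(sum(freq$n), 3L)
  expect_equal(sum(freq$pct), 100, tolerance = 0.2)
})

test_that("pairwise identity matches the published similarity arithmetic", {
  a <- strrep("A", 658)
  expect_equal(pairwise_identity(a, mutate_at(a, 1)), 99.85)
  expect_equal(pairwise_identity(a, mutate_at(a, 1:10)), 98.48)
  expect_equal(pairwise_identity(a, mutate_at(a, 1:11)), 98.33)
  expect_equal(pairwise_identity(a, a), 100.00)
  # gap/missing positions are excluded from the comparison
  b <- mutate_at(mutate_at(a, 1, "-"), 2, "N")
  expect_equal(pairwise_identity(a, b), 100.00)
  expect_warning(
    expect_true(is.na(pairwise_identity("N-", "AN"))),
    "undefined"
  )
  expect_error(pairwise_identity("ACGT", "ACG"), "equal")
})
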
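# Shared fixtures and independent oracles for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

# The 27-specimen two-marker synthetic survey, generated once per test run.
survey <- function(seed = 1L) {
  key <- paste0("survey", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_faw_survey(seed = seed)
  }
  .fixture_cache[[key]]
}

tiny_alignment <- function(seqs, marker = "m") {
  marker_alignment(seqs, marker = marker)
}

random_alignment <- function(n, L, seed, marker = "rnd") {
  set.seed(seed)
  seqs <- vapply(
    seq_len(n),
    function(i) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)
  )
  tiny_alignment(setNames(seqs, sprintf("s%02d", seq_len(n))), marker)
}

# Independent oracle for mean pairwise differences: per-column allele
# frequencies instead of pair enumeration. Columns with any non-ACGT
# character are dropped (complete deletion).
oracle_kbar_colwise <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  per_col <- apply(m, 2, function(col) {
    tab <- table(col)
    (sum(tab)^2 - sum(tab^2)) / 2 # unordered mismatching pairs in the column
  })
  sum(per_col) / choose(n, 2)
}

# Brute-force minimum spanning tree weight: enumerate all (n-1)-edge subsets
# and keep the lightest one that spans. Only for small n.
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  stopifnot(n <= 6)
  pairs <- t(combn(n, 2))
  w <- d[pairs]
  best <- Inf
  for (sel in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    for (e in sel) {
      ri <- find(pairs[e, 1])
      rj <- find(pairs[e, 2])
      if (ri != rj) parent[ri] <- rj
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) == 1) {
      best <- min(best, sum(w[sel]))
    }
  }
  best
}

# Mutate a sequence at given 1-based columns to a different base.
mutate_at <- function(seq, columns, base = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (cc in columns) {
    alt <- base %||% setdiff(c("A", "C", "G", "T"), chars[cc])[1]
    chars[cc] <- alt
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
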
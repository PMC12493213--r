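# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and Biostrings) so that agreement is evidence,
# not tautology.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# reverse complement by character table + rev, independent of Biostrings
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(s)), "")[[1]]),
        collapse = "")
}

# brute-force sliding-window start positions
oracle_window_starts <- function(L, k, step) {
  starts <- integer(0)
  s <- 1L
  while (s + k - 1L <= L) { starts <- c(starts, s); s <- s + step }
  starts
}

# read a shipped thermo table directly from its TSV, bypassing
# load_thermo_table()
oracle_read_table <- function(file) {
  path <- system.file("extdata", "thermo", file, package = "asodesign")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# spreadsheet-style NN Tm: explicit loop over doublets, then the OligoCalc
# closed form on magnitudes
oracle_nn_tm <- function(seq, table_df, na = 0.05, conc = 5e-8) {
  s <- toupper(chartr("U", "T", seq))
  dh <- 0; ds <- 0
  for (i in 1:(nchar(s) - 1)) {
    d <- substr(s, i, i + 1)
    row <- table_df[table_df$doublet == d, ]
    dh <- dh + row$dH_kcal
    ds <- ds + row$dS_cal
  }
  1000 * (abs(dh) - 3.4) / (abs(ds) + 1.987 * log(1 / conc)) -
    272.9 + 16.6 * log10(na)
}

# exhaustive enumeration of all nested pairings (Watson-Crick only,
# minimum hairpin loop of 3) returning the maximum pair count; naive
# recursion, no memoization
oracle_max_pairs <- function(seq) {
  b <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  wc <- function(x, y) (x == "A" && y == "T") || (x == "T" && y == "A") ||
    (x == "G" && y == "C") || (x == "C" && y == "G")
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    best <- rec(i, j - 1L)                # j unpaired
    for (k in i:(j - 4L)) {
      if (wc(b[k], b[j])) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        best <- max(best, 1L + left + rec(k + 1L, j - 1L))
      }
    }
    best
  }
  if (length(b) < 2L) return(0L)
  rec(1L, length(b))
}

# builtin-equivalent pair count extracted from a fold
pkg_max_pairs <- function(seq) {
  t1 <- fold_ensemble(seq, max_topologies = 1)$topologies[[1]]
  sum(t1$pairing > 0) / 2
}

# assemble a structure ensemble directly from dot-bracket strings
ensemble_from_db <- function(...) {
  tops <- lapply(list(...), parse_dot_bracket)
  asodesign:::.new_ensemble(tops, nchar(..1), "test fixture")
}

expect_valid_pairing <- function(pairing) {
  p <- which(pairing > 0)
  expect_true(all(pairing[pairing[p]] == p))
  expect_false(any(pairing[p] == p))
}
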
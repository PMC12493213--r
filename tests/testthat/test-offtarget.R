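# helper: plant the binding site for `aso` (i.e. its reverse complement)
# into a random host at a given position
plant_site <- function(host, at, aso) {
  site <- oracle_revcomp(aso)
  substr(host, at, at + nchar(site) - 1L) <- site
  host
}

test_that("builtin scanner recovers planted matches exactly", {
  set.seed(61)
  aso <- "ACGGATTTCAGCTACGTA"          # non-palindromic 18-mer
  decoy <- plant_site(random_dna(200), 101, aso)
  db <- c(decoy_1 = decoy)

  hits <- scan_builtin(aso, db, max_mismatches = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$subject_start, 101)
  expect_equal(hits$subject_end, 118)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)

  # mutate one base of the planted site
  mut <- decoy
  substr(mut, 110, 110) <- if (substr(mut, 110, 110) == "A") "C" else "A"
  expect_equal(nrow(scan_builtin(aso, c(d = mut), 0)), 0)
  h1 <- scan_builtin(aso, c(d = mut), 1)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$mismatches, 1)
  expect_equal(h1$identities, 17)
})

test_that("the self-hit at the intended locus is found and excluded", {
  set.seed(62)
  t <- target_sequence(random_dna(120), name = "gene")
  g <- generate_asos(t, 18, 1)
  rec <- g[40, ]
  hits <- scan_builtin(rec$sequence, t, 0)
  expect_gte(nrow(hits), 1)
  expect_true(any(hits$subject_start == rec$target_start &
                    hits$strand == "+"))
  expect_equal(summarize_offtargets(
    hits, list(id = "gene", start = rec$target_start,
               end = rec$target_end)), 0)
  expect_equal(summarize_offtargets(hits[0, ], NULL), 0)

  # self-hit plus one decoy hit -> count 1
  decoy <- target_sequence(
    plant_site(random_dna(90), 30, rec$sequence), name = "decoy")
  hits2 <- scan_builtin(rec$sequence, list(t, decoy), 0)
  expect_equal(summarize_offtargets(
    hits2, list(id = "gene", start = rec$target_start,
                end = rec$target_end)), 1)
})

test_that("planting k copies yields exactly k hits across strands and
           records", {
  set.seed(63)
  aso <- "TTGACCGTAGGCATCAAG"
  r1 <- plant_site(random_dna(150), 11, aso)
  r1 <- plant_site(r1, 90, aso)
  # a minus-strand site carries the ASO letters themselves
  r2 <- random_dna(150)
  substr(r2, 61, 78) <- chartr("U", "T", aso)
  hits <- scan_builtin(aso, c(a = r1, b = r2), 0)
  expect_equal(nrow(hits), 3)
  expect_equal(sum(hits$strand == "+"), 2)
  expect_equal(hits$db_record[hits$strand == "-"], "b")
})

test_that("external blastn agrees with the builtin scanner on exact
           matches", {
  set.seed(64)
  aso <- "GATCCGTTAACGGATGCA"
  rec1 <- plant_site(random_dna(300), 120, aso)
  rec2 <- random_dna(300)
  db_fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">rec1", rec1, ">rec2", rec2), db_fa)

  ext <- run_external_aligner(c(ASO_1 = aso), db_fa)
  exact_ext <- ext[ext$mismatches == 0 & ext$identities == nchar(aso), ,
                   drop = FALSE]
  blt <- scan_builtin(aso, c(rec1 = rec1, rec2 = rec2), 0)
  expect_equal(nrow(exact_ext), nrow(blt))
  expect_equal(exact_ext$db_record, blt$db_record)
  expect_equal(exact_ext$subject_start, blt$subject_start)
  expect_true(all(is.finite(exact_ext$evalue)))
})

test_that("empty databases and missing inputs error clearly", {
  expect_error(scan_builtin("ACGTACGT", list()), "empty")
  expect_error(run_external_aligner(c(a = "ACGT"), "/nonexistent.fa"),
               "not found")
})
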
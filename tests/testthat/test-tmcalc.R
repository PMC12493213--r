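test_that("thermo tables are complete, stabilizing, and documented", {
  for (chem in c("DNA/DNA", "RNA/RNA", "RNA/PS-RNA", "RNA/2OMe-RNA")) {
    tab <- load_thermo_table(chem)
    expect_equal(nrow(tab$doublet_params), 16)
    expect_setequal(tab$doublet_params$doublet,
                    as.vector(outer(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"), paste0)))
    expect_true(all(tab$doublet_params$dH_kcal < 0))
    expect_true(all(tab$doublet_params$dS_cal < 0))
    expect_match(tab$provenance, "Breslauer|Xia")  # cites its source
  }
  expect_error(load_thermo_table("RNA/LNA"), "no published")
  expect_error(load_thermo_table("PMO"), "no published")
})

test_that("nearest-neighbor sums equal hand lookups in the shipped table", {
  dna <- load_thermo_table("dna_dna")
  raw <- oracle_read_table("dna_dna.tsv")
  aa <- raw[raw$doublet == "AA", ]
  s2 <- nn_sums("AA", dna)
  expect_equal(s2$dH_sum, aa$dH_kcal)
  expect_equal(s2$dS_sum, aa$dS_cal)
  s3 <- nn_sums("AAA", dna)
  expect_equal(s3$dH_sum, 2 * aa$dH_kcal)
  expect_equal(s3$dS_sum, 2 * aa$dS_cal)
  # self-complementary sequence reads the same from either strand
  expect_equal(nn_sums("ATAT", dna), nn_sums(oracle_revcomp("ATAT"), dna))
  expect_error(nn_sums("A", dna), "at least 2")
})

test_that("basic and salt-adjusted methods reproduce the closed forms", {
  expect_equal(tm_basic("ATGC"), 12)
  expect_equal(tm_basic(strrep("A", 13)), 26)
  s20 <- paste0(strrep("G", 5), strrep("C", 5), strrep("A", 5),
                strrep("T", 5))
  expect_equal(tm_basic(s20), 64.9 + 41 * (10 - 16.4) / 20)
  expect_equal(tm_salt_adjusted(s20, "DNA", 0.05),
               100.5 + 41 * 0.5 - 820 / 20 + 16.6 * log10(0.05))
  expect_equal(tm_salt_adjusted(s20, "RNA", 0.05),
               79.8 + 18.5 * log10(0.05) + 58.4 * 0.5 + 11.8 * 0.25 -
                 820 / 20)
})

test_that("composition-only methods are permutation-invariant; NN is not", {
  set.seed(31)
  s <- random_dna(16)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(tm_basic(s), tm_basic(perm))
  expect_equal(tm_salt_adjusted(s, "RNA", 0.2),
               tm_salt_adjusted(perm, "RNA", 0.2))
  # a permuted sequence with identical composition can shift the NN value:
  # poly-purine block vs alternating arrangement
  a <- paste0(strrep("G", 8), strrep("A", 8))
  b <- strrep("GA", 8)
  expect_false(isTRUE(all.equal(tm_nearest_neighbor(a, "RNA/RNA"),
                                tm_nearest_neighbor(b, "RNA/RNA"))))
})

test_that("NN model refuses short duplexes instead of extrapolating", {
  expect_error(tm_nearest_neighbor("ACGTACG", "DNA/DNA"),
               "8 nt or longer")
  r <- tm_for_window("ACGTACG", "nearest_neighbor", "DNA/DNA")
  expect_equal(r$method, "basic(fallback)")
  expect_equal(r$tm_C, tm_basic("ACGTACG"))
})

test_that("all Tm methods increase strictly with sodium concentration", {
  set.seed(32)
  s <- random_dna(18)
  nas <- c(0.01, 0.05, 0.2, 1)
  nn <- vapply(nas, function(x) tm_nearest_neighbor(s, "RNA/RNA", x), 0)
  sd <- vapply(nas, function(x) tm_salt_adjusted(s, "DNA", x), 0)
  sr <- vapply(nas, function(x) tm_salt_adjusted(s, "RNA", x), 0)
  expect_true(all(diff(nn) > 0))
  expect_true(all(diff(sd) > 0))
  expect_true(all(diff(sr) > 0))
  # basic-method Tm is bounded by the GC -> n, n -> Inf limit
  for (rep in 1:50) {
    comp <- base_composition(random_dna(sample(14:60, 1)))
    expect_lt(tm_basic(comp), 64.9 + 41.0)
  }
})

test_that("GC-rich duplexes melt higher than AT-rich in every table", {
  for (chem in c("DNA/DNA", "RNA/RNA", "RNA/PS-RNA", "RNA/2OMe-RNA")) {
    expect_gt(tm_nearest_neighbor(strrep("G", 8), chem),
              tm_nearest_neighbor(strrep("A", 8), chem))
  }
  # chemistry ordering at fixed sequence: 2'OMe stabilizes, PS destabilizes
  s <- strrep("AGCUAGCU", 2)
  expect_gt(tm_nearest_neighbor(s, "RNA/2OMe-RNA"),
            tm_nearest_neighbor(s, "RNA/RNA"))
  expect_lt(tm_nearest_neighbor(s, "RNA/PS-RNA"),
            tm_nearest_neighbor(s, "RNA/RNA"))
})
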
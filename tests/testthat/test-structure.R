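test_that("builtin folder finds the planted hairpin and leaves unfoldable
           sequences open", {
  e <- fold_ensemble("GGGAAACCC")
  expect_equal(as_dot_bracket(e$topologies[[1]]), "(((...)))")
  expect_equal(e$topologies[[1]]$energy, -3)

  e2 <- fold_ensemble("AAAAAA")
  expect_length(e2$topologies, 1)
  expect_true(all(e2$topologies[[1]]$pairing == 0))

  e3 <- fold_ensemble("GGGGAAAACCCCGGGGAAAACCCC", max_topologies = 1)
  expect_length(e3$topologies, 1)

  expect_error(fold_ensemble(strrep("A", 9001)), "9000")
})

test_that("dot-bracket and CT parsing build valid involutions and
           round-trip", {
  t <- parse_dot_bracket("((..))")
  expect_equal(t$pairing, c(6L, 5L, 0L, 0L, 2L, 1L))
  expect_valid_pairing(t$pairing)
  expect_error(parse_dot_bracket(")("), "unbalanced")
  expect_error(parse_dot_bracket("(.."), "unbalanced")
  expect_error(parse_dot_bracket("(x)"), "invalid")

  set.seed(41)
  for (rep in 1:20) {
    s <- random_dna(sample(8:30, 1))
    db <- as_dot_bracket(fold_ensemble(s)$topologies[[1]])
    expect_equal(as_dot_bracket(parse_dot_bracket(db)), db)
  }

  # CT round-trip
  top <- fold_ensemble("GGGAAACCC")$topologies[[1]]
  ct <- withr::local_tempfile(fileext = ".ct")
  n <- length(top$pairing)
  writeLines(c(paste(n, "test"),
               vapply(1:n, function(i)
                 paste(i, substr("GGGAAACCC", i, i), i - 1,
                       if (i < n) i + 1 else 0, top$pairing[i], i),
                 "")), ct)
  expect_equal(parse_ct(ct)$pairing, top$pairing)

  writeLines(c("3 bad", "1 G 0 2 0 1", "3 G 2 0 0 3"), ct)
  expect_error(parse_ct(ct), "declares 3")
})

test_that("builtin folder attains the exhaustive-enumeration maximum on
           short sequences", {
  set.seed(42)
  for (rep in 1:60) {
    s <- random_dna(sample(4:12, 1))
    expect_equal(pkg_max_pairs(s), oracle_max_pairs(s), label = s)
  }
})

test_that("accessibility profiles superimpose topologies correctly", {
  ens <- ensemble_from_db("((..))", ".(..).")
  p_int <- single_stranded_profile(ens, "intersection")
  expect_equal(p_int$fraction, c(.5, 0, 1, 1, 0, .5))
  expect_equal(which(p_int$always_single), c(3L, 4L))
  p_mfe <- single_stranded_profile(ens, "mfe_only")
  expect_equal(p_mfe$indicator, c(0, 0, 1, 1, 0, 0))

  expect_equal(window_accessibility(p_mfe, 2, 5), 0.5)
  expect_equal(window_accessibility(p_mfe, 3, 4), 1.0)
  expect_equal(window_accessibility(p_mfe, 1, 2), 0.0)
  expect_error(window_accessibility(p_mfe, 0, 3), "outside")

  # single-topology ensemble: intersection degenerates to mfe_only
  e1 <- ensemble_from_db("((..))")
  expect_equal(single_stranded_profile(e1, "intersection")$indicator,
               single_stranded_profile(e1, "mfe_only")$indicator)

  # all-unpaired ensemble
  e2 <- ensemble_from_db("....", "....")
  expect_equal(single_stranded_profile(e2, "intersection")$fraction,
               rep(1, 4))

  # profiles are invariant under topology reordering
  ens_r <- ensemble_from_db(".(..).", "((..))")
  expect_equal(single_stranded_profile(ens_r, "intersection")$fraction,
               p_int$fraction)
})

test_that("intersection accessibility never exceeds mfe-only
           accessibility", {
  set.seed(43)
  for (rep in 1:15) {
    s <- random_dna(sample(20:40, 1))
    ens <- fold_ensemble(s, max_topologies = 4)
    pm <- single_stranded_profile(ens, "mfe_only")
    pi <- single_stranded_profile(ens, "intersection")
    # always-single implies unpaired in the rank-1 topology
    expect_true(all(pi$indicator <= pm$indicator))
    st <- sample(nchar(s) - 5, 1)
    expect_lte(window_accessibility(pi, st, st + 5),
               window_accessibility(pm, st, st + 5))
  }
})

test_that("self-folding flags stable hairpins and honors the threshold", {
  r1 <- self_fold("ACACACAC", threshold_kcal = -1)
  expect_false(r1$flagged)
  expect_equal(r1$mfe_energy, 0)

  r2 <- self_fold("GGGGAAAACCCC", threshold_kcal = -1)
  expect_true(r2$flagged)
  expect_lte(r2$mfe_energy, -4)

  r3 <- self_fold("GGGGAAAACCCC", threshold_kcal = -Inf)
  expect_false(r3$flagged)
})

test_that("the ViennaRNA backend is a drop-in for folding and self-fold", {
  ens <- fold_ensemble("GGGGAAAACCCC", backend = "vienna",
                       max_topologies = 3)
  expect_lte(length(ens$topologies), 3)
  expect_valid_pairing(ens$topologies[[1]]$pairing)
  expect_lt(ens$topologies[[1]]$energy, 0)   # real kcal/mol MFE
  # ranks ordered by energy
  en <- vapply(ens$topologies, `[[`, 0, "energy")
  expect_true(!is.unsorted(en))

  sf <- self_fold("GGGGGAAAAACCCCC", threshold_kcal = -1,
                  backend = "vienna")
  expect_true(sf$flagged)
  expect_lt(sf$mfe_energy, -1)
})
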
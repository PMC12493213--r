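test_that("splice tracks load densely from sparse TSV rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tdonor_prob\tacceptor_prob", "50\t0.9\t0.0"), f)
  tr <- load_splice_track(f, 100)
  expect_equal(tr$donor_prob[50], 0.9)
  expect_equal(sum(tr$donor_prob), 0.9)
  expect_equal(sum(tr$acceptor_prob), 0)

  writeLines(character(0), f)
  tr0 <- load_splice_track(f, 100)
  expect_equal(sum(tr0$donor_prob) + sum(tr0$acceptor_prob), 0)

  writeLines(c("position\tdonor_prob\tacceptor_prob", "10\t1.2\t0"), f)
  expect_error(load_splice_track(f, 100), "\\[0, 1\\]")
  writeLines(c("position\tdonor_prob\tacceptor_prob", "101\t0.5\t0"), f)
  expect_error(load_splice_track(f, 100), "outside")
})

test_that("splice track writer round-trips through the loader", {
  tr <- splice_track(200)
  tr$donor_prob[c(20, 77)] <- c(0.8, 0.55)
  tr$acceptor_prob[150] <- 0.9
  f <- withr::local_tempfile(fileext = ".tsv")
  write_splice_track(tr, f)
  back <- load_splice_track(f, 200)
  expect_equal(back$donor_prob, tr$donor_prob)
  expect_equal(back$acceptor_prob, tr$acceptor_prob)
})

test_that("site calling thresholds behave and are anti-monotone", {
  tr <- splice_track(100)
  tr$donor_prob[50] <- 0.9
  s <- call_splice_sites(tr, 0.5)
  expect_equal(nrow(s), 1)
  expect_equal(s$position, 50)
  expect_equal(s$kind, "donor")
  expect_equal(nrow(call_splice_sites(tr, 0.95)), 0)

  tr$acceptor_prob[7] <- 0.6; tr$donor_prob[7] <- 0.6
  both <- call_splice_sites(tr, 0.5)
  expect_equal(sum(both$position == 7), 2)  # donor and acceptor at 7

  set.seed(51)
  tr2 <- splice_track(300, donor_prob = runif(300),
                      acceptor_prob = runif(300))
  counts <- vapply(c(.1, .3, .5, .7, .9),
                   function(th) nrow(call_splice_sites(tr2, th)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("masking labels ASOs whose window covers the site anchor", {
  recs <- data.frame(serial = 1:2, target_start = c(40L, 10L),
                     target_end = c(57L, 27L))
  sites <- data.frame(position = 50L, kind = "donor", probability = 0.9)
  out <- annotate_masking(recs, sites)
  expect_equal(out$masks_donor, c(TRUE, FALSE))
  expect_equal(out$masks_acceptor, c(FALSE, FALSE))

  # the splice-correction window geometry: an 18-mer starting at 1187
  # covers the cryptic donor anchored at 1197
  rec <- data.frame(serial = 1187L, target_start = 1187L,
                    target_end = 1204L)
  site <- data.frame(position = 1197L, kind = "donor", probability = 0.92)
  expect_true(annotate_masking(rec, site)$masks_donor)

  # min_overlap pushes the anchor away from the window edge
  edge <- data.frame(serial = 1L, target_start = 50L, target_end = 67L)
  expect_true(annotate_masking(edge, sites, min_overlap = 1)$masks_donor)
  expect_false(annotate_masking(edge, sites, min_overlap = 2)$masks_donor)
})

test_that("exhaustive generation masks a site with exactly min(k, L-pos+1,
           pos) windows", {
  set.seed(52)
  for (rep in 1:12) {
    L <- sample(40:120, 1); k <- sample(6:20, 1); pos <- sample(1:L, 1)
    t <- target_sequence(random_dna(L))
    g <- generate_asos(t, k, 1)
    sites <- data.frame(position = pos, kind = "donor", probability = 1)
    out <- annotate_masking(g, sites)
    expect_equal(sum(out$masks_donor), min(k, L - pos + 1, pos, L - k + 1),
                 label = paste("L", L, "k", k, "pos", pos))
  }
})
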
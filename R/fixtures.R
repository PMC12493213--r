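# Synthetic test-data generation. Fixtures emulate the features the
# pipeline keys on: random-composition targets, planted inverted repeats
# (stable hairpins), planted GT/AG splice motifs with probability tracks,
# and decoy off-target databases with planted exact or near-exact copies
# of target windows. All randomness is seeded; identical seeds give
# byte-identical outputs.

.random_dna <- function(n, gc_bias = 0.5) {
  p <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
         G = gc_bias / 2, T = (1 - gc_bias) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

.plant <- function(residues, at, motif) {
  if (at < 1L || at + nchar(motif) - 1L > nchar(residues))
    stop("planted motif at ", at, " (", nchar(motif),
         " nt) exceeds sequence length ", nchar(residues))
  substr(residues, at, at + nchar(motif) - 1L) <- motif
  residues
}

#' Generate a seeded synthetic target, splice track and decoy database
#'
#' Builds a random-composition target and optionally plants: a hairpin
#' (`hairpin_spec = list(position, stem, loop = 4)`: an inverted repeat
#' `stem` nt long whose arms flank a `loop`-nt loop, guaranteed to fold);
#' splice sites (`splice_spec` = list of `list(kind, position, prob)`,
#' planting the GT or AG dinucleotide at the anchor and setting the track
#' probability); and decoys (`decoy_spec = list(n_records, record_length,
#' plants)` where each plant is `list(record, at, from, length,
#' mismatches = 0)` copying the target window starting at `from` into a
#' decoy record, optionally with point mismatches).
#'
#' @param seed Integer seed; the function calls `set.seed(seed)`.
#' @param length Target length (nt).
#' @param gc_bias Probability mass on G+C (default 0.5).
#' @param hairpin_spec,splice_spec,decoy_spec See above; NULL disables.
#' @return List with `target` (`target_seq`), `track` (`splice_track`) and
#'   `decoys` (list of `target_seq`, possibly empty).
#' @export
make_fixture <- function(seed, length = 100L, gc_bias = 0.5,
                         hairpin_spec = NULL, splice_spec = NULL,
                         decoy_spec = NULL) {
  set.seed(as.integer(seed))
  length <- as.integer(length)
  res <- .random_dna(length, gc_bias)

  if (!is.null(hairpin_spec)) {
    stem <- hairpin_spec$stem
    loop <- if (is.null(hairpin_spec$loop)) 4L else hairpin_spec$loop
    if (loop < 3L) stop("hairpin loop must be >= 3 nt")
    arm <- .random_dna(stem, 0.8)  # GC-rich arm folds under any model
    motif <- paste0(arm, .random_dna(loop, 0.0), .revcomp(arm))
    res <- .plant(res, hairpin_spec$position, motif)
  }

  track <- splice_track(length)
  for (sp in splice_spec) {
    kind <- match.arg(sp$kind, c("donor", "acceptor"))
    pos <- sp$position
    if (kind == "donor") {
      res <- .plant(res, pos, "GT")
      track$donor_prob[pos] <- sp$prob
    } else {
      if (pos < 2L) stop("acceptor anchor must be >= 2")
      res <- .plant(res, pos - 1L, "AG")
      track$acceptor_prob[pos] <- sp$prob
    }
  }

  target <- target_sequence(res, name = "fixture_target",
                            source_note = paste0("synthetic (seed ", seed,
                                                 ")"))

  decoys <- list()
  if (!is.null(decoy_spec)) {
    rl <- decoy_spec$record_length
    decoys <- lapply(seq_len(decoy_spec$n_records), function(i)
      target_sequence(.random_dna(rl, gc_bias),
                      name = paste0("decoy_", i),
                      source_note = paste0("synthetic decoy (seed ", seed,
                                           ")")))
    for (pl in decoy_spec$plants) {
      win <- substr(target$residues, pl$from, pl$from + pl$length - 1L)
      mm <- if (is.null(pl$mismatches)) 0L else pl$mismatches
      if (mm > 0L) {
        at <- sample(nchar(win), mm)
        for (i in at) {
          cur <- substr(win, i, i)
          substr(win, i, i) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
        }
      }
      decoys[[pl$record]]$residues <- .plant(decoys[[pl$record]]$residues,
                                             pl$at, win)
    }
  }
  list(target = target, track = track, decoys = decoys)
}

#' Synthetic HBB-like worked example (beta-thalassemia IVS2-654)
#'
#' A deterministic, clearly synthetic stand-in for the 1708-nt HBB
#' pre-mRNA region (Ensembl GRCh38:11:5225414:5227121:-1) used to exercise
#' the splice-correction workflow offline; fetch the real region with
#' [fetch_ensembl_region()] when a network is available. The stand-in
#' reproduces the region's geometry, not its residues: 1708 nt with an
#' HBB-like layout (exon 1 at 50-191, intron 1 at 192-321, exon 2 at
#' 322-544, intron 2 at 545-1394 — 850 nt, as in HBB — and exon 3 at
#' 1395-1655), so position 654 of intron 2 (IVS2-654) maps to target
#' coordinate 1198. The pre-mutation sequence carries G at 1197 and C at
#' 1198; applying the IVS2-654 C>T edit creates a GT donor dinucleotide
#' anchored at G1197, mirroring how the real mutation activates a cryptic
#' 5' splice site. Canonical donors/acceptors are planted at the intron
#' boundaries with high track probabilities; the returned track also
#' carries the cryptic donor at 1197 (probability 0.92), representing a
#' predictor run on the mutated sequence.
#'
#' @param seed Integer seed for the random background sequence.
#' @return List with `target` (unmutated `target_seq`), `mutation`
#'   (`list(position, ref, alt, label)`), `mutated` (the edited target)
#'   and `track` (post-mutation `splice_track`).
#' @export
synthetic_hbb_example <- function(seed = 654L) {
  set.seed(as.integer(seed))
  L <- 1708L
  res <- .random_dna(L, 0.5)
  # canonical splice motifs at the HBB-like intron boundaries
  res <- .plant(res, 192L, "GTAAGT")    # intron 1 donor, anchor 192
  res <- .plant(res, 319L, "AG")        # intron 1 acceptor, anchor 320
  res <- .plant(res, 545L, "GTAAGT")    # intron 2 donor, anchor 545
  res <- .plant(res, 1392L, "AG")       # intron 2 acceptor, anchor 1393
  # cryptic-donor context: G at 1197, C at 1198 (IVS2-654); C>T -> GT
  res <- .plant(res, 1197L, "GCAAGT")
  target <- target_sequence(
    res, name = "HBB_synthetic",
    source_note = paste0("synthetic stand-in for GRCh38:11:5225414:",
                         "5227121:-1 (seed ", seed, "); geometry only"))
  mutation <- list(position = 1198L, ref = "C", alt = "T",
                   label = "IVS2-654 C>T")
  mutated <- apply_point_mutation(target, mutation$position, mutation$ref,
                                  mutation$alt)
  track <- splice_track(L)
  track$donor_prob[c(192L, 545L)] <- 0.98
  track$acceptor_prob[c(320L, 1393L)] <- 0.97
  track$donor_prob[1197L] <- 0.92  # cryptic donor activated by the edit
  list(target = target, mutation = mutation, mutated = mutated,
       track = track)
}

#' Fetch a genomic region from the Ensembl REST API
#'
#' Optional network helper; nothing in the package or its tests depends on
#' it. Example region string: `"GRCh38:11:5225414:5227121:-1"` (the HBB
#' pre-mRNA region, minus strand).
#'
#' @param region `"assembly:chrom:start:end:strand"` region string.
#' @param species Species name for the REST endpoint.
#' @return A `target_seq`.
#' @export
fetch_ensembl_region <- function(region, species = "human") {
  f <- strsplit(region, ":", fixed = TRUE)[[1]]
  if (length(f) != 5L)
    stop("region must be 'assembly:chrom:start:end:strand'")
  url <- sprintf(
    "https://rest.ensembl.org/sequence/region/%s/%s:%s..%s:%s?content-type=text/x-fasta;coord_system_version=%s",
    species, f[2], f[3], f[4], f[5], f[1])
  tf <- tempfile(fileext = ".fa")
  status <- tryCatch(utils::download.file(url, tf, quiet = TRUE),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L))
    stop("could not reach the Ensembl REST API (offline?); use ",
         "synthetic_hbb_example() for a network-free stand-in")
  recs <- read_fasta(tf)
  unlink(tf)
  recs[[1]]$name <- region
  recs[[1]]$source_note <- paste0("Ensembl REST ", region)
  recs[[1]]
}
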
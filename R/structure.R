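# Secondary-structure handling: topologies (per-base pairing states),
# structure ensembles for the target, single-stranded accessibility
# profiles, and ASO self-folding. The builtin folder is a deterministic
# maximum-pairing dynamic program (minimum hairpin loop of 3, leftmost
# pairing on ties); the external backend adapts the ViennaRNA command-line
# tools when real free energies are wanted.

.base_codes <- function(sequence) {
  s <- toupper(chartr("U", "T", sequence))
  if (grepl("[^ACGT]", s)) stop("sequence contains non-ACGT characters")
  match(strsplit(s, "")[[1]], c("A", "C", "G", "T")) - 1L
}

.new_topology <- function(pairing, energy = NA_real_, rank = NA_integer_) {
  pairing <- as.integer(pairing)
  p <- which(pairing > 0L)
  stopifnot(all(pairing[pairing[p]] == p), !any(pairing[p] == p))
  structure(list(pairing = pairing, energy = energy, rank = rank),
            class = "topology")
}

#' Serialize a topology to dot-bracket notation
#' @param topology A `topology` object.
#' @return Character scalar of `(`, `)` and `.`.
#' @export
as_dot_bracket <- function(topology) {
  p <- topology$pairing
  ch <- rep(".", length(p))
  ch[p > seq_along(p)] <- "("
  ch[p > 0 & p < seq_along(p)] <- ")"
  paste(ch, collapse = "")
}

#' Parse dot-bracket notation into a topology
#'
#' @param text Balanced dot-bracket string (characters `(`, `)`, `.`).
#' @param energy Optional free energy (kcal/mol) to attach.
#' @return A `topology`: per-base partner index (0 = unpaired), an
#'   involution by construction.
#' @examples
#' parse_dot_bracket("((..))")$pairing # 6 5 0 0 2 1
#' @export
parse_dot_bracket <- function(text, energy = NA_real_) {
  ch <- strsplit(text, "")[[1]]
  if (length(bad <- setdiff(unique(ch), c("(", ")", "."))))
    stop("invalid dot-bracket character '", bad[1], "'")
  pairing <- integer(length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- open[length(open)]; open <- open[-length(open)]
      pairing[i] <- j; pairing[j] <- i
    }
  }
  if (length(open))
    stop("unbalanced dot-bracket: unmatched '(' at ", open[1])
  .new_topology(pairing, energy = energy)
}

#' Parse a CT (connectivity table) file into a topology
#'
#' Standard CT layout: a header line (`N title`) followed by one row per
#' base: index, base, previous, next, partner (0 = unpaired), original
#' index. Row indices must be dense 1..N.
#'
#' @param path Path to the CT file.
#' @return A `topology`.
#' @export
parse_ct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("CT file too short: ", path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  body <- lines[-1]
  if (length(body) != n)
    stop("CT file declares ", n, " bases but has ", length(body), " rows")
  fields <- strsplit(trimws(body), "\\s+")
  idx <- vapply(fields, function(f) as.integer(f[1]), integer(1))
  if (!identical(idx, seq_len(n)))
    stop("CT index gap: rows are not densely numbered 1..", n)
  partner <- vapply(fields, function(f) as.integer(f[5]), integer(1))
  if (any(partner < 0 | partner > n)) stop("CT partner index out of range")
  .new_topology(partner)
}

.new_ensemble <- function(topologies, sequence_length, backend_note) {
  stopifnot(length(topologies) >= 1L)
  for (i in seq_along(topologies)) topologies[[i]]$rank <- i
  structure(list(topologies = topologies, sequence_length = sequence_length,
                 backend_note = backend_note),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("Structure ensemble: ", length(x$topologies), " topologies over ",
      x$sequence_length, " nt (", x$backend_note, ")\n", sep = "")
  for (t in x$topologies[seq_len(min(3, length(x$topologies)))])
    cat(sprintf("  rank %d  energy %.2f  %s\n", t$rank, t$energy,
                if (x$sequence_length <= 60) as_dot_bracket(t) else ""))
  invisible(x)
}

.fold_builtin_pairing <- function(sequence, forbidden = NULL,
                                  wobble = FALSE) {
  codes <- .base_codes(sequence)
  if (is.null(forbidden)) forbidden <- rep(FALSE, length(codes))
  .nussinov_pairing(codes, forbidden, wobble, 3L)
}

.fold_builtin_ensemble <- function(sequence, max_topologies, wobble) {
  p1 <- .fold_builtin_pairing(sequence, wobble = wobble)
  tops <- list(.new_topology(p1, energy = -sum(p1 > 0) / 2))
  seen <- as_dot_bracket(tops[[1]])
  paired <- which(p1 > 0)
  for (pos in paired) {
    if (length(tops) >= max_topologies) break
    forb <- rep(FALSE, nchar(sequence)); forb[pos] <- TRUE
    p <- .fold_builtin_pairing(sequence, forbidden = forb, wobble = wobble)
    t <- .new_topology(p, energy = -sum(p > 0) / 2)
    db <- as_dot_bracket(t)
    if (!db %in% seen) { tops <- c(tops, list(t)); seen <- c(seen, db) }
  }
  ord <- order(vapply(tops, `[[`, 0, "energy"))
  tops[ord]
}

.fold_vienna_ensemble <- function(sequence, max_topologies) {
  exe <- Sys.which("RNAsubopt")
  if (!nzchar(exe))
    stop("external folding backend unavailable: RNAsubopt not on PATH; ",
         "use backend = 'builtin' explicitly if that is acceptable")
  rna <- chartr("T", "U", toupper(sequence))
  out <- system2(exe, args = c("--sorted", "-e", "2"), input = rna,
                 stdout = TRUE, stderr = FALSE)
  out <- grep("^[.()]+\\s", out, value = TRUE)
  if (!length(out)) stop("RNAsubopt produced no structures")
  out <- utils::head(out, max_topologies)
  lapply(out, function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    parse_dot_bracket(f[1], energy = as.numeric(f[2]))
  })
}

#' Predict an ensemble of secondary-structure topologies
#'
#' Folds the sequence into up to `max_topologies` topologies ordered by
#' predicted energy (rank 1 = lowest). The builtin backend is a
#' deterministic maximum-pairing folder (dynamic programming, minimum
#' hairpin loop of 3, leftmost-pairing tie-break); its reported energies
#' are the negated pair counts, a clearly-labelled pseudo-energy.
#' Suboptimal builtin topologies are generated deterministically by
#' re-folding with successive rank-1 paired positions forced
#' single-stranded. The `vienna` backend shells out to ViennaRNA's
#' `RNAsubopt` for thermodynamic structures and energies; it is never
#' substituted silently when unavailable.
#'
#' @param sequence Nucleotide sequence (<= 9000 nt).
#' @param backend `"builtin"` or `"vienna"`.
#' @param max_topologies Ensemble size cap (default 5).
#' @param wobble Allow G-T/G-U wobble pairs in the builtin folder.
#' @return A `structure_ensemble`.
#' @examples
#' fold_ensemble("GGGAAACCC", max_topologies = 1)
#' @export
fold_ensemble <- function(sequence, backend = c("builtin", "vienna"),
                          max_topologies = 5L, wobble = FALSE) {
  backend <- match.arg(backend)
  n <- nchar(sequence)
  if (n < 1L) stop("empty sequence")
  if (n > 9000L)
    stop("sequence of ", n, " nt exceeds the 9000-nt folding cap")
  if (max_topologies < 1L) stop("max_topologies must be >= 1")
  tops <- switch(backend,
    builtin = .fold_builtin_ensemble(sequence, max_topologies, wobble),
    vienna = .fold_vienna_ensemble(sequence, max_topologies))
  .new_ensemble(tops, n, backend_note = paste0(
    backend, if (backend == "builtin")
      " maximum-pairing folder (pseudo-energy = -pairs)" else
      " (ViennaRNA RNAsubopt)"))
}

#' Single-stranded accessibility profile of an ensemble
#'
#' `mfe_only` reports the 0/1 unpaired indicator of the rank-1 (lowest
#' energy) topology. `intersection` superimposes all topologies: per base,
#' the fraction of topologies in which it is unpaired, plus an
#' `always_single` flag marking bases unpaired in every topology — the
#' regions consistently predicted to remain unstructured.
#'
#' @param ensemble A `structure_ensemble`.
#' @param mode `"mfe_only"` or `"intersection"`.
#' @return A `ss_profile` list: `mode`, `fraction` (per-base numeric),
#'   `indicator` (per-base 0/1 used for window accessibility) and, for
#'   intersection mode, `always_single`.
#' @export
single_stranded_profile <- function(ensemble,
                                    mode = c("mfe_only", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (!length(ensemble$topologies)) stop("empty ensemble")
  unpaired <- vapply(ensemble$topologies,
                     function(t) t$pairing == 0L,
                     logical(ensemble$sequence_length))
  unpaired <- matrix(unpaired, nrow = ensemble$sequence_length)
  if (mode == "mfe_only") {
    ind <- as.numeric(unpaired[, 1])
    structure(list(mode = mode, fraction = ind, indicator = ind),
              class = "ss_profile")
  } else {
    frac <- rowMeans(unpaired)
    always <- frac == 1
    structure(list(mode = mode, fraction = frac,
                   indicator = as.numeric(always), always_single = always),
              class = "ss_profile")
  }
}

#' Accessibility of a binding-site window
#'
#' Mean of the profile's per-base indicator over `[start, end]`: the
#' unpaired indicator for `mfe_only` profiles, the always-single-stranded
#' indicator for `intersection` profiles. The intersection value can never
#' exceed the mfe-only value for the same ensemble and window.
#'
#' @param profile A `ss_profile`.
#' @param start,end 1-based inclusive window bounds.
#' @return Fraction in `[0, 1]`.
#' @export
window_accessibility <- function(profile, start, end) {
  stopifnot(inherits(profile, "ss_profile"))
  L <- length(profile$indicator)
  if (start < 1L || end > L || start > end)
    stop("window ", start, "-", end, " outside profile of length ", L)
  mean(profile$indicator[start:end])
}

#' Self-folding assessment of an ASO
#'
#' Folds the oligonucleotide itself and flags candidates predicted to form
#' stable intramolecular structure, which can impair hybridization to the
#' target. With the builtin backend the reported energy is the
#' pseudo-energy -(number of pairs); with the `vienna` backend it is the
#' RNAfold MFE in kcal/mol.
#'
#' @param aso_sequence Oligonucleotide sequence (DNA or RNA letters).
#' @param threshold_kcal Flagging threshold: `flagged` is true iff the
#'   predicted energy is strictly below this value.
#' @param backend `"builtin"` or `"vienna"`.
#' @return A `selffold_report` list: `mfe_energy`, `dot_bracket`, `flagged`.
#' @examples
#' self_fold("GGGGAAAACCCC", threshold_kcal = -1)
#' @export
self_fold <- function(aso_sequence, threshold_kcal = -1,
                      backend = c("builtin", "vienna")) {
  backend <- match.arg(backend)
  if (!nchar(aso_sequence)) stop("empty ASO sequence")
  if (backend == "builtin") {
    p <- .fold_builtin_pairing(aso_sequence)
    top <- .new_topology(p, energy = -sum(p > 0) / 2)
    energy <- top$energy
    db <- as_dot_bracket(top)
  } else {
    exe <- Sys.which("RNAfold")
    if (!nzchar(exe))
      stop("external folding backend unavailable: RNAfold not on PATH")
    rna <- chartr("T", "U", toupper(aso_sequence))
    out <- system2(exe, args = "--noPS", input = rna, stdout = TRUE,
                   stderr = FALSE)
    line <- grep("^[.()]+\\s*\\(", out, value = TRUE)[1]
    db <- sub("\\s.*$", "", line)
    energy <- suppressWarnings(
      as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line)))
    if (!length(energy) || is.na(energy)) energy <- 0
  }
  structure(list(mfe_energy = energy, dot_bracket = db,
                 flagged = is.finite(threshold_kcal) &&
                   energy < threshold_kcal),
            class = "selffold_report")
}
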
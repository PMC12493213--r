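# Splice-site annotation. Donor (5', GT) and acceptor (3', AG) site
# probabilities are consumed as a precomputed per-position track (e.g. the
# output of a deep splice-site predictor); the predictor itself is outside
# this package. Sites called from the track are used to label ASOs whose
# binding window masks them.

#' Construct a splice-probability track
#'
#' @param length Target length (nt).
#' @param donor_prob,acceptor_prob Per-position probabilities; recycled
#'   scalars accepted.
#' @return A `splice_track` list with `length`, `donor_prob`,
#'   `acceptor_prob`.
#' @export
splice_track <- function(length, donor_prob = 0, acceptor_prob = 0) {
  length <- as.integer(length)
  dp <- rep_len(donor_prob, length); ap <- rep_len(acceptor_prob, length)
  if (any(dp < 0 | dp > 1 | ap < 0 | ap > 1))
    stop("splice probabilities must lie in [0, 1]")
  structure(list(length = length, donor_prob = dp, acceptor_prob = ap),
            class = "splice_track")
}

#' Load a splice-probability track from TSV
#'
#' Expects columns `position`, `donor_prob`, `acceptor_prob`; positions may
#' be sparse (missing positions get probability 0). An empty file yields an
#' all-zero track.
#'
#' @param path Path to the TSV file.
#' @param target_length Length of the target the track annotates.
#' @return A `splice_track` of length `target_length`.
#' @export
load_splice_track <- function(path, target_length) {
  target_length <- as.integer(target_length)
  tr <- splice_track(target_length)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) return(tr)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "donor_prob", "acceptor_prob")
  if (!all(need %in% names(tab)))
    stop("splice track must have columns: ", paste(need, collapse = ", "))
  if (!nrow(tab)) return(tr)
  pos <- as.integer(tab$position)
  if (any(pos < 1L | pos > target_length))
    stop("splice-track position outside 1..", target_length)
  if (any(tab$donor_prob < 0 | tab$donor_prob > 1 |
          tab$acceptor_prob < 0 | tab$acceptor_prob > 1))
    stop("splice probability outside [0, 1]")
  tr$donor_prob[pos] <- tab$donor_prob
  tr$acceptor_prob[pos] <- tab$acceptor_prob
  tr
}

#' Write a splice track as TSV (sparse: nonzero positions only)
#' @param track A `splice_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_splice_track <- function(track, path) {
  keep <- which(track$donor_prob > 0 | track$acceptor_prob > 0)
  tab <- data.frame(position = keep, donor_prob = track$donor_prob[keep],
                    acceptor_prob = track$acceptor_prob[keep])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call splice sites from a probability track
#'
#' Every position whose donor (resp. acceptor) probability meets the
#' threshold is emitted as a donor (resp. acceptor) site; a position can
#' yield both. Raising the threshold never increases the number of calls.
#'
#' @param track A `splice_track`.
#' @param threshold Calling threshold in (0, 1]; default 0.5, the
#'   conventional operating point for splice predictor probabilities.
#' @return Data frame of sites: `position`, `kind` (`"donor"` or
#'   `"acceptor"`), `probability`, sorted by position.
#' @export
call_splice_sites <- function(track, threshold = 0.5) {
  stopifnot(inherits(track, "splice_track"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  d <- which(track$donor_prob >= threshold)
  a <- which(track$acceptor_prob >= threshold)
  out <- rbind(
    data.frame(position = d, kind = rep("donor", length(d)),
               probability = track$donor_prob[d], stringsAsFactors = FALSE),
    data.frame(position = a, kind = rep("acceptor", length(a)),
               probability = track$acceptor_prob[a],
               stringsAsFactors = FALSE))
  out[order(out$position, out$kind), , drop = FALSE]
}

#' Label ASO records that mask splice sites
#'
#' An ASO masks a site when its binding window overlaps the site's anchor
#' position. With `min_overlap > 1` the definition tightens: the anchor
#' must be covered with at least `min_overlap` ASO bases on its shorter
#' flank (i.e. `min(anchor - start, end - anchor) + 1 >= min_overlap`), so
#' the site cannot sit at the very edge of the oligonucleotide.
#'
#' @param records ASO data frame from [generate_asos()].
#' @param sites Site data frame from [call_splice_sites()].
#' @param min_overlap Minimum flank coverage of the anchor (default 1 =
#'   plain overlap).
#' @return `records` with logical columns `masks_donor`, `masks_acceptor`.
#' @export
annotate_masking <- function(records, sites, min_overlap = 1L) {
  masks <- function(kind) {
    pos <- sites$position[sites$kind == kind]
    vapply(seq_len(nrow(records)), function(i) {
      s <- records$target_start[i]; e <- records$target_end[i]
      any(pos >= s & pos <= e &
            pmin(pos - s, e - pos) + 1L >= min_overlap)
    }, logical(1))
  }
  records$masks_donor <- if (nrow(records)) masks("donor") else logical(0)
  records$masks_acceptor <- if (nrow(records)) masks("acceptor")
                            else logical(0)
  records
}
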
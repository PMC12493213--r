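#' Base composition of an oligonucleotide
#'
#' Counts of the four bases, with U counted as T. These counts (w = A,
#' x = T/U, y = G, z = C) are the inputs of the composition-only melting
#' temperature formulas.
#'
#' @param sequence Nucleotide string (DNA or RNA letters).
#' @return A `base_composition` list with elements `w`, `x`, `y`, `z`, `n`.
#' @examples
#' base_composition("ATGC")
#' @export
base_composition <- function(sequence) {
  s <- toupper(chartr("U", "T", sequence))
  if (grepl("[^ACGT]", s)) stop("sequence contains non-ACGT characters")
  b <- strsplit(s, "")[[1]]
  comp <- structure(list(w = sum(b == "A"), x = sum(b == "T"),
                         y = sum(b == "G"), z = sum(b == "C"),
                         n = length(b)),
                    class = "base_composition")
  comp
}

#' GC content as a percentage
#'
#' @param comp A `base_composition`, or a sequence string (coerced).
#' @return `100 * (G + C) / n`.
#' @export
gc_percent <- function(comp) {
  if (is.character(comp)) comp <- base_composition(comp)
  if (comp$n == 0L) stop("empty sequence has no GC content")
  100 * (comp$y + comp$z) / comp$n
}

#' Enumerate candidate ASOs by a sliding window
#'
#' For each requested window width `k`, windows start at positions
#' `1, 1 + step, 1 + 2*step, ...` while they fit on the target; each window
#' yields one antisense candidate. Records are ordered length-major (all
#' windows of the shortest length first), then by start coordinate, and
#' serials run 1..N in that order — so with a single length and step 1 the
#' serial number equals the binding-site start coordinate.
#'
#' @param target A `target_seq`.
#' @param lengths Integer vector of window widths (nt).
#' @param step Stride between successive window starts (>= 1).
#' @param chemistry Output alphabet for the ASO sequences, see
#'   [antisense_of()].
#' @return A data frame with one row per candidate: `serial`,
#'   `target_start`, `target_end` (1-based inclusive), `length`, `sequence`
#'   (antisense, 5'->3') and `gc_percent`.
#' @examples
#' t <- target_sequence(strrep("ACGT", 25))
#' nrow(generate_asos(t, lengths = 18, step = 1)) # 83
#' @export
generate_asos <- function(target, lengths, step = 1L, chemistry = "DNA") {
  stopifnot(inherits(target, "target_seq"))
  lengths <- sort(unique(as.integer(lengths)))
  step <- as.integer(step)
  if (!length(lengths)) stop("at least one window length is required")
  if (any(lengths < 1L)) stop("window lengths must be positive")
  if (step < 1L) stop("step must be >= 1")
  too_long <- lengths[lengths > target$length]
  if (length(too_long))
    stop("window length ", too_long[1], " exceeds target length ",
         target$length)
  rows <- lapply(lengths, function(k) {
    starts <- seq.int(1L, target$length - k + 1L, by = step)
    data.frame(target_start = starts, target_end = starts + k - 1L,
               length = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # the antisense of window [s, e] is the matching substring of the
  # reverse-complemented target, so complement once rather than per window
  chemistry <- match.arg(chemistry, .CHEMISTRIES)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(target$residues)))
  L <- target$length
  out$sequence <- substring(rc, L - out$target_end + 1L,
                            L - out$target_start + 1L)
  if (chemistry != "DNA") out$sequence <- chartr("T", "U", out$sequence)
  gc_counts <- nchar(gsub("[^GCgc]", "", out$sequence))
  out$gc_percent <- 100 * gc_counts / out$length
  out <- data.frame(serial = seq_len(nrow(out)), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
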
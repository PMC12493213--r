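#' Construct a validated target sequence
#'
#' Normalizes raw nucleotide text into the internal canonical DNA alphabet:
#' whitespace and digits are stripped, letters upper-cased, and U converted
#' to T. The canonical alphabet is strictly \{A, C, G, T\}; IUPAC ambiguity
#' codes are rejected because melting temperature and folding are undefined
#' on ambiguous bases.
#'
#' @param residues Character scalar of nucleotide letters (DNA or RNA case
#'   insensitive; may contain whitespace or position digits, which are
#'   removed).
#' @param name Identifier for the sequence.
#' @param source_note Free-text provenance (e.g. an accession string).
#' @return An object of class `target_seq`: a list with elements `name`,
#'   `residues` (canonical DNA string), `length`, `mutations` (data frame
#'   with columns `position`, `ref`, `alt`) and `source_note`.
#' @examples
#' target_sequence("acgu", name = "x")
#' @export
target_sequence <- function(residues, name = "query", source_note = "") {
  stopifnot(is.character(residues), length(residues) == 1L)
  s <- toupper(gsub("[[:space:][:digit:]]", "", residues))
  s <- gsub("U", "T", s, fixed = TRUE)
  if (nchar(s) == 0L)
    stop("empty sequence for record '", name, "'")
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L)
    stop("invalid character '", substr(s, bad, bad), "' at position ", bad,
         " in record '", name, "': only A/C/G/T/U are accepted ",
         "(IUPAC ambiguity codes are rejected)")
  structure(
    list(name = name, residues = s, length = nchar(s),
         mutations = data.frame(position = integer(), ref = character(),
                                alt = character(), stringsAsFactors = FALSE),
         source_note = source_note),
    class = "target_seq")
}

#' @export
print.target_seq <- function(x, ...) {
  cat("Target sequence '", x$name, "': ", x$length, " nt\n", sep = "")
  show <- if (x$length > 60) paste0(substr(x$residues, 1, 57), "...")
          else x$residues
  cat("  ", show, "\n", sep = "")
  if (nrow(x$mutations))
    cat("  mutations applied: ",
        paste0(x$mutations$ref, x$mutations$position, x$mutations$alt,
               collapse = ", "), "\n", sep = "")
  if (nzchar(x$source_note)) cat("  source: ", x$source_note, "\n", sep = "")
  invisible(x)
}

#' Read target sequences from FASTA or bare text
#'
#' Accepts standard (multi-record, wrapped or unwrapped) FASTA. A headerless
#' file is accepted as a single anonymous record named `"query"`, mirroring
#' free-text sequence input. All records are validated and normalized by
#' [target_sequence()].
#'
#' @param path Path to the input file.
#' @return A list of `target_seq` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("empty input file: ", path)
  first <- lines[nzchar(trimws(lines))][1]
  if (!startsWith(trimws(first), ">")) {
    return(list(target_sequence(paste(lines, collapse = ""),
                                name = "query", source_note = path)))
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    target_sequence(as.character(set[[i]]), name = nm[i], source_note = path))
}

#' Write target sequences as FASTA
#'
#' @param targets A `target_seq` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(targets, path) {
  if (inherits(targets, "target_seq")) targets <- list(targets)
  set <- Biostrings::DNAStringSet(vapply(targets, `[[`, "", "residues"))
  names(set) <- vapply(targets, `[[`, "", "name")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Apply a point mutation to a target sequence
#'
#' Edits one base and records the edit in the target's mutation list. The
#' stated reference base must match the current base at that position; a
#' mismatch signals a wrong coordinate system and is an error rather than a
#' silent overwrite.
#'
#' @param target A `target_seq`.
#' @param position 1-based coordinate of the base to edit.
#' @param ref Expected current base at `position`.
#' @param alt Replacement base.
#' @return A new `target_seq` differing only at `position`.
#' @examples
#' hbb <- target_sequence("ACGTC")
#' apply_point_mutation(hbb, 5, "C", "T")
#' @export
apply_point_mutation <- function(target, position, ref, alt) {
  stopifnot(inherits(target, "target_seq"))
  position <- as.integer(position)
  ref <- toupper(chartr("U", "T", ref)); alt <- toupper(chartr("U", "T", alt))
  if (position < 1L || position > target$length)
    stop("mutation position ", position, " outside sequence 1..",
         target$length)
  if (!alt %in% c("A", "C", "G", "T"))
    stop("invalid replacement base '", alt, "'")
  cur <- substr(target$residues, position, position)
  if (cur != ref)
    stop("reference mismatch at position ", position, ": sequence has '",
         cur, "' but '", ref, "' was stated; check the coordinate system")
  out <- target
  substr(out$residues, position, position) <- alt
  out$mutations <- rbind(out$mutations,
                         data.frame(position = position, ref = ref, alt = alt,
                                    stringsAsFactors = FALSE))
  out
}

.CHEMISTRIES <- c("DNA", "RNA", "PS-RNA", "2OMe-RNA")

#' Antisense oligonucleotide for a target window
#'
#' Returns the reverse complement of the (sense-strand) window, written
#' 5'->3' in the output chemistry's alphabet. RNA-family chemistries (RNA,
#' PS-RNA, 2'OMe-RNA) emit U in place of T; backbone or sugar modifications
#' affect downstream thermodynamics only, never the letters.
#'
#' @param window Target subsequence over the canonical DNA alphabet (U is
#'   accepted and treated as T).
#' @param chemistry Output alphabet: one of `"DNA"`, `"RNA"`, `"PS-RNA"`,
#'   `"2OMe-RNA"`.
#' @return Character scalar, the ASO sequence 5'->3'.
#' @examples
#' antisense_of("ATGC", "DNA") # "GCAT"
#' antisense_of("ATGC", "RNA") # "GCAU"
#' @export
antisense_of <- function(window, chemistry = "DNA") {
  chemistry <- match.arg(chemistry, .CHEMISTRIES)
  s <- toupper(chartr("U", "T", window))
  if (grepl("[^ACGT]", s))
    stop("window contains non-ACGT characters")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (chemistry == "DNA") rc else chartr("T", "U", rc)
}
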
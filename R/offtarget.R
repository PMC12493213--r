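# Off-target screening. The builtin scanner is a deliberately brute-force,
# exhaustive ungapped search (every offset, both strands) so that it can
# serve as the ground-truth oracle; the external wrapper drives NCBI blastn
# with short-query-appropriate parameters for realistic databases.

.db_as_list <- function(db) {
  if (inherits(db, "target_seq")) db <- list(db)
  if (is.character(db)) {
    if (is.null(names(db)) || any(!nzchar(names(db))))
      stop("a character database must be named (id -> sequence)")
    db <- lapply(names(db), function(nm) target_sequence(db[[nm]], nm))
  }
  if (!length(db)) stop("empty off-target database")
  stopifnot(all(vapply(db, inherits, TRUE, "target_seq")))
  db
}

.empty_hits <- function() {
  data.frame(db_record = character(), subject_start = integer(),
             subject_end = integer(), strand = character(),
             identities = integer(), mismatches = integer(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

#' Exhaustive built-in off-target scan
#'
#' Slides the ASO across every subject at every offset on both strands and
#' reports every ungapped alignment with at most `max_mismatches`
#' mismatches. A plus-strand hit is a sense-strand site the ASO would
#' hybridize to (subject window matching the reverse complement of the
#' ASO); a minus-strand hit matches the ASO letters themselves.
#'
#' @param aso_sequence ASO sequence 5'->3' (RNA letters accepted).
#' @param db Database: named character vector, `target_seq`, or list of
#'   `target_seq`.
#' @param max_mismatches Maximum mismatches per hit (default 0).
#' @return Data frame of hits: `db_record`, `subject_start`, `subject_end`
#'   (1-based inclusive), `strand`, `identities`, `mismatches`, `evalue`
#'   (NA for the builtin scanner).
#' @export
scan_builtin <- function(aso_sequence, db, max_mismatches = 0L) {
  db <- .db_as_list(db)
  aso <- toupper(chartr("U", "T", aso_sequence))
  if (grepl("[^ACGT]", aso)) stop("ASO contains non-ACGT characters")
  k <- nchar(aso)
  site_plus <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(aso))), "")[[1]]
  site_minus <- strsplit(aso, "")[[1]]
  out <- list()
  for (rec in db) {
    L <- rec$length
    if (L < k) next
    subj <- strsplit(rec$residues, "")[[1]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") site_plus else site_minus
      for (off in 1:(L - k + 1)) {
        mm <- sum(pat != subj[off:(off + k - 1L)])
        if (mm <= max_mismatches) {
          out[[length(out) + 1L]] <- data.frame(
            db_record = rec$name, subject_start = off,
            subject_end = off + k - 1L, strand = strand,
            identities = k - mm, mismatches = mm, evalue = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(.empty_hits())
  do.call(rbind, out)
}

#' Screen ASOs with an external BLASTn installation
#'
#' Writes the ASOs (as DNA) to a temporary query FASTA, formats the
#' database with `makeblastdb`, and runs `blastn` with short-query
#' parameters (18-mer queries vanish under default megablast settings):
#' task `blastn-short`, word size 7, e-value 10, dust off. Tabular
#' (`-outfmt 6`) output is parsed into hit records. Plus-strand hits are
#' reported for subject windows matching the reverse complement of the
#' ASO, mirroring [scan_builtin()].
#'
#' @param asos Named character vector of ASO sequences (names become query
#'   ids, e.g. `ASO_5`), or the record data frame from [generate_asos()].
#' @param db_path Path to a FASTA database.
#' @param params List overriding `word_size`, `evalue`, `task`, `dust`.
#' @return Data frame of hits as in [scan_builtin()], plus `aso_serial`
#'   parsed from the query id, with `evalue` populated.
#' @export
run_external_aligner <- function(asos, db_path,
                                 params = list(word_size = 7, evalue = 10,
                                               task = "blastn-short",
                                               dust = "no")) {
  blastn <- Sys.which("blastn"); makedb <- Sys.which("makeblastdb")
  if (!nzchar(blastn) || !nzchar(makedb))
    stop("blastn/makeblastdb not found on PATH; use the builtin scanner ",
         "(scan_builtin) instead")
  if (!file.exists(db_path)) stop("database FASTA not found: ", db_path)
  if (is.data.frame(asos))
    asos <- setNames(asos$sequence, paste0("ASO_", asos$serial))
  if (is.null(names(asos))) names(asos) <- paste0("ASO_", seq_along(asos))
  qf <- tempfile(fileext = ".fa")
  writeLines(paste0(">", names(asos), "\n",
                    toupper(chartr("U", "T", asos))), qf)
  dbdir <- tempfile("blastdb"); dir.create(dbdir)
  dbpref <- file.path(dbdir, "db")
  st <- system2(makedb, c("-in", shQuote(db_path), "-dbtype", "nucl",
                          "-out", shQuote(dbpref)),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("makeblastdb failed on ", db_path)
  p <- utils::modifyList(list(word_size = 7, evalue = 10,
                              task = "blastn-short", dust = "no"), params)
  lines <- system2(blastn,
                   c("-query", shQuote(qf), "-db", shQuote(dbpref),
                     "-task", p$task, "-word_size", p$word_size,
                     "-evalue", p$evalue, "-dust", p$dust,
                     "-outfmt", "6"),
                   stdout = TRUE, stderr = FALSE)
  unlink(c(qf, dbdir), recursive = TRUE)
  if (!length(lines)) {
    h <- .empty_hits(); h$aso_serial <- integer(0); return(h)
  }
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 12L)
      stop("malformed blastn tabular line: ", ln)
    ss <- as.integer(f[9]); se <- as.integer(f[10])
    # blastn reports the subject interval reversed for minus-strand hits;
    # subject-plus orientation here means the site matches revcomp(ASO).
    strand <- if (ss <= se) "+" else "-"
    alen <- as.integer(f[4]); mism <- as.integer(f[5])
    data.frame(db_record = f[2], subject_start = min(ss, se),
               subject_end = max(ss, se), strand = strand,
               identities = alen - mism, mismatches = mism,
               evalue = as.numeric(f[11]),
               aso_serial = suppressWarnings(
                 as.integer(sub("^ASO_", "", f[1]))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count non-self off-target hits
#'
#' Excludes hits that overlap the ASO's intended binding locus on its
#' source record (the self-hit) and counts what remains.
#'
#' @param hits Hit data frame from [scan_builtin()] or
#'   [run_external_aligner()].
#' @param intended_locus List with `id` (source record name), `start`,
#'   `end` (1-based inclusive binding site), or NULL to count all hits.
#' @return Integer count of non-self hits.
#' @export
summarize_offtargets <- function(hits, intended_locus = NULL) {
  if (!nrow(hits)) return(0L)
  keep <- rep(TRUE, nrow(hits))
  if (!is.null(intended_locus)) {
    self <- hits$db_record == intended_locus$id &
      hits$subject_start <= intended_locus$end &
      hits$subject_end >= intended_locus$start
    keep <- !self
  }
  sum(keep)
}
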
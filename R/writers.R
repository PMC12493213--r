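# Report writers: TSV (full record table), BED (binding sites, 0-based
# half-open), JSON (full dataset including target summary), plus a run
# manifest for reproducibility.

.TSV_COLUMNS <- c("serial", "sequence", "length", "gc_percent",
                  "target_start", "target_end", "tm_C", "method",
                  "ss_fraction_mfe", "ss_fraction_ensemble", "masks_donor",
                  "masks_acceptor", "selffold_kcal", "selffold_flag",
                  "offtarget_count")

#' Write an ASO dataset as TSV
#'
#' Fixed column order: serial, sequence, length, gc_percent, target_start,
#' target_end, tm_C, method, ss_fraction_mfe, ss_fraction_ensemble,
#' masks_donor, masks_acceptor, selffold_kcal, selffold_flag,
#' offtarget_count. An empty dataset yields a header-only file.
#'
#' @param dataset An `aso_dataset` (or a bare record data frame).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(dataset, path) {
  rec <- if (inherits(dataset, "aso_dataset")) dataset$records else dataset
  write.table(rec[, .TSV_COLUMNS, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by [write_tsv()]
#' @param path Path to the TSV.
#' @return Record data frame.
#' @export
read_aso_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write ASO binding sites as BED
#'
#' Coordinates convert from the 1-based inclusive internal convention to
#' BED's 0-based half-open intervals. Names are `ASO_<serial>`, score is
#' the rounded GC percent, and strand is `-` (the ASO is the antisense
#' strand of the window).
#'
#' @param dataset An `aso_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(dataset, path) {
  rec <- dataset$records
  bed <- data.frame(chrom = dataset$target$name,
                    start = rec$target_start - 1L,
                    end = rec$target_end,
                    name = paste0("ASO_", rec$serial),
                    score = round(rec$gc_percent),
                    strand = "-")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the full dataset as JSON
#'
#' Mirrors the dataset: job metadata, target summary (name, length,
#' mutations, splice sites, ensemble dot-brackets and energies) and all
#' records.
#'
#' @param dataset An `aso_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_json <- function(dataset, path) {
  obj <- list(
    meta = dataset$meta,
    target = list(name = dataset$target$name,
                  length = dataset$target$length,
                  residues = dataset$target$residues,
                  mutations = dataset$target$mutations,
                  source_note = dataset$target$source_note),
    splice_sites = dataset$splice_sites,
    ensemble = list(
      backend_note = dataset$ensemble$backend_note,
      topologies = lapply(dataset$ensemble$topologies, function(t)
        list(rank = t$rank, energy = t$energy,
             dot_bracket = as_dot_bracket(t)))),
    records = dataset$records)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write all report formats plus a run manifest
#'
#' Writes `<prefix>.tsv`, `<prefix>.bed`, `<prefix>.json` and
#' `<prefix>.manifest.json` (configuration echo, package version, input
#' checksum) into `dir`.
#'
#' @param dataset An `aso_dataset`.
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix (default the job name).
#' @return Invisibly, the named vector of paths written.
#' @export
write_dataset <- function(dataset, dir, prefix = dataset$meta$job) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tsv = file.path(dir, paste0(prefix, ".tsv")),
             bed = file.path(dir, paste0(prefix, ".bed")),
             json = file.path(dir, paste0(prefix, ".json")),
             manifest = file.path(dir, paste0(prefix, ".manifest.json")))
  write_tsv(dataset, paths["tsv"])
  write_bed(dataset, paths["bed"])
  write_json(dataset, paths["json"])
  tf <- tempfile()
  writeLines(dataset$target$residues, tf)
  manifest <- list(
    package = "asodesign",
    version = as.character(utils::packageVersion("asodesign")),
    meta = dataset$meta,
    target_md5 = unname(tools::md5sum(tf)))
  unlink(tf)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
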
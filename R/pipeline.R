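# Pipeline orchestration: target processing (splice-site calling and
# structure-ensemble folding) -> window generation -> off-target screening
# -> self-folding and melting temperature -> report records.

#' Pipeline configuration
#'
#' Collects every tunable of the ASO-generation pipeline with its default.
#' Defaults follow the standard annealing conditions (50 nM duplex, 50 mM
#' Na+), an RNA/RNA duplex, exhaustive 18-mer windows, a 5-topology
#' ensemble, a 0.5 splice-calling threshold and a -1 self-fold threshold
#' (pseudo-energy units for the builtin folder).
#'
#' @param duplex_type Duplex chemistry (see [load_thermo_table()]).
#' @param lengths Window widths (nt).
#' @param step Window stride.
#' @param na_molar,duplex_molar Annealing conditions (mol/L).
#' @param tm_method `"nearest_neighbor"`, `"basic"` or `"salt_adjusted"`.
#' @param fold_backend `"builtin"` or `"vienna"`.
#' @param max_topologies Target ensemble size.
#' @param splice_track Optional path to a splice-track TSV, or a
#'   `splice_track` object.
#' @param splice_threshold Site-calling threshold.
#' @param min_overlap Masking strictness, see [annotate_masking()].
#' @param selffold_threshold Self-fold flagging threshold (kcal/mol, or
#'   pseudo-energy for the builtin folder).
#' @param db_path Optional FASTA database for off-target screening, or a
#'   database object accepted by [scan_builtin()].
#' @param max_mismatches Builtin scanner mismatch cap.
#' @param use_external Use blastn instead of the builtin scanner.
#' @param wobble Allow G-T/G-U pairs in the builtin folder.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(duplex_type = "RNA/RNA",
                            lengths = 18L, step = 1L,
                            na_molar = 0.05, duplex_molar = 5e-8,
                            tm_method = "nearest_neighbor",
                            fold_backend = "builtin",
                            max_topologies = 5L,
                            splice_track = NULL,
                            splice_threshold = 0.5,
                            min_overlap = 1L,
                            selffold_threshold = -1,
                            db_path = NULL,
                            max_mismatches = 0L,
                            use_external = FALSE,
                            wobble = FALSE) {
  .normalize_duplex_type(duplex_type)  # fail fast on unsupported chemistry
  structure(as.list(environment()), class = "pipeline_config")
}

.aso_chemistry <- function(duplex_type) {
  switch(.normalize_duplex_type(duplex_type),
         dna_dna = "DNA", rna_rna = "RNA", rna_ps = "PS-RNA",
         rna_2ome = "2OMe-RNA")
}

#' Run the full ASO design pipeline
#'
#' Stage order: (1) target processing — splice sites called from the
#' configured track and a secondary-structure ensemble folded for the
#' target; (2) sliding-window ASO generation; (3) off-target screening
#' (when a database is configured); (4) per-record self-folding and
#' melting temperature. Output ordering is deterministic (length-major,
#' then start coordinate; serials 1..N).
#'
#' @param target A `target_seq`.
#' @param config A `pipeline_config`.
#' @param quiet Suppress per-stage progress messages (stderr).
#' @return An `aso_dataset`: list with `meta` (job metadata), `target`
#'   (the `target_seq`), `splice_sites`, `ensemble` and `records` (the
#'   fully annotated ASO data frame).
#' @export
run_pipeline <- function(target, config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(target, "target_seq"),
            inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[asodesign] ", ...)

  say("target processing: ", target$name, " (", target$length, " nt)")
  track <- config$splice_track
  if (is.character(track)) track <- load_splice_track(track, target$length)
  if (is.null(track)) track <- splice_track(target$length)
  if (track$length != target$length)
    stop("splice track length ", track$length, " != target length ",
         target$length)
  sites <- call_splice_sites(track, config$splice_threshold)
  say("  ", nrow(sites), " splice site(s) called at threshold ",
      config$splice_threshold)

  ensemble <- fold_ensemble(target$residues, backend = config$fold_backend,
                            max_topologies = config$max_topologies,
                            wobble = config$wobble)
  prof_mfe <- single_stranded_profile(ensemble, "mfe_only")
  prof_int <- single_stranded_profile(ensemble, "intersection")
  say("  ensemble of ", length(ensemble$topologies), " topologies (",
      config$fold_backend, ")")

  say("generation: lengths {", paste(config$lengths, collapse = ","),
      "}, step ", config$step)
  chem <- .aso_chemistry(config$duplex_type)
  records <- generate_asos(target, config$lengths, config$step, chem)
  say("  ", nrow(records), " candidate ASO(s)")

  records <- annotate_masking(records, sites, config$min_overlap)
  records$ss_fraction_mfe <- vapply(seq_len(nrow(records)), function(i)
    window_accessibility(prof_mfe, records$target_start[i],
                         records$target_end[i]), numeric(1))
  records$ss_fraction_ensemble <- vapply(seq_len(nrow(records)), function(i)
    window_accessibility(prof_int, records$target_start[i],
                         records$target_end[i]), numeric(1))

  if (!is.null(config$db_path)) {
    say("off-target screening (",
        if (config$use_external) "blastn" else "builtin", ")")
    records$offtarget_count <- .screen_records(records, target, config)
  } else {
    records$offtarget_count <- NA_integer_
    say("off-target screening skipped: no database configured")
  }

  say("self-folding and melting temperature (", config$tm_method, ", ",
      config$duplex_type, ")")
  selffold <- lapply(records$sequence, self_fold,
                     threshold_kcal = config$selffold_threshold,
                     backend = config$fold_backend)
  records$selffold_kcal <- vapply(selffold, `[[`, 0, "mfe_energy")
  records$selffold_flag <- vapply(selffold, `[[`, TRUE, "flagged")
  tm <- lapply(seq_len(nrow(records)), function(i) {
    win <- substr(target$residues, records$target_start[i],
                  records$target_end[i])
    tm_for_window(win, config$tm_method, config$duplex_type,
                  config$na_molar, config$duplex_molar)
  })
  records$tm_C <- vapply(tm, `[[`, 0, "tm_C")
  records$method <- vapply(tm, `[[`, "", "method")

  records <- records[, c("serial", "sequence", "length", "gc_percent",
                         "target_start", "target_end", "tm_C", "method",
                         "ss_fraction_mfe", "ss_fraction_ensemble",
                         "masks_donor", "masks_acceptor", "selffold_kcal",
                         "selffold_flag", "offtarget_count")]
  structure(list(
    meta = list(job = target$name, duplex_type = config$duplex_type,
                lengths = config$lengths, step = config$step,
                tm_method = config$tm_method,
                fold_backend = config$fold_backend,
                n_records = nrow(records),
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    target = target, splice_sites = sites, ensemble = ensemble,
    records = records), class = "aso_dataset")
}

.screen_records <- function(records, target, config) {
  if (config$use_external) {
    db_path <- config$db_path
    if (!is.character(db_path))
      stop("use_external = TRUE requires db_path to be a FASTA path")
    hits <- run_external_aligner(records, db_path)
    vapply(records$serial, function(s) {
      h <- hits[!is.na(hits$aso_serial) & hits$aso_serial == s, ,
                drop = FALSE]
      i <- records$serial == s
      summarize_offtargets(h, list(id = target$name,
                                   start = records$target_start[i],
                                   end = records$target_end[i]))
    }, integer(1))
  } else {
    db <- config$db_path
    if (is.character(db) && length(db) == 1L && file.exists(db))
      db <- read_fasta(db)
    vapply(seq_len(nrow(records)), function(i) {
      hits <- scan_builtin(records$sequence[i], db, config$max_mismatches)
      summarize_offtargets(hits, list(id = target$name,
                                      start = records$target_start[i],
                                      end = records$target_end[i]))
    }, integer(1))
  }
}

#' @export
print.aso_dataset <- function(x, ...) {
  cat("ASO dataset '", x$meta$job, "': ", nrow(x$records),
      " records, duplex ", x$meta$duplex_type, ", lengths {",
      paste(x$meta$lengths, collapse = ","), "}, step ", x$meta$step,
      "\n", sep = "")
  cat("  splice sites: ", nrow(x$splice_sites), "; ensemble: ",
      length(x$ensemble$topologies), " topologies\n", sep = "")
  invisible(x)
}
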
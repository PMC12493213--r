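# Melting-temperature methods for ASO/target duplexes. Three methods are
# provided: the nearest-neighbor (NN) model for duplexes of 8 nt or longer
# (chemistry-aware via per-duplex thermodynamic tables), the composition-only
# "basic" method, and its salt-adjusted variant. Standard annealing
# conditions throughout: 50 nM duplex, 50 mM Na+, pH 7.0.

.GAS_CONSTANT <- 1.987   # cal / (mol K)

.DUPLEX_TYPES <- c(dna_dna = "dna_dna.tsv",
                   rna_rna = "rna_rna.tsv",
                   rna_ps = "rna_ps_synthetic.tsv",
                   rna_2ome = "rna_2ome_synthetic.tsv")

.normalize_duplex_type <- function(chemistry) {
  key <- tolower(gsub("[/' _’-]", "", chemistry))
  map <- c(dnadna = "dna_dna", rnarna = "rna_rna",
           rnapsrna = "rna_ps", rnaps = "rna_ps",
           rna2omerna = "rna_2ome", rna2ome = "rna_2ome")
  if (!key %in% names(map))
    stop("unsupported duplex chemistry '", chemistry, "': no published ",
         "nearest-neighbor parameters are available for it (supported: ",
         "DNA/DNA, RNA/RNA, RNA/PS-RNA, RNA/2OMe-RNA)")
  unname(map[key])
}

#' Load the nearest-neighbor thermodynamic table for a duplex chemistry
#'
#' Tables ship with the package as delimited text under
#' `inst/extdata/thermo/`, one per duplex type, each carrying a provenance
#' comment block. Doublet keys are read 5'->3' on the target strand (T
#' denotes U for RNA strands); all 16 doublets are present, with dH < 0
#' kcal/mol and dS < 0 cal/(mol K) for every stacking step.
#'
#' @param chemistry Duplex type: `"DNA/DNA"`, `"RNA/RNA"`, `"RNA/PS-RNA"`
#'   or `"RNA/2OMe-RNA"` (compact forms `dna_dna`, `rna_rna`, `rna_ps`,
#'   `rna_2ome` also accepted). Anything else (e.g. LNA) is an error: no
#'   published parameters.
#' @return A `thermo_table` list: `chemistry`, `doublet_params` (data frame
#'   keyed by `doublet`), `init_dH`, `init_dS` (initiation corrections in the
#'   table's convention; the fixed -3.4 kcal/mol helix-initiation correction
#'   of the NN equation is applied in [tm_nearest_neighbor()], not here) and
#'   `provenance`.
#' @export
load_thermo_table <- function(chemistry) {
  type <- .normalize_duplex_type(chemistry)
  path <- system.file("extdata", "thermo", .DUPLEX_TYPES[[type]],
                      package = "asodesign", mustWork = TRUE)
  prov <- grep("^#", readLines(path), value = TRUE)
  prov <- paste(sub("^#\\s?", "", prov), collapse = " ")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 16L, all(tab$dH_kcal < 0), all(tab$dS_cal < 0))
  structure(list(chemistry = type, doublet_params = tab,
                 init_dH = 0, init_dS = 0, provenance = prov),
            class = "thermo_table")
}

#' Nearest-neighbor enthalpy and entropy sums for a target window
#'
#' Sums dH and dS over the n-1 overlapping doublets of the window (read
#' 5'->3' on the target strand, which is also the table key for
#' heteroduplexes: the chemical modification selects the table, never the
#' key), plus the table's initiation terms.
#'
#' @param target_window Target-strand sequence, length >= 2.
#' @param table A `thermo_table` from [load_thermo_table()].
#' @return List with `dH_sum` (kcal/mol) and `dS_sum` (cal/(mol K)), both
#'   negative for stabilizing duplexes.
#' @export
nn_sums <- function(target_window, table) {
  stopifnot(inherits(table, "thermo_table"))
  s <- toupper(chartr("U", "T", target_window))
  n <- nchar(s)
  if (n < 2L) stop("nearest-neighbor sums need at least 2 nucleotides")
  if (grepl("[^ACGT]", s)) stop("window contains non-ACGT characters")
  doublets <- substring(s, 1:(n - 1L), 2:n)
  p <- table$doublet_params
  idx <- match(doublets, p$doublet)
  list(dH_sum = sum(p$dH_kcal[idx]) + table$init_dH,
       dS_sum = sum(p$dS_cal[idx]) + table$init_dS)
}

#' Melting temperature by the nearest-neighbor model
#'
#' For duplexes of 8 nt or longer. With `|dH|` and `|dS|` the magnitudes of
#' the doublet sums (kcal/mol and cal/(mol K)):
#'
#' \deqn{T_m = \frac{1000\,(|\Delta H| - 3.4)}{|\Delta S| + R\,\ln(1/[duplex])}
#'       - 272.9 + 16.6\,\log_{10}[Na^+]}
#'
#' with R = 1.987 cal/(mol K), a fixed 3.4 kcal/mol helix-initiation
#' correction, and the natural log in the concentration term. Assumes pH
#' 7.0. Windows shorter than 8 nt are outside the model's stated domain and
#' raise an error directing the caller to [tm_basic()]; there is no silent
#' fallback.
#'
#' @param target_window Target-strand binding site, 5'->3' (>= 8 nt).
#' @param chemistry Duplex type, see [load_thermo_table()]. A pre-loaded
#'   `thermo_table` is also accepted.
#' @param na_molar Sodium concentration, mol/L (default 0.05).
#' @param duplex_molar Duplex (oligonucleotide) concentration, mol/L
#'   (default 5e-8, i.e. 50 nM).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' tm_nearest_neighbor("ATGCATGCATGCATGCAT", "DNA/DNA")
#' @export
tm_nearest_neighbor <- function(target_window, chemistry,
                                na_molar = 0.05, duplex_molar = 5e-8) {
  if (na_molar <= 0 || duplex_molar <= 0)
    stop("na_molar and duplex_molar must be positive")
  n <- nchar(target_window)
  if (n < 8L)
    stop("nearest-neighbor model applies to duplexes of 8 nt or longer ",
         "(got ", n, " nt); use tm_basic()/tm_salt_adjusted() for shorter ",
         "oligonucleotides")
  table <- if (inherits(chemistry, "thermo_table")) chemistry
           else load_thermo_table(chemistry)
  s <- nn_sums(target_window, table)
  dh <- -s$dH_sum   # magnitudes, kcal/mol
  ds <- -s$dS_sum   # magnitudes, cal/(mol K)
  1000 * (dh - 3.4) / (ds + .GAS_CONSTANT * log(1 / duplex_molar)) -
    272.9 + 16.6 * log10(na_molar)
}

.as_composition <- function(x) {
  if (inherits(x, "base_composition")) x else base_composition(x)
}

#' Melting temperature by the basic (composition-only) method
#'
#' The Wallace rule for oligonucleotides of 13 nt or fewer,
#' `Tm = 2(A+T) + 4(G+C)`, and for 14 nt or longer
#' `Tm = 64.9 + 41*(G+C-16.4)/n`. Both assume 50 nM primer, 50 mM Na+ and
#' pH 7.0. Reads only the base composition, so any permutation of the
#' sequence gives the same value.
#'
#' @param x A sequence string or a `base_composition`.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' tm_basic("ATGC")            # 12
#' tm_basic(strrep("A", 13))   # 26
#' @export
tm_basic <- function(x) {
  c <- .as_composition(x)
  if (c$n < 1L) stop("empty sequence")
  if (c$n <= 13L) {
    (c$w + c$x) * 2 + (c$y + c$z) * 4
  } else {
    64.9 + 41.0 * (c$y + c$z - 16.4) / c$n
  }
}

#' Melting temperature by the salt-adjusted basic method
#'
#' DNA, <= 13 nt: the Wallace rule plus `-16.6 log10(0.05) + 16.6
#' log10([Na+])`, so at 50 mM Na+ the value equals [tm_basic()] exactly.
#' DNA, >= 14 nt: `Tm = 100.5 + 41 r - 820/n + 16.6 log10([Na+])` with
#' the GC fraction r = (G+C)/n. RNA (any length):
#' `Tm = 79.8 + 18.5 log10([Na+]) + 58.4 r + 11.8 r^2 - 820/n`.
#' All assume 50 nM primer and pH 7.0.
#'
#' @param x A sequence string or a `base_composition`.
#' @param kind `"DNA"` or `"RNA"` (selects the equation family).
#' @param na_molar Sodium concentration, mol/L.
#' @return Melting temperature in degrees Celsius.
#' @export
tm_salt_adjusted <- function(x, kind = c("DNA", "RNA"), na_molar = 0.05) {
  kind <- match.arg(kind)
  if (na_molar <= 0) stop("na_molar must be positive")
  c <- .as_composition(x)
  if (c$n < 1L) stop("empty sequence")
  r <- (c$y + c$z) / c$n
  if (kind == "DNA") {
    if (c$n <= 13L) {
      # salt term computed as one difference so it cancels exactly (to the
      # last bit) at the 50 mM reference concentration
      salt <- 16.6 * log10(na_molar) - 16.6 * log10(0.05)
      (c$w + c$x) * 2 + (c$y + c$z) * 4 + salt
    } else {
      100.5 + 41 * r - 820 / c$n + 16.6 * log10(na_molar)
    }
  } else {
    79.8 + 18.5 * log10(na_molar) + 58.4 * r + 11.8 * r^2 - 820 / c$n
  }
}

#' Melting temperature dispatcher used by the pipeline
#'
#' Applies the configured method to one target window. For the
#' nearest-neighbor method on windows shorter than 8 nt the pipeline falls
#' back to the basic method and labels the record, rather than silently
#' extending the NN model below its domain.
#'
#' @param target_window Target-strand binding site sequence.
#' @param method One of `"nearest_neighbor"`, `"basic"`, `"salt_adjusted"`.
#' @param chemistry Duplex type (used by the NN method; also selects DNA vs
#'   RNA equations for `salt_adjusted`).
#' @param na_molar,duplex_molar Annealing conditions.
#' @return List with `tm_C` and `method` (the method actually used, e.g.
#'   `"basic(fallback)"`).
#' @export
tm_for_window <- function(target_window,
                          method = c("nearest_neighbor", "basic",
                                     "salt_adjusted"),
                          chemistry = "RNA/RNA",
                          na_molar = 0.05, duplex_molar = 5e-8) {
  method <- match.arg(method)
  if (method == "nearest_neighbor") {
    if (nchar(target_window) >= 8L)
      return(list(tm_C = tm_nearest_neighbor(target_window, chemistry,
                                             na_molar, duplex_molar),
                  method = "nearest_neighbor"))
    return(list(tm_C = tm_basic(target_window), method = "basic(fallback)"))
  }
  if (method == "basic")
    return(list(tm_C = tm_basic(target_window), method = "basic"))
  kind <- if (.normalize_duplex_type(chemistry) == "dna_dna") "DNA" else "RNA"
  list(tm_C = tm_salt_adjusted(target_window, kind, na_molar),
       method = "salt_adjusted")
}
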
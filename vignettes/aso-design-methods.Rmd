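---
title: "Models and methods behind asodesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind asodesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asodesign)
```

# The design problem

An antisense oligonucleotide (ASO) is a short nucleic acid, typically
15–25 nt and often chemically modified, that hybridizes to a target RNA by
Watson–Crick complementarity and thereby modulates splicing, translation
or transcript stability. Designing an active ASO against a given
pre-mRNA is a screening problem: the space of candidate binding sites is
the set of all windows over the target, and the candidates differ in
properties that are cheap to compute — duplex stability, accessibility of
the binding site within the target's secondary structure, whether the
window occludes a splice signal, the oligonucleotide's own propensity to
fold on itself, and its specificity against the rest of the
transcriptome. `asodesign` computes exactly these properties for an
exhaustive (or strided) enumeration of windows, so that candidate
selection becomes a filtering exercise over one table.

The pipeline runs its stages in a fixed order: the target is processed
first (splice-site calling from a probability track, then folding into a
structure ensemble), windows are enumerated, off-targets are screened when
a database is configured, and finally self-folding and hybridization
thermodynamics are computed per candidate.

# Coordinates and serials

All core coordinates are 1-based with inclusive ends, on the input strand
as given; BED output converts to 0-based half-open intervals. Windows are
enumerated length-major (all windows of the shortest requested length
first), then by start position, and serial identifiers run 1..N in that
order. A deliberate consequence: with a single length and step 1, a
candidate's serial number *is* its binding-site start coordinate, which
makes serials meaningful when discussing specific loci (an 18-mer with
serial 1187 binds 1187–1204 and covers position 1197).

The internal alphabet is canonical DNA: U is normalized to T on input and
restored on output for the RNA-family chemistries. This keeps a single
code path for complementation, folding and window arithmetic while
allowing either DNA or RNA input text. IUPAC ambiguity codes are rejected
outright — melting temperature and folding are undefined on ambiguous
bases, and a fail-fast error (naming the character and its position) beats
a silently degraded annotation.

# Melting temperature

Three methods are implemented, mirroring established oligo-calculator
practice. Standard annealing conditions are 50 nM duplex, 50 mM Na⁺,
pH 7.0; these are the defaults everywhere.

**Nearest-neighbor model** (preferred; duplexes ≥ 8 nt). With ΔH_d and
ΔS_d the per-doublet stacking parameters summed over the n−1 doublets of
the binding site,

$$T_m = \frac{1000\,(|\sum\Delta H_d| - 3.4)}
             {|\sum\Delta S_d| + R\,\ln(1/[\mathrm{duplex}])}
        - 272.9 + 16.6\log_{10}[\mathrm{Na^+}]$$

with R = 1.987 cal·mol⁻¹·K⁻¹, ΔH in kcal/mol, ΔS in cal/(mol·K), a fixed
3.4 kcal/mol helix-initiation correction, and the natural logarithm in the
concentration term. The tables store ΔH and ΔS as negative (stabilizing)
quantities; the equation consumes their magnitudes, which is the
convention of the calculator lineage this formula comes from. Windows
shorter than 8 nt are outside the model's stated domain: the low-level
function refuses them, and the pipeline falls back to the basic method
while labelling the record `basic(fallback)` — explicit over implicit.

**Basic method** (composition only). For n ≤ 13 the Wallace rule
Tm = 2(A+T) + 4(G+C); for n ≥ 14, Tm = 64.9 + 41·(G+C − 16.4)/n. Because
only the composition enters, any permutation of a sequence has the same
basic Tm (the nearest-neighbor value, by contrast, depends on the
arrangement). The n ≥ 14 form is bounded above by 64.9 + 41 ≈ 105.9 °C.

**Salt-adjusted method.** For DNA with n ≤ 13 the Wallace value plus
16.6·log₁₀([Na⁺]) − 16.6·log₁₀(0.05); the correction is computed as a
single difference so that at the 50 mM reference it cancels *exactly*, to
the last bit — a property the test suite asserts over random sequences.
For DNA with n ≥ 14, Tm = 100.5 + 41·r − 820/n + 16.6·log₁₀([Na⁺]) with
r the GC fraction; for RNA (any length),
Tm = 79.8 + 18.5·log₁₀([Na⁺]) + 58.4·r + 11.8·r² − 820/n. No short-RNA
variant of the salt-adjusted family is published, so the RNA form is
applied at all lengths; users screening very short RNA oligos should
prefer the basic method.

## Thermodynamic tables and chemistries

Four duplex chemistries are supported, each with its own 16-doublet table
shipped as commented, delimited text under `inst/extdata/thermo/` (unit
statement and citation in the header; `load_thermo_table()` surfaces the
provenance string):

* **DNA/DNA** — Breslauer et al. (1986), the parameter set of the classic
  nearest-neighbor calculator this module follows.
* **RNA/RNA** — Xia et al. (1998) Watson–Crick stacks.
* **RNA/PS-RNA** and **RNA/2'OMe-RNA** — *synthetic tables*, clearly
  labelled as such in their filenames and headers. Measured per-doublet
  parameters for these heteroduplexes were not available for
  transcription, so the shipped tables derive from the Xia RNA/RNA stacks
  with a uniform per-step free-energy increment: +0.30 kcal/mol for
  phosphorothioate (destabilizing, consistent with the commonly reported
  ~0.5 °C Tm loss per PS linkage) and −0.40 kcal/mol for 2'-O-methyl
  (stabilizing, consistent with published per-residue increments). The
  increments are applied to ΔH with ΔS unchanged. Anyone with access to
  measured tables can drop them in without code changes; every test and
  property in the package is independent of the particular values beyond
  the invariants (16 doublets, all stacks stabilizing).

The doublet lookup key is always the unmodified target strand read
5'→3'; the chemical modification selects the table and never alters the
key, so hetero- and homoduplexes share one code path. Chemistries without
published parameters (LNA, PMO, PNA, 2'MOE) raise an explicit
"no published parameters" error rather than guessing.

Out of scope by design: pH corrections, Mg²⁺/divalent corrections,
mismatch and dangling-end parameters, and mixed-chemistry (gapmer)
thermodynamics.

# Target structure and accessibility

An ASO can only nucleate hybridization where the target is single
stranded, so each candidate is annotated with the fraction of its binding
site predicted unpaired. Two views are computed from a structure
ensemble:

* `ss_fraction_mfe` — unpaired fraction in the rank-1 (lowest-energy)
  topology alone;
* `ss_fraction_ensemble` — the fraction of window bases that are unpaired
  in *every* topology of the ensemble ("always single-stranded"), obtained
  by superimposing the topologies. This is necessarily ≤ the MFE-only
  value, and the suite asserts that inequality everywhere.

The builtin folder is a maximum-pairing dynamic program (Nussinov-style):
Watson–Crick pairs (optionally G·T/G·U wobble), minimum hairpin loop of
3 nt, nested structures only, with a deterministic leftmost-pairing
tie-break so identical inputs always give identical structures. Its
reported "energies" are the negated pair counts — a pseudo-energy, clearly
labelled in the ensemble's `backend_note`, chosen instead of fabricating
thermodynamic weights the model does not have. Suboptimal topologies are
generated deterministically by re-folding with successive rank-1 paired
positions forced single-stranded, deduplicating, and keeping the best
`max_topologies` (default 5; a small default bounds runtime on multi-kb
targets and is configurable). On every sequence up to 12 nt the builtin
folder provably attains the maximum of an exhaustive enumeration of all
valid pairings — the test suite checks 500 random cases per run.

For thermodynamically grounded structures the `vienna` backend shells out
to the ViennaRNA tools (`RNAsubopt` for ensembles, `RNAfold` for
self-folding) and parses their dot-bracket output; energies are then real
kcal/mol. The backend is never substituted silently: if the executables
are absent, the error says so. Dot-bracket and CT files from any external
folder can also be ingested directly (`parse_dot_bracket()`,
`parse_ct()`). Folding is capped at 9000 nt; pseudoknots and RNA-binding
protein occupancy are not modelled.

Self-folding of each candidate uses the same machinery: the
oligonucleotide is folded alone and flagged when its predicted energy
falls below `selffold_threshold` (default −1; in pseudo-energy units under
the builtin folder, i.e. "more than one self-pairing worth of structure",
and in kcal/mol under `vienna`).

# Splice sites and masking

Splice-site prediction is consumed, not performed: the pipeline reads a
per-position track of donor and acceptor probabilities (TSV: `position`,
`donor_prob`, `acceptor_prob`, sparse rows allowed), as produced by any
modern splice predictor run on the same coordinates. Sites are called
where a probability meets the threshold (default 0.5, the conventional
operating point for such predictors; raising the threshold can only
shrink the call set). A candidate `masks_donor`/`masks_acceptor` when its
window covers the site's anchor position. The optional `min_overlap`
parameter tightens this to require the anchor be at least that many bases
from the window edge, for users who consider edge-grazing oligos unlikely
to occlude the signal; the default (1) is plain overlap, matching the
usual reading of "ASOs overlapping the site". Under exhaustive
generation, exactly `min(k, pos, L − pos + 1, L − k + 1)` windows mask a
site — an identity the suite verifies by brute force.

# Off-target screening

Two interchangeable screens report hits of a candidate elsewhere than its
intended locus. The builtin scanner is an intentionally brute-force,
exhaustive ungapped search: every subject, every offset, both strands,
every alignment with at most `max_mismatches` mismatches. Plus-strand
hits are sense sites the ASO would actually hybridize to (subject window
equal to the reverse complement of the ASO); minus-strand hits match the
ASO letters themselves. Because it is exhaustive by construction it
doubles as the ground truth for the external wrapper, which drives NCBI
`blastn` with short-query-appropriate parameters (task `blastn-short`,
word size 7, e-value 10, dust off — 18-mer queries vanish under default
megablast settings). Hits overlapping the candidate's own locus on its
source record are excluded before counting (`summarize_offtargets()`);
whether other transcripts of the same gene should count as off-target is
left to the user's choice of database.

# Synthetic data

`make_fixture()` generates the study material for the test suite:
random-composition targets with, on request, a planted inverted repeat
(GC-rich arms flanking an A/T loop, guaranteed foldable), planted GT/AG
splice motifs with matching track probabilities, and decoy databases
carrying exact or near-exact copies of chosen target windows. All
randomness flows from one `set.seed(seed)` call, and identical seeds give
byte-identical outputs. These fixtures emulate the *features the pipeline
keys on*, not real transcripts: real pre-mRNAs have biased composition,
splice-site context beyond the GT/AG dinucleotide, and structure far
richer than one planted hairpin — so green tests demonstrate correctness
of the computations, not biological performance of any particular design.

`synthetic_hbb_example()` is a deterministic stand-in for the
β-thalassemia splice-correction scenario: a 1708-nt target with an
HBB-like exon/intron layout (intron 2 of 850 nt starting at position
545), in which the IVS2-654 C>T edit (target coordinate 1198) converts a
GC into a GT donor dinucleotide anchored at G1197 — the same mechanism by
which the real mutation activates a cryptic 5' splice site in HBB
intron 2. Running the exhaustive 18-mer pipeline on the mutated stand-in
yields 1691 candidates, of which the 18 windows starting at 1180–1197
mask the cryptic donor; serial 1187 (binding 1187–1204) sits in the
middle of that set, reproducing the geometry under which a
splice-correcting ASO is recovered by donor-masking filtration. The
stand-in reproduces geometry only, never HBB's residues; the real region
can be fetched with `fetch_ensembl_region("GRCh38:11:5225414:5227121:-1")`
when a network is available.

# Numerical and design choices

* Defaults: Na⁺ 0.05 M, duplex 5×10⁻⁸ M, threshold 0.5 for splice calls,
  ensemble of 5 topologies, self-fold threshold −1, blastn word size 7.
* Multi-length enumeration is length-major; any fixed deterministic order
  would do, but one had to be chosen and documented for serials to be
  stable.
* The `[duplex]` concentration in the NN equation is the oligonucleotide
  concentration as entered (the calculator convention followed here);
  users comparing against tools that use total-strand/4 conventions will
  see small constant offsets.
* Mutation application refuses a reference-base mismatch instead of
  overwriting, since a mismatch almost always means the caller's
  coordinates are off by one or on the wrong strand.
* Ties in the folder's traceback resolve to the leftmost partner;
  profiles are invariant under topology reordering by construction.
* Problem sizes in the shipped tests: 500 folding-oracle sequences of
  4–12 nt, 1000 salt-cancellation sequences, 200 generation triples,
  50 NN oracle sequences per chemistry, one full 1708-nt pipeline run —
  sizes at which every oracle is exact and a complete run stays
  comfortably interactive.

# Known limitations

The accessibility model ranks sites by pairing counts, not free energies,
unless the ViennaRNA backend is used; PS/2'OMe tables are uniform-shift
stand-ins pending measured parameters; no RBP competition, no gapmers, no
toxicity or machine-learned off-target scoring; splice-site probabilities
must be supplied externally. These mirror the boundaries of the screening
approach itself: the output is a ranked, annotated candidate table, not a
guarantee of biological activity.
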
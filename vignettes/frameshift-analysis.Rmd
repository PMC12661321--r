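---
title: "Detecting and quantifying +1 ribosomal frameshifting with ribofs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying +1 ribosomal frameshifting with ribofs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In *Saccharomyces cerevisiae* a handful of genes are expressed through +1
programmed ribosomal frameshifting: an elongating ribosome slips one
nucleotide forward at a defined heptameric signal and continues in the +1
reading frame, producing a trans-frame protein whose N- and C-terminal parts
are encoded in different frames. The known efficient signals are seven
nucleotides spanning the P-site codon and the two overlapping A-site codons:

| name | heptamer (DNA) | P-site re-pairing with the +1 codon |
|------|----------------|-------------------------------------|
| Ty1  | `CTT AGG C`    | yes (CUU -> UUA, both Leu-tRNA)      |
| EST3 | `CTT AGT T`    | yes                                 |
| Ty3  | `GCG AGT T`    | no                                  |
| OAZ1 | `GCG TGA C`    | no (0-frame A-site is a stop)       |

`ribofs` implements the computational side of characterising such loci:
finding heptamers and building dual-ORF gene models, estimating
frameshifting efficiency from ribosome-profiling P-site counts and from
dual-luciferase reporters, scanning codon alignments for depressed
synonymous substitution rates (the footprint of an overlapping RNA element),
and detecting a stimulatory stem-loop upstream of the shift site together
with its chemical-probing support. Every input can be generated by the
package's simulators with known ground truth, so the whole pipeline is
testable without any external data.

## Coordinates and sequence conventions

All coordinates are 1-based closed intervals, the R/Bioconductor convention
(GFF3 needs no conversion; `Biostrings`/`GenomicRanges` interoperate
directly). RNA input is normalised to DNA (U -> T) on read so a single
alphabet is used internally; `N` is accepted and never matches a motif; any
other character is an error. The stop set is TAA/TAG/TGA (standard nuclear
code — these are nuclear genes).

## Dual-ORF gene models and frame fusion

`scan_heptamers()` reports every motif occurrence whose first base is in
frame 0 relative to the anchor ATG; out-of-frame occurrences cannot act as
P-site codons and are excluded. When several heptamers occur in one ORF each
yields its own candidate model — scanning is exhaustive and no attempt is
made to pick "the" site, since downstream evidence (footprint density,
conservation) is what discriminates. No distance filter between the heptamer
and the 0-frame stop is imposed; natural sites sit both close to the start
and close to the stop, so any such filter belongs to the caller.

`build_dual_orf_model()` extends the site into a gene model: the 0-frame ORF
ends at the first in-frame stop at/after the heptamer (for the OAZ1-type
signal that stop is the TGA *inside* the heptamer), and the +1 ORF runs in
codon steps from heptamer base 5 to the first +1-frame stop. Missing either
boundary is an "open model" error naming the missing stop.

`fuse_frames()` joins the two frames by deleting the single nucleotide at
heptamer base 4 — for Ty1 this is the documented `CTTAGGC -> CTTGGC`
spelling used to build in-frame alignments against non-frameshifting
orthologs. The rule is applied uniformly to all four motifs (e.g.
`GCGTGAC -> GCGGAC`): deleting base 4 is the unique one-base deletion that
preserves both the P-site codon and the +1 A-site codon for every motif, and
it reproduces the printed Ty1 case. By construction
`trans_frame_protein()` (translation of the fused CDS) equals the 0-frame
peptide through the P-site codon concatenated with the +1-ORF peptide; the
package tests this identity on hundreds of simulated genes per run.

## Frameshifting efficiency from ribosome profiling

The estimator is a codon-normalised density ratio: with footprint sums
$R_0, R_1$ over the 0-frame and +1 regions of $c_0, c_1$ codons,

$$\mathrm{FS\%} = 100 \times \frac{R_1 / c_1}{R_0 / c_0}.$$

Region 0 runs from the start codon to the heptamer P-site codon (the part of
the ORF every ribosome traverses); region 1 from the first +1 codon entirely
past the 0-frame stop to the +1 stop (the part only frameshifted ribosomes
reach). Both regions are trimmed by `trim_codons` (default 1) at each end
because initiation and termination codons carry well-known footprint peaks;
the default is deliberately mild and configurable. Two counting modes are
provided because "footprints per frame, normalised by codons" admits two
readings: `region` (default) counts everything inside each region, `frame`
counts only positions in the region's own reading frame. They coincide
exactly when P-site assignment is perfectly frame-accurate and differ under
frame noise; neither is asserted to be "the" published pipeline. A region-0
sum of zero yields an *undefined* estimate (flagged, never 0): no signal is
not the same as no frameshifting.

`aggregate_fs()` summarises estimates across datasets in box-plot
convention: quartiles by linear interpolation (`quantile` type 7 — the
convention is stated because none is universal), whiskers to the most
extreme values within 1.5 IQR. `assign_psite()` converts raw 5'-end
positions to P-sites with a per-read-length offset table (default 12 nt for
28–30-mers, the usual yeast monosome offsets; fully overridable).

## Reporter efficiencies

`fs_from_luciferase()` computes the ratio of firefly/Renilla ratios between
test and in-frame control constructs, times 100. The default
`mean_of_ratios` averages per-well ratios within each class first, matching
the per-well structure of plate assays (n = 8 wells per class is the typical
design); `ratio_of_means` pools signal first and is provided because the
choice is not standardised. The SD is first-order error propagation of the
two class-level coefficients of variation,
$\mathrm{sd} = \mathrm{FS\%}\sqrt{cv_t^2 + cv_c^2}$, with a bootstrap
alternative. Efficiency is exactly invariant to rescaling all readings,
which is what makes ratios of ratios comparable across instruments.
`context_fold_change()` expresses context effects (stimulators and
attenuators) as a ratio of two such efficiencies.

## Synonymous-site conservation scan

An RNA element overlapping a coding region constrains synonymous sites, so a
window of depressed synonymous substitution is evidence for one. The scan
classifies every (row, column) of a codon alignment against the reference as
identical / synonymous / non-synonymous / gap, then slides a window
(default 17 codons, step 1; truncated edge windows are skipped) counting
observed synonymous calls. The null expectation is the alignment-wide
synonymous rate among *eligible* slots — both codons ungapped and encoding
the same amino acid, i.e. exactly the slots that could have differed
synonymously — and each window is tested with a one-sided binomial lower
tail $P(X \le \mathrm{obs})$.

This is a deliberate simplification of phylogeny-aware scans: the null
ignores tree structure and shared ancestry, so obs/exp ratios and p-values
are comparable in *kind*, not in value, to tools built on a phylogenetic
neutral model. The binomial tail is conservative (discreteness pushes
p-values up), which the calibration test quantifies: under the null the
fraction of windows with p < 0.05 sits near 0.04–0.05. Raw p-values are
reported by default (the natural display is a p-per-window track against a
0.05 line); Benjamini–Hochberg adjustment is available via `p_adjust =
"BH"`. When the alignment contains no synonymous variation at all the null
rate is 0 and every window is flagged undefined rather than degenerately
"significant at p = 1".

`back_translate_alignment()` produces codon alignments from a gapped protein
alignment plus per-row CDSs, verifying that each CDS translates to its row
and threading source codons through the gaps — the standard
protein-guided codon alignment construction.

## Upstream stem-loop detection and DMS support

`find_best_hairpin()` searches a window (≤ 200 nt) for the best *single*
hairpin: one helix of nested pairs with at most two internal loops/bulges of
at most 3 nt each, closing a terminal loop of at least 3 nt. Scores are
ordinal stacking scores — +2 per Watson–Crick pair, +1 per G·U wobble, −2
per helix interruption, −3 to open — **not** free energies: the question the
analysis asks is "is there a credible hairpin here and where is its base",
which needs a ranking, not a ΔG. Nothing above 0 means no hairpin. The
dynamic program tracks (score, helix length, 5'-position) for tie-breaking
and is verified against exhaustive enumeration of all legal hairpins on
short windows. One asymmetry is worth knowing: with wobble pairs enabled the
reverse complement of a hairpin is *not* guaranteed an equal-scoring hairpin
(G·U maps to A·C, which does not pair); with `allow_gu = FALSE` the fold is
exactly mirror-symmetric and the test suite checks that.

`spacer_to_site()` measures the nucleotides between the hairpin base and the
heptamer (the natural stimulator geometry is a 6-nt, two-codon spacer; codon
insertions between the two widen it codon by codon).
`dms_consistency()` scores agreement with dimethyl-sulfate probing, which
modifies unpaired A and C: the score is the probability that a random
unpaired A/C in the hairpin span is more reactive than a random paired A/C
(ties 0.5) — a rank statistic, chosen because DMS-seq scales vary between
experiments and any threshold on raw reactivity would not transfer. With
exponential reactivities of mean ratio $s$ the expected score is $s/(s+1)$:
0.5 when exchangeable, 2/3 at $s = 2$, approaching 1 only for strong
separation. Judging structure support therefore means comparing the score
against this scale, not against an absolute cut-off.

## The simulators

Each generator emulates one data class at the level the estimators actually
see, with every true parameter recorded:

- `simulate_gene()` plants exactly one heptamer in a random CDS with
  requested ORF spans, rejection-sampling away accidental in-frame motifs
  and stray stops, so scan + model building always round-trip.
- `simulate_ribo_profile()` treats frameshifting as a branch at the
  heptamer: all ribosomes traverse the ORF to the P-site codon, a fraction
  θ continues into the +1 ORF, the rest finishes frame 0. Counts are
  per-codon Poisson with gamma codon rates (shape 5 by default, a mid-range
  codon-to-codon variability); P-sites land in-frame with probability
  `frame_fidelity` (default 0.9, a typical fraction of frame-supporting
  footprints), else ±1 nt. It does not model UTR ramps, ligation bias,
  multi-mapping or stalling, so passing recovery tests demonstrates
  estimator correctness under idealised periodicity, not robustness to
  every library artefact.
- `simulate_codon_alignment()` mutates each codon of each row independently:
  synonymous with probability `syn_rate` (default 0.3, a plausible
  codon-level synonymous divergence for related budding-yeast species),
  reduced by `constraint_factor` inside a designated window; non-synonymous
  single-nucleotide neighbours at a low independent rate (0.02). There is no
  phylogeny — rows are independent draws — which exactly matches the
  scan's pairwise null and is exactly what real orthologs violate; the
  calibration result should be read with that in mind.
- `simulate_luciferase()` draws lognormal replicate noise (σ = 0.1 by
  default, i.e. ~10% well-to-well CV) around class ratios `base_ratio` and
  `base_ratio × θ`. Because both classes carry the same multiplicative
  noise model, the ratio-of-ratios estimator is mean-unbiased to first
  order.
- `simulate_dms()` draws exponential reactivities (mean `dms_snr` unpaired
  vs 1 paired) on A/C and NaN elsewhere.

All generators are bit-reproducible given a seed, and `simulate_inputs()`
writes a complete input bundle (FASTA, GFF3, counts TSV, luciferase TSV,
codon-alignment FASTA, reactivity TSV, manifest JSON) for end-to-end runs.

## Pipeline

`run_pipeline()` validates its configuration (paths, mode, method) before
any stage runs, then executes scan → {ribo-seq quantification, folding} plus
the independent reporter and conservation stages, writing one TSV per stage,
a combined per-site report and a `summary.json`. A failing stage halts its
dependents, independent stages still complete, and the failure is recorded.
Intermediates are plain files and every stage can be re-run from them; given
the same config and seed, outputs are byte-identical. Stage caching keyed on
input hashes was considered and dropped: at this scale re-running a stage is
cheaper than correct cache invalidation, and plain-file intermediates
already give inspectability.

## Verification at a glance

The test suite checks each operation against an independent oracle
(exhaustive window matching for the scan, brute-force hairpin enumeration,
position-map back-translation, all-pairs rank comparison) and each estimator
against simulated ground truth: mean ribo-seq recovery within 2 percentage
points at θ ∈ {0.03, 0.10, 0.15, 0.40, 0.60} (100 profiles of 10⁵ reads
each), reporter recovery within 5% relative at θ = 0.4 (200 assays of 8
wells), null scan false-positive fraction within [0.02, 0.08] and
constrained-window localisation within ±3 codons in ≥ 90% of runs (200
alignments of 20 rows × 200 codons each way). These problem sizes are the
package's reference conditions and are what `scripts/acceptance.R`
recomputes. The same caveat applies throughout: the simulators are the
conditions under which correctness is proven; real libraries and real
phylogenies add structure the generators deliberately omit.

## Known limitations

- −1 frameshifting, stop-codon readthrough and non-heptamer shift sites are
  out of scope, as is homology search for new loci.
- The hairpin model is single-helix with ordinal scores; multi-branch
  structures, pseudoknots and true thermodynamics are not modelled.
- The conservation null is pairwise-to-reference and phylogeny-free.
- Reporter analysis starts from tidy replicate tables; plate-reader file
  dialects are not parsed.
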
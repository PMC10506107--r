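---
title: "Detecting and quantifying termination codon readthrough with tcrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying termination codon readthrough with tcrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrkit)
```

## The biological question

Termination codon readthrough (TCR) occurs when a translating ribosome
decodes a stop codon as a sense codon and continues in the same reading
frame until the next in-frame stop. The protein gains a C-terminal
extension encoded by the *inter-stop-codon region* (ISR), the stretch of
3'UTR between the canonical stop ("stop 1") and the first downstream
in-frame stop ("stop 2"). Readthrough isoforms can differ functionally
from the canonical protein — the motivating case is neuronatin (NNAT),
whose readthrough isoform carries an 89-amino-acid extension and loses
the canonical protein's calcium-signalling activity.

Three independent lines of computational evidence support TCR on a
transcript, and `tcrkit` implements all three:

1. **Sequence**: an ISR exists (a downstream in-frame stop within the
   3'UTR) and the peptide it encodes is conserved across species —
   random 3'UTR sequence is not.
2. **Ribosome occupancy**: ribosome-profiling footprints, which mark
   actively translated regions, are denser over the ISR than over the
   3'UTR distal to stop 2.
3. **Reporter assay**: a dual-luciferase construct carrying the stop
   codon and ISR between *RLUC* and *FLUC* produces firefly luciferase
   at a measurable fraction of a no-stop control.

## ISR discovery and the extension peptide

`find_downstream_inframe_stop()` scans codon triplets starting
immediately 3' of the canonical stop, in the CDS frame only, and takes
the first triplet in {TAA, TAG, TGA} as stop 2. Only the CDS frame is
scanned: out-of-frame reporter controls show background luminescence
only, so out-of-frame extension is not modelled. All internal
coordinates are 0-based and half-open; printed reports are 1-based and
closed, with the conversion isolated at the report boundary.

The ISR length is a multiple of 3 by construction and the extension
peptide is its standard-genetic-code translation, stop-free by
definition of the scan. A 267-nt ISR (the human neuronatin case) gives
an 89-aa extension; with canonical isoforms of 81 and 54 aa the
readthrough products are 170 and 143 aa:

```{r isr}
tx <- make_transcript(synthetic_spec(seed = 267, isr_len = 267))
tx$annotation
extended_isoform_length(c(81, 54), tx$annotation$extension_len_aa)
```

One documented discrepancy is worth knowing about: the mouse ISR is
276 nt (92 codons), yet the published isoform arithmetic adds 89 aa to
both mouse isoforms. `extended_isoform_length()` implements the
arithmetic as printed and takes the extension length as an argument; it
does not attempt to resolve the tension.

### Conservation scoring

`score_conservation()` reduces a panel of orthologous extension
peptides to per-column identity: the fraction of non-gap residues
matching the column's majority residue (ties broken alphabetically),
with a conserved-column mask at threshold `tau` (default 0.8 — the
original alignment figure shades "conserved residues" without a stated
cutoff, so the threshold is a tunable display convention, not an
inference).

Unaligned peptides are stacked into a pseudo-alignment by global
pairwise alignment of every sequence against the first, with identity
scoring (match +1, mismatch 0, gap −1) and insertions relative to the
reference dropped. No alignment method was specified for the original
figure; this scheme is chosen because it is fully specified and
reproducible. It makes the profile depend on which sequence is the
reference — column statistics are order-invariant only for pre-aligned
input (`prealigned = TRUE`), which is how the permutation-invariance
property is tested. Phylogeny-aware conservation scores are out of
scope.

## Footprint region densities

The ribosome-profiling analysis is deliberately minimal and mirrors a
single-transcript workflow: no genome alignment, no spliced mapping.

* **Trimming** (`trim_adapter()`): exact-match 3'-adapter removal — the
  read is cut at the leftmost position where an adapter prefix of at
  least `min_overlap` nt matches exactly and runs to the read's 3' end.
  Pre-trimmed FASTQ is the documented default input.
* **Filtering** (`filter_reads()`): reads shorter than 24 nt are
  dropped (inclusive boundary: 24 is kept), as are reads containing
  `N`, which can never satisfy the exact-match rule.
* **Mapping** (`map_reads()`): 100% exact substring match on the sense
  strand. Exactly one occurrence places the read; none is `unmapped`;
  two or more is `ambiguous` and excluded from densities but counted.
  Footprints derive from the mRNA sense strand, so sense-only matching
  is the default (`strand = "both"` adds a reverse-complement search).
* **Region assignment** (`build_region_scheme()`, `assign_region()`):
  the transcript is partitioned into 5'UTR, CDS body, *ISR window*, and
  distal 3'UTR. The ISR window runs from 12 nt upstream of the first
  nucleotide of stop 1 to 22 nt upstream of stop 2. A read belongs to
  the region containing its 5'-end position: the −12 nt offset is the
  canonical distance from a footprint's 5' end to the ribosomal P-site,
  so the window acts as a P-site proxy for ribosomes decoding the ISR.
  A majority-overlap rule is available behind `rule = "overlap"`. Both
  offsets are configuration values, not constants, so sensitivity to
  them can be tested directly; whether the "12 nt upstream" should be
  measured from the first or the last nucleotide of the stop codon is
  ambiguous in prose, and the configurable offsets expose both
  readings.
* **Densities** (`compute_densities()`): reads per nucleotide — region
  count divided by region length. Every run satisfies the accounting
  identity `assigned + unmapped + ambiguous + filtered = total`.
* **Comparison** (`compare_isr_vs_utr()`): across libraries, a
  two-sided t-test with Welch's correction between the per-library ISR
  and distal-3'UTR densities, plus per-library density ratios.
  Libraries are treated as independent samples (public datasets from
  different studies); a paired variant exists behind `paired = TRUE`.

A degenerate ISR window (ISR too short for the offsets) is rejected
with an error stating the minimum ISR length, rather than silently
producing an empty region.

## Reporter quantification

Readthrough efficiency from the dual-luciferase assay is

$$\%\,\mathrm{TCR} = 100 \cdot
  \frac{\overline{(F/R)}_{\text{with-stop}}}
       {\overline{(F/R)}_{\text{no-stop}}}$$

computed exactly in this order: per-replicate FLuc/RLuc ratios are
averaged *within* each construct, then the two means are divided
(mean-of-ratios; the published worked examples are reproducible only
under this reading). The estimate is scale-invariant under any common
rescaling of the luminescence readings, and the no-stop construct
scores 100% against itself by construction. No background subtraction
is applied by default; a background construct label can be supplied to
subtract its mean ratio from both constructs.

Display truncates percent values at one decimal rather than rounding:
the three published efficiencies (11.1%, 7.2%, 16.5%) follow from their
printed construct means only under truncation — 0.0273/0.3748 is
7.28%, reported as 7.2%. The unrounded value is always kept on the
estimate object.

```{r tcr}
percent_tcr(0.0705, 0.6347)
percent_tcr(0.0273, 0.3748)
```

Helpers round out the quantification toolkit: `welch_ttest()`
(two-sided; unpaired Welch by default, paired and pooled-variance
variants selectable — identical zero-variance groups return t = 0,
p = 1 rather than erroring), `ddct_fold_change()` for qPCR relative
expression (2^−ΔΔCt), and `densitometry_normalize()` for Western-blot
band intensities relative to a loading control. Multiple-testing
correction is deliberately not applied: comparisons are reported
per-test, as in the source assays.

## The synthetic-data model

All validation runs on generated data with known truth
(`synthetic_spec()` holds every parameter and the seed; generators are
bit-reproducible under it).

* **Transcripts** (`make_transcript()`): 5'UTR, CDS drawn from the 61
  sense codons and ended by a canonical stop (TGA by default, the stop
  most permissive to readthrough), an ISR of sense codons, a planted
  stop 2, and a distal 3'UTR. Because CDS and ISR contain no in-frame
  stop by construction, the planted stop is provably the first one the
  scan can find. Defaults emulate the neuronatin geometry: 90-nt 5'UTR,
  246-nt CDS (81 aa + stop), 267-nt ISR, 300-nt distal 3'UTR.
* **Footprints** (`simulate_footprints()`): 5'-end positions are drawn
  per-nucleotide from a piecewise-constant Poisson intensity — `d` on
  the CDS body (default 0.05 reads/nt), `b + r·d` on the ISR window,
  `b` elsewhere (default background 5e-4, readthrough fraction 0.1) —
  scaled so the library has 50,000 expected reads by default. Lengths
  are uniform on 24–34 nt and sequences are copied exactly from the
  transcript, so clean reads map at 100% identity by construction.
  5'-end placement (not fragment midpoint) is the generative primitive,
  mirroring the assignment rule, so recovery is well-posed: the plug-in
  estimator `r̂ = (ISR density − 3'UTR density) / CDS density` is
  unbiased up to sampling noise. Optional mismatch and adapter
  contamination support negative tests. Not modelled: rRNA
  contamination, UMIs, ligation bias — passing recovery tests show the
  pipeline arithmetic is correct, not that real libraries are this
  clean.
* **Region counts** (`simulate_region_counts()`): Poisson counts drawn
  per region from `intensity × region length`. Region counts are sums
  of independent per-nucleotide Poisson counts, so this is the exact
  count-level marginal of the intensity model; it is also free of the
  read-placement edge effect (a read must fit on the transcript, so
  read-level libraries slightly under-cover the last ~23 nt of the
  distal 3'UTR). Calibration studies over hundreds of replicate panels
  use this sampler.
* **Luciferase** (`simulate_luciferase()`): no-stop ratios log-normal
  around 0.63 (cosmetically near the published no-stop mean of 0.6347),
  with-stop ratios log-normal around `0.63 · π`, multiplicative noise
  σ = 0.2 on the log scale, 6 replicates; RLuc is drawn per replicate
  and FLuc reconstructed as ratio × RLuc.
* **Ortholog panels** (`simulate_ortholog_peptides()`): i.i.d.
  per-column substitution (default probability 0.1 across 8 species) to
  a uniformly chosen different residue, with the mutated columns
  recorded as truth.

## Problem sizes and numerical choices

Validation uses the study-scale conditions throughout: 15-library
panels for the density comparison, 50,000-read libraries and 10 seeds
per readthrough fraction for recovery, 200 replicate panels for null
calibration (count-level), and 200 seeds for luciferase recovery. On a
single CPU the full test suite runs in about a minute and the
acceptance script in under a minute.

Degenerate and edge cases are handled explicitly rather than left to
underflow: adjacent stop codons give a zero-length ISR and an empty
peptide (valid, not an error); a transcript with no downstream in-frame
stop is flagged, not errored; empty footprint input yields zero counts
and zero densities; identical groups in the Welch test give t = 0,
p = 1; ties in conservation majorities break alphabetically. Stop-2
codon identity is reported verbatim but no codon-specific readthrough
efficiency model is implemented (selenocysteine and near-cognate
decoding are out of scope).

## Pipeline and reproducibility

`run_config()` validates a configuration (YAML or list) against the
analysis defaults — 24-nt minimum read length, offsets (12, 22),
τ = 0.8 — reporting offending fields before anything runs.
`run_pipeline()` executes the requested stages in order and writes a
manifest with the config hash, package version, input checksums, and
per-stage read accounting; manifests contain no timestamps, so an
identical configuration reproduces byte-identical outputs. A thin
command-line wrapper (`inst/scripts/tcr-kit.R`) exposes the same
functions as `scan-isr`, `ribo-density`, `ribo-compare`,
`reporter-tcr`, and `simulate` subcommands.

## Known limitations

* Transcript coordinates only: no exon-aware (genomic) scanning.
* Single-transcript exact matching: no external aligners, no multi-gene
  quantification; multi-mapping reads are counted but discarded from
  densities.
* The conservation profile is reference-anchored, not a true MSA, and
  carries no phylogenetic weighting.
* The synthetic luciferase model has purely multiplicative noise;
  plate-position or batch effects are not emulated.
* P-site offsets are taken as given, not calibrated from start-codon
  metagene profiles.
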
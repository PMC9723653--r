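---
title: "Untargeted DIA metaproteomics with metadia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted DIA metaproteomics with metadia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadia)
```

# The problem

Data-independent acquisition (DIA) mass spectrometry fragments *all*
precursor ions in fixed m/z isolation windows every cycle. This removes the
stochastic precursor sampling of data-dependent acquisition (DDA) — the main
cause of poor run-to-run reproducibility in metaproteomics — but produces
chimeric MS2 spectra in which fragments from many co-eluting peptides are
mixed. In complex microbial communities co-elution is the rule, so
conventional spectrum-centric database search cannot be applied directly.

`metadia` implements a library-free workflow: the DIA data themselves are
deconvolved into DDA-like **pseudospectra**, those pseudospectra are
identified by a conventional database search with target-decoy FDR control,
the identified spectra form a **pseudospectral library**, and that library
drives targeted fragment-level quantification of every run. Peptides are
finally annotated taxonomically and functionally by a peptide-centric
consensus over their possible source proteins, with no protein inference.

# Deconvolution model

A DIA run is modelled as interleaved cycles: one MS1 survey scan (375–1500
m/z) followed by one MS2 scan per isolation window (default 40 consecutive
15 m/z windows covering 400–1000 m/z; windows are half-open `[lower,
upper)` so a precursor at a boundary belongs to exactly one window).

Deconvolution proceeds in four steps:

1. **Two-dimensional ion-trace detection.** Within the MS1 map and within
   each window's MS2 map, peaks in consecutive scans are greedily linked
   into chromatographic traces when they fall within `trace_mz_tolerance`
   (10 ppm) of the running intensity-weighted trace m/z. Assignment is
   deterministic: nearest m/z wins, ties go to the lower-m/z peak. Traces
   tolerate `max_gap` (1) missing scans, and must span at least
   `min_trace_length` (4) scans.
2. **MS1 de-isotoping and charge estimation.** A trace sitting one isotope
   spacing (1.00335/z Da, z = 1–4) above a stronger co-apexing trace is the
   M+1 satellite of that trace's envelope and is removed; without this step
   every precursor would yield a duplicate pseudospectrum from its own
   isotope peak. Charge is then read from the apex MS1 scan as the z whose
   isotope companion is most intense, falling back to 2+ (the dominant
   tryptic charge state) when no companion exists.
3. **Precursor–fragment grouping.** Candidate fragments for a precursor are
   the MS2 traces of the window containing the precursor m/z whose apex
   lies within `apex_rt_tolerance` (1.5 cycles) and whose elution profile
   has Pearson correlation at least `corr_min` (0.8) with the precursor
   profile, both profiles resampled onto the shared cycle grid with missing
   cycles as zeros. A fragment trace may join several groups: co-eluting
   precursors legitimately share signal.
4. **Complementary-ion flagging and assembly.** Fragment pairs (assumed
   singly charged) summing to the precursor neutral mass plus two proton
   masses within 0.02 Da are flagged as likely b/y complements. The flag is
   annotation only — pseudospectra are filtered by the downstream search,
   not by ion content. Groups with at least `min_fragments` (3) fragments
   become pseudospectra, ordered deterministically by RT then m/z.

Published descriptions of this deconvolution family do not state the
correlation or apex thresholds; the defaults above mirror common practice
and every one is exposed in the configuration.

# Database search and FDR

The search is a single built-in engine (the original workflow ran two
external engines and combined them; the union step is out of scope here and
one well-tested scorer exercises the same contract):

* **Digestion**: trypsin (cleave after K/R except before P), up to 2 missed
  cleavages, peptide length 7–50, peptides containing X excluded.
* **Masses**: monoisotopic residue masses; carbamidomethyl-C (+57.02146 Da)
  fixed, reflecting iodoacetamide alkylation; at most one oxidized
  methionine (+15.99491 Da) as a variable modification.
* **Matching**: parent tolerance 10 ppm on the neutral mass, fragment
  tolerance 0.02 Da. Theoretical b/y ladders are singly charged, plus
  doubly charged for precursors at 3+ and above.
* **Score**: a hyperscore-style function, ln[(Σ matched intensity) ·
  min(N~b~, 20)! · min(N~y~, 20)!] with observed intensities normalized to
  a base peak of 100. It is deterministic, closed-form and hand-verifiable;
  an unmatched peak can only lower it (through renormalization), never
  raise it.
* **FDR**: reversed-sequence decoys (one per target; reversal rather than
  shuffling keeps the decoy space RNG-free and reproducible). With the best
  match per pseudospectrum, the estimator at score cutoff s is
  (#decoys ≥ s + 1) / max(#targets ≥ s, 1); q-values are the running
  minimum of this estimate from low to high score, and targets with
  q ≤ 0.01 are accepted. The +1 makes the estimator conservative: with
  fewer than 100 spectra nothing can reach 1%, which is the correct
  behaviour for so little evidence.

# Library and quantification

Accepted matches are grouped by (peptide, charge); the best-scoring
supporting pseudospectrum contributes up to 6 fragments (the matched
theoretical ions only, top-N by intensity, minimum 3), with intensities
normalized to a maximum of 1. Charge states are kept as separate assays and
aggregated only at quantification. The stored precursor m/z is the
theoretical value, which stabilises extraction windows. Reference RT is the
raw run RT — the design assumes a single gradient, and cross-run shifts are
handled by alignment rather than iRT normalization.

Quantification extracts, per library entry, a chromatogram per fragment
(±0.02 Da, within `rt_half_window` = 150 s of the aligned reference RT,
from the single window containing the precursor). Candidate peaks are local
maxima of the lightly smoothed summed chromatogram, with maxima below 5% of
the base peak discarded. Candidates are ranked by a composite of three
sub-scores: mean pairwise Pearson correlation of the fragment chromatograms
over the peak span (co-elution), correlation of the candidate fragment
areas with the library relative intensities (an interfering peptide can
co-elute perfectly but rarely reproduces the library intensity pattern),
and a penalty of 0.5·|Δrt|/`rt_half_window` on distance from the library
RT. Peak bounds descend monotonically to the nearest valley or to 5% of the
apex; areas are trapezoidal; a peptide's quantity is the summed fragment
area of its best peak group, summed over charge states.

Cross-run RT alignment is a deliberate simplification of graph-based
feature alignment: anchor peptides are entries confidently found in every
run (co-elution score ≥ 0.9), and each run's shift is the median of
(apex − reference) over anchors, with a zero-shift fallback (and a warning)
below 3 anchors. Replicate correlations are computed on log10(area + 1) —
the log scale is the field's convention for spanning the dynamic range, and
the +1 keeps zero areas finite.

# Peptide-centric annotation

Each peptide is assigned to all its possible source proteins (targets
only). At each rank (phylum, genus, KEGG functional category,
independently): if the annotated sources agree the peptide takes that
label; unannotated sources are ignored because they cannot conflict; if no
source is annotated the peptide is `unknown`; if two or more labels occur
it is `ambiguous`. Profiles report label percentages over all peptides;
named labels holding strictly less than 0.5% of the total are merged into
`other` (exactly 0.5% is retained — the boundary follows the "less than"
wording the thresholds derive from), while `ambiguous` and `unknown` are
always reported as their own categories. The ranks are fixed rather than
resolved by lowest common ancestor: fixed ranks keep taxonomic and
functional annotation symmetric, and functional categories have no tree for
LCA anyway.

# The simulator: what it emulates, and what it does not

The ground-truth generator exists so that every stage is testable offline.
It emulates: a multi-taxon community (default 12 gut genera) whose proteins
are concatenations of tryptic peptides; a configurable fraction of peptides
shared across genera (to exercise ambiguous annotation); log-normal
peptide abundances (meanlog log(2·10⁴), sdlog 1.0 — two to three decades of
dynamic range) with a per-peptide log-normal fragment response; Gaussian
elution (σ = 6 s) over a desk-scale gradient (600 s default, 3 s cycles);
MS1 isotope pairs (monoisotopic + M+1 at half intensity, enough for charge
estimation and deliberately nothing more); per-peak fragment dropout
(5%); and Poisson-rate uniform-m/z noise peaks (20 per scan, log-normal
intensities). Planted peptides are constrained to 2+/3+ precursors inside
the DIA range, and a peptide's ladder fragments are kept at least 0.05 Da
apart so that in the idealized no-noise layout every planted fragment is a
resolvable trace — the exact-recovery checks assume a world where signals
are separable, which is what "non-co-eluting, noise-free" means.

It does **not** emulate: retention-time prediction, isotope fine structure,
fragment ions beyond singly charged b/y, chimeric fragment interference
beyond genuine co-elution, ionization physics, or missing-value structure
beyond dropout. A green simulator-based test therefore establishes that the
algorithms are implemented correctly under the stated model — not that the
pipeline reproduces any particular instrument's behaviour.

# Numerical choices and degenerate inputs

* m/z is Thomson, RT is seconds internally (mzML minutes converted on
  read); mass constants are fixed at 5 decimals (proton 1.007276, water
  18.010565, isotope spacing 1.00335).
* Pearson correlations are undefined (NA) for constant profiles or fewer
  than 3 shared cycles; undefined correlations never satisfy a threshold.
* Empty inputs return empty outputs everywhere (empty pseudospectrum list,
  empty library, empty quantity matrix); contract violations (an MS2
  spectrum without an isolation window, profile-mode data, a peptide with
  no source proteins) raise explicit errors instead.
* Ties are always broken deterministically (lower m/z, lexicographic
  peptide, target before decoy), so identical inputs give byte-identical
  artifacts; the pipeline log is the only timestamped output.
* Seeds are mandatory for every stochastic component; RNG state is saved
  and restored around simulator calls.

# Known limitations

Single search engine (no two-engine union); no semi-tryptic search; no
peak-group q-values (the composite score ranks candidates but is not
calibrated); alignment is a single global shift per run, not a warped RT
map; the mzML layer covers the subset of mzML 1.1 this pipeline writes
(centroided spectra, isolation windows, uncompressed 64-bit arrays) and
rejects rather than converts profile data; quantification aggregates
fragment areas by summation, so entries whose library fragments differ
across builds quantify on different evidence.
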